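test_that("noiseless batch simulation reproduces planted ratios exactly", {
  # the full planted set, including a published-style ratio row
  targets <- list(
    list(p_per_hac = 0.5, gly_per_hac = 0.5, phb_per_hac = 1.0, phv_per_hac = 0.2,
         p_per_pha = 0.41, gly_per_pha = 0.42),
    list(p_per_hac = 0.94, gly_per_hac = 0.44, phb_per_hac = 0.90, phv_per_hac = 0.19,
         p_per_pha = 1.04, gly_per_pha = 0.47)
  )
  for (tr in targets) {
    ts <- sim_batch_timeseries(batch_sim_spec(target_ratios = tr, noise_sd = 0,
                                              initial_glycogen = 3,
                                              initial_phosphate = 0.5))
    ana <- anaerobic_ratios(ts)
    expect_equal(ana$p_per_hac, tr$p_per_hac, tolerance = 1e-10)
    expect_equal(ana$gly_per_hac, tr$gly_per_hac, tolerance = 1e-10)
    expect_equal(ana$phb_per_hac, tr$phb_per_hac, tolerance = 1e-10)
    expect_equal(ana$phv_per_hac, tr$phv_per_hac, tolerance = 1e-10)
    expect_equal(ana$pha_per_hac, tr$phb_per_hac + tr$phv_per_hac, tolerance = 1e-10)
    aer <- aerobic_ratios(ts)
    expect_equal(aer$p_per_pha, tr$p_per_pha, tolerance = 1e-10)
    expect_equal(aer$gly_per_pha, tr$gly_per_pha, tolerance = 1e-10)
  }
})

test_that("batch generator is deterministic given its seed and flags infeasible specs", {
  a <- sim_batch_timeseries(batch_sim_spec(noise_sd = 0.05, rng_seed = 42))
  b <- sim_batch_timeseries(batch_sim_spec(noise_sd = 0.05, rng_seed = 42))
  expect_identical(a, b)
  d <- sim_batch_timeseries(batch_sim_spec(noise_sd = 0.05, rng_seed = 43))
  expect_false(identical(a, d))

  # glycogen demand beyond the initial pool cannot be simulated
  expect_error(sim_batch_timeseries(batch_sim_spec(
    target_ratios = list(p_per_hac = 0.5, gly_per_hac = 10, phb_per_hac = 1,
                         phv_per_hac = 0, p_per_pha = 0.4, gly_per_pha = 0.4),
    noise_sd = 0)), "infeasible")
})

test_that("noisy batch simulation recovers planted P/HAc without bias", {
  target <- 0.5
  est <- vapply(1:100, function(s) {
    ts <- sim_batch_timeseries(batch_sim_spec(
      target_ratios = list(p_per_hac = target, gly_per_hac = 0.5, phb_per_hac = 1.0,
                           phv_per_hac = 0.2, p_per_pha = 0.4, gly_per_pha = 0.4),
      noise_sd = 0.02, rng_seed = s))
    anaerobic_ratios(ts)$p_per_hac
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 3 * se + 1e-12)
})

test_that("OTU count generator plants exact depths and recoverable step factors", {
  spec <- otu_sim_spec(n_otus = 80, depth = 1e5, step_factor = c(2, rep(1, 79)),
                       log_noise_sd = 0.05, rng_seed = 5)
  tab <- sim_otu_counts(spec)
  m <- otu_counts(tab)
  expect_true(all(colSums(m) == 1e5))
  expect_identical(dim(m), c(80L, 10L))

  # planted factor-2 OTU: epoch-mean relative abundance ratio ~ 2
  fc <- epoch_fold_change(tab, "OTU_0001", split = c(4, 6))
  expect_lt(abs(fc$fold_change - 2), 0.1 * 2)

  # determinism
  expect_identical(sim_otu_counts(spec), sim_otu_counts(spec))
})

test_that("AR(1) option induces positive lag-1 autocorrelation of log abundances", {
  acf1 <- function(rho, seed) {
    tab <- sim_otu_counts(otu_sim_spec(n_otus = 150, depth = 5e4, ar1_rho = rho,
                                       log_noise_sd = 0.4, rng_seed = seed))
    lm10 <- log_normalize(tab)
    mean(apply(lm10, 1, function(x) {
      x <- x - mean(x)
      sum(x[-1] * x[-length(x)]) / sum(x^2)
    }))
  }
  expect_gt(acf1(0.9, 1), acf1(0, 1) + 0.2)
  expect_gt(acf1(0.9, 2), 0.2)
})

test_that("read generator plants probe sites at the requested rates", {
  probes <- as_probe_set(data.frame(
    probe_id = c("UNIV", "PAO651"),
    sequence = c("GCTGCCTCCCGTAGGAGT", "CCCTCTGCCAAACTCCAG")), universal = "UNIV")

  # every read of a single carrier taxon carries the site
  reads <- sim_probe_reads(read_sim_spec(c(pao = 1), list(pao = "PAO651"), probes,
                                         n_reads = 100, universal_fraction = 0,
                                         rng_seed = 3))
  hits <- count_probe_hits(reads, probes)
  expect_equal(hits$raw_hits[hits$probe == "PAO651"], 100)

  # 5% carrier abundance at n = 1e4: binomial recovery
  n <- 1e4
  reads2 <- sim_probe_reads(read_sim_spec(c(pao = 0.05, rest = 0.95),
                                          list(pao = "PAO651"), probes,
                                          n_reads = n, universal_fraction = 1,
                                          rng_seed = 9))
  res <- efish(reads2, probes)
  pao <- res[res$probe == "PAO651", ]
  sigma <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(pao$normalized - 0.05), 3 * sigma + 5e-3)

  # probe longer than the read is infeasible
  expect_error(read_sim_spec(c(a = 1), list(a = "PAO651"), probes, read_length = 10),
               "infeasible")
})

test_that("strand randomisation hides about half the hits from forward-only matching", {
  probes <- as_probe_set(data.frame(probe_id = c("U", "P"),
                                    sequence = c("ACGTACGTACGTACGTAC", "GGATTCAGCTAGGACCTA")),
                         universal = "U")
  reads <- sim_probe_reads(read_sim_spec(c(t1 = 1), list(t1 = "P"), probes,
                                         n_reads = 2000, universal_fraction = 0,
                                         randomize_strand = TRUE, rng_seed = 21))
  fwd_only <- vapply(reads$sequence, function(s) {
    Biostrings::countPattern("GGATTCAGCTAGGACCTA", Biostrings::DNAString(s)) > 0
  }, logical(1))
  frac <- mean(fwd_only)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
  # strand-aware matching still finds all of them
  expect_equal(count_probe_hits(reads, probes)$raw_hits[2], 2000)
})
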