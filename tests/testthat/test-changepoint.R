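test_that("rarefaction preserves column sums exactly and never exceeds originals", {
  tab <- sim_otu_counts(otu_sim_spec(n_otus = 40, depth = 3000, rng_seed = 2))
  r <- rarefy_counts(tab, 1000, seed = 7)
  m0 <- otu_counts(tab); m1 <- otu_counts(r)
  expect_true(all(colSums(m1) == 1000))
  expect_true(all(m1 <= m0))

  # drawing the full depth returns the table unchanged
  full <- rarefy_counts(tab, 3000, seed = 7)
  expect_identical(otu_counts(full), m0)

  # depth 0 zeroes everything; over-depth errors and names the sample
  expect_true(all(otu_counts(rarefy_counts(tab, 0)) == 0))
  expect_error(rarefy_counts(tab, 4000), "exceeds")

  # single-draw determinism under the recorded seed
  expect_identical(rarefy_counts(tab, 1000, seed = 7), r)
})

test_that("rarefaction is hypergeometric in expectation", {
  tab <- sim_otu_counts(otu_sim_spec(n_otus = 10, depth = 2000, rng_seed = 3))
  m <- otu_counts(tab)
  otu <- which.max(m[, 1])
  draws <- vapply(1:2000, function(s) otu_counts(rarefy_counts(tab, 1000, seed = s))[otu, 1],
                  numeric(1))
  expected <- m[otu, 1] / 2
  # hypergeometric s.e. of the mean over replicates
  n <- 1000; N <- 2000; K <- m[otu, 1]
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  expect_lt(abs(mean(draws) - expected), 3 * sqrt(v / length(draws)))
})

test_that("log normalisation is elementwise log10(x + 1)", {
  m <- matrix(c(0, 9, 999, 3), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  lm10 <- log_normalize(m)
  expect_identical(dim(lm10), dim(m))
  expect_equal(lm10, log10(m + 1))
  expect_equal(lm10[1, 1], 0)
  expect_equal(lm10[2, 1], 1)
  expect_equal(lm10[1, 2], 3)
})

test_that("step-change statistic matches its hand-computed value and edge cases", {
  r <- step_change_test(c(1, 2, 1, 2, 3, 4, 3, 4, 3, 4), c(4, 6))
  expect_equal(r$difference, 2)
  expect_equal(r$f_statistic, 30.72)
  expect_equal(r$p_raw, pf(30.72, 1, 8, lower.tail = FALSE))
  expect_lt(abs(r$p_raw - 5.4e-4), 5e-5)

  const <- step_change_test(rep(2, 10), c(4, 6))
  expect_equal(const$difference, 0)
  expect_equal(const$f_statistic, 0)
  expect_equal(const$p_raw, 1)

  degen <- step_change_test(rep(c(0, 1), c(4, 6)), c(4, 6))
  expect_equal(degen$flag, "degenerate")
  expect_lt(degen$p_raw, 1e-300)

  expect_error(step_change_test(1:9, c(4, 6)), "length")
  expect_error(step_change_test(1:5, c(1, 4)), ">= 2")
})

test_that("step-change statistic equals the one-way ANOVA oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    y <- rnorm(n1 + n2)
    g <- factor(rep(1:2, c(n1, n2)))
    ora <- summary(aov(y ~ g))[[1]]
    r <- step_change_test(y, c(n1, n2))
    expect_equal(r$f_statistic, ora[["F value"]][1], tolerance = 1e-10)
    expect_equal(r$p_raw, ora[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("step-change statistic is invariant under affine transforms", {
  set.seed(77)
  for (i in 1:50) {
    y <- rnorm(10)
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    r0 <- step_change_test(y, c(4, 6))
    r1 <- step_change_test(a * y + b, c(4, 6))
    expect_equal(r1$f_statistic, r0$f_statistic, tolerance = 1e-9)
    expect_equal(r1$p_raw, r0$p_raw, tolerance = 1e-9)
    expect_equal(r1$difference, a * r0$difference, tolerance = 1e-9)
  }
})

test_that("q-values: BH equivalence at pi0 = 1, monotonicity, and sane pi0", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(storey_qvalues(p, pi0 = 1)$q, rep(0.04, 4))
  # matches p.adjust("BH") on random vectors when pi0 is forced to 1
  set.seed(5)
  for (i in 1:20) {
    pr <- runif(50, 1e-6, 1)
    expect_equal(storey_qvalues(pr, pi0 = 1)$q, p.adjust(pr, "BH"), tolerance = 1e-12)
  }
  # q never smaller than the pi0-scaled BH value; monotone along sorted p
  pr <- runif(500)
  qv <- storey_qvalues(pr)
  expect_true(all(qv$q >= qv$pi0 * p.adjust(pr, "BH") - 1e-12))
  expect_true(all(diff(qv$q[order(pr)]) >= -1e-12))

  expect_equal(storey_qvalues(1)$q, 1)
  expect_equal(storey_qvalues(1)$pi0, 1)
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 0)), "0, 1")
})

test_that("pi0 estimator approaches 1 on uniform nulls", {
  set.seed(11)
  p <- runif(1e4)
  expect_lt(abs(storey_qvalues(p)$pi0 - 1), 0.1)
})

test_that("taxon aggregation sums member OTUs and ignores unclassified ranks", {
  counts <- matrix(c(174, 87, 65, 9674,
                     174, 87, 65, 9674), ncol = 2,
                   dimnames = list(NULL, c("2013-05-29", "2013-06-05")))
  df <- tibble::tibble(
    otu_id = c("acc1", "acc2", "acc3", "other"),
    `2013-05-29` = counts[, 1], `2013-06-05` = counts[, 2],
    taxonomy = c(rep("k__Bacteria; p__Proteobacteria; g__Candidatus Accumulibacter; s__", 3),
                 "k__Bacteria; p__; g__; s__"))
  tab <- as_otu_table(df)
  res <- taxon_relative_abundance(tab, "g__Candidatus Accumulibacter")
  expect_equal(res$n_otus, 3)
  # 1.74% + 0.87% + 0.65% = 3.26% collectively
  expect_equal(res$overall, (174 + 87 + 65) / 10000, tolerance = 1e-12)
  expect_equal(res$per_sample$fraction, rep(0.0326, 2), tolerance = 1e-12)

  # unclassified g__ never matches a named query; match-all gives 100%
  none <- taxon_relative_abundance(tab, "g__")
  expect_equal(none$n_otus, 0)
  expect_equal(none$overall, 0)
  all_k <- taxon_relative_abundance(tab, "k__Bacteria")
  expect_equal(all_k$overall, 1)

  # single-OTU taxon equals that OTU's own fraction
  single <- tibble::tibble(otu_id = c("a", "b"), `2013-05-29` = c(30L, 70L),
                           taxonomy = c("k__Bacteria; g__Foo; s__", "k__Bacteria; g__Bar; s__"))
  res1 <- taxon_relative_abundance(as_otu_table(single), "g__Foo")
  expect_equal(res1$overall, 0.3)
})

test_that("table-level screen filters to ubiquitous OTUs and orders by q", {
  spec <- otu_sim_spec(n_otus = 200, depth = 2e4,
                       step_factor = c(rep(4, 10), rep(1, 190)),
                       log_noise_sd = 0.15, rng_seed = 13)
  tab <- sim_otu_counts(spec)
  res <- test_step_changes(tab, split = c(4, 6))
  m <- otu_counts(tab)
  expect_equal(nrow(res), sum(rowSums(m > 0) == 10))
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(!is.null(attr(res, "pi0")))

  # the planted changers dominate the top of the list, with positive difference
  top10 <- res$otu_id[1:10]
  expect_gt(mean(top10 %in% sprintf("OTU_%04d", 1:10)), 0.8)
  expect_true(all(res$difference[res$otu_id %in% sprintf("OTU_%04d", 1:10)] > 0))
})

test_that("epoch fold changes report direction and handle zero baselines", {
  # column sums equal in both epochs so relative = count/600
  counts <- rbind(up = rep(c(100L, 200L), c(4, 6)),
                  down = rep(c(300L, 100L), c(4, 6)),
                  filler = rep(c(100L, 200L), c(4, 6)),
                  flat = rep(100L, 10))
  df <- as.data.frame(counts)
  names(df) <- format(as.Date("2013-05-29") + 7 * 0:9)
  df <- cbind(otu_id = rownames(counts), df,
              taxonomy = "k__Bacteria; g__; s__")
  tab <- as_otu_table(df)
  up <- epoch_fold_change(tab, "up")
  expect_equal(up$direction, "increase")
  expect_equal(up$fold_change, 2)
  down <- epoch_fold_change(tab, "down")
  expect_equal(down$direction, "decrease")
  expect_equal(down$factor, 3)
  flat <- epoch_fold_change(tab, "flat")
  expect_equal(flat$direction, "none")
  expect_equal(flat$fold_change, 1)

  counts2 <- rbind(absent_then_present = rep(c(0L, 10L), c(4, 6)),
                   other = rep(100L, 10))
  df2 <- as.data.frame(counts2)
  names(df2) <- names(df)[2:11]
  df2 <- cbind(otu_id = rownames(counts2), df2, taxonomy = "k__Bacteria; g__; s__")
  zero <- epoch_fold_change(as_otu_table(df2), "absent_then_present")
  expect_equal(zero$flag, "undefined")
})

test_that("planted fold changes are recovered within tolerance", {
  # flat 1% baselines and sampling-only noise: the multinomial draw is the
  # only stochastic term, so the closure effect stays below the tolerance
  spec <- otu_sim_spec(n_otus = 100, depth = 1e5,
                       step_factor = c(2, 1/3, rep(1, 98)),
                       log_baseline_sd = 0, log_noise_sd = 0, rng_seed = 19)
  tab <- sim_otu_counts(spec)
  fc_up <- epoch_fold_change(tab, "OTU_0001")
  expect_lt(abs(fc_up$fold_change - 2) / 2, 0.05)
  fc_down <- epoch_fold_change(tab, "OTU_0002")
  expect_equal(fc_down$direction, "decrease")
  expect_lt(abs(fc_down$factor - 3) / 3, 0.08)
})

test_that("null rejection rate sits at the nominal level and rises with effect and rho", {
  rates <- simulate_error_rates(effect_grid = c(0, 10), rho_grid = c(0, 0.6),
                                reps = 2000, alpha = 0.05, rng_seed = 4)
  null_iid <- rates$rejection_rate[rates$effect == 0 & rates$rho == 0]
  expect_lt(abs(null_iid - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # separation limit: an enormous shift is always detected
  expect_equal(rates$rejection_rate[rates$effect == 10 & rates$rho == 0], 1)
  # positive autocorrelation can only inflate the null rejection rate
  null_ar <- rates$rejection_rate[rates$effect == 0 & rates$rho == 0.6]
  expect_gte(null_ar, null_iid - 0.02)
})
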