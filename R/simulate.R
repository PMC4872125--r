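#' Specification for a simulated batch-test cycle
#'
#' Defines the planted truth of one anaerobic/aerobic batch cycle: the
#' target transformation ratios, the initial acetate dose, the biomass
#' concentration and the measurement noise.  Within each phase the
#' analyte profiles are piecewise-linear in time; the transformation
#' ratios are determined by the phase endpoints, so the within-phase shape
#' does not affect them.
#'
#' @param target_ratios Named list/vector of planted ratios:
#'   `p_per_hac`, `gly_per_hac`, `phb_per_hac`, `phv_per_hac` (anaerobic,
#'   per C-mol acetate) and `p_per_pha`, `gly_per_pha` (aerobic, per C-mol
#'   PHA).  `pha_per_hac` is implied as `phb_per_hac + phv_per_hac`.
#' @param initial_acetate Acetate dose at the start of the anaerobic
#'   phase, C-mmol/L.
#' @param vss Biomass as volatile suspended solids, g/L.
#' @param n_per_phase Number of sampling points per phase (>= 2).
#' @param noise_sd Gaussian measurement noise, expressed as a fraction of
#'   each analyte's dynamic range; 0 gives noiseless profiles.
#' @param initial_glycogen,initial_phb,initial_phv Initial intracellular
#'   pools, C-mmol per g VSS.
#' @param initial_phosphate Initial orthophosphate, P-mmol/L.
#' @param phase_minutes Duration of each phase, minutes.
#' @param rng_seed Integer seed.
#' @return A list of class `batch_sim_spec`.
#' @export
batch_sim_spec <- function(target_ratios = list(p_per_hac = 0.89,
                                                gly_per_hac = 0.60,
                                                phb_per_hac = 0.83,
                                                phv_per_hac = 0.11,
                                                p_per_pha = 0.76,
                                                gly_per_pha = 0.61),
                           initial_acetate = 1.25,
                           vss = 2.5,
                           n_per_phase = 7L,
                           noise_sd = 0.02,
                           initial_glycogen = 2,
                           initial_phb = 0.2,
                           initial_phv = 0.05,
                           initial_phosphate = 0.1,
                           phase_minutes = 180,
                           rng_seed = 1L) {
  tr <- as.list(target_ratios)
  needed <- c("p_per_hac", "gly_per_hac", "phb_per_hac", "phv_per_hac",
              "p_per_pha", "gly_per_pha")
  miss <- setdiff(needed, names(tr))
  if (length(miss) > 0) stop_validation("target_ratios missing: %s", paste(miss, collapse = ", "))
  for (r in needed) check_number(tr[[r]], r, lower = 0)
  check_number(initial_acetate, "initial_acetate", lower = 1e-9)
  check_number(vss, "vss", lower = 1e-9)
  check_count(n_per_phase, "n_per_phase", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(target_ratios = tr, initial_acetate = initial_acetate,
                 vss = vss, n_per_phase = as.integer(n_per_phase),
                 noise_sd = noise_sd, initial_glycogen = initial_glycogen,
                 initial_phb = initial_phb, initial_phv = initial_phv,
                 initial_phosphate = initial_phosphate,
                 phase_minutes = phase_minutes, rng_seed = as.integer(rng_seed)),
            class = "batch_sim_spec")
}

#' Simulate one batch-test cycle with known planted stoichiometry
#'
#' Anaerobic phase: acetate is drawn down linearly to zero while
#' orthophosphate is released, PHB/PHV accumulate and glycogen is
#' consumed, all in proportion to the planted anaerobic ratios.  Aerobic
#' phase: the accumulated PHA is consumed again while phosphate is taken
#' up and glycogen replenished in proportion to the planted aerobic
#' ratios.  Gaussian noise is added to every measurement; with
#' `noise_sd = 0` the recomputed ratios equal the planted ones exactly.
#'
#' @param spec A [batch_sim_spec()].
#' @return An `ebpr_batch` tibble (see [read_batch_timeseries()]).
#' @export
#' @examples
#' ts <- sim_batch_timeseries(batch_sim_spec(noise_sd = 0))
#' anaerobic_ratios(ts)
sim_batch_timeseries <- function(spec) {
  stopifnot(inherits(spec, "batch_sim_spec"))
  tr <- spec$target_ratios
  n <- spec$n_per_phase
  # anaerobic deltas (per g VSS for intracellular pools, per L for liquid)
  d_hac_l <- spec$initial_acetate                       # C-mmol/L
  d_hac <- d_hac_l / spec$vss                           # C-mmol/gVSS
  d_p_l <- tr$p_per_hac * d_hac_l                       # P-mmol/L released
  d_phb <- tr$phb_per_hac * d_hac                       # C-mmol/gVSS
  d_phv <- tr$phv_per_hac * d_hac
  d_gly <- tr$gly_per_hac * d_hac
  if (d_gly > spec$initial_glycogen) {
    stop_validation("infeasible spec: glycogen demand %.3f exceeds initial pool %.3f C-mmol/gVSS",
                    d_gly, spec$initial_glycogen)
  }
  # aerobic: consume the accumulated PHA back down
  d_pha_aer <- d_phb + d_phv
  frac_b <- if (d_pha_aer > 0) d_phb / d_pha_aer else 0
  d_p_aer_l <- tr$p_per_pha * d_pha_aer * spec$vss      # P-mmol/L taken up
  if (d_p_aer_l > spec$initial_phosphate + d_p_l) {
    stop_validation("infeasible spec: aerobic P uptake would drive phosphate negative")
  }
  d_gly_aer <- tr$gly_per_pha * d_pha_aer

  ramp <- function(from, to, k) seq(from, to, length.out = k)
  t_ana <- seq(0, spec$phase_minutes, length.out = n)
  t_aer <- seq(spec$phase_minutes, 2 * spec$phase_minutes, length.out = n + 1)[-1]
  prof <- tibble(
    time_min = c(t_ana, t_aer),
    phase = c(rep("anaerobic", n), rep("aerobic", n)),
    acetate = c(ramp(spec$initial_acetate, 0, n), rep(0, n)),
    phosphate = c(ramp(spec$initial_phosphate, spec$initial_phosphate + d_p_l, n),
                  ramp(spec$initial_phosphate + d_p_l,
                       spec$initial_phosphate + d_p_l - d_p_aer_l, n + 1)[-1]),
    phb = c(ramp(spec$initial_phb, spec$initial_phb + d_phb, n),
            ramp(spec$initial_phb + d_phb,
                 spec$initial_phb + d_phb - frac_b * d_pha_aer, n + 1)[-1]),
    phv = c(ramp(spec$initial_phv, spec$initial_phv + d_phv, n),
            ramp(spec$initial_phv + d_phv,
                 spec$initial_phv + d_phv - (1 - frac_b) * d_pha_aer, n + 1)[-1]),
    glycogen = c(ramp(spec$initial_glycogen, spec$initial_glycogen - d_gly, n),
                 ramp(spec$initial_glycogen - d_gly,
                      spec$initial_glycogen - d_gly + d_gly_aer, n + 1)[-1]),
    vss = spec$vss
  )
  if (spec$noise_sd > 0) {
    prof <- with_seed(spec$rng_seed, {
      for (a in c("acetate", "phosphate", "phb", "phv", "glycogen")) {
        scale <- diff(range(prof[[a]]))
        if (scale == 0) scale <- max(abs(prof[[a]]), 1e-3)
        prof[[a]] <- pmax(0, prof[[a]] + rnorm(nrow(prof), 0, spec$noise_sd * scale))
      }
      prof
    })
  }
  as_batch_timeseries(prof)
}

#' Specification for a simulated OTU count table
#'
#' Counts emulate a 16S survey over a fixed number of dated samples:
#' each OTU has a log10-normal baseline relative abundance, OTUs may be
#' planted with a multiplicative step change after the first `split[1]`
#' samples, temporal dependence can be added as an AR(1) process on the
#' log scale, and reads are drawn multinomially at a fixed depth.
#'
#' @param n_otus Number of OTUs.
#' @param n_samples Number of dated samples (default 10).
#' @param split Integer pair `(n1, n2)`: the step change (if any) occurs
#'   between samples `n1` and `n1 + 1`.
#' @param step_factor Scalar or length-`n_otus` vector of multiplicative
#'   changes in expected relative abundance after the step (1 = null).
#' @param ar1_rho AR(1) correlation of log abundances in `[0, 1)`.
#' @param depth Reads per sample.
#' @param log_baseline_sd Between-OTU s.d. of baseline log10 abundances.
#' @param log_noise_sd Per-sample s.d. of log10 abundance fluctuations.
#' @param start_date Date of the first sample; samples are weekly.
#' @param rng_seed Integer seed.
#' @return A list of class `otu_sim_spec`.
#' @export
otu_sim_spec <- function(n_otus = 300L,
                         n_samples = 10L,
                         split = c(4L, 6L),
                         step_factor = 1,
                         ar1_rho = 0,
                         depth = 20000L,
                         log_baseline_sd = 0.8,
                         log_noise_sd = 0.25,
                         start_date = as.Date("2013-05-29"),
                         rng_seed = 1L) {
  check_count(n_otus, "n_otus", lower = 1)
  check_count(n_samples, "n_samples", lower = 4)
  if (length(split) != 2 || sum(split) != n_samples) {
    stop_validation("`split` must be two integers summing to n_samples")
  }
  if (any(step_factor <= 0)) stop_validation("`step_factor` must be positive")
  check_number(ar1_rho, "ar1_rho", lower = 0, upper = 1 - 1e-9)
  check_count(depth, "depth", lower = 1)
  if (!length(step_factor) %in% c(1L, n_otus)) {
    stop_validation("`step_factor` must be length 1 or n_otus")
  }
  structure(list(n_otus = as.integer(n_otus), n_samples = as.integer(n_samples),
                 split = as.integer(split),
                 step_factor = rep_len(step_factor, n_otus),
                 ar1_rho = ar1_rho, depth = as.integer(depth),
                 log_baseline_sd = log_baseline_sd, log_noise_sd = log_noise_sd,
                 start_date = as.Date(start_date), rng_seed = as.integer(rng_seed)),
            class = "otu_sim_spec")
}

#' Simulate an OTU count table with planted step changes
#'
#' @param spec An [otu_sim_spec()].
#' @return An `ebpr_otu` tibble whose sample columns each sum exactly to
#'   `spec$depth`.  The attribute `truth` records the planted per-OTU
#'   step factors.
#' @export
#' @examples
#' tab <- sim_otu_counts(otu_sim_spec(n_otus = 50, depth = 5000))
#' colSums(otu_counts(tab))
sim_otu_counts <- function(spec) {
  stopifnot(inherits(spec, "otu_sim_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_otus
    s <- spec$n_samples
    base <- rnorm(n, 0, spec$log_baseline_sd)            # log10 baseline
    eps <- matrix(0, n, s)                               # AR(1) log noise
    eps[, 1] <- rnorm(n, 0, spec$log_noise_sd)
    if (s > 1) {
      for (j in 2:s) {
        eps[, j] <- spec$ar1_rho * eps[, j - 1] +
          sqrt(1 - spec$ar1_rho^2) * rnorm(n, 0, spec$log_noise_sd)
      }
    }
    step <- matrix(rep(c(rep(0, spec$split[1]), rep(1, spec$split[2])), each = n), n, s)
    loglam <- base + eps + step * log10(spec$step_factor)
    lam <- 10^loglam
    counts <- sapply(seq_len(s), function(j) {
      rmultinom(1, spec$depth, lam[, j] / sum(lam[, j]))[, 1]
    })
    dates <- format(spec$start_date + 7 * (seq_len(s) - 1))
    out <- as_tibble(counts, .name_repair = ~dates)
    out <- dplyr::bind_cols(tibble(otu_id = sprintf("OTU_%04d", seq_len(n))), out)
    out$taxonomy <- rep("k__Bacteria; p__; c__; o__; f__; g__; s__", n)
    out <- as_otu_table(out)
    attr(out, "truth") <- tibble(otu_id = sprintf("OTU_%04d", seq_len(n)),
                                 step_factor = spec$step_factor)
    out
  })
}

#' Specification for simulated shotgun reads with planted probe sites
#'
#' @param taxon_abundances Named numeric vector of taxon fractions
#'   (must sum to 1 within 1e-9).
#' @param probe_sites Named list mapping taxon to the probe ids whose
#'   target sites its reads carry.
#' @param probes An `ebpr_probes` set supplying the site sequences.
#' @param read_length Read length, nt.
#' @param n_reads Number of reads.
#' @param universal_fraction Fraction of reads (all taxa) carrying the
#'   universal target site.
#' @param site_rate Probability that a read from a carrier taxon actually
#'   contains the group-probe site.
#' @param randomize_strand Reverse-complement each read with probability
#'   1/2.
#' @param error_rate Uniform per-base substitution probability applied
#'   after site planting (default 0: error-free reads).
#' @param rng_seed Integer seed.
#' @return A list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(taxon_abundances,
                          probe_sites,
                          probes,
                          read_length = 150L,
                          n_reads = 10000L,
                          universal_fraction = 1,
                          site_rate = 1,
                          randomize_strand = TRUE,
                          error_rate = 0,
                          rng_seed = 1L) {
  if (abs(sum(taxon_abundances) - 1) > 1e-9) {
    stop_validation("taxon abundances must sum to 1 (got %.12f)", sum(taxon_abundances))
  }
  stopifnot(inherits(probes, "ebpr_probes"))
  maxlen <- max(nchar(probes$sequence))
  if (read_length < maxlen) {
    stop_validation("infeasible spec: read_length %d shorter than longest probe (%d nt)",
                    read_length, maxlen)
  }
  check_count(n_reads, "n_reads", lower = 1)
  check_number(universal_fraction, "universal_fraction", lower = 0, upper = 1)
  check_number(site_rate, "site_rate", lower = 0, upper = 1)
  check_number(error_rate, "error_rate", lower = 0, upper = 1)
  structure(list(taxon_abundances = taxon_abundances, probe_sites = probe_sites,
                 probes = probes, read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 universal_fraction = universal_fraction, site_rate = site_rate,
                 randomize_strand = randomize_strand, error_rate = error_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "read_sim_spec")
}

iupac_expand <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# draw one concrete instance of a possibly degenerate IUPAC sequence
instantiate_iupac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(iupac_expand[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate shotgun reads carrying planted probe target sites
#'
#' Each read is assigned to a taxon according to the abundance vector;
#' reads from a taxon carry concrete instances of that taxon's probe
#' sites at random non-overlapping offsets.  The universal site is
#' planted in `universal_fraction` of all reads.  With strand
#' randomisation on, each finished read is reverse-complemented with
#' probability 1/2.
#'
#' @param spec A [read_sim_spec()].
#' @return A tibble with columns `read_id`, `taxon`, `sequence` and the
#'   attribute `truth` (per-probe planted carrier fractions).
#' @export
sim_probe_reads <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  with_seed(spec$rng_seed, {
    taxa <- names(spec$taxon_abundances)
    assign <- sample(taxa, spec$n_reads, replace = TRUE, prob = spec$taxon_abundances)
    seqs <- character(spec$n_reads)
    probe_seq <- setNames(spec$probes$sequence, spec$probes$probe_id)
    universal_ids <- spec$probes$probe_id[spec$probes$role == "universal"]
    for (i in seq_len(spec$n_reads)) {
      sites <- character(0)
      if (runif(1) < spec$universal_fraction && length(universal_ids) > 0) {
        sites <- instantiate_iupac(probe_seq[[sample(universal_ids, 1)]])
      }
      carried <- spec$probe_sites[[assign[i]]] %||% character(0)
      for (p in carried) {
        if (runif(1) < spec$site_rate) sites <- c(sites, instantiate_iupac(probe_seq[[p]]))
      }
      seqs[i] <- plant_sites(spec$read_length, sites)
    }
    if (spec$error_rate > 0) seqs <- add_substitutions(seqs, spec$error_rate)
    if (spec$randomize_strand) {
      flip <- runif(spec$n_reads) < 0.5
      seqs[flip] <- revcomp_chr(seqs[flip])
    }
    out <- tibble(read_id = sprintf("read_%06d", seq_len(spec$n_reads)),
                  taxon = assign, sequence = seqs)
    carriers <- vapply(spec$probes$probe_id, function(p) {
      tax_with <- names(Filter(function(v) p %in% v, spec$probe_sites))
      sum(spec$taxon_abundances[tax_with]) * spec$site_rate
    }, numeric(1))
    carriers[universal_ids] <- spec$universal_fraction
    attr(out, "truth") <- tibble(probe_id = spec$probes$probe_id,
                                 planted_fraction = unname(carriers))
    out
  })
}

# build one read of length L containing the given concrete sites at
# random non-overlapping offsets, random background elsewhere
plant_sites <- function(L, sites) {
  bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (length(sites) > 0) {
    if (sum(nchar(sites)) > L) {
      stop_validation("infeasible spec: planted sites (%d nt) exceed read length %d",
                      sum(nchar(sites)), L)
    }
    taken <- rep(FALSE, L)
    for (s in sites) {
      w <- nchar(s)
      ok_start <- which(vapply(seq_len(L - w + 1), function(st) !any(taken[st:(st + w - 1)]),
                               logical(1)))
      st <- if (length(ok_start) == 1) ok_start else sample(ok_start, 1)
      bg[st:(st + w - 1)] <- strsplit(s, "")[[1]]
      taken[st:(st + w - 1)] <- TRUE
    }
  }
  paste(bg, collapse = "")
}

add_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated reads to FASTA
#' @param reads Tibble from [sim_probe_reads()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  set <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
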