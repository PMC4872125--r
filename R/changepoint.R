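#' Rarefy an OTU table to even depth
#'
#' A single random subsample without replacement per sample, so that
#' every sample column sums exactly to `depth`.  The draw is controlled
#' by an explicit seed and is not averaged over replicates, keeping the
#' pipeline deterministic given its configuration.
#'
#' @param table An `ebpr_otu` tibble.
#' @param depth Target reads per sample; must not exceed any sample's
#'   total.
#' @param seed Integer seed for the draw.
#' @return An `ebpr_otu` tibble whose sample columns each sum to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  check_count(depth, "depth", lower = 0)
  m <- otu_counts(table)
  tot <- colSums(m)
  short <- tot < depth
  if (any(short)) {
    stop_validation("rarefaction depth %d exceeds the total of sample(s): %s",
                    depth, paste(colnames(m)[short], collapse = ", "))
  }
  out <- table
  sub <- if (depth == 0) {
    matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    with_seed(seed, t(vegan::rrarefy(t(m), depth)))
  }
  for (j in colnames(m)) out[[j]] <- as.integer(sub[, j])
  out
}

#' Log10 pseudo-count normalisation
#'
#' Elementwise `log10(x + 1)` of a rarefied count matrix (or table).
#'
#' @param x An `ebpr_otu` tibble or a numeric matrix.
#' @return A numeric matrix of the same shape (OTUs x samples).
#' @export
log_normalize <- function(x) {
  m <- if (is.data.frame(x)) otu_counts(x) else x
  log10(m + 1)
}

#' Relative abundance of a taxon across samples
#'
#' Sums the reads of every OTU whose lineage contains the queried
#' rank-prefixed name (exact match on the rank value, e.g.
#' `g__Candidatus Accumulibacter`) and expresses the sum as a fraction of
#' all reads, per sample and pooled.  Unclassified ranks never match a
#' named query.
#'
#' @param table An `ebpr_otu` tibble.
#' @param taxon Rank-prefixed taxon string, e.g.
#'   `"g__Candidatus Accumulibacter"`, or a bare name matched at the
#'   given `rank`.
#' @param rank Rank letter used when `taxon` has no `x__` prefix.
#' @return A list with `per_sample` (tibble: sample, fraction), `overall`
#'   (pooled fraction) and `n_otus` matched.
#' @export
taxon_relative_abundance <- function(table, taxon, rank = "g") {
  if (grepl("^[kpcofgs]__", taxon)) {
    rank <- substr(taxon, 1, 1)
    name <- sub("^[kpcofgs]__", "", taxon)
  } else {
    name <- taxon
  }
  vals <- taxonomy_rank(table$taxonomy, rank)
  hit <- !is.na(vals) & vals == name
  m <- otu_counts(table)
  tot <- colSums(m)
  part <- if (any(hit)) colSums(m[hit, , drop = FALSE]) else setNames(rep(0, ncol(m)), colnames(m))
  list(per_sample = tibble(sample = colnames(m), fraction = unname(part / tot)),
       overall = sum(part) / sum(tot),
       n_otus = sum(hit))
}

#' Step-change statistic for one series
#'
#' Measures a step-like change in the mean level of a series between a
#' first segment of `split[1]` and a second segment of `split[2]`
#' consecutive observations: the two-segment one-way ANOVA F statistic
#' with 1 and n-2 degrees of freedom, with the change point fixed by the
#' experimental design (not searched).
#'
#' @param y Numeric series of length `sum(split)` (typically log10
#'   normalised abundances).
#' @param split Integer pair `(n1, n2)`.
#' @return A one-row tibble: `difference` (second-segment mean minus
#'   first), `f_statistic`, `p_raw`, and `flag` (`"degenerate"` when the
#'   within-segment variance is zero with a nonzero difference, in which
#'   case `p_raw` is the numerical floor).
#' @export
#' @examples
#' step_change_test(c(1, 2, 1, 2, 3, 4, 3, 4, 3, 4), c(4, 6))
step_change_test <- function(y, split = c(4L, 6L)) {
  n1 <- split[1]; n2 <- split[2]; n <- n1 + n2
  if (length(y) != n) stop_validation("series length %d does not match split (%d, %d)",
                                      length(y), n1, n2)
  if (n1 < 2 || n2 < 2) stop_validation("both segments need >= 2 observations")
  g1 <- y[seq_len(n1)]; g2 <- y[n1 + seq_len(n2)]
  m1 <- mean(g1); m2 <- mean(g2)
  ssb <- n1 * n2 / n * (m2 - m1)^2
  ssw <- sum((g1 - m1)^2) + sum((g2 - m2)^2)
  flag <- NA_character_
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- .Machine$double.xmin; flag <- "degenerate"
    }
  } else {
    f <- ssb / (ssw / (n - 2))
    p <- pf(f, 1, n - 2, lower.tail = FALSE)
  }
  tibble(difference = m2 - m1, f_statistic = f, p_raw = p, flag = flag)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 by smoothing
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` with a natural cubic
#' smoother over `lambda = 0.05, 0.10, ..., 0.95` and evaluating the fit
#' at `lambda = 0.95`; for fewer than 100 p-values the estimate falls
#' back to the single point `lambda = 0.5`.  q-values are the
#' pi0-scaled step-up quantities
#' `q(p_i) = min_{p_(j) >= p_i} pi0 * m * p_(j) / j`, monotone in p.
#'
#' @param p Vector of p-values in (0, 1].
#' @param lambda Tuning grid for the pi0 estimator.
#' @param pi0 Optional fixed null proportion overriding the estimator;
#'   `pi0 = 1` gives Benjamini-Hochberg adjusted p-values.
#' @return A list with `q` (vector, same order as `p`) and `pi0`.
#' @export
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (length(p) == 0) stop_validation("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop_validation("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (!is.null(pi0)) {
    check_number(pi0, "pi0", lower = 0, upper = 1)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))[ro]
    return(list(q = q, pi0 = pi0))
  }
  pi0 <- if (m < 100) {
    mean(p > 0.5) / 0.5
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))[ro]
  list(q = q, pi0 = pi0)
}

#' Step-change screen over an OTU table
#'
#' The full community change-point pipeline: rarefy to even depth, keep
#' the ubiquitous OTUs (nonzero counts at every sampling event), log10
#' pseudo-count normalise, apply [step_change_test()] to every retained
#' OTU at the designed split, and control the FDR with
#' [storey_qvalues()].
#'
#' @param table An `ebpr_otu` tibble.
#' @param split Integer pair `(n1, n2)`; samples are taken in date order.
#' @param depth Rarefaction depth; `NULL` skips rarefaction (counts
#'   already even).
#' @param seed Seed for the rarefaction draw.
#' @return A tibble of class `ebpr_changepoint`, sorted by `q`:
#'   `otu_id`, `difference` (low- minus high-epoch mean of the log10
#'   normalised series), `f_statistic`, `p_raw`, `q`, `annotation`.
#'   The attribute `pi0` stores the estimated null proportion.
#' @export
test_step_changes <- function(table, split = c(4L, 6L), depth = NULL, seed = 1L) {
  if (!is.null(depth)) table <- rarefy_counts(table, depth, seed = seed)
  m <- otu_counts(table)
  if (ncol(m) != sum(split)) {
    stop_validation("table has %d samples but split implies %d", ncol(m), sum(split))
  }
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) stop_validation("no OTU is detected in every sample")
  lm10 <- log_normalize(m[keep, , drop = FALSE])
  res <- purrr::map_dfr(seq_len(nrow(lm10)), function(i) step_change_test(lm10[i, ], split))
  qv <- storey_qvalues(res$p_raw)
  out <- tibble(otu_id = rownames(lm10),
                difference = res$difference,
                f_statistic = res$f_statistic,
                p_raw = res$p_raw,
                q = qv$q,
                annotation = table$taxonomy[match(rownames(lm10), table$otu_id)]) %>%
    arrange(.data$q, .data$p_raw)
  attr(out, "pi0") <- qv$pi0
  class(out) <- c("ebpr_changepoint", class(out))
  out
}

#' Epoch fold change of an OTU or taxon
#'
#' Ratio of the mean relative abundance over the low-aeration samples to
#' that over the high-aeration samples (fold changes are computed on
#' relative abundances, never on the log-normalised values, and no
#' pseudo-count enters).  Decreases are reported as factors greater than
#' one with direction `"decrease"`.
#'
#' @param table An `ebpr_otu` tibble.
#' @param id OTU id, or a rank-prefixed taxon string (see
#'   [taxon_relative_abundance()]).
#' @param split Integer pair `(n1, n2)` defining the epochs in date
#'   order.
#' @return A one-row tibble: `id`, `fold_change` (low/high), `factor`
#'   (>= 1), `direction`, and `flag` (`"undefined"` when the high-epoch
#'   mean is zero).
#' @export
epoch_fold_change <- function(table, id, split = c(4L, 6L)) {
  m <- otu_counts(table)
  rel <- sweep(m, 2, colSums(m), "/")
  frac <- if (id %in% rownames(rel)) {
    rel[id, ]
  } else {
    taxon_relative_abundance(table, id)$per_sample$fraction
  }
  idx_high <- seq_len(split[1])
  idx_low <- split[1] + seq_len(split[2])
  mh <- mean(frac[idx_high]); ml <- mean(frac[idx_low])
  if (mh == 0) {
    return(tibble(id = id, fold_change = NA_real_, factor = NA_real_,
                  direction = NA_character_, flag = "undefined"))
  }
  fc <- ml / mh
  tibble(id = id, fold_change = fc,
         factor = if (fc >= 1) fc else 1 / fc,
         direction = if (fc > 1) "increase" else if (fc < 1) "decrease" else "none",
         flag = NA_character_)
}

#' Empirical error rates of the step-change test
#'
#' Monte-Carlo characterisation of the designed test: series of length
#' `n1 + n2` are drawn as stationary Gaussian AR(1) processes (unit
#' marginal variance) with a mean shift of `effect` (in within-segment
#' s.d. units) after the first segment, and the rejection rate of
#' [step_change_test()] at level `alpha` is recorded per grid cell.
#' `effect = 0` rows measure the type-I error; `rho > 0` rows measure
#' autocorrelation-induced inflation.
#'
#' @param effect_grid Mean shifts in s.d. units (0 = null).
#' @param rho_grid AR(1) coefficients in `[0, 1)`.
#' @param split Integer pair `(n1, n2)`.
#' @param reps Replicates per cell (>= 1000 for reportable rates).
#' @param alpha Nominal level.
#' @param rng_seed Integer seed.
#' @return A tibble of class `ebpr_error_rates`: `effect`, `rho`,
#'   `rejection_rate`, `reps`, `alpha`.
#' @export
simulate_error_rates <- function(effect_grid = c(0, 0.5, 1, 2),
                                 rho_grid = c(0, 0.3, 0.6),
                                 split = c(4L, 6L),
                                 reps = 1000L,
                                 alpha = 0.05,
                                 rng_seed = 1L) {
  check_count(reps, "reps", lower = 1)
  if (reps < 1000) warn("fewer than 1000 replicates per cell; rates are indicative only")
  n <- sum(split)
  shift <- rep(c(0, 1), split)
  with_seed(rng_seed, {
    grid <- tidyr::expand_grid(effect = effect_grid, rho = rho_grid)
    grid$rejection_rate <- purrr::map2_dbl(grid$effect, grid$rho, function(eff, rho) {
      rej <- 0L
      for (r in seq_len(reps)) {
        z <- rnorm(n)
        e <- numeric(n)
        e[1] <- z[1]
        for (t in 2:n) e[t] <- rho * e[t - 1] + sqrt(1 - rho^2) * z[t]
        y <- e + eff * shift
        if (step_change_test(y, split)$p_raw < alpha) rej <- rej + 1L
      }
      rej / reps
    })
    grid$reps <- reps
    grid$alpha <- alpha
    class(grid) <- c("ebpr_error_rates", class(grid))
    grid
  })
}
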