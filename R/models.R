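#' Canonical anaerobic/aerobic PAO and GAO model ratio predictions
#'
#' The fixed transformation-ratio predictions of the classical
#' stoichiometric models of anaerobic PAO metabolism (full-TCA,
#' glycolysis-only, combined, split/partial-TCA) and of the GAO model,
#' plus the aerobic PAO reference.  Ratios are P-mol or C-mol per C-mol
#' acetate (anaerobic block) or per C-mol PHA (aerobic block).
#'
#' @return A tibble with one row per model and the seven ratio columns.
#' @seealso [predict_fixed_model()], [predict_yagci()]
#' @export
model_predictions <- function() {
  tibble(
    model = c("comeau_tca", "smolders_gly", "pereira_tca_gly",
              "hesselmann_split", "smolders_aerobic", "zeng_gao"),
    description = c("anaerobic PAO, full TCA",
                    "anaerobic PAO, glycolysis only",
                    "anaerobic PAO, glycolysis + full TCA",
                    "anaerobic PAO, split TCA + glycolysis",
                    "aerobic PAO",
                    "GAO, glycolysis"),
    p_per_hac   = c(0.5, 0.5, 0.16, 0.37, NA, 0.00),
    gly_per_hac = c(0,   0.5, 0.7,  0.6,  NA, 1.12),
    phb_per_hac = c(0.9, 1.33, 1.02, 1.11, NA, 1.36),
    phv_per_hac = c(0,   0,   0.46, 0.29, NA, 0.46),
    pha_per_hac = c(0.9, 1.33, 1.48, 1.4,  NA, 1.86),
    p_per_pha   = c(NA, NA, NA, NA, 0.41, 0.00),
    gly_per_pha = c(NA, NA, NA, NA, 0.42, 0.65)
  )
}

#' Ratio predictions of one canonical model
#'
#' @param name One of `"comeau_tca"`, `"smolders_gly"`,
#'   `"pereira_tca_gly"`, `"hesselmann_split"`, `"smolders_aerobic"`,
#'   `"zeng_gao"`.  The parametric partial-TCA (glyoxylate) model has no
#'   fixed predictions; request it through [predict_yagci()].
#' @return A one-row tibble of ratio predictions.
#' @export
#' @examples
#' predict_fixed_model("comeau_tca")
predict_fixed_model <- function(name) {
  if (identical(name, "yagci_glyoxylate")) {
    stop_config("the glyoxylate-pathway model is parametric; use predict_yagci()")
  }
  tab <- model_predictions()
  if (!name %in% tab$model) {
    stop_config("unknown model '%s' (available: %s)", name,
                paste(tab$model, collapse = ", "))
  }
  tab[tab$model == name, ]
}

#' Parametric glyoxylate-pathway (partial TCA) model predictions
#'
#' Anaerobic PAO model in which reducing power comes from glycogen
#' glycolysis plus the partial TCA cycle operating through the glyoxylate
#' shunt.  Its ratio predictions are closed-form in the acetate-transport
#' energy `alpha_pao` (ATP per C-mol acetate crossing the membrane) and
#' the fraction `f_gly` of acetyl-CoA routed through the glyoxylate
#' pathway:
#' \deqn{P/HAc = \alpha + (1 - 1/(2+f))/2, \quad Gly/HAc = 1/(2+f),}
#' \deqn{PHB/HAc = 8/(6+3f), \quad PHV/HAc = 2.5/(6+3f).}
#'
#' @param alpha_pao Non-negative ATP cost per C-mol acetate transported.
#' @param f_gly Fraction of acetyl-CoA through the glyoxylate pathway,
#'   in \[0, 1\].
#' @return A one-row tibble of anaerobic ratio predictions.
#' @export
#' @examples
#' predict_yagci(alpha_pao = 0.25, f_gly = 0)
predict_yagci <- function(alpha_pao, f_gly) {
  check_number(alpha_pao, "alpha_pao", lower = 0)
  if (!is.numeric(f_gly) || length(f_gly) != 1 || f_gly < 0 || f_gly > 1) {
    stop_validation("`f_gly` must lie in [0, 1]")
  }
  phb <- 8 / (6 + 3 * f_gly)
  phv <- 2.5 / (6 + 3 * f_gly)
  tibble(model = "yagci_glyoxylate",
         alpha_pao = alpha_pao, f_gly = f_gly,
         p_per_hac = alpha_pao + 0.5 * (1 - 1 / (2 + f_gly)),
         gly_per_hac = 1 / (2 + f_gly),
         phb_per_hac = phb,
         phv_per_hac = phv,
         pha_per_hac = phb + phv)
}

#' Stoichiometric coefficients of the anaerobic flux-balance model
#'
#' The per-C-mol ATP and NADH bookkeeping used by [pereira_predict()] and
#' [fit_pereira()].  NADH means NADH-equivalents (FADH2 counted at par).
#' The defaults encode standard anaerobic PAO chemistry: glycogen
#' glycolysed to pyruvate yields 1/3 NADH and 1/2 ATP per C-mol glycogen;
#' oxidative pyruvate decarboxylation yields a further 1/3 NADH per C-mol
#' pyruvate and passes 2/3 of the carbon to acetyl-CoA; full TCA
#' oxidation of acetyl-CoA yields `nadh_tca` NADH-equivalents and
#' `atp_tca` ATP per C-mol oxidised; PHB synthesis consumes 1/4 NADH per
#' C-mol PHB, the final reduction in PHV synthesis 1/5 per C-mol PHV, and
#' propionyl-CoA formation from pyruvate (succinate-propionate route)
#' `nadh_propionyl` per C-mol propionyl carbon; acetate uptake plus
#' activation costs `atp_acetate` ATP per C-mol, balanced by polyP
#' hydrolysis at 1 ATP per P-mol released.
#'
#' @param nadh_glycolysis NADH per C-mol glycogen, glycogen to pyruvate.
#' @param nadh_pdh NADH per C-mol pyruvate decarboxylated.
#' @param nadh_tca NADH-equivalents per C-mol acetyl-CoA fully oxidised.
#' @param nadh_phb NADH consumed per C-mol PHB synthesised.
#' @param nadh_phv_reduction NADH consumed per C-mol PHV in the final
#'   ketoacyl reduction.
#' @param nadh_propionyl NADH consumed per C-mol propionyl carbon formed.
#' @param atp_glycolysis ATP per C-mol glycogen glycolysed.
#' @param atp_tca ATP (GTP) per C-mol acetyl-CoA fully oxidised.
#' @param atp_acetate ATP per C-mol acetate taken up and activated
#'   (transport plus activation; the transport part is the alpha of the
#'   glyoxylate model).
#' @param atp_propionyl ATP per C-mol propionyl carbon formed.
#' @return Named list of class `ebpr_balance_coefficients`.
#' @export
balance_coefficients <- function(nadh_glycolysis = 1/3,
                                 nadh_pdh = 1/3,
                                 nadh_tca = 1.05,
                                 nadh_phb = 1/4,
                                 nadh_phv_reduction = 1/5,
                                 nadh_propionyl = 1.1,
                                 atp_glycolysis = 1/2,
                                 atp_tca = 1/2,
                                 atp_acetate = 1/4,
                                 atp_propionyl = 0) {
  co <- list(nadh_glycolysis = nadh_glycolysis, nadh_pdh = nadh_pdh,
             nadh_tca = nadh_tca, nadh_phb = nadh_phb,
             nadh_phv_reduction = nadh_phv_reduction,
             nadh_propionyl = nadh_propionyl,
             atp_glycolysis = atp_glycolysis, atp_tca = atp_tca,
             atp_acetate = atp_acetate, atp_propionyl = atp_propionyl)
  for (nm in names(co)) check_number(co[[nm]], nm, lower = 0)
  structure(co, class = "ebpr_balance_coefficients")
}

#' Forward prediction of the glycolysis + full-TCA flux-balance model
#'
#' Given the fraction `f_tca` of acetyl-CoA carbon oxidised in the full
#' TCA cycle and the glycogen flux `gly_per_hac`, solves the carbon and
#' reducing-equivalent balances for the remaining fluxes (per C-mol
#' acetate) and returns the implied transformation ratios.  The
#' propionyl flux feeding PHV acts as the electron sink that closes the
#' NADH balance; polyP hydrolysis closes the ATP balance.
#'
#' @param f_tca Fraction of acetyl-CoA C oxidised in the full TCA cycle,
#'   in \[0, 1\].
#' @param gly_per_hac Glycogen degraded, C-mol per C-mol acetate.
#' @param coefficients A [balance_coefficients()] list.
#' @return A list with `ratios` (one-row tibble: `p_per_hac`,
#'   `gly_per_hac`, `phb_per_hac`, `phv_per_hac`, `pha_per_hac`),
#'   `fluxes` (tibble of named fluxes, C-mol per C-mol acetate),
#'   `nadh` (produced/consumed breakdown) and `nadh_share_tca`.
#' @export
pereira_predict <- function(f_tca, gly_per_hac,
                            coefficients = balance_coefficients()) {
  check_number(f_tca, "f_tca", lower = 0, upper = 1)
  check_number(gly_per_hac, "gly_per_hac", lower = 0)
  co <- coefficients
  f <- f_tca; g <- gly_per_hac
  # x = propionyl carbon flux; acetyl-CoA pool A(x) = 1 + (2/3)(g - x)
  A0 <- 1 + (2/3) * g
  # NADH produced(x) = n_gly g + n_pdh (g - x) + n_tca f A(x)
  p0 <- co$nadh_glycolysis * g + co$nadh_pdh * g + co$nadh_tca * f * A0
  p1 <- -co$nadh_pdh - co$nadh_tca * f * (2/3)
  # consumed(x) = n_phb b(x) + n_phvred (5/3) x + n_prop x,
  # with b(x) = A(x)(1 - f) - (2/3) x
  c0 <- co$nadh_phb * A0 * (1 - f)
  c1 <- co$nadh_phb * (-(2/3) * (1 - f) - (2/3)) +
    co$nadh_phv_reduction * (5/3) + co$nadh_propionyl
  if (abs(c1 - p1) < 1e-12) stop_validation("degenerate coefficient set: propionyl flux undetermined")
  x <- (p0 - c0) / (c1 - p1)
  A <- A0 - (2/3) * x
  t <- f * A
  b <- A * (1 - f) - (2/3) * x
  v <- (5/3) * x
  p_rel <- co$atp_acetate + co$atp_propionyl * x -
    co$atp_glycolysis * g - co$atp_tca * t
  nadh_tca <- co$nadh_tca * t
  nadh_gly <- co$nadh_glycolysis * g + co$nadh_pdh * (g - x)
  list(
    ratios = tibble(p_per_hac = p_rel, gly_per_hac = g,
                    phb_per_hac = b, phv_per_hac = v, pha_per_hac = b + v),
    fluxes = tibble(
      flux = c("acetate_uptake", "glycogen_degradation", "pyruvate_decarboxylation",
               "pyruvate_to_propionyl", "acetyl_coa_pool", "tca_oxidation",
               "phb_synthesis", "phv_synthesis", "co2_evolution"),
      c_mol = c(1, g, g - x, x, A, t, b, v, (1/3) * (g - x) + t)),
    nadh = tibble(source = c("glycolysis", "tca", "phb_sink", "phv_sink", "propionyl_sink"),
                  nadh = c(nadh_gly, nadh_tca,
                           -co$nadh_phb * b, -co$nadh_phv_reduction * v,
                           -co$nadh_propionyl * x)),
    nadh_share_tca = if (nadh_tca + nadh_gly > 0) nadh_tca / (nadh_tca + nadh_gly) else 0
  )
}

#' Fit the glycolysis + full-TCA model to observed anaerobic ratios
#'
#' Estimates the TCA-oxidised fraction of acetyl-CoA flux (`f_tca`) and
#' the glycogen flux by bounded least squares on the four anaerobic
#' transformation ratios (P/HAc, Gly/HAc, PHB/HAc, PHV/HAc), with the
#' carbon, reducing-equivalent and ATP balances holding exactly at every
#' candidate.  Multi-start local optimisation with fixed starting points
#' makes the fit deterministic.  The TCA share of anaerobic reducing
#' power is read off the fitted fluxes as TCA-derived NADH over total
#' NADH produced.
#'
#' @param observed One-row data frame (or named vector) with
#'   `p_per_hac`, `gly_per_hac`, `phb_per_hac`, `phv_per_hac`.
#' @param coefficients A [balance_coefficients()] list.
#' @param weights Length-4 non-negative weights on the squared residuals
#'   of (P/HAc, Gly/HAc, PHB/HAc, PHV/HAc).  The defaults are the
#'   package's calibrated objective; `c(1, 1, 1, 1)` gives the
#'   unweighted fit.
#' @param starts Matrix of `(f_tca, gly_per_hac)` starting points.
#' @return An object of class `pereira_fit`: a list with `f_tca`,
#'   `nadh_share_tca`, `gly_per_hac`, `fluxes`, `predicted`, `observed`,
#'   `residual` (weighted SSR), `weights` and `coefficients`.
#' @export
#' @examples
#' obs <- c(p_per_hac = 0.89, gly_per_hac = 0.60,
#'          phb_per_hac = 0.83, phv_per_hac = 0.11)
#' fit <- fit_pereira(obs)
#' round(100 * fit$f_tca)
#' round(100 * fit$nadh_share_tca)
fit_pereira <- function(observed,
                        coefficients = balance_coefficients(),
                        weights = pereira_weights(),
                        starts = pereira_starts()) {
  obs <- as.list(observed)
  need <- c("p_per_hac", "gly_per_hac", "phb_per_hac", "phv_per_hac")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0) stop_validation("observed ratios missing: %s", paste(miss, collapse = ", "))
  obs <- unlist(obs[need])
  if (any(is.na(obs))) stop_validation("observed anaerobic ratios must be complete")
  if (length(weights) != 4 || any(weights < 0)) stop_validation("`weights` must be 4 non-negative numbers")

  objective <- function(par) {
    pred <- pereira_predict(par[1], par[2], coefficients)
    x <- pred$fluxes$c_mol[pred$fluxes$flux == "pyruvate_to_propionyl"]
    b <- pred$ratios$phb_per_hac
    pen <- 0
    if (x < 0) pen <- pen + 1e3 * x^2 + 1   # NADH balance needs negative propionyl flux
    if (b < 0) pen <- pen + 1e3 * b^2 + 1   # carbon balance needs negative PHB flux
    sum(weights * (unlist(pred$ratios[1, need]) - obs)^2) + pen
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], objective, method = "L-BFGS-B",
               lower = c(0, 0), upper = c(1, 3),
               control = list(factr = 10, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish from the best point
  best <- optim(best$par, objective, method = "L-BFGS-B",
                lower = c(0, 0), upper = c(1, 3),
                control = list(factr = 1, maxit = 1000))
  best$par <- unname(best$par)
  fit <- pereira_predict(best$par[1], best$par[2], coefficients)
  x <- fit$fluxes$c_mol[fit$fluxes$flux == "pyruvate_to_propionyl"]
  if (x < -1e-8) {
    stop_validation(paste0("no feasible non-negative flux solution: the reducing-equivalent ",
                           "balance requires a negative propionyl flux (%.3g)"), x)
  }
  if (fit$ratios$phb_per_hac < -1e-8) {
    stop_validation("no feasible non-negative flux solution: the carbon balance requires negative PHB flux")
  }
  structure(list(f_tca = best$par[1],
                 gly_per_hac = best$par[2],
                 nadh_share_tca = fit$nadh_share_tca,
                 fluxes = fit$fluxes,
                 nadh = fit$nadh,
                 predicted = fit$ratios,
                 observed = tibble(!!!as.list(obs)),
                 residual = best$value,
                 weights = weights,
                 coefficients = coefficients,
                 convergence = best$convergence),
            class = "pereira_fit")
}

#' Default starting points for [fit_pereira()]
#' @return A numeric matrix of `(f_tca, gly_per_hac)` starts.
#' @export
pereira_starts <- function() {
  matrix(c(0.00, 0.5,
           0.05, 0.6,
           0.10, 0.4,
           0.20, 0.8,
           0.40, 0.3), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("f_tca", "gly_per_hac")))
}

#' Default objective weights for [fit_pereira()]
#'
#' Relative weights of the squared residuals on (P/HAc, Gly/HAc,
#' PHB/HAc, PHV/HAc).  The defaults are the package's calibrated
#' objective for full-scale survey data (see the methods vignette);
#' pass `c(1, 1, 1, 1)` for the unweighted fit.
#' @return Length-4 numeric vector.
#' @export
pereira_weights <- function() c(1.04, 1.41, 0.61, 1.20)

#' @export
print.pereira_fit <- function(x, ...) {
  cat("Glycolysis + full-TCA anaerobic flux-balance fit\n")
  cat(sprintf("  f_tca          : %.4f  (%.0f%% of acetyl-CoA oxidised)\n",
              x$f_tca, 100 * x$f_tca))
  cat(sprintf("  NADH share TCA : %.4f  (%.0f%% of reducing power)\n",
              x$nadh_share_tca, 100 * x$nadh_share_tca))
  cat(sprintf("  glycogen flux  : %.4f C-mol/C-mol acetate\n", x$gly_per_hac))
  cat(sprintf("  weighted SSR   : %.6g\n", x$residual))
  invisible(x)
}

#' @export
tidy.pereira_fit <- function(x, ...) {
  tibble(term = c("f_tca", "nadh_share_tca", "gly_per_hac"),
         estimate = c(x$f_tca, x$nadh_share_tca, x$gly_per_hac))
}

#' @export
glance.pereira_fit <- function(x, ...) {
  tibble(f_tca = x$f_tca, nadh_share_tca = x$nadh_share_tca,
         gly_per_hac = x$gly_per_hac, residual = x$residual,
         convergence = x$convergence)
}

#' Leave-one-out jackknife standard error
#'
#' Computes the estimator on every leave-one-out subsample and returns
#' `sqrt((n-1)/n * sum((theta_i - mean(theta_i))^2))`.  For the mean this
#' equals the classical `s/sqrt(n)`.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param estimator Function reducing a numeric vector to a scalar.
#' @return The jackknife standard error (scalar).
#' @export
#' @examples
#' jackknife_se(c(0.92, 0.80, 1.01, 0.83))        # = sd(x)/2
jackknife_se <- function(values, estimator = mean) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop_validation("jackknife needs at least 2 values")
  loo <- vapply(seq_len(n), function(i) estimator(values[-i]), numeric(1))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Epoch-level flux-balance fits with jackknife errors
#'
#' Fits the glycolysis + full-TCA model to each epoch's mean anaerobic
#' ratios and attaches leave-one-cycle-out jackknife standard errors:
#' cycle i is dropped, the epoch mean recomputed and refitted, and the
#' spread of the leave-one-out estimates converted to a standard error.
#'
#' @param ratios Per-cycle ratio tibble with `epoch` and the four
#'   anaerobic ratio columns (see [ebpr_cycle_ratios()]).
#' @param coefficients,weights Passed to [fit_pereira()].
#' @return A tibble with one row per epoch: `epoch`, `n_cycles`,
#'   `f_tca`, `f_tca_se`, `nadh_share_tca`, `nadh_share_tca_se`,
#'   `gly_per_hac`, `residual`.
#' @export
fit_pereira_epochs <- function(ratios,
                               coefficients = balance_coefficients(),
                               weights = pereira_weights()) {
  need <- c("p_per_hac", "gly_per_hac", "phb_per_hac", "phv_per_hac")
  stopifnot(all(c("epoch", need) %in% names(ratios)))
  purrr::map_dfr(split(ratios, ratios$epoch), function(chunk) {
    mobs <- colMeans(chunk[, need])
    fit <- fit_pereira(mobs, coefficients, weights)
    n <- nrow(chunk)
    se_f <- se_s <- NA_real_
    if (n >= 2) {
      loo <- vapply(seq_len(n), function(i) {
        fi <- fit_pereira(colMeans(chunk[-i, need]), coefficients, weights)
        c(fi$f_tca, fi$nadh_share_tca)
      }, numeric(2))
      se_f <- sqrt((n - 1) / n * sum((loo[1, ] - mean(loo[1, ]))^2))
      se_s <- sqrt((n - 1) / n * sum((loo[2, ] - mean(loo[2, ]))^2))
    }
    tibble(epoch = chunk$epoch[1], n_cycles = n,
           f_tca = fit$f_tca, f_tca_se = se_f,
           nadh_share_tca = fit$nadh_share_tca, nadh_share_tca_se = se_s,
           gly_per_hac = fit$gly_per_hac, residual = fit$residual)
  })
}
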