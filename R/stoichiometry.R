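#' Per-phase analyte changes of a batch cycle
#'
#' Computes the absolute change of every analyte between the first and
#' last sample of a phase.  Liquid analytes (acetate, phosphate) are
#' divided by the biomass concentration so that all deltas share the
#' C-mmol (or P-mmol) per g VSS basis; intracellular pools (PHB, PHV,
#' glycogen) are already biomass-normalised.  Direction is tracked
#' separately so consumed and produced analytes both report positive
#' deltas.
#'
#' @param ts An `ebpr_batch` tibble.
#' @param phase `"anaerobic"` or `"aerobic"`.
#' @return A tibble with columns `analyte`, `start`, `end`, `delta`
#'   (absolute, per g VSS) and `direction` (`"consumed"`, `"produced"`
#'   or `"constant"`).
#' @export
phase_deltas <- function(ts, phase = c("anaerobic", "aerobic")) {
  phase <- match.arg(phase)
  sub <- ts[as.character(ts$phase) == phase, ]
  if (nrow(sub) < 2) stop_validation("phase '%s' needs at least 2 points (found %d)",
                                     phase, nrow(sub))
  vss <- if ("vss" %in% names(sub)) mean(sub$vss, na.rm = TRUE) else NA_real_
  liquid <- c("acetate", "phosphate")
  analytes <- intersect(c(liquid, "phb", "phv", "glycogen"), names(sub))
  rows <- lapply(analytes, function(a) {
    x <- sub[[a]]
    first <- x[1]; last <- x[length(x)]
    if (a %in% liquid) {
      if (!is.finite(vss) || vss <= 0) stop_validation("VSS must be positive to normalise liquid analytes")
      first <- first / vss; last <- last / vss
    }
    d <- last - first
    tibble(analyte = a, start = first, end = last, delta = abs(d),
           direction = if (is.na(d)) NA_character_
                       else if (d < 0) "consumed" else if (d > 0) "produced" else "constant")
  })
  bind_rows(rows)
}

ratio_or_na <- function(num, den) if (is.na(num)) NA_real_ else num / den

#' Anaerobic transformation ratios of a batch cycle
#'
#' Ratios of phosphorus released, glycogen consumed and PHB/PHV produced
#' per C-mol of acetate taken up during the anaerobic phase, using the
#' phase start/end deltas.  `pha_per_hac` is the sum of the PHB and PHV
#' ratios by construction.
#'
#' @param ts An `ebpr_batch` tibble.
#' @return A one-row tibble with `p_per_hac`, `gly_per_hac`,
#'   `phb_per_hac`, `phv_per_hac`, `pha_per_hac` (missing analytes yield
#'   `NA`, never zero).
#' @export
#' @examples
#' ts <- sim_batch_timeseries(batch_sim_spec(noise_sd = 0))
#' anaerobic_ratios(ts)
anaerobic_ratios <- function(ts) {
  d <- phase_deltas(ts, "anaerobic")
  get <- function(a) if (a %in% d$analyte) d$delta[d$analyte == a] else NA_real_
  d_hac <- get("acetate")
  if (is.na(d_hac) || d_hac <= 0) {
    stop_validation("anaerobic acetate uptake is zero or missing; ratios are undefined")
  }
  phb <- ratio_or_na(get("phb"), d_hac)
  phv <- ratio_or_na(get("phv"), d_hac)
  tibble(p_per_hac = ratio_or_na(get("phosphate"), d_hac),
         gly_per_hac = ratio_or_na(get("glycogen"), d_hac),
         phb_per_hac = phb,
         phv_per_hac = phv,
         pha_per_hac = phb + phv)
}

#' Aerobic transformation ratios of a batch cycle
#'
#' Phosphorus taken up and glycogen replenished per C-mol of PHA consumed
#' during the aerobic phase.  When the glycogen series is absent the
#' Gly/PHA ratio is reported missing while the others are computed.
#'
#' @param ts An `ebpr_batch` tibble.
#' @return A one-row tibble with `p_per_pha` and `gly_per_pha`.
#' @export
aerobic_ratios <- function(ts) {
  d <- phase_deltas(ts, "aerobic")
  get <- function(a) if (a %in% d$analyte) d$delta[d$analyte == a] else NA_real_
  d_pha <- sum(get("phb"), get("phv"), na.rm = TRUE)
  if (!any(c("phb", "phv") %in% d$analyte) || d_pha <= 0) {
    stop_validation("aerobic PHA consumption is zero or missing; ratios are undefined")
  }
  tibble(p_per_pha = ratio_or_na(get("phosphate"), d_pha),
         gly_per_pha = ratio_or_na(get("glycogen"), d_pha))
}

#' All seven transformation ratios of one batch cycle
#'
#' Convenience wrapper combining [anaerobic_ratios()] and
#' [aerobic_ratios()] into the full per-cycle ratio record.
#'
#' @param ts An `ebpr_batch` tibble.
#' @param date Optional cycle date.
#' @param epoch Optional epoch label (`"high"`/`"low"`).
#' @return A one-row tibble with all seven ratios plus `date` and
#'   `epoch` when supplied.
#' @export
cycle_ratios <- function(ts, date = NULL, epoch = NULL) {
  out <- dplyr::bind_cols(anaerobic_ratios(ts), aerobic_ratios(ts))
  if (!is.null(date)) out <- dplyr::bind_cols(tibble(date = as.Date(date)), out)
  if (!is.null(epoch)) out$epoch <- epoch
  out
}

ratio_columns <- function() {
  c("p_per_hac", "gly_per_hac", "phb_per_hac", "phv_per_hac", "pha_per_hac",
    "p_per_pha", "gly_per_pha")
}

#' Summarise per-cycle ratios by aeration epoch
#'
#' Arithmetic mean and sample (n-1) standard deviation of each ratio over
#' the cycles of one epoch, ignoring missing values.  Values are kept at
#' full precision; round only at report time.
#'
#' @param ratios Tibble of per-cycle ratios (one row per cycle) with an
#'   `epoch` column, as from [cycle_ratios()] or [ebpr_cycle_ratios()].
#' @param epoch Optional single epoch label to restrict to.
#' @return A tibble with one row per epoch and ratio: columns `epoch`,
#'   `ratio`, `mean`, `sd`, `n_cycles`.  `sd` is `NA` for a single cycle.
#' @export
#' @examples
#' epoch_summary(ebpr_cycle_ratios())
epoch_summary <- function(ratios, epoch = NULL) {
  if (!"epoch" %in% names(ratios)) stop_validation("`ratios` must carry an `epoch` column")
  if (!is.null(epoch)) {
    ratios <- ratios[ratios$epoch %in% epoch, ]
    if (nrow(ratios) == 0) stop_validation("no cycles in epoch '%s'", paste(epoch, collapse = ","))
  }
  cols <- intersect(ratio_columns(), names(ratios))
  ratios %>%
    tidyr::pivot_longer(all_of(cols), names_to = "ratio", values_to = "value") %>%
    group_by(.data$epoch, .data$ratio) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = if (sum(!is.na(.data$value)) >= 2) sd(.data$value, na.rm = TRUE) else NA_real_,
              n_cycles = sum(!is.na(.data$value)),
              .groups = "drop") %>%
    mutate(ratio = factor(.data$ratio, levels = cols)) %>%
    arrange(.data$epoch, .data$ratio) %>%
    mutate(ratio = as.character(.data$ratio))
}

#' Bundled per-cycle transformation ratios from a full-scale EBPR survey
#'
#' Per-date anaerobic and aerobic transformation ratios measured in
#' lab-scale batch tests on sludge from a full-scale tropical EBPR plant,
#' spanning a high-aeration epoch (four cycles) and a low-aeration epoch
#' (six cycles).  One aerobic glycogen measurement is missing and is
#' recorded as `NA`.  These values are the worked-example input for
#' [epoch_summary()] and [fit_pereira()].
#'
#' @return A tibble with `date`, `epoch` and the seven ratio columns.
#' @export
ebpr_cycle_ratios <- function() {
  path <- system.file("extdata", "batch_cycle_ratios.tsv", package = "ebprtools",
                      mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df$date <- as.Date(df$date)
  df
}
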