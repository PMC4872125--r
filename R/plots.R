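#' Plot a batch-cycle time series
#'
#' Analyte profiles over one anaerobic/aerobic cycle, faceted by
#' analyte, with the phase switch marked.
#'
#' @param object An `ebpr_batch` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebpr_batch <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::any_of(c("acetate", "phosphate", "phb", "phv", "glycogen")),
                              names_to = "analyte", values_to = "value")
  switch_t <- max(object$time_min[object$phase == "anaerobic"])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = switch_t, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration",
                  colour = "phase") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a step-change screen
#'
#' Per-OTU change in log10 normalised abundance against statistical
#' support, with the FDR threshold marked.
#'
#' @param object An `ebpr_changepoint` tibble from [test_step_changes()].
#' @param alpha FDR threshold drawn as a reference.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebpr_changepoint <- function(object, alpha = 0.1, ...) {
  df <- as_tibble(object)
  df$significant <- df$q < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference, y = -log10(.data$p_raw),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                                 name = sprintf("q < %.2g", alpha)) +
    ggplot2::labs(x = "difference in log10 abundance (low - high epoch)",
                  y = expression(-log[10]~p)) +
    ggplot2::theme_minimal()
}

#' Bar plot of normalised probe counts
#'
#' Probe target abundance per sample, normalised to the universal
#' aggregate.
#'
#' @param object A normalised `ebpr_efish` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebpr_efish <- function(object, ...) {
  df <- as_tibble(object)
  if (!"normalized" %in% names(df)) {
    stop_validation("counts are not normalised; call normalize_probe_counts() first")
  }
  df <- df[df$role != "universal", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probe, y = .data$normalized,
                                   fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "hits / universal-probe hits", fill = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heat map of empirical rejection rates
#'
#' @param object An `ebpr_error_rates` tibble from
#'   [simulate_error_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebpr_error_rates <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$rho), y = factor(.data$effect),
                               fill = .data$rejection_rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$rejection_rate)),
                       colour = "white", size = 3) +
    ggplot2::labs(x = expression(AR(1)~rho), y = "effect (s.d. units)",
                  fill = "rejection\nrate") +
    ggplot2::theme_minimal()
}

#' Compare observed epoch ratios with model predictions
#'
#' Dot plot of the per-epoch mean anaerobic ratios beside the canonical
#' model predictions.
#'
#' @param summary Tibble from [epoch_summary()].
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(summary) {
  anaerobic <- c("p_per_hac", "gly_per_hac", "phb_per_hac", "phv_per_hac", "pha_per_hac")
  obs <- summary %>%
    filter(.data$ratio %in% anaerobic) %>%
    mutate(source = paste0("observed (", .data$epoch, ")")) %>%
    select("source", "ratio", value = "mean")
  mod <- model_predictions() %>%
    tidyr::pivot_longer(all_of(anaerobic), names_to = "ratio", values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    select(source = "model", "ratio", "value")
  df <- bind_rows(obs, mod)
  df$ratio <- factor(df$ratio, levels = anaerobic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$value,
                                   colour = .data$source, group = .data$source)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5), size = 2) +
    ggplot2::labs(x = NULL, y = "ratio (C- or P-mol per C-mol)", colour = NULL) +
    ggplot2::theme_minimal()
}
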