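#' Plot a simulated well trajectory
#'
#' Facets the main observables (live/apoptotic/necrotic cells, per-cell
#' mRNA/COX-2/reporter, measured GFP signal, cumulative PGE2, confluence)
#' over time.
#'
#' @param object A `cox2_trajectory` from [simulate_well()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cox2_trajectory <- function(object, ...) {
  long <- as_tibble(object) |>
    select("time_h", "n_live", "n_apop", "n_nec", "mrna", "cox2",
           "gfp_signal", "pge2_pg_ml", "confluence_pct") |>
    tidyr::pivot_longer(-"time_h", names_to = "observable")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = attr(object, "drug")$name) +
    ggplot2::theme_minimal()
}

#' Quadrant plot of screen scores
#'
#' The screen's summary dot plot: confluency score against GFP score per
#' compound, with the hit thresholds as dashed lines and the cytotoxic
#' categories highlighted.
#'
#' @param object A `cox2_scores` table from [score_screen()].
#' @param highlight Categories to colour (default antineoplastic and
#'   anthelmintic).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cox2_scores <- function(object,
                                 highlight = c("antineoplastic", "anthelmintic"),
                                 ...) {
  cfg <- attr(object, "config") %||% scoring_config()
  d <- as_tibble(object) |>
    filter(!.data$qc_autofluorescent) |>
    mutate(group = if_else(.data$category %in% highlight, .data$category,
                           "other"))
  ggplot2::ggplot(d, ggplot2::aes(.data$confluency_score, .data$gfp_score,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.3) +
    ggplot2::geom_hline(yintercept = cfg$gfp_score_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cfg$confluency_score_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(antineoplastic = "#e6550d",
                                            anthelmintic = "#74c0e3",
                                            other = "grey70")) +
    ggplot2::labs(x = "confluency score (mean fold change vs DMSO)",
                  y = "GFP score (time-normalized AUC of fold change)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group-level induction over time
#'
#' @param group_fc Output of [group_fc_over_time()].
#' @return A ggplot.
#' @export
plot_group_fc <- function(group_fc) {
  ggplot2::ggplot(group_fc,
                  ggplot2::aes(.data$time_h, .data$mean_log2fc,
                               colour = .data$label, group = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_log2fc - .data$sd_log2fc,
      ymax = .data$mean_log2fc + .data$sd_log2fc)) +
    ggplot2::labs(x = "time (h)", y = "log2 fold change", colour = "baseline") +
    ggplot2::theme_minimal()
}
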