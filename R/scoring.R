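#' Scoring configuration
#'
#' Thresholds and conventions of the screen's scoring stage. GFP scores are
#' the area under the fold-change curve; the default `time_normalized` mode
#' divides the trapezoidal AUC by the total duration so a flat fold change of
#' 1 (a DMSO-like well) scores 1 and the published hit threshold of 5 reads
#' as "average five-fold induction". `raw_hours` keeps the AUC in
#' fold-change-hours; `baseline_subtracted` subtracts the series' first value
#' before integrating (time-normalized).
#'
#' @param gfp_score_threshold Hit threshold on the GFP score (default 5).
#' @param confluency_score_threshold Hit threshold on the confluency score
#'   (default 0.65).
#' @param control_floor_gcu Floor (GCU) applied to control means before
#'   dividing (default 0.05).
#' @param control_floor_conf Floor (percentage points) for confluence
#'   control means (default 1).
#' @param auc_mode One of `"time_normalized"`, `"raw_hours"`,
#'   `"baseline_subtracted"`.
#' @param qc_early_window_h Autofluorescence QC window (h, default 4).
#' @param qc_early_fc_cutoff GFP fold change above which a compound is
#'   flagged inside the early window (default 2): reporter-driven signal
#'   cannot rise that fast given transcription, translation and maturation
#'   lags, so early jumps indicate compound fluorescence.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(gfp_score_threshold = 5,
                           confluency_score_threshold = 0.65,
                           control_floor_gcu = 0.05,
                           control_floor_conf = 1,
                           auc_mode = c("time_normalized", "raw_hours",
                                        "baseline_subtracted"),
                           qc_early_window_h = 4,
                           qc_early_fc_cutoff = 2) {
  auc_mode <- match.arg(auc_mode)
  stopifnot(gfp_score_threshold > 0, confluency_score_threshold > 0,
            control_floor_gcu > 0, control_floor_conf > 0,
            qc_early_window_h > 0, qc_early_fc_cutoff > 0)
  structure(list(gfp_score_threshold = gfp_score_threshold,
                 confluency_score_threshold = confluency_score_threshold,
                 control_floor_gcu = control_floor_gcu,
                 control_floor_conf = control_floor_conf,
                 auc_mode = auc_mode,
                 qc_early_window_h = qc_early_window_h,
                 qc_early_fc_cutoff = qc_early_fc_cutoff),
            class = "scoring_config")
}

#' Per-plate, per-time mean of control wells
#'
#' Averages the control wells of each plate at each time point — the
#' normalization reference of the screen. Controls are never pooled across
#' plates.
#'
#' @param timeseries Well time-series table (needs `plate_id`, `well`,
#'   `role`, `time_h` and the metric columns).
#' @param role Control role to average (default `"dmso_control"`).
#' @param metrics Metric columns (default confluence and GFP).
#' @return Tibble `plate_id`, `time_h`, one column per metric (the control
#'   mean).
#' @export
control_mean_series <- function(timeseries, role = "dmso_control",
                                metrics = c("confluence_pct", "gfp_mean_gcu")) {
  plates <- unique(timeseries$plate_id)
  have <- unique(timeseries$plate_id[timeseries$role == role])
  missing <- setdiff(plates, have)
  if (length(missing) > 0) {
    abort(paste0("control_mean_series: no '", role, "' wells on plate(s) ",
                 paste(missing, collapse = ", ")))
  }
  timeseries |>
    filter(.data$role == !!role) |>
    group_by(.data$plate_id, .data$time_h) |>
    summarise(across(dplyr::all_of(metrics), mean), .groups = "drop")
}

#' Fold-change series of a well against its plate control mean
#'
#' `FC(t) = well(t) / max(control(t), floor)`.
#'
#' @param well_values,control_values Numeric vectors on a shared grid.
#' @param floor Control floor.
#' @return Fold-change vector.
#' @export
fold_change_series <- function(well_values, control_values, floor = 0.05) {
  if (length(well_values) != length(control_values)) {
    abort("fold_change_series: series lengths differ (grid mismatch)")
  }
  well_values / pmax(control_values, floor)
}

#' GFP score: AUC of the GFP fold-change curve
#'
#' Trapezoidal area under `FC(t)`; by default time-normalized (divided by
#' the duration), so a flat series of 1 scores exactly 1.
#'
#' @param fc Fold-change values.
#' @param times Time grid (h).
#' @param config [scoring_config()] (controls the AUC mode).
#' @return Scalar score.
#' @export
#' @examples
#' gfp_score(seq(1, 9, length.out = 37), seq(0, 72, by = 2))  # 5.0
gfp_score <- function(fc, times, config = scoring_config()) {
  if (length(fc) < 2) abort("gfp_score: need at least 2 time points")
  if (length(fc) != length(times)) abort("gfp_score: grid mismatch")
  y <- switch(config$auc_mode,
              time_normalized = fc,
              raw_hours = fc,
              baseline_subtracted = fc - fc[1])
  a <- trapz(times, y)
  if (config$auc_mode == "raw_hours") a else a / diff(range(times))
}

#' Confluency score: mean confluence fold change
#'
#' Arithmetic mean of the confluence fold change over all acquired time
#' points.
#'
#' @param fc Fold-change values.
#' @return Scalar score.
#' @export
confluency_score <- function(fc) {
  if (length(fc) < 1) abort("confluency_score: empty series")
  mean(fc)
}

#' Autofluorescence QC flag
#'
#' Flags a compound whose GFP fold change exceeds the cutoff at any acquired
#' time inside the early window. A destabilized reporter cannot produce a
#' multi-fold signal within a few hours of dosing, so early jumps are
#' compound fluorescence, not promoter activity.
#'
#' @param fc GFP fold-change values.
#' @param times Time grid (h).
#' @param config [scoring_config()].
#' @return Logical flag.
#' @export
autofluorescence_qc <- function(fc, times, config = scoring_config()) {
  sel <- times <= config$qc_early_window_h & times > 0
  any(fc[sel] > config$qc_early_fc_cutoff)
}

#' Classify a scored compound into hit classes
#'
#' Quadrants at the published thresholds: `arrested_induced` (GFP score
#' above and confluency score below threshold), `arrested_only`,
#' `induced_only`, `inactive`; `excluded` overrides everything for
#' QC-flagged compounds.
#'
#' @param gfp_score,confluency_score Scores.
#' @param qc_autofluorescent Logical QC flag.
#' @param config [scoring_config()].
#' @return Character hit class (vectorized).
#' @export
classify_hits <- function(gfp_score, confluency_score,
                          qc_autofluorescent = FALSE,
                          config = scoring_config()) {
  g <- gfp_score > config$gfp_score_threshold
  a <- confluency_score < config$confluency_score_threshold
  cls <- dplyr::case_when(
    qc_autofluorescent ~ "excluded",
    g & a ~ "arrested_induced",
    a ~ "arrested_only",
    g ~ "induced_only",
    TRUE ~ "inactive")
  cls
}

#' Score every compound of a screen
#'
#' Runs the full scoring stage on a well time-series table: per-plate DMSO
#' control means per time point, per-well GFP and confluence fold-change
#' curves, time-normalized GFP score (AUC) and confluency score (mean),
#' autofluorescence QC, and hit classification.
#'
#' @param timeseries Table from [generate_timeseries()] or
#'   [segment_timelapse()] joined with roles/compounds (columns `plate_id`,
#'   `well`, `role`, `compound_id`, `time_h`, `confluence_pct`,
#'   `gfp_mean_gcu`).
#' @param library Compound library (for `category`).
#' @param config [scoring_config()].
#' @return A tibble of class `cox2_scores`: `compound_id`, `name`,
#'   `category`, `gfp_score`, `confluency_score`, `qc_autofluorescent`,
#'   `hit_class`.
#' @export
#' @examples
#' scr <- simulate_screen(library_spec(n_total = 40,
#'   category_counts = c(antineoplastic = 10),
#'   category_props = c(antibacterial = 0.5)), seed = 1)
#' score_screen(scr$timeseries, scr$library)
score_screen <- function(timeseries, library, config = scoring_config()) {
  ctrl <- control_mean_series(timeseries, "dmso_control")
  joined <- timeseries |>
    filter(.data$role == "compound") |>
    inner_join(ctrl, by = c("plate_id", "time_h"), suffix = c("", "_ctrl")) |>
    arrange(.data$plate_id, .data$well, .data$time_h)

  scores <- joined |>
    group_by(.data$plate_id, .data$well, .data$compound_id) |>
    summarise(
      gfp_score = gfp_score(
        fold_change_series(.data$gfp_mean_gcu, .data$gfp_mean_gcu_ctrl,
                           config$control_floor_gcu),
        .data$time_h, config),
      confluency_score = confluency_score(
        fold_change_series(.data$confluence_pct, .data$confluence_pct_ctrl,
                           config$control_floor_conf)),
      qc_autofluorescent = autofluorescence_qc(
        fold_change_series(.data$gfp_mean_gcu, .data$gfp_mean_gcu_ctrl,
                           config$control_floor_gcu),
        .data$time_h, config),
      .groups = "drop")

  out <- scores |>
    left_join(library |> select("compound_id", "name", "category"),
              by = "compound_id") |>
    mutate(hit_class = classify_hits(.data$gfp_score, .data$confluency_score,
                                     .data$qc_autofluorescent, config)) |>
    select("compound_id", "name", "category", "gfp_score",
           "confluency_score", "qc_autofluorescent", "hit_class")
  class(out) <- c("cox2_scores", class(out))
  attr(out, "config") <- config
  out
}

#' Confluency-GFP correlation within a therapeutic category
#'
#' Spearman rank correlation between confluency and GFP scores over the
#' QC-passing compounds of one category — the screen's headline statistic
#' (strongly negative for cytotoxic categories: compounds that arrest
#' growth induce the reporter).
#'
#' @param scores Table from [score_screen()].
#' @param category Category label.
#' @return A `cox2_cor` object (see [spearman_cor()]).
#' @export
category_correlation <- function(scores, category) {
  rows <- scores[scores$category == category & !scores$qc_autofluorescent, ]
  if (nrow(rows) < 4) {
    abort(paste0("category_correlation: need >= 4 QC-passing compounds in '",
                 category, "', got ", nrow(rows)))
  }
  spearman_cor(rows$confluency_score, rows$gfp_score)
}
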