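#' Pipeline configuration
#'
#' One place for every tunable constant of the pipeline, each overridable
#' and serializable to YAML ([write_config()] / [read_config()]). The
#' defaults are the screen's published constants (10 um top-hat radius,
#' 0.2 GCU threshold, 80/250 um^2 area filters, score thresholds 5 / 0.65,
#' 9 control wells of each role on the 240 inner wells, 72 h every 2 h) plus
#' this package's documented simulation defaults.
#'
#' @param seed Integer seed.
#' @param times Acquisition grid (h).
#' @param segmentation [seg_params()].
#' @param scoring [scoring_config()].
#' @param library [library_spec()].
#' @param acquisition [acquisition_config()].
#' @param render [render_params()].
#' @param panel [panel_spec()].
#' @param outdir Output directory for pipeline runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, times = seq(0, 72, by = 2),
                            segmentation = seg_params(),
                            scoring = scoring_config(),
                            library = library_spec(),
                            acquisition = acquisition_config(times = times),
                            render = render_params(),
                            panel = panel_spec(),
                            outdir = "cox2screen_out") {
  structure(list(seed = as.integer(seed), times = times,
                 segmentation = segmentation, scoring = scoring,
                 library = library, acquisition = acquisition,
                 render = render, panel = panel, outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- purrr::map(x, strip)
      attributes(x) <- list(names = names(x))
    } else if (is.atomic(x) && !is.null(names(x))) {
      x <- as.list(x)  # yaml drops names of atomic vectors; maps keep them
    }
    x
  }
  cls <- purrr::map(config, function(x) class(x)[1])
  yaml::write_yaml(list(classes = strip(cls), values = strip(config)), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- raw$values
  restore <- function(x, cls) {
    if (!is.null(cls) && cls %in% c("seg_params", "scoring_config",
                                    "library_spec", "acquisition_config",
                                    "render_params", "panel_spec",
                                    "pipeline_config")) {
      class(x) <- cls
    }
    x
  }
  # tibbles inside library_spec come back as lists of columns
  if (!is.null(vals$library$autofluorescent)) {
    vals$library$autofluorescent <- as_tibble(vals$library$autofluorescent)
  }
  renum <- function(v) {
    if (is.list(v)) v <- unlist(v)
    storage.mode(v) <- "double"
    v
  }
  for (fld in c("category_counts", "category_props")) {
    vals$library[[fld]] <- renum(vals$library[[fld]])
  }
  for (fld in c("fc_frac", "fc_frac_noise_sd")) {
    vals$panel[[fld]] <- renum(vals$panel[[fld]])
  }
  vals$times <- as.numeric(unlist(vals$times))
  vals$acquisition$times <- as.numeric(unlist(vals$acquisition$times))
  out <- purrr::imap(vals, function(x, nm) restore(x, raw$classes[[nm]]))
  class(out) <- "pipeline_config"
  out
}

# run-info sidecar: parameters + seed + package version for reproducibility
write_run_info <- function(outdir, config, stage) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  info <- c(sprintf("stage: %s", stage),
            sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            sprintf("package_version: %s",
                    as.character(utils::packageVersion("cox2screen"))),
            sprintf("seed: %d", config$seed))
  writeLines(info, file.path(outdir, paste0("run_info_", stage, ".txt")))
  write_config(config, file.path(outdir, paste0("config_", stage, ".yaml")))
  invisible(outdir)
}

#' Run the screen-simulation stage and write its tables
#'
#' Simulates the synthetic screen (fast path) and writes `library.csv`,
#' `platemap.csv` and `timeseries.csv` (plus a run-info sidecar) to
#' `config$outdir`. All writes are atomic.
#'
#' @param config [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_simulate_screen <- function(config = pipeline_config()) {
  scr <- simulate_screen(config$library, seed = config$seed,
                         config = config$acquisition)
  out <- config$outdir
  write_run_info(out, config, "simulate_screen")
  write_csv_atomic(scr$library, file.path(out, "library.csv"))
  write_csv_atomic(scr$layouts, file.path(out, "platemap.csv"))
  write_csv_atomic(scr$timeseries, file.path(out, "timeseries.csv"))
  invisible(out)
}

#' Run the scoring stage from CSV inputs
#'
#' Reads a time-series table, plate map and library from CSV, scores every
#' compound, and writes `scores.csv` and `correlations.csv` (Spearman
#' confluency-GFP correlation per category with >= 4 QC-passing compounds).
#'
#' @param timeseries_csv,platemap_csv,library_csv Input files.
#' @param config [pipeline_config()].
#' @return The scores tibble, invisibly.
#' @export
run_score <- function(timeseries_csv, platemap_csv, library_csv,
                      config = pipeline_config()) {
  ts <- read_csv_quiet(timeseries_csv)
  lib <- read_csv_quiet(library_csv)
  for (col in c("plate_id", "well", "role", "time_h", "confluence_pct",
                "gfp_mean_gcu")) {
    if (!col %in% names(ts)) {
      abort(paste0("run_score: ", timeseries_csv, " lacks column '", col, "'"))
    }
  }
  if (!"compound_id" %in% names(ts)) {
    pm <- read_csv_quiet(platemap_csv)
    ts <- left_join(ts, pm[, c("plate_id", "well", "role", "compound_id")],
                    by = c("plate_id", "well", "role"))
  }
  scores <- score_screen(ts, lib, config$scoring)
  cors <- purrr::map_dfr(
    sort(unique(scores$category)), function(cat) {
      ok <- sum(scores$category == cat & !scores$qc_autofluorescent)
      if (ok < 4) return(NULL)
      cc <- category_correlation(scores, cat)
      tibble(category = cat, rho = cc$rho, p_value = cc$p_value, n = cc$n)
    })
  out <- config$outdir
  write_run_info(out, config, "score")
  write_csv_atomic(as_tibble(scores), file.path(out, "scores.csv"))
  write_csv_atomic(cors, file.path(out, "correlations.csv"))
  invisible(scores)
}

#' Run the expression-pharmacodynamics stage
#'
#' Either simulates a panel (`baseline_csv = NULL`) or reads panel CSVs,
#' then writes `split.csv` (baseline pos/neg call), `sensitivity.csv`
#' (per-drug GI50-induction Spearman correlation) and `group_fc.csv`
#' (group-level induction over time).
#'
#' @param config [pipeline_config()].
#' @param baseline_csv,fc_csv,gi50_csv Optional CSV inputs (`line_id,
#'   log2_expr`; `line_id, drug, time_h, log2fc`; `line_id, drug,
#'   log10_gi50`).
#' @return The baseline split, invisibly.
#' @export
run_expression <- function(config = pipeline_config(), baseline_csv = NULL,
                           fc_csv = NULL, gi50_csv = NULL) {
  if (is.null(baseline_csv)) {
    panel <- simulate_panel(config$panel, seed = config$seed)
  } else {
    panel <- structure(list(baseline = read_csv_quiet(baseline_csv),
                            fc = read_csv_quiet(fc_csv),
                            gi50 = read_csv_quiet(gi50_csv)),
                       class = "expression_panel")
  }
  split <- split_baseline(panel$baseline)
  drugs <- sort(unique(panel$fc$drug))
  sens <- purrr::map_dfr(drugs, function(dr) {
    cc <- tryCatch(sensitivity_correlation(panel, dr), error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    tibble(drug = dr, rho = cc$rho, p_value = cc$p_value, n = cc$n)
  })
  gfc <- purrr::map_dfr(drugs, function(dr) {
    mutate(group_fc_over_time(panel, split, dr), drug = dr, .before = 1)
  })
  out <- config$outdir
  write_run_info(out, config, "expression")
  write_csv_atomic(tibble(as_tibble(split),
                          threshold = attr(split, "threshold")),
                   file.path(out, "split.csv"))
  write_csv_atomic(sens, file.path(out, "sensitivity.csv"))
  write_csv_atomic(gfc, file.path(out, "group_fc.csv"))
  if (is.null(baseline_csv)) {
    write_csv_atomic(panel$baseline, file.path(out, "baseline.csv"))
    write_csv_atomic(panel$fc, file.path(out, "fc.csv"))
    write_csv_atomic(panel$gi50, file.path(out, "gi50.csv"))
  }
  invisible(split)
}
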