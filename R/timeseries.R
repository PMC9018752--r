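#' Acquisition settings for the synthetic screen
#'
#' Fixed linear calibration from per-cell reporter signal to instrument Green
#' Calibrated Units (`gcu = kappa * gfp_signal + b0`), multiplicative
#' lognormal measurement noise, and the imaging grid. `kappa = 0.3`, `b0 = 0`
#' puts untreated reporter wells at ~0.3 GCU baseline.
#'
#' @param kappa GCU per unit reporter signal.
#' @param b0 Additive GCU offset of the instrument calibration.
#' @param noise_sd Lognormal sd of multiplicative measurement noise applied
#'   independently per well and time point to confluence and GFP mean.
#' @param times Acquisition grid (h); default every 2 h over 72 h (37 points).
#' @param field_count Imaged fields per well (means are averaged over fields).
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(kappa = 0.3, b0 = 0, noise_sd = 0.05,
                               times = seq(0, 72, by = 2), field_count = 1) {
  stopifnot(kappa > 0, b0 >= 0, noise_sd >= 0, field_count >= 1)
  structure(list(kappa = kappa, b0 = b0, noise_sd = noise_sd,
                 times = times, field_count = field_count),
            class = "acquisition_config")
}

#' Generate per-well time series for laid-out plates (fast path)
#'
#' Simulates every non-buffer well of the layouts with [simulate_well()]:
#' compound wells use the compound's ground-truth effect, `dmso_control`
#' wells the DMSO preset and `pos_control` wells the 5-FU preset. The
#' measured GFP mean is `kappa * gfp_signal + b0` (plus a constant offset for
#' autofluorescent compounds, present from t = 0); confluence and GFP then
#' receive independent multiplicative lognormal noise per time point. With
#' `field_count > 1`, each field is measured with independent noise and the
#' per-well value is the mean over fields.
#'
#' @param layouts Plate layouts from [build_plate_layouts()].
#' @param library Compound library from [build_library()].
#' @param params Cell-line parameters (default the 4T1 reporter preset).
#' @param config [acquisition_config()].
#' @param seed Integer seed; same seed, same table.
#' @return A tibble: `plate_id`, `well`, `role`, `compound_id`, `time_h`,
#'   `confluence_pct`, `gfp_mean_gcu`.
#' @export
#' @examples
#' lib <- build_library(seed = 1)[1:4, ]
#' lay <- build_plate_layouts(lib)
#' ts <- generate_timeseries(lay, lib, seed = 1)
generate_timeseries <- function(layouts, library, params = preset("4T1"),
                                config = acquisition_config(), seed = 1) {
  wells <- layouts[layouts$role %in% c("compound", "dmso_control", "pos_control"), ]
  cpd <- wells$role == "compound"
  dangling <- cpd & !(wells$compound_id %in% library$compound_id)
  if (any(dangling)) {
    abort(paste0("generate_timeseries: no library record for compound well(s) ",
                 paste(paste0(wells$plate_id[dangling], ":", wells$well[dangling]),
                       collapse = ", ")))
  }

  # one deterministic trajectory per distinct treatment
  effects <- c(
    list(.dmso = preset("DMSO"), .pos = preset("5FU_100uM")),
    purrr::map(split(library, library$compound_id), compound_effect)
  )
  trajs <- purrr::map(effects, function(d) {
    tr <- simulate_well(params, d, times = config$times)
    tibble(time_h = tr$time_h, confluence_pct = tr$confluence_pct,
           gcu = config$kappa * tr$gfp_signal + config$b0)
  })
  offset <- setNames(library$autofl_offset_gcu, library$compound_id)

  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(wells)), function(i) {
      key <- switch(wells$role[i], dmso_control = ".dmso", pos_control = ".pos",
                    wells$compound_id[i])
      tr <- trajs[[key]]
      off <- if (wells$role[i] == "compound") offset[[key]] else 0
      nt <- nrow(tr)
      nf <- config$field_count
      noise <- function() {
        if (config$noise_sd == 0) return(rep(1, nt))
        rowMeans(matrix(exp(rnorm(nt * nf, 0, config$noise_sd)), nt, nf))
      }
      tibble(plate_id = wells$plate_id[i], well = wells$well[i],
             role = wells$role[i],
             compound_id = wells$compound_id[i],
             time_h = tr$time_h,
             confluence_pct = pmin(100, tr$confluence_pct * noise()),
             gfp_mean_gcu = (tr$gcu + off) * noise())
    })
  })
}

#' Run the full synthetic screen fast path
#'
#' Convenience wrapper: draw the library, lay out plates, and generate the
#' per-well time-series table.
#'
#' @param spec [library_spec()].
#' @param seed Integer seed used for both the library draw and the
#'   measurement noise.
#' @param params,config Passed to [generate_timeseries()].
#' @return A list with `library`, `layouts`, `timeseries`.
#' @export
simulate_screen <- function(spec = library_spec(), seed = 1,
                            params = preset("4T1"),
                            config = acquisition_config()) {
  lib <- build_library(spec, seed = seed)
  lay <- build_plate_layouts(lib)
  ts <- generate_timeseries(lay, lib, params = params, config = config,
                            seed = seed + 1L)
  list(library = lib, layouts = lay, timeseries = ts)
}
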