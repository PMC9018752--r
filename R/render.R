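#' Rendering parameters for synthetic two-channel fields
#'
#' Controls the synthetic microscope: field geometry, cell shapes and
#' intensity statistics, background structure and noise. Cells are placed in
#' loose colonies (adherent epithelial cells grow clustered, and the
#' confluence mask's `> 250 um^2` debris filter presumes multi-cell
#' components); each cell is an ellipse with a parabolic radial intensity
#' profile (bright centre, dim rim), which is also what lets compact cells
#' survive white top-hat subtraction the way real cells do.
#'
#' @param width_px,height_px Field size in pixels.
#' @param um_per_px Pixel size (um/px).
#' @param cell_axis_um Range of ellipse axis lengths (um).
#' @param gfp_lognorm_sd Lognormal sd of per-cell GFP brightness around the
#'   well's per-cell level.
#' @param bg_n_blobs,bg_sigma_um,bg_amplitude_gcu Smooth background: number
#'   of Gaussian blobs, their width, and the max amplitude (GCU).
#' @param read_noise_gcu Gaussian read noise sd (GCU).
#' @param precip_diam_um,precip_gcu Diameter and intensity ranges of
#'   punctate autofluorescent precipitates.
#' @param cluster_mean_cells Mean cells per colony (Poisson + 1).
#' @param cluster_sd_um Spread of cells around their colony centre.
#' @param phase_bg,phase_texture_sd Phase-channel background level and
#'   within-cell texture sd.
#' @return A `render_params` list.
#' @export
render_params <- function(width_px = 512, height_px = 512, um_per_px = 2,
                          cell_axis_um = c(12, 30), gfp_lognorm_sd = 0.3,
                          bg_n_blobs = 3, bg_sigma_um = 150,
                          bg_amplitude_gcu = 0.15, read_noise_gcu = 0.02,
                          precip_diam_um = c(12, 20), precip_gcu = c(0.5, 2),
                          cluster_mean_cells = 4, cluster_sd_um = 30,
                          phase_bg = 0.5, phase_texture_sd = 0.12) {
  stopifnot(width_px >= 32, height_px >= 32, um_per_px > 0)
  structure(list(width_px = width_px, height_px = height_px,
                 um_per_px = um_per_px, cell_axis_um = cell_axis_um,
                 gfp_lognorm_sd = gfp_lognorm_sd, bg_n_blobs = bg_n_blobs,
                 bg_sigma_um = bg_sigma_um, bg_amplitude_gcu = bg_amplitude_gcu,
                 read_noise_gcu = read_noise_gcu,
                 precip_diam_um = precip_diam_um, precip_gcu = precip_gcu,
                 cluster_mean_cells = cluster_mean_cells,
                 cluster_sd_um = cluster_sd_um, phase_bg = phase_bg,
                 phase_texture_sd = phase_texture_sd),
            class = "render_params")
}

# Place n non-overlapping cells (circle approximation) in colonies.
# Returns a data.frame of centres (px), semi-axes (px) and orientation.
.place_cells <- function(n, rp) {
  if (n == 0) {
    return(data.frame(cx = numeric(), cy = numeric(), a = numeric(),
                      b = numeric(), theta = numeric()))
  }
  ppu <- 1 / rp$um_per_px
  ax <- matrix(runif(2 * n, rp$cell_axis_um[1], rp$cell_axis_um[2]), n, 2)
  a <- ax[, 1] / 2 * ppu; b <- ax[, 2] / 2 * ppu   # semi-axes, px
  rad <- sqrt(a * b)
  margin <- max(rad) + 2
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0
  csd <- rp$cluster_sd_um * ppu
  while (placed < n) {
    ccx <- runif(1, margin, rp$width_px - margin)
    ccy <- runif(1, margin, rp$height_px - margin)
    size <- 1 + stats::rpois(1, rp$cluster_mean_cells - 1)
    for (k in seq_len(min(size, n - placed))) {
      ok <- FALSE
      for (try in 1:40) {
        px <- ccx + rnorm(1, 0, csd); py <- ccy + rnorm(1, 0, csd)
        if (px < margin || px > rp$width_px - margin ||
            py < margin || py > rp$height_px - margin) next
        i <- placed + 1
        if (placed > 0) {
          dd <- sqrt((cx[1:placed] - px)^2 + (cy[1:placed] - py)^2)
          if (any(dd < rad[1:placed] + rad[i] + 0.5)) next
        }
        cx[i] <- px; cy[i] <- py; ok <- TRUE; break
      }
      if (ok) placed <- placed + 1
    }
  }
  data.frame(cx = cx, cy = cy, a = a, b = b, theta = runif(n, 0, pi))
}

#' Render one two-channel field with ground truth
#'
#' Draws a synthetic phase + green field for one well at one time point.
#' Live and apoptotic cells are rendered as elliptical colonies; each cell's
#' green intensity is its well-level per-cell GCU (`gcu_per_cell`, scaled by
#' `w_apop` for apoptotic cells) times lognormal cell-to-cell variation,
#' shaped by a parabolic radial profile. The green background is a smooth
#' Gaussian-blob field plus read noise; autofluorescent wells additionally
#' carry bright punctate precipitates. The returned manifest lists every
#' rendered object with its centroid, area and true mean GCU (profile mean,
#' before background/noise).
#'
#' @param well_state List with `n_live`, `n_apop` (cell counts),
#'   `gcu_per_cell` (per-cell GCU of a live cell), optional `w_apop`
#'   (default 0.95), `n_precip` (precipitate count, default 0).
#' @param rp [render_params()].
#' @param seed Integer seed.
#' @return List with `green` and `phase` matrices (row = y) and `truth`
#'   tibble (`id`, `type`, `x_um`, `y_um`, `area_um2`, `mean_gcu`).
#' @export
render_field <- function(well_state, rp = render_params(), seed = 1) {
  n_live <- as.integer(well_state$n_live %||% 0)
  n_apop <- as.integer(well_state$n_apop %||% 0)
  n_prec <- as.integer(well_state$n_precip %||% 0)
  w_apop <- well_state$w_apop %||% 0.95
  gcu <- well_state$gcu_per_cell %||% 0.3
  n <- n_live + n_apop
  field_area <- rp$width_px * rp$height_px * rp$um_per_px^2
  mean_cell <- pi / 4 * mean(rp$cell_axis_um)^2
  if (n * mean_cell > field_area) {
    abort("render_field: requested cell count exceeds 100% confluence")
  }

  withr::with_seed(seed, {
    nr <- rp$height_px; nc <- rp$width_px
    green <- matrix(0, nr, nc)
    phase <- matrix(rp$phase_bg, nr, nc)

    # smooth green background: Gaussian blobs, scale >= blob sigma
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), nc), nr, nc)
    for (bbi in seq_len(rp$bg_n_blobs)) {
      bx <- runif(1, 1, nc); by <- runif(1, 1, nr)
      amp <- runif(1, 0.3, 1) * rp$bg_amplitude_gcu
      sg <- rp$bg_sigma_um / rp$um_per_px
      green <- green + amp * exp(-((xs - bx)^2 + (ys - by)^2) / (2 * sg^2))
    }

    cells <- .place_cells(n, rp)
    type <- c(rep("live", n_live), rep("apop", n_apop))
    i0 <- gcu * exp(rnorm(n, 0, rp$gfp_lognorm_sd)) * 2  # profile mean = i0/2
    i0[type == "apop"] <- i0[type == "apop"] * w_apop
    truth <- vector("list", n + n_prec)
    for (i in seq_len(n)) {
      ci <- cells[i, ]
      ext <- max(ci$a, ci$b)
      x0 <- max(1, floor(ci$cx - ext)); x1 <- min(nc, ceiling(ci$cx + ext))
      y0 <- max(1, floor(ci$cy - ext)); y1 <- min(nr, ceiling(ci$cy + ext))
      gx <- x0:x1; gy <- y0:y1
      dx <- outer(rep(1, length(gy)), gx - ci$cx)
      dy <- outer(gy - ci$cy, rep(1, length(gx)))
      u <- (dx * cos(ci$theta) + dy * sin(ci$theta)) / ci$a
      v <- (-dx * sin(ci$theta) + dy * cos(ci$theta)) / ci$b
      rho2 <- u^2 + v^2
      inside <- rho2 <= 1
      prof <- i0[i] * pmax(0, 1 - rho2)
      green[gy, gx][inside] <- green[gy, gx][inside] + prof[inside]
      ph_tex <- rnorm(sum(inside), 0.08, rp$phase_texture_sd)
      phase[gy, gx][inside] <- phase[gy, gx][inside] + ph_tex
      truth[[i]] <- tibble(
        id = i, type = type[i],
        x_um = ci$cx * rp$um_per_px, y_um = ci$cy * rp$um_per_px,
        area_um2 = sum(inside) * rp$um_per_px^2,
        mean_gcu = mean(prof[inside]))
    }

    for (j in seq_len(n_prec)) {
      d <- runif(1, rp$precip_diam_um[1], rp$precip_diam_um[2]) / rp$um_per_px
      amp <- runif(1, rp$precip_gcu[1], rp$precip_gcu[2])
      px <- runif(1, d, nc - d); py <- runif(1, d, nr - d)
      x0 <- max(1, floor(px - d)); x1 <- min(nc, ceiling(px + d))
      y0 <- max(1, floor(py - d)); y1 <- min(nr, ceiling(py + d))
      gx <- x0:x1; gy <- y0:y1
      rho2 <- (outer(rep(1, length(gy)), gx - px)^2 +
               outer(gy - py, rep(1, length(gx)))^2) / (d / 2)^2
      inside <- rho2 <= 1
      green[gy, gx][inside] <- green[gy, gx][inside] + amp
      truth[[n + j]] <- tibble(
        id = n + j, type = "precipitate",
        x_um = px * rp$um_per_px, y_um = py * rp$um_per_px,
        area_um2 = sum(inside) * rp$um_per_px^2, mean_gcu = amp)
    }

    green <- green + matrix(rnorm(nr * nc, 0, rp$read_noise_gcu), nr, nc)
    green[green < 0] <- 0
    phase <- phase + matrix(rnorm(nr * nc, 0, 0.005), nr, nc)
    phase[phase < 0] <- 0; phase[phase > 1] <- 1
    list(green = green, phase = phase,
         truth = if (n + n_prec > 0) bind_rows(truth) else
           tibble(id = integer(), type = character(), x_um = numeric(),
                  y_um = numeric(), area_um2 = numeric(), mean_gcu = numeric()))
  })
}

#' Write a rendered field as 16-bit TIFFs and return manifest rows
#'
#' Files are named `{plate}_{well}_{t:03d}h_{channel}.tif`. The green
#' channel is stored as GCU / `gcu_scale` of full scale; phase is stored
#' as-is in `[0, 1]`.
#'
#' @param field Result of [render_field()].
#' @param dir Output directory (created if needed).
#' @param plate_id,well,time_h Identifiers for naming.
#' @param gcu_scale GCU value mapped to full scale (keep consistent with
#'   [seg_params()]).
#' @return Tibble of manifest rows (`plate_id`, `well`, `time_h`, `channel`,
#'   `path`).
#' @export
write_field_images <- function(field, dir, plate_id, well, time_h,
                               gcu_scale = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- sprintf("%s_%s_%03dh", plate_id, well, as.integer(time_h))
  gp <- file.path(dir, paste0(base, "_green.tif"))
  pp <- file.path(dir, paste0(base, "_phase.tif"))
  g <- pmin(field$green / gcu_scale, 1)
  EBImage::writeImage(g, gp, type = "tiff", bits.per.sample = 16L)
  EBImage::writeImage(pmin(field$phase, 1), pp, type = "tiff",
                      bits.per.sample = 16L)
  tibble(plate_id = plate_id, well = well, time_h = time_h,
         channel = c("green", "phase"), path = c(gp, pp))
}
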