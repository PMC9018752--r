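#' Segmentation parameters for the two analysis masks
#'
#' Settings of the GFP-object mask (white top-hat background subtraction,
#' GCU threshold, area filter) and the confluence mask (local texture
#' segmentation with a debris area filter), matching the screen's published
#' analysis definitions: top-hat radius 10 um, threshold 0.2 GCU, GFP area
#' filter > 80 um^2, confluence area filter > 250 um^2. Area filters are
#' strict inequalities.
#'
#' @param um_per_px Pixel size (um/px), > 0.
#' @param tophat_radius_um Disc radius of the top-hat structuring element (um).
#' @param gcu_threshold GFP mask threshold (GCU), applied to the
#'   background-subtracted image.
#' @param gfp_min_area_um2 GFP objects must exceed this area (um^2, strict).
#' @param confluence_min_area_um2 Confluence components must exceed this area
#'   (um^2, strict); excludes cell debris.
#' @param connectivity Pixel connectivity for components, 4 or 8.
#' @param texture_window_um Side of the local standard-deviation window used
#'   by the confluence mask (um).
#' @param texture_threshold Local-sd cutoff separating textured (cellular)
#'   from smooth background pixels.
#' @param gcu_scale GCU value mapped to full scale when reading/writing
#'   16-bit green-channel TIFFs.
#' @return A `seg_params` list.
#' @export
seg_params <- function(um_per_px = 2, tophat_radius_um = 10,
                       gcu_threshold = 0.2, gfp_min_area_um2 = 80,
                       confluence_min_area_um2 = 250, connectivity = 8,
                       texture_window_um = 10, texture_threshold = 0.06,
                       gcu_scale = 4) {
  if (um_per_px <= 0) abort("seg_params: um_per_px must be > 0")
  if (!connectivity %in% c(4, 8)) abort("seg_params: connectivity must be 4 or 8")
  if (gcu_threshold <= 0 || gfp_min_area_um2 <= 0 || confluence_min_area_um2 <= 0 ||
      texture_threshold <= 0) {
    abort("seg_params: thresholds and area filters must be > 0")
  }
  structure(list(um_per_px = um_per_px, tophat_radius_um = tophat_radius_um,
                 gcu_threshold = gcu_threshold,
                 gfp_min_area_um2 = gfp_min_area_um2,
                 confluence_min_area_um2 = confluence_min_area_um2,
                 connectivity = connectivity,
                 texture_window_um = texture_window_um,
                 texture_threshold = texture_threshold,
                 gcu_scale = gcu_scale),
            class = "seg_params")
}

#' White top-hat background subtraction
#'
#' Subtracts the morphological opening (disc structuring element) from the
#' image: structures wider than the disc — i.e. slowly varying background —
#' are removed, compact bright objects are kept. The disc radius is
#' `round(tophat_radius_um / um_per_px)` pixels.
#'
#' @param image Numeric matrix (single channel, GCU).
#' @param params [seg_params()].
#' @return Background-subtracted matrix, non-negative everywhere.
#' @export
tophat <- function(image, params = seg_params()) {
  r <- round(params$tophat_radius_um / params$um_per_px)
  if (r < 1) abort("tophat: structuring-element radius is < 1 px at this pixel scale")
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  opened <- EBImage::opening(image, brush)
  out <- image - opened
  out[out < 0] <- 0
  out
}

# Connected-component labelling at 4- or 8-connectivity.
# EBImage::bwlabel is 4-connected; for 8-connectivity, 4-labels that touch
# diagonally are merged with a union-find pass.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1) return(lab)

  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Detect GFP-positive objects in a background-subtracted image
#'
#' Thresholds the (already top-hat subtracted) green image at
#' `gcu_threshold`, labels connected components, and keeps components whose
#' area strictly exceeds `gfp_min_area_um2`. Each object is one cell or a
#' small cluster of neighbouring cells. The per-object mean is computed on
#' the same subtracted image the threshold was applied to (configurable by
#' passing a different `measure_image`), so the mean may fall below the
#' threshold even though every pixel passed it before averaging regions near
#' the cutoff.
#'
#' @param image Background-subtracted green image (GCU), e.g. from
#'   [tophat()].
#' @param params [seg_params()].
#' @param measure_image Image on which per-object means are measured
#'   (defaults to `image` itself).
#' @return A tibble with one row per object: `label`, `area_um2`,
#'   `mean_gcu`, `x_um`, `y_um` (centroid, origin top-left, x right/y down).
#' @export
detect_gfp_objects <- function(image, params = seg_params(),
                               measure_image = image) {
  mask <- image >= params$gcu_threshold
  if (!any(mask)) {
    return(tibble(label = integer(), area_um2 = numeric(),
                  mean_gcu = numeric(), x_um = numeric(), y_um = numeric()))
  }
  lab <- label_components(mask, params$connectivity)
  px_area <- params$um_per_px^2
  idx <- which(lab > 0)
  labs <- lab[idx]
  # row index = y (down), column index = x (right); 0-based pixel centres
  rr <- (idx - 1) %% nrow(lab)
  cc <- (idx - 1) %/% nrow(lab)
  vals <- measure_image[idx]
  agg <- tibble(label = labs, v = vals, x = cc, y = rr) |>
    group_by(.data$label) |>
    summarise(area_um2 = n() * px_area,
              mean_gcu = mean(.data$v),
              x_um = (mean(.data$x) + 0.5) * params$um_per_px,
              y_um = (mean(.data$y) + 0.5) * params$um_per_px,
              .groups = "drop")
  out <- agg[agg$area_um2 > params$gfp_min_area_um2, ]
  out$label <- seq_len(nrow(out))
  out
}

#' Mean well GFP intensity over detected objects
#'
#' Unweighted mean of the per-object mean intensities; pooled across fields
#' when objects from several fields of the same well are concatenated.
#' Defined as 0 when no objects were detected ("no signal").
#'
#' @param objects Object table from [detect_gfp_objects()] (one or several
#'   fields row-bound together).
#' @return Mean GCU (scalar).
#' @export
well_gfp_mean <- function(objects) {
  if (is.null(objects) || nrow(objects) == 0) return(0)
  mean(objects$mean_gcu)
}

#' Percent confluence from a phase-contrast-like image
#'
#' Segments cell-covered area by local texture: the standard deviation in a
#' square window (`texture_window_um`) is compared with `texture_threshold`;
#' the binary mask is eroded by half the window (undoing the dilation the
#' windowed filter applies to textured regions), components with area
#' `<= confluence_min_area_um2` are dropped as debris, and the covered
#' fraction of the field is returned as a percentage.
#'
#' @param phase_image Numeric matrix (phase-like channel).
#' @param params [seg_params()].
#' @return Percent of image area covered (0-100).
#' @export
confluence_percent <- function(phase_image, params = seg_params()) {
  w <- max(3L, 2L * floor(params$texture_window_um / params$um_per_px / 2) + 1L)
  kern <- matrix(1 / (w * w), w, w)
  m1 <- EBImage::filter2(phase_image, kern, boundary = "replicate")
  m2 <- EBImage::filter2(phase_image^2, kern, boundary = "replicate")
  s <- sqrt(pmax(m2 - m1^2, 0))
  mask <- s > params$texture_threshold
  if (!any(mask)) return(0)
  # erode by a quarter window: the std window marks a ~w/2 halo around
  # texture edges; a 1-px erosion at the default window keeps isolated thin
  # cells while trimming most of the halo
  er <- max(1L, floor(w / 4))
  if (er >= 1) {
    mask <- EBImage::erode(mask, EBImage::makeBrush(2L * er + 1L, shape = "disc")) > 0
  }
  if (!any(mask)) return(0)
  lab <- label_components(mask, params$connectivity)
  px_area <- params$um_per_px^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * px_area > params$confluence_min_area_um2)
  100 * sum(sizes[keep]) / length(phase_image)
}

#' Segment a rendered time-lapse into a per-well time-series table
#'
#' Applies [tophat()] + [detect_gfp_objects()] + [well_gfp_mean()] to each
#' green frame and [confluence_percent()] to each phase frame listed in an
#' image manifest, and assembles the measured `WellTimeSeries` table. Missing
#' time points simply yield no row (no interpolation).
#'
#' @param manifest Data frame with columns `plate_id`, `well`, `time_h`,
#'   `channel` (`"green"`/`"phase"`), `path` (TIFF files, written by
#'   [write_field_images()]).
#' @param params [seg_params()].
#' @return A tibble: `plate_id`, `well`, `time_h`, `confluence_pct`,
#'   `gfp_mean_gcu`, `n_gfp_objects`, sorted by plate, well, time.
#' @export
segment_timelapse <- function(manifest, params = seg_params()) {
  missing <- !file.exists(manifest$path)
  if (any(missing)) {
    abort(paste0("segment_timelapse: image file not found: ",
                 paste(utils::head(manifest$path[missing], 3), collapse = ", ")))
  }
  keys <- split(manifest, list(manifest$plate_id, manifest$well, manifest$time_h),
                drop = TRUE)
  rows <- purrr::map(keys, function(mf) {
    gr <- mf[mf$channel == "green", ]
    ph <- mf[mf$channel == "phase", ]
    objs <- purrr::map_dfr(gr$path, function(p) {
      img <- read_field_tiff(p, scale = params$gcu_scale)
      detect_gfp_objects(tophat(img, params), params)
    })
    conf <- mean(purrr::map_dbl(ph$path, function(p) {
      confluence_percent(read_field_tiff(p, scale = 1), params)
    }))
    tibble(plate_id = mf$plate_id[1], well = mf$well[1], time_h = mf$time_h[1],
           confluence_pct = conf, gfp_mean_gcu = well_gfp_mean(objs),
           n_gfp_objects = nrow(objs))
  })
  out <- bind_rows(rows)
  out[order(out$plate_id, out$well, out$time_h), ]
}

# Read one single-channel 16-bit TIFF back into physical units.
read_field_tiff <- function(path, scale = 1) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- matrix(as.numeric(img), d[1], d[2])
  m * scale
}
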