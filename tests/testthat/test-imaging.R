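# Segmentation masks: top-hat, GFP objects, confluence.

disc_image <- function(nr = 64, nc = 64, cx, cy, r_px, value, base = 0) {
  img <- matrix(base, nr, nc)
  for (i in seq_along(cx)) {
    dx <- outer(rep(1, nr), seq_len(nc) - cx[i])
    dy <- outer(seq_len(nr) - cy[i], rep(1, nc))
    img[dx^2 + dy^2 <= r_px[i]^2] <- base + value[i]
  }
  img
}

test_that("top-hat of a constant image is zero everywhere", {
  sp <- seg_params()
  expect_equal(max(abs(tophat(matrix(0.7, 64, 64), sp))), 0)
})

test_that("top-hat keeps compact bright discs and removes flat background", {
  sp <- seg_params()  # 2 um/px, radius 5 px
  img <- disc_image(cx = 32, cy = 32, r_px = 2, value = 1, base = 0.5)
  th <- tophat(img, sp)
  expect_equal(th[32, 32], 1, tolerance = 0.05)        # disc retained
  expect_lt(max(th[1:10, 1:10]), 1e-9)                 # background removed
})

test_that("top-hat passes almost nothing of a smooth large-scale gradient", {
  sp <- seg_params()
  ramp <- outer(rep(1, 128), seq(0, 1, length.out = 128))  # scale >> disc
  th <- tophat(ramp, sp)
  expect_lt(max(th), 0.05 * 1)
})

test_that("top-hat is idempotent-in-effect on flat-background output", {
  sp <- seg_params()
  img <- disc_image(cx = c(20, 45), cy = c(20, 40), r_px = c(2, 3),
                    value = c(1, 0.6), base = 0.3)
  th1 <- tophat(img, sp)
  th2 <- tophat(th1, sp)
  expect_lt(max(abs(th2 - th1)), 1e-6)
})

test_that("top-hat rejects a sub-pixel structuring element", {
  expect_error(tophat(matrix(0, 8, 8), seg_params(um_per_px = 25)), "< 1 px")
})

test_that("GFP objects respect the strict area filter and the GCU threshold", {
  sp <- seg_params()  # 2 um/px: 1 px = 4 um^2
  # two discs with > 80 um^2 above threshold plus one small one
  img <- disc_image(nr = 96, nc = 96, cx = c(20, 60, 85), cy = c(20, 60, 85),
                    r_px = c(3, 3, 1.6), value = c(0.5, 0.5, 0.5))
  obj <- detect_gfp_objects(img, sp)
  expect_equal(nrow(obj), 2)
  expect_true(all(obj$area_um2 > sp$gfp_min_area_um2))
  expect_equal(obj$mean_gcu, c(0.5, 0.5))
  # below 0.2 GCU: nothing
  dim_img <- disc_image(cx = 32, cy = 32, r_px = 4, value = 0.1)
  expect_equal(nrow(detect_gfp_objects(dim_img, sp)), 0)
})

test_that("a component of exactly 80 um^2 is rejected (strict inequality)", {
  sp <- seg_params()  # 4 um^2/px -> 20 px = exactly 80 um^2
  img <- matrix(0, 32, 32)
  img[10:13, 10:14] <- 1  # 4 x 5 = 20 px block
  expect_equal(nrow(detect_gfp_objects(img, sp)), 0)
  img[10:13, 10:15] <- 1  # 24 px = 96 um^2
  expect_equal(nrow(detect_gfp_objects(img, sp)), 1)
})

test_that("connectivity 8 merges diagonal components, connectivity 4 does not", {
  img <- matrix(0, 40, 40)
  img[10:14, 10:14] <- 1
  img[15:19, 15:19] <- 1  # touches only at the corner
  o8 <- detect_gfp_objects(img, seg_params(connectivity = 8))
  o4 <- detect_gfp_objects(img, seg_params(connectivity = 4))
  expect_equal(nrow(o8), 1)
  expect_equal(nrow(o4), 2)
})

test_that("object detection is translation-equivariant", {
  sp <- seg_params()
  img <- disc_image(nr = 96, nc = 96, cx = c(30, 60), cy = c(25, 55),
                    r_px = c(3, 4), value = c(0.5, 0.9))
  shifted <- matrix(0, 96, 96)
  shifted[9:96, 7:96] <- img[1:88, 1:90]  # shift by (+8 rows, +6 cols)
  a <- detect_gfp_objects(img, sp)
  b <- detect_gfp_objects(shifted, sp)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(b$area_um2), sort(a$area_um2))
  expect_equal(sort(b$mean_gcu), sort(a$mean_gcu), tolerance = 1e-12)
  expect_equal(sort(b$y_um - a$y_um[order(a$x_um)][order(order(b$x_um))]),
               rep(8 * sp$um_per_px, 2), tolerance = 1e-9)
})

test_that("well mean is the unweighted object mean, 0 with no objects", {
  expect_equal(well_gfp_mean(tibble::tibble(mean_gcu = c(1, 3))), 2)
  expect_equal(well_gfp_mean(tibble::tibble(mean_gcu = 0.7)), 0.7)
  expect_equal(well_gfp_mean(NULL), 0)
  expect_equal(well_gfp_mean(tibble::tibble(mean_gcu = numeric())), 0)
  o <- tibble::tibble(mean_gcu = c(0.2, 0.9, 2.4))
  expect_equal(well_gfp_mean(o), well_gfp_mean(o[c(3, 1, 2), ]))
})

test_that("confluence is 0 on blank and ~100 on fully textured images", {
  sp <- seg_params()
  expect_equal(confluence_percent(matrix(0.5, 128, 128), sp), 0)
  withr::with_seed(1, {
    noisy <- matrix(stats::runif(128 * 128, 0, 1), 128, 128)
  })
  expect_gt(confluence_percent(noisy, sp), 95)
})

test_that("confluence of a rendered field is within 5 points of ground truth", {
  for (s in c(1, 2)) {
    fld <- render_field(list(n_live = 500, n_apop = 0, gcu_per_cell = 0.3),
                        seed = s)
    truth_pct <- 100 * sum(fld$truth$area_um2) / (512 * 512 * 4)
    meas <- confluence_percent(fld$phase, seg_params())
    expect_lt(abs(meas - truth_pct), 5)
  }
})

test_that("segmentation of rendered fields recovers the manifest objects", {
  sp <- seg_params()
  fld <- render_field(list(n_live = 220, n_apop = 30, gcu_per_cell = 1),
                      seed = 11)
  th <- tophat(fld$green, sp)
  obj <- detect_gfp_objects(th, sp)
  truth <- fld$truth
  eligible <- truth$area_um2 > sp$gfp_min_area_um2 &
    truth$mean_gcu >= sp$gcu_threshold
  lab <- cox2screen:::label_components(th >= sp$gcu_threshold, sp$connectivity)
  hit <- lab[cbind(pmax(1, round(truth$y_um / sp$um_per_px)),
                   pmax(1, round(truth$x_um / sp$um_per_px)))] > 0
  expect_gte(mean(hit[eligible]), 0.95)
  expect_lte(abs(nrow(obj) - sum(eligible)) / sum(eligible), 0.05)
})

test_that("segment_timelapse measures rendered frames and reports missing files", {
  fld <- render_field(list(n_live = 120, n_apop = 0, gcu_per_cell = 1), seed = 3)
  dir <- withr::local_tempdir()
  mf <- write_field_images(fld, dir, "P01", "D4", 10)
  ts <- segment_timelapse(mf, seg_params())
  expect_equal(nrow(ts), 1)
  expect_gt(ts$gfp_mean_gcu, 0.2)
  expect_gt(ts$n_gfp_objects, 100)
  truth_pct <- 100 * sum(fld$truth$area_um2) / (512 * 512 * 4)
  expect_lt(abs(ts$confluence_pct - truth_pct), 5)
  mf2 <- mf
  mf2$path[1] <- file.path(dir, "nope.tif")
  expect_error(segment_timelapse(mf2, seg_params()), "nope.tif")
})
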