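# Scoring: control means, fold changes, scores, QC, classification.

mini_ts <- function() {
  # 1 plate, 3 dmso wells, 2 compound wells, 3 time points
  grid <- c(0, 2, 4)
  bind_rows(
    purrr::map_dfr(1:3, function(i) {
      tibble::tibble(plate_id = "P01", well = paste0("C", i + 2),
                     role = "dmso_control", compound_id = NA_character_,
                     time_h = grid, confluence_pct = c(10, 12, 14) + i - 2,
                     gfp_mean_gcu = c(0.3, 0.3, 0.3))
    }),
    tibble::tibble(plate_id = "P01", well = "E3", role = "compound",
                   compound_id = "C0001", time_h = grid,
                   confluence_pct = c(10, 12, 14), gfp_mean_gcu = c(0.3, 0.6, 0.9))
  )
}

test_that("control means are per-plate, per-time arithmetic means", {
  ts <- mini_ts()
  cm <- control_mean_series(ts, "dmso_control")
  expect_equal(cm$confluence_pct, c(10, 12, 14))  # mean of {9,10,11} etc.
  expect_equal(cm$gfp_mean_gcu, rep(0.3, 3))
  ts2 <- ts
  ts2$plate_id[ts2$role == "compound"] <- "P02"
  expect_error(control_mean_series(ts2, "dmso_control"), "P02")
})

test_that("fold change divides by the floored control", {
  expect_equal(fold_change_series(c(2, 4), c(1, 2)), c(2, 2))
  expect_equal(fold_change_series(c(1, 1), c(1, 1)), c(1, 1))
  expect_equal(fold_change_series(0.5, 0, floor = 0.05), 10)
  expect_error(fold_change_series(1:3, 1:2), "grid mismatch")
})

test_that("GFP score conventions: normalized, raw and baseline-subtracted", {
  times <- seq(0, 72, by = 2)
  flat <- rep(1, length(times))
  ramp <- seq(1, 9, length.out = length(times))
  expect_equal(gfp_score(flat, times), 1)
  expect_equal(gfp_score(ramp, times), 5)          # mean of a 1 -> 9 ramp
  expect_equal(gfp_score(ramp, times,
                         scoring_config(auc_mode = "raw_hours")), 360)
  expect_equal(gfp_score(ramp, times,
                         scoring_config(auc_mode = "baseline_subtracted")), 4)
  expect_error(gfp_score(1, 0), "2 time points")
})

test_that("trapezoid AUC equals the closed form for piecewise-linear series", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k <- sample(3:12, 1)
      knots_t <- sort(c(0, 72, runif(k - 2, 0, 72)))
      knots_v <- runif(k, 0, 10)
      times <- seq(0, 72, by = 2)
      v <- stats::approx(knots_t, knots_v, xout = times)$y
      # closed form: sum of trapezoids between consecutive grid points
      closed <- sum((v[-1] + v[-length(v)]) / 2 * diff(times))
      expect_equal(gfp_score(v, times, scoring_config(auc_mode = "raw_hours")),
                   closed, tolerance = 1e-12)
      expect_equal(gfp_score(v, times), closed / 72, tolerance = 1e-12)
    }
  })
})

test_that("confluency score is the plain mean of the fold change", {
  expect_equal(confluency_score(c(1, 1, 1)), 1)
  expect_equal(confluency_score(c(1, 0.3)), 0.65)
  expect_error(confluency_score(numeric()), "empty")
})

test_that("early-window QC flags fast risers but not genuine induction", {
  times <- seq(0, 72, by = 2)
  fast <- rep(1, length(times)); fast[2] <- 5  # FC 5 at 2 h
  expect_true(autofluorescence_qc(fast, times))
  expect_false(autofluorescence_qc(rep(1, length(times)), times))
  # the 5-FU preset rises only later: FC below 2 up to 4 h
  ctrl <- simulate_well(preset("4T1"), preset("DMSO"))
  trt <- simulate_well(preset("4T1"), preset("5FU_100uM"))
  fc <- fold_change_series(trt$gfp_signal, ctrl$gfp_signal, 0.05)
  expect_false(autofluorescence_qc(fc, ctrl$time_h))
  expect_lt(max(fc[ctrl$time_h <= 4]), 2)
})

test_that("hit classes follow the published score quadrants", {
  expect_equal(classify_hits(6, 0.5), "arrested_induced")
  expect_equal(classify_hits(1, 1), "inactive")
  expect_equal(classify_hits(6, 0.9), "induced_only")
  expect_equal(classify_hits(2, 0.4), "arrested_only")
  expect_equal(classify_hits(6, 0.5, qc_autofluorescent = TRUE), "excluded")
  # boundary values are not hits (strict > and <)
  expect_equal(classify_hits(5, 0.65), "inactive")
})

test_that("score_screen scores a small screen and classifies the controls' effect", {
  lib <- build_library(small_spec(), seed = 2)
  scr_ts <- generate_timeseries(build_plate_layouts(lib), lib, seed = 3)
  sc <- score_screen(scr_ts, lib)
  expect_equal(nrow(sc), nrow(lib))
  expect_true(all(is.finite(sc$gfp_score)))
  expect_true(all(sc$hit_class[sc$qc_autofluorescent] == "excluded"))
  expect_true(all(sc$hit_class[!sc$qc_autofluorescent] != "excluded"))
})

test_that("DMSO wells scored leave-one-out against their plate stay near 1", {
  lib <- build_library(small_spec(), seed = 4)
  ts <- generate_timeseries(build_plate_layouts(lib), lib, seed = 5)
  dmso <- ts[ts$role == "dmso_control", ]
  wells <- unique(dmso$well)
  expect_length(wells, 9)
  for (w in wells) {
    rest <- dmso[dmso$well != w, ] |>
      dplyr::group_by(time_h) |>
      dplyr::summarise(conf = mean(confluence_pct), gcu = mean(gfp_mean_gcu))
    one <- dmso[dmso$well == w, ]
    g <- gfp_score(fold_change_series(one$gfp_mean_gcu, rest$gcu, 0.05),
                   one$time_h)
    cf <- confluency_score(fold_change_series(one$confluence_pct, rest$conf, 1))
    expect_gt(g, 0.8); expect_lt(g, 1.2)
    expect_gt(cf, 0.8); expect_lt(cf, 1.2)
  }
})

test_that("scores are monotone in the generative effect sizes", {
  ctrl <- simulate_well(preset("4T1"), preset("DMSO"))
  gfp <- vapply(c(1, 2, 4, 7, 10), function(b) {
    tr <- simulate_well(preset("4T1"),
                        drug_effect(arrest = 0.5, beta = b, tau_ind = 10,
                                    t_death = 30, k_d = 0.02))
    gfp_score(fold_change_series(tr$gfp_signal, ctrl$gfp_signal, 0.05),
              tr$time_h)
  }, numeric(1))
  expect_true(all(diff(gfp) > 0))
  conf <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    tr <- simulate_well(preset("4T1"),
                        drug_effect(arrest = a, beta = 1, tau_ind = 10))
    confluency_score(fold_change_series(tr$confluence_pct,
                                        ctrl$confluence_pct, 1))
  }, numeric(1))
  expect_true(all(diff(conf) < 0))
})

test_that("category correlation needs enough QC-passing compounds", {
  sc <- tibble::tibble(compound_id = sprintf("C%02d", 1:3),
                       category = "antineoplastic",
                       gfp_score = c(1, 2, 3), confluency_score = c(3, 2, 1),
                       qc_autofluorescent = FALSE)
  expect_error(category_correlation(sc, "antineoplastic"), ">= 4")
})
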