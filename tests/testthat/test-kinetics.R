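# Reporter kinetics: ODE behaviour, steady states, calibration of presets.

test_that("vehicle treatment reproduces the control trajectory exactly", {
  p <- preset("4T1")
  dmso <- preset("DMSO")
  null_drug <- drug_effect(arrest = 0, beta = 1, k_d = 0, k_n = 0, tau_ind = 5)
  a <- simulate_well(p, dmso)
  b <- simulate_well(p, null_drug)
  expect_equal(a$pge2_pg_ml, b$pge2_pg_ml, tolerance = 1e-12)
  expect_equal(fold_vs_control(a, b, "pge2_pg_ml", 48), 1, tolerance = 1e-10)
  # per-cell amounts sit at their steady state the whole time
  expect_equal(a$mrna, rep(a$mrna[1], nrow(a)), tolerance = 1e-8)
  expect_equal(a$gfp, rep(a$gfp[1], nrow(a)), tolerance = 1e-8)
})

test_that("a COX-2-negative line produces no mRNA, reporter or PGE2", {
  ko <- preset("4T1_COX2KO")
  for (drug in list(preset("DMSO"), preset("5FU_100uM"))) {
    tr <- simulate_well(ko, drug)
    expect_equal(max(tr$mrna), 0)
    expect_equal(max(tr$cox2), 0)
    expect_equal(max(tr$gfp), 0)
    expect_equal(max(tr$pge2_pg_ml), 0)
  }
})

test_that("constitutive-promoter line is not induced by 5-FU", {
  rest <- preset("4T1_COX2REST")
  trt <- simulate_well(rest, preset("5FU_100uM"))
  ctl <- simulate_well(rest, preset("DMSO"))
  # transcription is untouched: per-cell mRNA identical to control
  expect_equal(trt$mrna, ctl$mrna, tolerance = 1e-8)
  # PGE2 is not elevated (cytostatic/cytotoxic effects can only lower it)
  expect_lt(fold_vs_control(trt, ctl, "pge2_pg_ml", 48), 1.2)
})

test_that("5-FU preset reaches a seven-fold PGE2 increase over DMSO at 48 h", {
  ratio <- fold_vs_control(simulate_well(preset("4T1"), preset("5FU_100uM")),
                           simulate_well(preset("4T1"), preset("DMSO")),
                           "pge2_pg_ml", 48)
  expect_equal(ratio, 7, tolerance = 0.05)
})

test_that("preset peak times match the published kinetics", {
  tc <- simulate_well(preset("4T1"), preset("cisplatin_50uM"))
  tf <- simulate_well(preset("4T1"), preset("5FU_100uM"))
  expect_lte(abs(peak_time(tc, "pge2_rate") - 8), 2)
  expect_lte(abs(peak_time(tc, "gfp_signal") - 24), 2)
  expect_lte(abs(peak_time(tf, "gfp_signal") - 48), 2)
  # cisplatin GFP peaks before 5-FU GFP
  expect_lt(peak_time(tc, "gfp_signal"), peak_time(tf, "gfp_signal"))
})

test_that("peak_time picks the earliest maximum and rejects empty series", {
  d <- data.frame(time_h = seq(0, 72, 2), v = seq(0, 72, 2))
  expect_equal(peak_time(d, "v"), 72)
  d$w <- c(0, 5, rep(5, 35))  # tie: earliest wins
  expect_equal(peak_time(d, "w"), 2)
  expect_error(peak_time(d, "missing_col"), "empty or missing")
})

test_that("drug-free trajectory matches the closed-form logistic solution", {
  p <- preset("4T1")
  tr <- simulate_well(p, drug_effect(arrest = 0, beta = 1, k_d = 0, k_n = 0))
  t <- tr$time_h
  n_exact <- p$K / (1 + (p$K - p$N0) / p$N0 * exp(-p$r * t))
  expect_equal(tr$n_live, n_exact, tolerance = 1e-6)
  # cumulative PGE2 has a closed form too: k_p * c_ss * integral of N
  c_ss <- p$k_c * (p$alpha0 / p$delta_m) / p$delta_c
  p_exact <- p$k_p * c_ss * (p$K / p$r) *
    log(((p$K - p$N0) + p$N0 * exp(p$r * t)) / p$K)
  expect_equal(tr$pge2_pg_ml, p_exact, tolerance = 1e-6)
})

test_that("fixed-step integrator agrees with an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  p <- preset("4T1")
  for (dr in list(preset("cisplatin_50uM"), preset("5FU_100uM"))) {
    mine <- simulate_well(p, dr)
    ref <- desolve_trajectory(p, dr)
    for (col in c("n_live", "n_apop", "mrna", "cox2", "gfp", "pge2_pg_ml")) {
      scale <- max(abs(ref[[col]])) + 1e-12
      expect_lt(max(abs(mine[[col]] - ref[[col]])) / scale, 1e-4)
    }
  }
})

test_that("induced expression is strictly proportional to baseline expression", {
  drug <- preset("5FU_100uM")
  alphas <- c(0.1, 0.3, 1, 3, 10)
  m24 <- vapply(alphas, function(a) {
    p <- kinetic_params(alpha0 = a)
    simulate_well(p, drug)$mrna[13]  # t = 24 h
  }, numeric(1))
  fit <- stats::lm(log(m24) ~ log(alphas))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.01)
  # and exactly linear: m(alpha0)/alpha0 constant
  expect_equal(max(m24 / alphas) / min(m24 / alphas), 1, tolerance = 1e-6)
})

test_that("states stay non-negative, PGE2 and total cells non-decreasing", {
  withr::with_seed(42, {
    for (i in 1:25) {
      p <- kinetic_params(alpha0 = runif(1, 0, 3), delta_m = runif(1, 0.1, 1),
                          k_c = runif(1, 0.05, 0.5), delta_c = runif(1, 0.1, 1),
                          k_g = runif(1, 0.05, 0.5), delta_g = runif(1, 0.1, 1),
                          k_p = runif(1, 0, 0.01), eps_apop = runif(1),
                          r = runif(1, 0.01, 0.15), K = runif(1, 500, 5000),
                          N0 = runif(1, 50, 400))
      d <- drug_effect(arrest = runif(1), beta = 1 + runif(1, 0, 12),
                       tau_ind = runif(1, 0, 24), t_death = runif(1, 0, 60),
                       k_d = runif(1, 0, 0.3), k_n = runif(1, 0, 0.1))
      tr <- simulate_well(p, d)
      expect_true(all(as.matrix(tr[, -1]) >= 0))
      expect_true(all(diff(tr$pge2_pg_ml) >= -1e-9))
      ntot <- tr$n_live + tr$n_apop + tr$n_nec
      expect_true(all(diff(ntot) >= -1e-6 * max(ntot)))
      expect_true(all(tr$confluence_pct >= 0 & tr$confluence_pct <= 100))
    }
  })
})

test_that("reporter decays with its design half-life after transcription shutoff", {
  p <- preset("4T1")
  induced <- simulate_well(p, preset("5FU_100uM"))
  state <- unlist(induced[13, c("n_live", "n_apop", "n_nec", "mrna", "cox2",
                                "gfp", "pge2_pg_ml")])
  state["mrna"] <- 0  # transcript already gone: pure reporter turnover
  silent <- kinetic_params(alpha0 = 0, delta_g = p$delta_g, k_g = p$k_g,
                           delta_m = p$delta_m, r = 0, K = p$K, N0 = state[1])
  off <- simulate_well(silent, drug_effect(), times = seq(0, 24, 2),
                       init = state)
  slope <- coef(stats::lm(log(off$gfp) ~ off$time_h))[2]
  expect_equal(unname(slope), -p$delta_g, tolerance = 1e-4)
  expect_equal(off$gfp[2] / off$gfp[1], 0.5, tolerance = 1e-5)  # 2 h half-life
  expect_equal(log(2) / p$delta_g, 2, tolerance = 1e-10)
})

test_that("fold_vs_control applies the documented floor and grid checks", {
  a <- simulate_well(preset("4T1"), preset("DMSO"), times = seq(0, 8, 2))
  b <- a
  b$pge2_pg_ml <- rep(0, nrow(b))
  a$pge2_pg_ml <- rep(0.5, nrow(a))
  expect_equal(fold_vs_control(a, b, "pge2_pg_ml", 4, floor = 0.05), 10)
  expect_error(fold_vs_control(a, b, "pge2_pg_ml", 3), "not on the grid")
  b2 <- simulate_well(preset("4T1"), preset("DMSO"), times = seq(0, 8, 4))
  expect_error(fold_vs_control(a, b2, "pge2_pg_ml", 4), "time grid")
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(kinetic_params(alpha0 = -1), ">= 0")
  expect_error(kinetic_params(delta_m = 0), "> 0")
  expect_error(kinetic_params(eps_apop = 1.5), "\\[0, 1\\]")
  expect_error(kinetic_params(alpha0 = NA_real_), "non-finite")
  expect_error(drug_effect(beta = 0.5), ">= 1")
  expect_error(drug_effect(arrest = 2), "\\[0, 1\\]")
  expect_error(simulate_well(preset("4T1"), preset("DMSO"), times = c(2, 4)),
               "start at 0")
  expect_error(simulate_well(preset("4T1"), preset("DMSO"), h = 2), "0, 0.5")
  expect_error(preset("nonexistent"), "known presets")
})

test_that("trajectory CSV export writes the long-format columns", {
  tr <- simulate_well(preset("4T1"), preset("DMSO"), times = seq(0, 8, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_named(back, c("time_h", "n_live", "n_apop", "n_nec", "mrna", "cox2",
                       "gfp", "gfp_signal", "pge2_pg_ml", "confluence_pct"))
  expect_equal(back$pge2_pg_ml, tr$pge2_pg_ml, tolerance = 1e-9)
})
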