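# Shared fixtures, built once per test run.

# A small screen spec: 1 plate's worth of compounds, all categories present.
small_spec <- function(n_total = 60) {
  library_spec(
    n_total = n_total,
    category_counts = c(antineoplastic = 15, anthelmintic = 8),
    category_props = c(antibacterial = 0.2),
    autofluorescent = default_autofluorescent()[c(1, 2), ]
  )
}

# Default-condition screen used by several acceptance checks (built lazily
# and cached for the session).
.fixture_env <- new.env(parent = emptyenv())

default_screen <- function(seed = 20260929) {
  key <- paste0("screen_", seed)
  if (is.null(.fixture_env[[key]])) {
    scr <- simulate_screen(seed = seed)
    scr$scores <- score_screen(scr$timeseries, scr$library)
    .fixture_env[[key]] <- scr
  }
  .fixture_env[[key]]
}

# Independent trajectory oracle: same ODE system integrated with deSolve's
# adaptive lsoda. The apoptosis switch is handled exactly by integrating
# piecewise up to and from t_death.
desolve_trajectory <- function(params, drug, times = seq(0, 72, by = 2)) {
  beta_eff <- if (params$inducible) drug$beta else 1
  derivs <- function(death_on) function(t, y, parms) {
    u <- if (drug$tau_ind > 0) 1 - exp(-t / drug$tau_ind) else 1
    Nl <- y[1]; Na <- y[2]; Nn <- y[3]; m <- y[4]; cc <- y[5]; g <- y[6]
    grow <- params$r * (1 - drug$arrest * u) * Nl * (1 - (Nl + Na + Nn) / params$K)
    die <- if (death_on) drug$k_d * Nl else 0
    list(c(grow - die,
           die - drug$k_n * Na,
           drug$k_n * Na,
           params$alpha0 * (1 + (beta_eff - 1) * u) - params$delta_m * m,
           params$k_c * m - params$delta_c * cc,
           params$k_g * m - params$delta_g * g,
           params$k_p * cc * (Nl + params$eps_apop * Na)))
  }
  m0 <- params$alpha0 / params$delta_m
  y0 <- c(params$N0, 0, 0, m0, params$k_c * m0 / params$delta_c,
          params$k_g * m0 / params$delta_g, 0)
  td <- drug$t_death
  solve_seg <- function(y0, tt, death_on) {
    deSolve::lsoda(y0, tt, derivs(death_on), parms = NULL,
                   rtol = 1e-10, atol = 1e-10)
  }
  if (!is.finite(td) || td >= max(times)) {
    out <- solve_seg(y0, times, FALSE)
  } else {
    t1 <- sort(unique(c(times[times <= td], td)))
    seg1 <- solve_seg(y0, t1, FALSE)
    y_td <- seg1[nrow(seg1), -1]
    t2 <- sort(unique(c(td, times[times >= td])))
    seg2 <- solve_seg(y_td, t2, TRUE)
    keep1 <- seg1[seg1[, 1] %in% times & seg1[, 1] < td, , drop = FALSE]
    keep2 <- seg2[seg2[, 1] %in% times, , drop = FALSE]
    out <- rbind(keep1, keep2)
  }
  colnames(out) <- c("time_h", "n_live", "n_apop", "n_nec", "mrna", "cox2",
                     "gfp", "pge2_pg_ml")
  as.data.frame(out)
}

# Brute-force Spearman rho: explicit average ranks + explicit Pearson formula.
brute_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
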