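#' Cell-line kinetic parameters for the reporter model
#'
#' Bundles the drug-free parameters of one reporter cell line: logistic
#' growth, *Ptgs2* transcription, COX-2 protein and destabilized-GFP (d2EGFP)
#' reporter turnover, and PGE2 secretion. All rates are per hour; amounts of
#' mRNA/protein/reporter are in arbitrary per-cell units; cell numbers are
#' cells per imaged field.
#'
#' @param alpha0 Baseline *Ptgs2* transcription rate (a.u./h). `alpha0 = 0`
#'   encodes a COX-2-negative line.
#' @param delta_m mRNA decay rate (1/h); *Ptgs2* mRNA is short-lived.
#' @param k_c,delta_c COX-2 protein synthesis (per mRNA) and decay rates (1/h).
#' @param k_g,delta_g Reporter synthesis and decay rates (1/h). The default
#'   `delta_g = log(2)/2` gives the ~2 h half-life of d2EGFP, which is what
#'   makes the reporter track ongoing transcription on a 2 h imaging grid.
#' @param k_p PGE2 secretion per unit COX-2 per live cell (pg/ml per a.u. per
#'   cell per h).
#' @param eps_apop Fraction of full PGE2 output contributed by an apoptotic
#'   cell, in `[0, 1]`.
#' @param r Intrinsic growth rate (1/h).
#' @param K Carrying capacity (cells/field).
#' @param N0 Seeding density (cells/field).
#' @param w_apop Fraction of reporter fluorescence retained by an apoptotic
#'   cell, in `[0, 1]`; used by the measured well-GFP observable (see
#'   [simulate_well()]).
#' @param inducible Logical; `FALSE` encodes a constitutive-promoter line
#'   whose transcription cannot be induced (effective fold induction 1).
#' @param name Label for the parameter set.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [drug_effect()], [simulate_well()], [preset()]
#' @export
#' @examples
#' kinetic_params(alpha0 = 0)  # a COX-2 knockout line
kinetic_params <- function(alpha0 = 1, delta_m = 0.35,
                           k_c = 0.35 * 0.35, delta_c = 0.35,
                           k_g = 0.5 * log(2) * 0.35, delta_g = log(2) / 2,
                           k_p = 0.002, eps_apop = 0.15,
                           r = 0.105, K = 2200, N0 = 650,
                           w_apop = 0.95, inducible = TRUE,
                           name = "custom") {
  p <- list(alpha0 = alpha0, delta_m = delta_m, k_c = k_c, delta_c = delta_c,
            k_g = k_g, delta_g = delta_g, k_p = k_p, eps_apop = eps_apop,
            r = r, K = K, N0 = N0, w_apop = w_apop,
            inducible = isTRUE(inducible), name = name)
  num <- p[setdiff(names(p), c("inducible", "name"))]
  bad <- !vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                 logical(1))
  if (any(bad)) {
    abort(paste0("kinetic_params: non-finite or non-scalar value for ",
                 paste(names(num)[bad], collapse = ", ")))
  }
  if (any(unlist(num) < 0)) {
    abort("kinetic_params: all rates and amounts must be >= 0")
  }
  if (delta_m <= 0 || delta_c <= 0 || delta_g <= 0) {
    abort("kinetic_params: delta_m, delta_c and delta_g must be > 0")
  }
  if (eps_apop > 1 || w_apop > 1) {
    abort("kinetic_params: eps_apop and w_apop must lie in [0, 1]")
  }
  if (K <= 0) abort("kinetic_params: K must be > 0")
  structure(p, class = "kinetic_params")
}

#' Treatment-effect parameters of one compound
#'
#' Describes how a compound perturbs the reporter line: growth-rate
#' suppression, fold induction of *Ptgs2* transcription, the shared
#' smooth-exponential onset ramp `u(t) = 1 - exp(-t/tau_ind)`, and an
#' apoptosis program (onset time, apoptosis rate, apoptotic-to-secondary-
#' necrotic transition rate).
#'
#' @param arrest Growth-rate suppression fraction at full effect, in `[0, 1]`.
#' @param beta Fold induction of transcription at full effect (>= 1).
#' @param tau_ind Onset ramp time constant (h); `0` means instantaneous.
#' @param t_death Apoptosis onset time (h); `Inf` for no death.
#' @param k_d Apoptosis rate after onset (1/h).
#' @param k_n Apoptotic to secondary-necrotic transition rate (1/h).
#' @param autofluorescent Logical; compound fluoresces in the green channel
#'   independent of the reporter.
#' @param name,category Labels.
#'
#' @return An object of class `drug_effect` (a named list).
#' @export
#' @examples
#' drug_effect(arrest = 0.9, beta = 15, tau_ind = 18, t_death = 36, k_d = 0.045)
drug_effect <- function(arrest = 0, beta = 1, tau_ind = 2,
                        t_death = Inf, k_d = 0, k_n = 0.01,
                        autofluorescent = FALSE,
                        name = "custom", category = "other") {
  num <- list(arrest = arrest, beta = beta, tau_ind = tau_ind,
              t_death = t_death, k_d = k_d, k_n = k_n)
  bad <- !vapply(num, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                 logical(1))
  if (any(bad)) {
    abort(paste0("drug_effect: non-numeric or non-scalar value for ",
                 paste(names(num)[bad], collapse = ", ")))
  }
  if (arrest < 0 || arrest > 1) abort("drug_effect: arrest must lie in [0, 1]")
  if (beta < 1) abort("drug_effect: beta must be >= 1 (fold induction)")
  if (t_death < 0) abort("drug_effect: t_death must be >= 0")
  if (tau_ind < 0 || k_d < 0 || k_n < 0) {
    abort("drug_effect: tau_ind, k_d and k_n must be >= 0")
  }
  structure(list(arrest = arrest, beta = beta, tau_ind = tau_ind,
                 t_death = t_death, k_d = k_d, k_n = k_n,
                 autofluorescent = isTRUE(autofluorescent),
                 name = name, category = category),
            class = "drug_effect")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>", x$name, "\n")
  flds <- setdiff(names(x), "name")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.drug_effect <- function(x, ...) {
  cat("<drug_effect>", x$name, paste0("[", x$category, "]"), "\n")
  flds <- setdiff(names(x), c("name", "category"))
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

#' Simulate one well of the reporter kinetics model
#'
#' Integrates the deterministic ODE system coupling logistic growth, drug-
#' induced growth arrest and apoptosis, *Ptgs2* transcription with smooth
#' onset ramp, COX-2 protein, d2EGFP reporter, and cumulative PGE2 in the
#' medium. mRNA, protein and reporter start at their drug-free steady states;
#' integration is fixed-step classical RK4 (internal step `h`, default 0.5 h)
#' sampled onto `times`.
#'
#' Besides the raw states, the returned trajectory carries the measured
#' observables:
#' \describe{
#'   \item{`gfp_signal`}{well-mean GFP intensity proxy,
#'     `g * (N_live + w_apop*N_apop) / (N_live + N_apop + N_nec)`. Apoptotic
#'     cells retain a fraction `w_apop` of reporter fluorescence and
#'     secondary-necrotic corpses are dark, so the measured signal decays as
#'     the well dies even though per-cell reporter `gfp` does not.}
#'   \item{`pge2_rate`}{instantaneous PGE2 release rate
#'     `k_p * c * (N_live + eps_apop*N_apop)` (pg/ml/h).}
#'   \item{`confluence_pct`}{percent field area covered,
#'     `100 * (A_live*N_live + A_apop*N_apop) / A_field` with footprints
#'     400/200 um^2 and a 1.048576 mm^2 field; necrotic cells detach and
#'     contribute nothing.}
#'   \item{`caspase_signal`}{apoptotic-cell count proxy (`n_apop`).}
#' }
#'
#' @param params A [kinetic_params()] object.
#' @param drug A [drug_effect()] object.
#' @param times Strictly increasing sampling grid starting at 0 (hours).
#'   Default `seq(0, 72, by = 2)`, the screen's acquisition grid.
#' @param h Internal integration step (h), at most 0.5.
#' @param init Optional named 7-vector of initial states
#'   (`n_live, n_apop, n_nec, mrna, cox2, gfp, pge2_pg_ml`) overriding the
#'   steady-state initialization, e.g. to model transcription shutoff from an
#'   induced state.
#'
#' @return A tibble of class `cox2_trajectory` with columns `time_h`,
#'   `n_live`, `n_apop`, `n_nec`, `mrna`, `cox2`, `gfp`, `gfp_signal`,
#'   `pge2_pg_ml`, `pge2_rate`, `confluence_pct`, `caspase_signal`.
#' @export
#' @examples
#' tr <- simulate_well(preset("4T1"), preset("5FU_100uM"))
#' peak_time(tr, "gfp_signal")
simulate_well <- function(params, drug, times = seq(0, 72, by = 2),
                          h = 0.5, init = NULL) {
  stopifnot(inherits(params, "kinetic_params"), inherits(drug, "drug_effect"))
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    abort("simulate_well: times must be strictly increasing and start at 0")
  }
  if (!is.numeric(h) || h <= 0 || h > 0.5) {
    abort("simulate_well: internal step h must lie in (0, 0.5]")
  }
  beta_eff <- if (params$inducible) drug$beta else 1
  pars <- c(r = params$r, K = params$K, alpha0 = params$alpha0,
            delta_m = params$delta_m, k_c = params$k_c, delta_c = params$delta_c,
            k_g = params$k_g, delta_g = params$delta_g, k_p = params$k_p,
            eps_apop = params$eps_apop, arrest = drug$arrest, beta = beta_eff,
            tau_ind = drug$tau_ind,
            t_death = if (is.finite(drug$t_death)) drug$t_death else 1e9,
            k_d = drug$k_d, k_n = drug$k_n)
  if (is.null(init)) {
    m0 <- params$alpha0 / params$delta_m
    init <- c(params$N0, 0, 0, m0, params$k_c * m0 / params$delta_c,
              params$k_g * m0 / params$delta_g, 0)
  } else {
    if (length(init) != 7) abort("simulate_well: init must have 7 states")
    init <- as.numeric(init)
  }
  # align integration steps with the apoptosis onset so the indicator
  # switches exactly at t_death rather than inside a step
  tt <- as.numeric(times)
  td <- drug$t_death
  if (is.finite(td) && td > 0 && td < max(tt) && !(td %in% tt)) {
    tt <- sort(c(tt, td))
  }
  raw <- .sim_kinetics_cpp(pars, tt, h, init)
  raw <- raw[match(as.numeric(times), tt), , drop = FALSE]
  out <- as_tibble(as.data.frame(raw))
  ntot <- out$n_live + out$n_apop + out$n_nec
  out$gfp_signal <- ifelse(ntot > 0,
                           out$gfp * (out$n_live + params$w_apop * out$n_apop) / ntot,
                           0)
  out$pge2_rate <- params$k_p * out$cox2 * (out$n_live + params$eps_apop * out$n_apop)
  out$confluence_pct <- pmin(100, 100 * (400 * out$n_live + 200 * out$n_apop) / 1048576)
  out$caspase_signal <- out$n_apop
  attr(out, "params") <- params
  attr(out, "drug") <- drug
  class(out) <- c("cox2_trajectory", class(out))
  out
}

#' Fold change of a trajectory observable relative to a control trajectory
#'
#' @param traj,control_traj Trajectories from [simulate_well()] on the same
#'   time grid.
#' @param observable Column to compare (default `"pge2_pg_ml"`).
#' @param t Time point (h); must be on the grid.
#' @param floor Lower bound applied to the control value before division, so
#'   that wells measured against a silent control report a large, finite fold
#'   change rather than dividing by zero.
#' @return A single fold-change value.
#' @export
#' @examples
#' ctrl <- simulate_well(preset("4T1"), preset("DMSO"))
#' trt <- simulate_well(preset("4T1"), preset("5FU_100uM"))
#' fold_vs_control(trt, ctrl, "pge2_pg_ml", t = 48)
fold_vs_control <- function(traj, control_traj, observable = "pge2_pg_ml",
                            t = 48, floor = 0.05) {
  if (!identical(traj$time_h, control_traj$time_h)) {
    abort("fold_vs_control: trajectories must share the same time grid")
  }
  i <- match(t, traj$time_h)
  if (is.na(i)) abort(paste0("fold_vs_control: t = ", t, " h is not on the grid"))
  if (!observable %in% names(traj)) {
    abort(paste0("fold_vs_control: unknown observable '", observable, "'"))
  }
  traj[[observable]][i] / max(control_traj[[observable]][i], floor)
}

#' Time of the first maximum of a trajectory observable
#'
#' Returns the grid time at which `observable` first attains its maximum
#' (ties broken towards the earliest time). Used, e.g., to read off the PGE2
#' release-rate peak or the measured GFP peak of a preset.
#'
#' @param data A trajectory tibble (or any data frame with a time column).
#' @param observable Column name of the series to scan.
#' @param time Column name of the time grid (default `"time_h"`).
#' @return The time of the first maximum (same units as `time`).
#' @export
#' @examples
#' tr <- simulate_well(preset("4T1"), preset("cisplatin_50uM"))
#' peak_time(tr, "pge2_rate")   # PGE2 release-rate peak
peak_time <- function(data, observable, time = "time_h") {
  v <- data[[observable]]
  if (is.null(v) || length(v) == 0) {
    abort(paste0("peak_time: empty or missing series '", observable, "'"))
  }
  data[[time]][which.max(v)]
}

#' Export a trajectory as a long-format CSV
#'
#' @param traj A trajectory from [simulate_well()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("time_h", "n_live", "n_apop", "n_nec", "mrna", "cox2", "gfp",
            "gfp_signal", "pge2_pg_ml", "confluence_pct")
  write_csv_atomic(as_tibble(traj)[cols], path)
  invisible(path)
}
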