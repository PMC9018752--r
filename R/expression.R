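#' Log2 fold change between treated and untreated log2 expression
#'
#' Fold changes are defined as the difference in log2 expression between
#' treated and corresponding untreated cells at each time point.
#'
#' @param treated_log2,untreated_log2 Finite numeric vectors (log2 scale).
#' @return `treated_log2 - untreated_log2`.
#' @export
#' @examples
#' log2fc(8.1, 6.1)  # 2
log2fc <- function(treated_log2, untreated_log2) {
  if (any(!is.finite(treated_log2)) || any(!is.finite(untreated_log2))) {
    abort("log2fc: inputs must be finite")
  }
  treated_log2 - untreated_log2
}

#' Split a cell-line panel into baseline-positive and -negative lines
#'
#' Separates lines by basal expression of the target gene. Method
#' `"mixture"` (default) fits a two-component univariate Gaussian mixture by
#' EM — deterministically initialized at the data quartiles — and places the
#' threshold at the posterior crossover between the two components. Method
#' `"fixed"` uses the supplied threshold directly. Lines at or above the
#' threshold are `pos`.
#'
#' @param baseline Data frame with `line_id` and `log2_expr`, or a named
#'   numeric vector.
#' @param method `"mixture"` or `"fixed"`.
#' @param threshold Required for `method = "fixed"`.
#' @return An object of class `baseline_split`: tibble (`line_id`,
#'   `log2_expr`, `label`) with attributes `threshold`, `method`,
#'   `mixture` (component parameters, mixture method only). Has [tidy()]
#'   and [glance()] methods.
#' @export
split_baseline <- function(baseline, method = c("mixture", "fixed"),
                           threshold = NULL) {
  method <- match.arg(method)
  if (is.numeric(baseline)) {
    baseline <- tibble(line_id = names(baseline) %||%
                         paste0("line", seq_along(baseline)),
                       log2_expr = as.numeric(baseline))
  }
  x <- baseline$log2_expr
  if (length(x) < 4) abort("split_baseline: need >= 4 lines")
  if (any(!is.finite(x))) abort("split_baseline: baseline must be finite")

  mix <- NULL
  if (method == "fixed") {
    if (is.null(threshold)) abort("split_baseline: method 'fixed' needs a threshold")
    thr <- threshold
  } else {
    if (sd(x) == 0) {
      abort("split_baseline: constant baseline; use method = 'fixed'")
    }
    mix <- .em_gmm2(x)
    thr <- mix$threshold
  }
  out <- tibble(line_id = baseline$line_id, log2_expr = x,
                label = if_else(x >= thr, "pos", "neg"))
  structure(out, class = c("baseline_split", class(out)),
            threshold = thr, method = method, mixture = mix)
}

# Deterministic 2-component 1-D Gaussian mixture EM, initialized at the data
# quartiles. Returns parameters and the posterior-crossover threshold.
.em_gmm2 <- function(x, max_iter = 500, tol = 1e-10) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- q
  s <- rep(max(sd(x) / 2, 1e-3), 2)
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], s[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    pi1 <- mean(g)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    s[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    s[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    s <- pmax(s, 1e-4)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  # order components low/high, then find the posterior crossover between means
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]
  w <- c(pi1, 1 - pi1)[ord]
  f <- function(t) w[2] * dnorm(t, mu[2], s[2]) - w[1] * dnorm(t, mu[1], s[1])
  thr <- if (mu[1] == mu[2]) mu[1] else
    tryCatch(uniroot(f, c(mu[1], mu[2]))$root,
             error = function(e) mean(mu))
  list(mu = mu, sigma = s, weight = w, threshold = thr,
       loglik = ll_old, iterations = it)
}

#' @rdname split_baseline
#' @param x A `baseline_split` object.
#' @param ... Unused.
#' @export
tidy.baseline_split <- function(x, ...) {
  as_tibble(x)
}

#' @rdname split_baseline
#' @export
glance.baseline_split <- function(x, ...) {
  tibble(threshold = attr(x, "threshold"), method = attr(x, "method"),
         n_pos = sum(x$label == "pos"), n_neg = sum(x$label == "neg"))
}

#' Quartile labels from GI50 drug-sensitivity values
#'
#' Cuts at the empirical 25/50/75 percentiles (linear-interpolation
#' definition); values tied with a cut go to the lower quartile, so groups
#' may be unequal in the presence of ties. Q1 contains the lowest GI50
#' values — the most drug-sensitive lines. Missing values get `NA`.
#'
#' @param gi50 Numeric vector (log10 GI50), may contain `NA`.
#' @return Factor with levels `Q1`-`Q4`, same length/order as input.
#' @export
#' @examples
#' gi50_quartiles(c(1, 1, 2, 3))  # tie at the Q1 cut goes to Q1
gi50_quartiles <- function(gi50) {
  obs <- gi50[!is.na(gi50)]
  if (length(obs) < 4) abort("gi50_quartiles: need >= 4 non-missing values")
  cuts <- quantile(obs, c(0.25, 0.5, 0.75), names = FALSE)
  lab <- rep(NA_character_, length(gi50))
  idx <- !is.na(gi50)
  # "<= cut" sends values tied with a cut into the lower quartile
  lab[idx] <- dplyr::case_when(gi50[idx] <= cuts[1] ~ "Q1",
                               gi50[idx] <= cuts[2] ~ "Q2",
                               gi50[idx] <= cuts[3] ~ "Q3",
                               TRUE ~ "Q4")
  factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Correlation between drug sensitivity and induction
#'
#' Spearman correlation of log10 GI50 against the 24 h log2 fold change of
#' the target gene across lines with both measurements. A negative rho means
#' more sensitive lines (lower GI50) induce more.
#'
#' @param panel An expression panel (list with `fc`, `gi50`; see
#'   [simulate_panel()]).
#' @param drug Drug name.
#' @param t Time point (h), default 24.
#' @return A `cox2_cor` object.
#' @export
sensitivity_correlation <- function(panel, drug, t = 24) {
  fc <- panel$fc |>
    filter(.data$drug == !!drug, .data$time_h == t) |>
    select("line_id", "log2fc")
  gi <- panel$gi50 |>
    filter(.data$drug == !!drug, !is.na(.data$log10_gi50)) |>
    select("line_id", "log10_gi50")
  d <- inner_join(fc, gi, by = "line_id")
  if (nrow(d) < 4) abort("sensitivity_correlation: need >= 4 lines with fc and GI50")
  spearman_cor(d$log10_gi50, d$log2fc)
}

#' Group-level induction over time
#'
#' Mean and dispersion of the log2 fold change per baseline group
#' (pos/neg) at each time point for one drug.
#'
#' @param panel Expression panel.
#' @param split A [split_baseline()] result.
#' @param drug Drug name.
#' @return Tibble `label`, `time_h`, `mean_log2fc`, `sd_log2fc`, `n`.
#' @export
group_fc_over_time <- function(panel, split, drug) {
  d <- panel$fc |>
    filter(.data$drug == !!drug) |>
    inner_join(as_tibble(split)[, c("line_id", "label")], by = "line_id")
  if (nrow(d) == 0 || length(unique(d$label)) < 2) {
    abort("group_fc_over_time: a baseline group is empty")
  }
  d |>
    group_by(.data$label, .data$time_h) |>
    summarise(mean_log2fc = mean(.data$log2fc), sd_log2fc = sd(.data$log2fc),
              n = n(), .groups = "drop")
}

#' Specification of the synthetic expression-pharmacodynamics panel
#'
#' Emulates the structure of an NCI-60-style transcriptional
#' pharmacodynamics dataset for a single target gene: bimodal baseline
#' expression (expressing vs silent lines), induction confined to
#' baseline-positive lines and proportional to drug sensitivity, and partly
#' missing GI50 data.
#'
#' Model: latent sensitivity `s ~ N(0, 1)` per line-drug;
#' `log10 GI50 = gi50_mu - gi50_sd * s` (observed for `n_lines -
#' n_missing_gi50` lines);
#' `fc24 = (mu_ind + gamma * s) * 1[pos] + N(0, fc_noise_sd)` — positive
#' lines induce on average (`mu_ind`) and more-sensitive lines induce more
#' (`gamma`), silent lines do not respond; `fc2, fc6` are fractions
#' `fc_frac` of `fc24` plus noise, giving the rising 2/6/24 h ramp.
#'
#' @param n_lines Panel size (default 60).
#' @param n_pos Number of baseline-positive lines (default 26).
#' @param baseline_mu,baseline_sd Means and common sd of the two baseline
#'   components (log2 scale).
#' @param drugs Drug names.
#' @param mu_ind Mean 24 h induction (log2FC) of a baseline-positive line of
#'   average sensitivity.
#' @param gamma Sensitivity-induction coupling (log2FC per sd of
#'   sensitivity).
#' @param fc_noise_sd Noise sd of `fc24`.
#' @param fc_frac Fractions of the 24 h response present at 2 h and 6 h.
#' @param fc_frac_noise_sd Noise sds at 2 h and 6 h.
#' @param gi50_mu,gi50_sd Location/scale of log10 GI50.
#' @param n_missing_gi50 Lines without GI50 data (default 22, leaving 38).
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_lines = 60, n_pos = 26,
                       baseline_mu = c(3, 9), baseline_sd = 0.5,
                       drugs = c("cisplatin", "doxorubicin", "gemcitabine",
                                 "topotecan", "paclitaxel"),
                       mu_ind = 0.8, gamma = 0.8, fc_noise_sd = 0.3,
                       fc_frac = c(`2` = 0.15, `6` = 0.4),
                       fc_frac_noise_sd = c(`2` = 0.1, `6` = 0.15),
                       gi50_mu = -5.3, gi50_sd = 0.5,
                       n_missing_gi50 = 22) {
  if (n_pos < 0 || n_pos > n_lines) {
    abort("panel_spec: n_pos must lie in [0, n_lines]")
  }
  if (n_missing_gi50 < 0 || n_missing_gi50 > n_lines - 4) {
    abort("panel_spec: n_missing_gi50 leaves fewer than 4 lines with GI50")
  }
  structure(list(n_lines = n_lines, n_pos = n_pos, baseline_mu = baseline_mu,
                 baseline_sd = baseline_sd, drugs = drugs,
                 mu_ind = mu_ind, gamma = gamma,
                 fc_noise_sd = fc_noise_sd, fc_frac = fc_frac,
                 fc_frac_noise_sd = fc_frac_noise_sd, gi50_mu = gi50_mu,
                 gi50_sd = gi50_sd, n_missing_gi50 = n_missing_gi50),
            class = "panel_spec")
}

#' Simulate a synthetic expression-pharmacodynamics panel
#'
#' Pure function of `(spec, seed)`. Ground-truth labels are retained in the
#' `truth` element.
#'
#' @param spec [panel_spec()].
#' @param seed Integer seed.
#' @return List of class `expression_panel` with tibbles `baseline`
#'   (`line_id`, `log2_expr`), `fc` (`line_id`, `drug`, `time_h`, `log2fc`),
#'   `gi50` (`line_id`, `drug`, `log10_gi50`; `NA` where unavailable) and
#'   `truth` (`line_id`, `label`).
#' @export
#' @examples
#' panel <- simulate_panel(seed = 1)
#' sensitivity_correlation(panel, "cisplatin")
simulate_panel <- function(spec = panel_spec(), seed = 1) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(seed, {
    n <- spec$n_lines
    ids <- sprintf("L%02d", seq_len(n))
    pos <- c(rep(TRUE, spec$n_pos), rep(FALSE, n - spec$n_pos))
    base <- ifelse(pos,
                   rnorm(n, spec$baseline_mu[2], spec$baseline_sd),
                   rnorm(n, spec$baseline_mu[1], spec$baseline_sd))
    miss <- sample(n, spec$n_missing_gi50)

    per_drug <- purrr::map(spec$drugs, function(dr) {
      s <- rnorm(n)
      gi <- spec$gi50_mu - spec$gi50_sd * s
      gi[miss] <- NA_real_
      fc24 <- (spec$mu_ind + spec$gamma * s) * pos + rnorm(n, 0, spec$fc_noise_sd)
      fc2 <- spec$fc_frac[["2"]] * fc24 + rnorm(n, 0, spec$fc_frac_noise_sd[["2"]])
      fc6 <- spec$fc_frac[["6"]] * fc24 + rnorm(n, 0, spec$fc_frac_noise_sd[["6"]])
      list(fc = tibble(line_id = rep(ids, 3), drug = dr,
                       time_h = rep(c(2, 6, 24), each = n),
                       log2fc = c(fc2, fc6, fc24)),
           gi50 = tibble(line_id = ids, drug = dr, log10_gi50 = gi))
    })
    structure(list(
      baseline = tibble(line_id = ids, log2_expr = base),
      fc = bind_rows(purrr::map(per_drug, "fc")),
      gi50 = bind_rows(purrr::map(per_drug, "gi50")),
      truth = tibble(line_id = ids, label = if_else(pos, "pos", "neg"))),
      class = "expression_panel")
  })
}
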