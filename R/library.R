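#' Specification of the synthetic compound library
#'
#' Describes how [build_library()] draws a synthetic market-approved compound
#' collection. The default mirrors the screened Prestwick-style library:
#' 1280 compounds; fixed counts for the two cytotoxic categories
#' (69 antineoplastic, 20 anthelmintic), proportions for the major inert
#' categories (antibacterial 13%, anti-inflammatory 8%, antihypertensive 8%,
#' analgesic 5%), the remainder labelled `other`; and the eight
#' autofluorescent compounds excluded from the original analysis, carried
#' here by name with a constant green-channel offset.
#'
#' Cytotoxic categories draw coupled effects from a copula:
#' `arrest ~ Beta(5, 2)` and
#' `beta = 1 + 9 * arrest^1.5 * exp(eps)`, `eps ~ N(0, 0.15)`,
#' so growth suppression and *Ptgs2* induction rise together. The apoptosis
#' rate is coupled to induction strength,
#' `k_d = kd_max * ((beta - 1)/9)^kd_pow * exp(N(0, 0.15))`:
#' confluence collapse requires death, and only strong inducers die fast,
#' which reproduces the observed pattern that every strongly growth-inhibited
#' compound also induces the reporter. Non-cytotoxic categories draw
#' `arrest ~ |N(0, 0.02)|`, `beta = 1 + |N(0, 0.04)|`.
#'
#' @param n_total Library size.
#' @param category_counts Named integer vector of fixed-size categories.
#' @param category_props Named numeric vector of proportional categories
#'   (fractions of `n_total`); remaining compounds become `other`.
#' @param cytotoxic_categories Categories using the coupled-effect copula.
#' @param copula_eps_sd Lognormal sd of the induction noise `eps`.
#' @param kd_max,kd_pow Apoptosis-rate coupling constants.
#' @param tau_range,t_death_range,k_n_range Uniform draw ranges (h, h, 1/h)
#'   for onset ramp, death onset and necrosis transition.
#' @param autofluorescent Data frame with columns `name`, `category` listing
#'   compounds flagged as autofluorescent.
#' @param autofl_offset_range Range (GCU) of the constant green offset added
#'   to measurements of autofluorescent compounds.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_total = 1280,
                         category_counts = c(antineoplastic = 69, anthelmintic = 20),
                         category_props = c(antibacterial = 0.13,
                                            "anti-inflammatory" = 0.08,
                                            antihypertensive = 0.08,
                                            analgesic = 0.05),
                         cytotoxic_categories = c("antineoplastic", "anthelmintic"),
                         copula_eps_sd = 0.15,
                         kd_max = 0.14, kd_pow = 6,
                         tau_range = c(8, 14),
                         t_death_range = c(18, 36),
                         k_n_range = c(0.008, 0.02),
                         autofluorescent = default_autofluorescent(),
                         autofl_offset_range = c(0.5, 1.5)) {
  if (sum(category_props) > 1) {
    abort("library_spec: category proportions must not exceed 1")
  }
  if (sum(category_counts) + sum(round(category_props * n_total)) > n_total) {
    abort("library_spec: category counts and proportions exceed n_total")
  }
  structure(list(n_total = n_total, category_counts = category_counts,
                 category_props = category_props,
                 cytotoxic_categories = cytotoxic_categories,
                 copula_eps_sd = copula_eps_sd, kd_max = kd_max, kd_pow = kd_pow,
                 tau_range = tau_range, t_death_range = t_death_range,
                 k_n_range = k_n_range, autofluorescent = autofluorescent,
                 autofl_offset_range = autofl_offset_range),
            class = "library_spec")
}

#' The eight autofluorescent library compounds
#'
#' The compounds excluded from the original screen analysis because their
#' intrinsic green fluorescence mimics reporter signal, with plausible
#' therapeutic categories.
#'
#' @return A tibble with columns `name`, `category`.
#' @export
default_autofluorescent <- function() {
  tibble(name = c("Merbromin", "Verteporfin", "Pyrvinium pamoate",
                  "1,8-Dihydroxyanthraquinone", "Dipyridamole",
                  "Quinacrine dihydrochloride hydrate", "Propidium iodide",
                  "Chicago sky blue 6B"),
         category = c("antibacterial", "antineoplastic", "anthelmintic",
                      "other", "other", "other", "other", "other"))
}

#' Draw a synthetic compound library
#'
#' Pure function of `(spec, seed)`: generates `spec$n_total` compound records
#' with therapeutic categories, coupled ground-truth effect parameters (see
#' [library_spec()]) and the autofluorescence roster.
#'
#' @param spec A [library_spec()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble with one row per compound: `compound_id`, `name`,
#'   `category`, `arrest`, `beta`, `tau_ind`, `t_death`, `k_d`, `k_n`,
#'   `autofluorescent`, `autofl_offset_gcu`.
#' @export
#' @examples
#' lib <- build_library(library_spec(), seed = 1)
#' dplyr::count(lib, category)
build_library <- function(spec = library_spec(), seed = 1) {
  stopifnot(inherits(spec, "library_spec"))
  withr::with_seed(seed, {
    n_prop <- round(spec$category_props * spec$n_total)
    cats <- c(rep(names(spec$category_counts), spec$category_counts),
              rep(names(n_prop), n_prop))
    n_other <- spec$n_total - length(cats)
    cats <- c(cats, rep("other", n_other))
    n <- length(cats)
    lib <- tibble(
      compound_id = sprintf("C%04d", seq_len(n)),
      name = sprintf("compound_%04d", seq_len(n)),
      category = cats
    )
    cyto <- lib$category %in% spec$cytotoxic_categories

    arrest <- beta <- numeric(n)
    arrest[cyto] <- rbeta(sum(cyto), 5, 2)
    beta[cyto] <- 1 + 9 * arrest[cyto]^1.5 *
      exp(rnorm(sum(cyto), 0, spec$copula_eps_sd))
    arrest[!cyto] <- pmin(1, abs(rnorm(sum(!cyto), 0, 0.02)))
    beta[!cyto] <- 1 + abs(rnorm(sum(!cyto), 0, 0.04))

    k_d <- numeric(n)
    k_d[cyto] <- spec$kd_max * pmin(1, (beta[cyto] - 1) / 9)^spec$kd_pow *
      exp(rnorm(sum(cyto), 0, 0.15))

    lib$arrest <- arrest
    lib$beta <- beta
    lib$tau_ind <- runif(n, spec$tau_range[1], spec$tau_range[2])
    lib$t_death <- runif(n, spec$t_death_range[1], spec$t_death_range[2])
    lib$k_d <- k_d
    lib$k_n <- runif(n, spec$k_n_range[1], spec$k_n_range[2])

    # plant the autofluorescent roster inside its categories
    lib$autofluorescent <- FALSE
    lib$autofl_offset_gcu <- 0
    af <- spec$autofluorescent
    for (i in seq_len(nrow(af))) {
      pool <- which(lib$category == af$category[i] & !lib$autofluorescent)
      if (length(pool) == 0) pool <- which(!lib$autofluorescent)
      j <- pool[1 + (i - 1) %% length(pool)]
      lib$name[j] <- af$name[i]
      lib$autofluorescent[j] <- TRUE
    }
    naf <- sum(lib$autofluorescent)
    lib$autofl_offset_gcu[lib$autofluorescent] <-
      runif(naf, spec$autofl_offset_range[1], spec$autofl_offset_range[2])
    lib
  })
}

#' Turn one library row into a [drug_effect()] object
#'
#' @param row One-row data frame (or list) with the library effect columns.
#' @return A [drug_effect()].
#' @export
compound_effect <- function(row) {
  drug_effect(arrest = row$arrest, beta = row$beta, tau_ind = row$tau_ind,
              t_death = row$t_death, k_d = row$k_d, k_n = row$k_n,
              autofluorescent = row$autofluorescent,
              name = row$name, category = row$category)
}
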