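#' Log-linear hazard specification
#'
#' Hazard of incident type 2 diabetes is Weibull at baseline and log-linear in
#' the exposure, the (true) metabolic signature, the standardized genetic risk
#' score, and a small set of covariates. Effects are log hazard ratios.
#'
#' @param theta_current Log-HR of current vs never smoking acting directly
#'   (not through the metabolome).
#' @param theta_former Log-HR of former vs never smoking (direct).
#' @param theta_signature Log-HR per unit of the true metabolic signature.
#' @param theta_grs Log-HR per SD of the genetic risk score.
#' @param covariate_strength Multiplier on the built-in covariate effects on
#'   the hazard (BMI, family history); set 0 for a covariate-free hazard.
#' @return A `hazard_spec` object.
#' @seealso [hazard_cells()] for planting exact joint-category hazards.
#' @export
hazard_loglinear <- function(theta_current, theta_former = 0,
                             theta_signature = 0, theta_grs = 0,
                             covariate_strength = 1) {
  structure(list(type = "loglinear",
                 theta_current = theta_current,
                 theta_former = theta_former,
                 theta_signature = theta_signature,
                 theta_grs = theta_grs,
                 covariate_strength = covariate_strength),
            class = "hazard_spec")
}

#' Joint-category hazard specification
#'
#' Plants an exact hazard multiplier per (genetic risk category x signature
#' level) cell. Because a log-linear model cannot represent exact additivity
#' of hazard ratios, this cell-table form is how an exactly additive
#' (RERI = 0) or exactly multiplicative generator is specified: the truth of
#' the additive-interaction null is then set directly, not approximated.
#'
#' Genetic risk categories are quintile-based (low = Q1, intermediate =
#' Q2-Q4, high = Q5 of the realized score); the signature level is a median
#' split of the true signature. Both group columns are emitted with the
#' cohort so downstream joint models can be run against known membership.
#'
#' @param hr_matrix 3 x 2 numeric matrix of hazard ratios, rows
#'   `low`/`intermediate`/`high` genetic risk, columns `low`/`high`
#'   signature. The reference cell `[1, 1]` must equal 1.
#' @return A `hazard_spec` object.
#' @export
hazard_cells <- function(hr_matrix) {
  hr_matrix <- as.matrix(hr_matrix)
  if (!all(dim(hr_matrix) == c(3, 2))) {
    abort("hr_matrix must be 3 x 2 (GRS low/intermediate/high x signature low/high)")
  }
  if (abs(hr_matrix[1, 1] - 1) > 1e-12) {
    abort("reference cell hr_matrix[1, 1] must be exactly 1")
  }
  if (any(hr_matrix <= 0)) abort("hazard ratios must be positive")
  dimnames(hr_matrix) <- list(c("low", "intermediate", "high"), c("low", "high"))
  structure(list(type = "cells", hr = hr_matrix), class = "hazard_spec")
}

#' Configuration of the synthetic biobank-style cohort
#'
#' Defines the generative model for a cohort with confounded three-level
#' smoking status, a correlated (latent-factor) metabolome with sparse signed
#' smoking effects, a weighted-allele genetic risk score, and a left-truncated
#' time-to-event diabetes outcome on the attained-age scale.
#'
#' Structural quantities (factor loadings, covariate effects on metabolites,
#' allele frequencies, GRS weights, which metabolites are log-normal) are
#' drawn once from `structure_seed` and are therefore shared by every cohort
#' generated from the same config -- baseline, repeat assessment and external
#' validation cohorts all measure "the same" metabolome.
#'
#' The default hazard is calibrated so that the total current-vs-never hazard
#' ratio is about 1.73 with about 38% of the excess log-hazard carried by the
#' metabolic-signature path, split between a direct smoking effect and an
#' indirect effect through the metabolome; under a rare outcome the true
#' proportion mediated is `theta_signature * delta / (theta_current +
#' theta_signature * delta)` where `delta` is the smoking-induced shift in the
#' true signature.
#'
#' @param n_participants Cohort size.
#' @param n_metabolites Number of metabolite columns (default 249).
#' @param n_latent_factors Rank of the shared latent-factor structure
#'   driving inter-metabolite correlation (default 35; with near-total
#'   communality this makes a few dozen principal components explain ~99%
#'   of metabolite variance, the regime NMR lipoprotein panels sit in).
#' @param smoking_prevalence Named probabilities for never/former/current
#'   (must sum to 1).
#' @param n_smoking_metabolites Number of metabolites with nonzero smoking
#'   effects in `"sparse"` mode (ignored otherwise).
#' @param beta_smoking_on_metabolites Optional full-length signed effect
#'   vector (per-SD units) of current smoking on each metabolite; overrides
#'   `smoking_effect_mode`.
#' @param smoking_effect_mode How default smoking effects are built.
#'   `"factor"` (default) routes the effect through the shared latent
#'   factors, giving dense signed per-metabolite effects aligned with the
#'   correlation structure -- the realistic case, where a learned signature
#'   cannot exceed the factor-space discrimination. `"sparse"` plants
#'   idiosyncratic effects of magnitude 0.05-0.4 SD in the first
#'   `n_smoking_metabolites` metabolites, giving clean truth labels for
#'   selection studies.
#' @param smoking_factor_shift Factor-space shift (in factor SD units)
#'   induced by current smoking in `"factor"` mode; 0.9 gives a signature
#'   variance explained by smoking in the mid single digits of percent at
#'   ~10% smoking prevalence.
#' @param former_attenuation Former-smoker metabolite effects as a fraction
#'   of current-smoker effects.
#' @param lognormal_fraction Fraction of metabolites observed on an
#'   exponentiated (right-skewed) scale.
#' @param confounder_strength Multiplier on covariate effects on smoking and
#'   on metabolites (0 = no confounding).
#' @param n_snps_grs Number of GRS SNPs.
#' @param hazard_spec A [hazard_loglinear()] or [hazard_cells()] object; the
#'   default is the calibrated log-linear hazard described above.
#' @param target_hr_total,target_proportion_mediated Calibration targets used
#'   to build the default hazard (ignored when `hazard_spec` is supplied).
#' @param theta_grs Log-HR per SD of GRS used by the default hazard.
#' @param baseline_shape,baseline_scale Weibull baseline hazard of attained
#'   age (years); defaults give roughly 2% cumulative incidence over
#'   follow-up for an average participant.
#' @param followup_years Administrative censoring horizon after entry.
#' @param censor_rate Rate (per year) of random loss to follow-up.
#' @param entry_age_mean,entry_age_sd Entry (enrollment) age distribution,
#'   truncated to 40-70 years.
#' @param n_centers Number of assessment centers.
#' @param ineligible_fraction Named rates of the three eligibility flags
#'   (prevalent diabetes, lipid-lowering drugs, missing core data).
#' @param structure_seed Seed for the structural draws described above.
#' @return A `cohort_config` object (a validated list).
#' @examples
#' cfg <- cohort_config(n_participants = 500, n_metabolites = 30)
#' cohort <- simulate_cohort(cfg, seed = 1)
#' @export
cohort_config <- function(n_participants = 20000,
                          n_metabolites = 249,
                          n_latent_factors = 35,
                          smoking_prevalence = c(never = 0.569, former = 0.327,
                                                 current = 0.104),
                          n_smoking_metabolites = 40,
                          beta_smoking_on_metabolites = NULL,
                          smoking_effect_mode = c("factor", "sparse"),
                          smoking_factor_shift = 0.9,
                          former_attenuation = 0.15,
                          lognormal_fraction = 0.3,
                          confounder_strength = 1,
                          n_snps_grs = 38,
                          hazard_spec = NULL,
                          target_hr_total = 1.73,
                          target_proportion_mediated = 0.383,
                          theta_grs = log(1.35),
                          baseline_shape = 6,
                          baseline_scale = 128,
                          followup_years = 14,
                          censor_rate = 0.005,
                          entry_age_mean = 56,
                          entry_age_sd = 8,
                          n_centers = 10,
                          ineligible_fraction = c(prevalent_diabetes = 0.03,
                                                  lipid_lowering_drug = 0.05,
                                                  missing_core_data = 0.02),
                          structure_seed = 20240778L) {
  if (n_participants < 1 || n_metabolites < 1 || n_latent_factors < 1 ||
      n_snps_grs < 1) {
    abort("dimensions must be positive integers")
  }
  if (abs(sum(smoking_prevalence) - 1) > 1e-8 || any(smoking_prevalence < 0)) {
    abort("smoking_prevalence must be a probability vector summing to 1")
  }
  if (!all(c("never", "former", "current") %in% names(smoking_prevalence))) {
    abort("smoking_prevalence must be named never/former/current")
  }
  if (former_attenuation < 0 || lognormal_fraction < 0 || lognormal_fraction > 1) {
    abort("former_attenuation must be >= 0 and lognormal_fraction in [0, 1]")
  }
  if (baseline_shape <= 0 || baseline_scale <= 0 || entry_age_sd <= 0) {
    abort("all variances/scales must be positive")
  }
  if (any(ineligible_fraction < 0) || any(ineligible_fraction >= 1)) {
    abort("ineligible_fraction rates must be in [0, 1)")
  }

  smoking_effect_mode <- match.arg(smoking_effect_mode)
  if (is.null(beta_smoking_on_metabolites)) {
    if (smoking_effect_mode == "factor") {
      # smoking acts through the shared latent factors, so its metabolite
      # effects are dense, signed, and aligned with the correlation
      # structure -- no linear combination can isolate the smoking signal
      # beyond the factor-space shift of size smoking_factor_shift
      ld <- draw_loadings(n_metabolites, n_latent_factors, structure_seed)
      nf <- min(4, n_latent_factors)
      g <- numeric(n_latent_factors)
      g[seq_len(nf)] <- smoking_factor_shift / sqrt(nf) *
        rep_len(c(1, -1), nf)
      beta_smoking_on_metabolites <- drop(ld$loadings %*% g)
    } else {
      k <- min(n_smoking_metabolites, n_metabolites)
      beta <- numeric(n_metabolites)
      if (k > 0) {
        mags <- seq(0.4, 0.05, length.out = k)
        beta[seq_len(k)] <- mags * rep_len(c(1, -1), k)
      }
      beta_smoking_on_metabolites <- beta
    }
  }
  if (length(beta_smoking_on_metabolites) != n_metabolites) {
    abort("beta_smoking_on_metabolites must have length n_metabolites")
  }

  # smoking-induced shift of the true signature (unit-vector weights)
  delta <- sqrt(sum(beta_smoking_on_metabolites^2))

  if (is.null(hazard_spec)) {
    log_total <- log(target_hr_total)
    pm <- target_proportion_mediated
    theta_sig <- if (delta > 0) pm * log_total / delta else 0
    hazard_spec <- hazard_loglinear(
      theta_current = (1 - pm) * log_total,
      theta_former = 0.05,
      theta_signature = theta_sig,
      theta_grs = theta_grs
    )
  }
  if (!inherits(hazard_spec, "hazard_spec")) {
    abort("hazard_spec must come from hazard_loglinear() or hazard_cells()")
  }

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_metabolites = as.integer(n_metabolites),
    n_latent_factors = as.integer(n_latent_factors),
    smoking_prevalence = smoking_prevalence[c("never", "former", "current")],
    beta_smoking_on_metabolites = beta_smoking_on_metabolites,
    smoking_effect_mode = smoking_effect_mode,
    former_attenuation = former_attenuation,
    lognormal_fraction = lognormal_fraction,
    confounder_strength = confounder_strength,
    n_snps_grs = as.integer(n_snps_grs),
    hazard_spec = hazard_spec,
    baseline_shape = baseline_shape,
    baseline_scale = baseline_scale,
    followup_years = followup_years,
    censor_rate = censor_rate,
    entry_age_mean = entry_age_mean,
    entry_age_sd = entry_age_sd,
    n_centers = as.integer(n_centers),
    ineligible_fraction = ineligible_fraction,
    structure_seed = as.integer(structure_seed)
  ), class = "cohort_config")
  cfg
}

#' True mediation parameters implied by a config
#'
#' For a log-linear hazard and a rare outcome, the natural direct log-HR of
#' current vs never smoking is `theta_current` and the natural indirect
#' log-HR through the metabolome is `theta_signature * delta`, where `delta`
#' is the smoking-induced mean shift of the true signature. Returns those
#' together with the implied true proportion mediated.
#'
#' @param config A [cohort_config()].
#' @return A one-row tibble with `log_hr_direct`, `log_hr_indirect`,
#'   `log_hr_total`, `proportion_mediated`.
#' @export
true_mediation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  hs <- config$hazard_spec
  if (hs$type != "loglinear") {
    abort("true mediation parameters are defined for log-linear hazards only")
  }
  delta <- sqrt(sum(config$beta_smoking_on_metabolites^2))
  nde <- hs$theta_current
  nie <- hs$theta_signature * delta
  tibble(log_hr_direct = nde, log_hr_indirect = nie,
         log_hr_total = nde + nie,
         proportion_mediated = if (nde + nie != 0) nie / (nde + nie) else NA_real_)
}

# Factor loadings shared by every cohort from one config. Communalities are
# high (0.85-0.998), as in NMR lipoprotein panels where a few dozen
# components carry nearly all the variance.
draw_loadings <- function(M, q, structure_seed) {
  old <- .Random.seed_exists()
  set.seed(structure_seed)
  on.exit(restore_rng(old), add = TRUE)
  raw <- matrix(rnorm(M * q), M, q)
  communality <- runif(M, 0.97, 0.999)
  loadings <- raw * sqrt(communality / rowSums(raw^2))
  list(loadings = loadings, noise_sd = sqrt(1 - communality))
}

# Structural (config-level) draws shared across cohorts from one config.
cohort_structure <- function(config) {
  M <- config$n_metabolites
  q <- config$n_latent_factors
  ld <- draw_loadings(M, q, config$structure_seed)
  loadings <- ld$loadings
  noise_sd <- ld$noise_sd
  old <- .Random.seed_exists()
  set.seed(derive_seed(config$structure_seed, "structure"))
  on.exit(restore_rng(old), add = TRUE)

  # covariate effects on metabolites (confounding paths)
  conf_names <- c("age_std", "sex_male", "bmi_std", "whr_std", "alcohol",
                  "oily_fish_std", "fasting_std")
  gamma <- matrix(rnorm(M * length(conf_names), 0, 0.08),
                  M, length(conf_names),
                  dimnames = list(NULL, conf_names)) * config$confounder_strength

  lognormal <- seq_len(M) %in%
    sample.int(M, size = round(config$lognormal_fraction * M))

  maf <- runif(config$n_snps_grs, 0.1, 0.5)
  grs_weights <- abs(rnorm(config$n_snps_grs, 0.10, 0.04)) + 0.01

  met_names <- sprintf("met_%03d", seq_len(M))
  snp_names <- sprintf("snp_%02d", seq_len(config$n_snps_grs))

  list(loadings = loadings, noise_sd = noise_sd, gamma = gamma,
       lognormal = lognormal, maf = maf, grs_weights = setNames(grs_weights, snp_names),
       met_names = met_names, snp_names = snp_names,
       signature_weights = {
         b <- config$beta_smoking_on_metabolites
         nb <- sqrt(sum(b^2))
         if (nb > 0) b / nb else b
       })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Config calibrated to a known true proportion mediated
#'
#' Builds a cohort configuration whose hazard carries the smoking effect
#' only through the direct path and the metabolome path, calibrated so the
#' true proportion mediated equals `pm_true` and the total current-vs-never
#' hazard ratio equals `hr_total`. Unrelated hazard paths (GRS, direct
#' covariate effects) are switched off so the mediation estimand is exact
#' rather than approximate; confounding of smoking and of the metabolome by
#' covariates is retained.
#'
#' @param pm_true Target true proportion mediated in `[0, 1]`.
#' @param hr_total Target total hazard ratio (current vs never).
#' @param n_participants,n_metabolites,n_smoking_metabolites Cohort
#'   dimensions (defaults sized for simulation studies).
#' @param baseline_scale Weibull scale; the default gives roughly 5%
#'   cumulative incidence so calibration runs carry enough events for the
#'   check to be informative.
#' @param ... Further arguments passed to [cohort_config()].
#' @return A `cohort_config` with the calibrated log-linear hazard.
#' @export
mediation_calibration_config <- function(pm_true = 0.40, hr_total = 1.73,
                                         n_participants = 20000,
                                         n_metabolites = 20,
                                         n_smoking_metabolites = 10,
                                         baseline_scale = 110, ...) {
  if (pm_true < 0 || pm_true > 1) abort("pm_true must be in [0, 1]")
  base <- cohort_config(n_participants = n_participants,
                        n_metabolites = n_metabolites,
                        n_smoking_metabolites = n_smoking_metabolites,
                        smoking_effect_mode = "sparse",
                        baseline_scale = baseline_scale, ...)
  delta <- sqrt(sum(base$beta_smoking_on_metabolites^2))
  base$hazard_spec <- hazard_loglinear(
    theta_current = (1 - pm_true) * log(hr_total),
    theta_former = 0,
    theta_signature = if (delta > 0) pm_true * log(hr_total) / delta else 0,
    theta_grs = 0,
    covariate_strength = 0
  )
  base
}
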