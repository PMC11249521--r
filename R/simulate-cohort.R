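#' Simulate a biobank-style cohort
#'
#' Generates one row per participant: covariates, confounded three-level
#' smoking status, a correlated metabolome with sparse signed smoking
#' effects, genotypes and a weighted genetic risk score, and a left-truncated
#' time-to-event outcome on the attained-age scale (entry age, exit age,
#' event indicator). A fraction of rows is flagged ineligible (prevalent
#' diabetes, lipid-lowering drugs, missing core data) for
#' [apply_eligibility_filters()] to remove.
#'
#' Identical `(config, seed)` pairs reproduce the table exactly. The column
#' `true_signature` holds the generating metabolic signature (the unit-norm
#' smoking-effect combination of metabolite latent values) and, under a
#' [hazard_cells()] spec, `signature_group` and `grs_category` hold the
#' planted group memberships used by the hazard.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for all participant-level randomness.
#' @return A tibble with one row per participant.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  st <- cohort_structure(config)
  n <- config$n_participants
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  cov <- simulate_covariates(n, config)
  smoking <- simulate_smoking(cov, config)
  met <- simulate_metabolome(cov, smoking, config, st)
  gen <- simulate_genotypes(n, config, st)

  true_sig <- drop(met$latent %*% st$signature_weights)
  grs_raw <- drop(gen$genotypes %*% st$grs_weights)
  grs_std <- as.numeric(scale(grs_raw))

  hs <- config$hazard_spec
  extra <- NULL
  if (hs$type == "loglinear") {
    eta <- hs$theta_current * (smoking == "current") +
      hs$theta_former * (smoking == "former") +
      hs$theta_signature * true_sig +
      hs$theta_grs * grs_std +
      hs$covariate_strength * (0.15 * cov$bmi_std + 0.25 * cov$family_history)
  } else {
    qs <- quantile(grs_raw, c(0.2, 0.8), type = 2)
    grs_category <- cut(grs_raw, c(-Inf, qs, Inf),
                        labels = c("low", "intermediate", "high"))
    signature_group <- factor(ifelse(true_sig > median(true_sig), "high", "low"),
                              levels = c("low", "high"))
    eta <- log(hs$hr[cbind(as.integer(grs_category),
                           as.integer(signature_group))])
    extra <- tibble(grs_category = grs_category, signature_group = signature_group)
  }

  surv <- simulate_survival(cov$entry_age, eta, config)

  flags <- tibble(
    prevalent_diabetes = runif(n) < config$ineligible_fraction[["prevalent_diabetes"]],
    lipid_lowering_drug = runif(n) < config$ineligible_fraction[["lipid_lowering_drug"]],
    missing_core_data = runif(n) < config$ineligible_fraction[["missing_core_data"]]
  )

  out <- bind_cols(
    tibble(participant_id = sprintf("P%07d", seq_len(n))),
    cov$table,
    tibble(smoking_status = smoking),
    as_tibble(met$observed),
    as_tibble(gen$genotypes),
    tibble(grs = grs_raw, true_signature = as.numeric(scale(true_sig))),
    if (!is.null(extra)) extra,
    tibble(entry_age = cov$entry_age,
           exit_age = surv$exit_age,
           event = surv$event),
    flags
  )
  attr(out, "metabolite_names") <- st$met_names
  attr(out, "snp_names") <- st$snp_names
  attr(out, "grs_weights") <- st$grs_weights
  out
}

# --- participant-level building blocks -------------------------------------

simulate_covariates <- function(n, config) {
  age <- pmin(pmax(rnorm(n, config$entry_age_mean, config$entry_age_sd), 40), 70)
  sex <- factor(ifelse(runif(n) < 0.45, "male", "female"),
                levels = c("female", "male"))
  center <- factor(sprintf("center_%02d", sample.int(config$n_centers, n, TRUE)))
  education <- factor(ifelse(runif(n) < 0.48, "higher", "lower"),
                      levels = c("lower", "higher"))
  deprivation <- rnorm(n)
  bmi <- rnorm(n, 27, 4)
  whr <- rnorm(n, 0.86, 0.09)
  fasting_hours <- pmax(rnorm(n, 3.8, 1.5), 0)
  alcohol <- as.integer(runif(n) < 0.8)
  coffee_cups <- rpois(n, 2)
  tea_cups <- rpois(n, 3)
  oily_fish <- pmax(rnorm(n, 1.1, 0.8), 0)
  physical_activity <- as.integer(runif(n) < 0.6)
  family_history <- as.integer(runif(n) < 0.33)
  genotyping_batch <- factor(sprintf("batch_%d", sample.int(2, n, TRUE)))
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, sprintf("genetic_pc%02d", 1:10)))

  table <- bind_cols(
    tibble(age = age, sex = sex, center = center, education = education,
           deprivation = deprivation, bmi = bmi, whr = whr,
           fasting_hours = fasting_hours, alcohol = alcohol,
           coffee_cups = coffee_cups, tea_cups = tea_cups,
           oily_fish = oily_fish, physical_activity = physical_activity,
           family_history = family_history,
           genotyping_batch = genotyping_batch),
    as_tibble(pcs)
  )
  list(table = table,
       entry_age = age,
       age_std = as.numeric(scale(age)),
       sex_male = as.integer(sex == "male"),
       bmi_std = as.numeric(scale(bmi)),
       whr_std = as.numeric(scale(whr)),
       alcohol = alcohol,
       oily_fish_std = as.numeric(scale(oily_fish)),
       fasting_std = as.numeric(scale(fasting_hours)),
       higher_edu = as.integer(education == "higher"),
       deprivation_std = as.numeric(scale(deprivation)),
       family_history = family_history)
}

# Three-level smoking with covariate tilts; per-category multipliers are
# rescaled by fixed-point iteration so the marginal prevalence matches the
# configured vector regardless of confounder strength.
simulate_smoking <- function(cov, config) {
  n <- length(cov$entry_age)
  s <- config$confounder_strength
  tilt_former <- exp(s * (0.15 * cov$age_std + 0.15 * cov$sex_male))
  tilt_current <- exp(s * (-0.20 * cov$age_std + 0.25 * cov$sex_male -
                             0.20 * cov$higher_edu + 0.20 * cov$deprivation_std))
  tilt <- cbind(never = rep(1, n), former = tilt_former, current = tilt_current)
  r <- config$smoking_prevalence
  for (i in 1:40) {
    p <- sweep(tilt, 2, r, `*`)
    p <- p / rowSums(p)
    r <- r * config$smoking_prevalence / colMeans(p)
  }
  p <- sweep(tilt, 2, r, `*`)
  p <- p / rowSums(p)
  u <- runif(n)
  idx <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
  factor(c("never", "former", "current")[idx],
         levels = c("never", "former", "current"))
}

# Latent metabolite values: covariate confounding + shared factors + smoking
# shift + idiosyncratic noise; a configured subset is observed exponentiated.
simulate_metabolome <- function(cov, smoking, config, st) {
  n <- length(smoking)
  M <- config$n_metabolites
  Z <- matrix(rnorm(n * config$n_latent_factors), n, config$n_latent_factors)
  E <- matrix(rnorm(n * M), n, M) %*% diag(st$noise_sd, M)
  C <- cbind(age_std = cov$age_std, sex_male = cov$sex_male,
             bmi_std = cov$bmi_std, whr_std = cov$whr_std,
             alcohol = cov$alcohol, oily_fish_std = cov$oily_fish_std,
             fasting_std = cov$fasting_std)
  smoke_mult <- (smoking == "current") +
    config$former_attenuation * (smoking == "former")
  latent <- C %*% t(st$gamma) + Z %*% t(st$loadings) +
    outer(smoke_mult, config$beta_smoking_on_metabolites) + E
  observed <- latent
  observed[, st$lognormal] <- exp(latent[, st$lognormal, drop = FALSE])
  colnames(observed) <- st$met_names
  colnames(latent) <- st$met_names
  list(latent = latent, observed = observed)
}

simulate_genotypes <- function(n, config, st) {
  K <- config$n_snps_grs
  g <- vapply(seq_len(K), function(k) rbinom(n, 2L, st$maf[k]), integer(n))
  colnames(g) <- st$snp_names
  list(genotypes = g)
}

# Conditional Weibull sampling given survival to entry age (left truncation),
# then administrative + random censoring.
simulate_survival <- function(entry_age, eta, config) {
  n <- length(entry_age)
  b <- config$baseline_scale
  k <- config$baseline_shape
  u <- runif(n)
  t_event <- b * ((entry_age / b)^k - log(u) * exp(-eta))^(1 / k)
  cens <- entry_age + config$followup_years
  if (config$censor_rate > 0) {
    cens <- pmin(cens, entry_age + rexp(n, config$censor_rate))
  }
  event <- as.integer(t_event <= cens)
  exit_age <- pmin(t_event, cens)
  exit_age <- pmax(exit_age, entry_age + 1e-6)
  list(exit_age = exit_age, event = event)
}

#' Metabolite column names of a simulated cohort
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return Character vector of metabolite column names.
#' @export
metabolite_names <- function(cohort) {
  nm <- attr(cohort, "metabolite_names")
  if (is.null(nm)) nm <- grep("^met_", names(cohort), value = TRUE)
  nm
}

#' Remove ineligible participants
#'
#' Drops every row with any eligibility flag set (prevalent diabetes at
#' baseline, lipid-lowering medication, missing core data), mirroring a
#' complete-case study-population filter. Per-flag exclusion counts and the
#' size of their union are recorded in the `exclusion_log` attribute.
#'
#' @param cohort A cohort tibble with logical columns `prevalent_diabetes`,
#'   `lipid_lowering_drug`, `missing_core_data`.
#' @return The filtered tibble, with attribute `exclusion_log` (a tibble of
#'   per-flag and total exclusion counts).
#' @export
apply_eligibility_filters <- function(cohort) {
  flags <- c("prevalent_diabetes", "lipid_lowering_drug", "missing_core_data")
  missing_flags <- setdiff(flags, names(cohort))
  if (length(missing_flags) > 0) {
    abort(paste0("eligibility flags absent: ", paste(missing_flags, collapse = ", ")))
  }
  flag_mat <- as.matrix(cohort[flags])
  any_flag <- rowSums(flag_mat) > 0
  log <- tibble(
    flag = c(flags, "any"),
    n_excluded = unname(c(colSums(flag_mat), sum(any_flag)))
  )
  out <- cohort[!any_flag, , drop = FALSE]
  for (a in c("metabolite_names", "snp_names", "grs_weights")) {
    attr(out, a) <- attr(cohort, a)
  }
  attr(out, "exclusion_log") <- log
  out
}

#' Simulate a repeat-assessment visit
#'
#' Re-measures the metabolome for a subset of participants some years after
#' baseline. Smoking effects on metabolites are scaled by `attenuation`
#' (1 = unchanged, 0 = fully reversed) and measured with fresh latent-factor
#' and noise draws scaled by `noise_scale`; current smokers quit between
#' visits with probability `quit_probability` (quitters become former
#' smokers and their metabolite effects follow the former-smoker
#' attenuation).
#'
#' @param cohort Baseline cohort from [simulate_cohort()].
#' @param config The [cohort_config()] the cohort was generated from.
#' @param attenuation Multiplier in `[0, 1]` on smoking-metabolite effects at
#'   the repeat visit.
#' @param seed Integer seed.
#' @param subset_fraction Fraction of participants re-assessed.
#' @param quit_probability Probability a baseline current smoker has quit.
#' @param noise_scale Multiplier on fresh latent/noise draws (0 gives the
#'   deterministic covariate + smoking mean structure).
#' @return A tibble like the baseline cohort with metabolites and
#'   `smoking_status` replaced by repeat-visit values.
#' @export
simulate_repeat_assessment <- function(cohort, config, attenuation, seed,
                                       subset_fraction = 0.2,
                                       quit_probability = 0.1,
                                       noise_scale = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (attenuation < 0 || attenuation > 1) abort("attenuation must be in [0, 1]")
  st <- cohort_structure(config)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  n0 <- nrow(cohort)
  keep <- sort(sample.int(n0, size = max(2, round(subset_fraction * n0))))
  sub <- cohort[keep, , drop = FALSE]
  n <- nrow(sub)

  smoking <- as.character(sub$smoking_status)
  quit <- smoking == "current" & runif(n) < quit_probability
  smoking[quit] <- "former"
  smoking <- factor(smoking, levels = c("never", "former", "current"))

  cov <- list(age_std = as.numeric(scale(sub$age)),
              sex_male = as.integer(sub$sex == "male"),
              bmi_std = as.numeric(scale(sub$bmi)),
              whr_std = as.numeric(scale(sub$whr)),
              alcohol = sub$alcohol,
              oily_fish_std = as.numeric(scale(sub$oily_fish)),
              fasting_std = as.numeric(scale(sub$fasting_hours)))
  C <- cbind(age_std = cov$age_std, sex_male = cov$sex_male,
             bmi_std = cov$bmi_std, whr_std = cov$whr_std,
             alcohol = cov$alcohol, oily_fish_std = cov$oily_fish_std,
             fasting_std = cov$fasting_std)
  M <- config$n_metabolites
  Z <- matrix(rnorm(n * config$n_latent_factors), n, config$n_latent_factors)
  E <- matrix(rnorm(n * M), n, M) %*% diag(st$noise_sd, M)
  smoke_mult <- (smoking == "current") +
    config$former_attenuation * (smoking == "former")
  latent <- C %*% t(st$gamma) +
    noise_scale * (Z %*% t(st$loadings) + E) +
    attenuation * outer(smoke_mult, config$beta_smoking_on_metabolites)
  observed <- latent
  observed[, st$lognormal] <- exp(latent[, st$lognormal, drop = FALSE])
  colnames(observed) <- st$met_names

  out <- sub
  out[st$met_names] <- as_tibble(observed)
  out$smoking_status <- smoking
  out$true_signature <- as.numeric(scale(drop(latent %*% st$signature_weights)))
  for (a in c("metabolite_names", "snp_names", "grs_weights")) {
    attr(out, a) <- attr(cohort, a)
  }
  out
}
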