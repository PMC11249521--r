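#' Default covariate set for the prospective survival models
#'
#' Age and sex are controlled through stratification (entry-age bands
#' crossed with sex); the remaining main-model covariates are adjusted.
#'
#' @return Character vector of column names.
#' @export
default_survival_covariates <- function() {
  c("center", "education", "deprivation", "bmi", "physical_activity",
    "alcohol", "coffee_cups", "tea_cups", "oily_fish", "family_history")
}

#' Run the full smoking-metabolome-diabetes analysis end to end
#'
#' Executes the whole inference chain on simulated data: cohort generation
#' and eligibility filtering; metabolite preprocessing; the effective number
#' of tests; the current-vs-never metabolite screen; two-sample MR with
#' MR-PRESSO and direction-consistency confirmation; the elastic-net
#' metabolic signature with baseline, external-cohort and internal-external
#' validation; Cox models for smoking and the signature; natural-effects
#' mediation; and the GRS joint/additive/multiplicative interaction
#' analysis. Every stage draws its seed deterministically from the master
#' seed, so reruns with the same config and seed reproduce the report
#' exactly.
#'
#' @param config A [cohort_config()] (the default emulates the study
#'   conditions at desk scale).
#' @param seed Master seed.
#' @param n_boot Mediation bootstrap replicates.
#' @param n_sim_presso MR-PRESSO simulations per metabolite (0 disables the
#'   pleiotropy test).
#' @param run_mr Toggle the MR confirmation stage; when `FALSE` the screen
#'   selection feeds the signature directly and the report notes the skip.
#' @param pc_threshold Cumulative-variance threshold for the effective
#'   number of tests.
#' @param n_iv Number of MR instruments.
#' @param n_outlier_snps,pleiotropy_size Planted pleiotropy in the simulated
#'   summary statistics.
#' @param external_n External validation cohort size.
#' @param repeat_attenuation Smoking-effect attenuation at the repeat
#'   assessment.
#' @param iecv_cycles Internal-external cross-validation cycles.
#' @return A `pipeline_report` list; `print()` shows the headline numbers.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         n_boot = 100, n_sim_presso = 1000, run_mr = TRUE,
                         pc_threshold = 0.99, n_iv = 94,
                         n_outlier_snps = 2, pleiotropy_size = 0.05,
                         external_n = 4000, repeat_attenuation = 0.55,
                         iecv_cycles = 8) {
  cohort_raw <- simulate_cohort(config, derive_seed(seed, "cohort"))
  cohort <- apply_eligibility_filters(cohort_raw)
  met_cols <- metabolite_names(cohort)

  pr <- prep_metabolites(cohort[met_cols])
  eff <- effective_tests(pr$metabolites, threshold = pc_threshold)
  screen <- screen_metabolites(cohort, pr$metabolites, "current_vs_never")
  selected <- select_significant(screen, eff)

  if (run_mr && nrow(selected) > 0) {
    ss <- simulate_gwas_sumstats(config, n_iv = n_iv,
                                 n_outliers = n_outlier_snps,
                                 pleiotropy_size = pleiotropy_size,
                                 seed = derive_seed(seed, "sumstats"),
                                 metabolites = selected$metabolite)
    mr <- mr_screen(ss$exposure, ss$outcomes, n_sim = n_sim_presso,
                    seed = derive_seed(seed, "presso"))
    confirmed <- confirm_metabolites(selected, mr)
  } else {
    ss <- NULL; mr <- NULL
    confirmed <- selected %>% mutate(screen_beta = .data$beta)
  }
  if (nrow(confirmed) < 2) abort("fewer than 2 confirmed metabolites")

  model <- build_signature(cohort, metabolite_cols = confirmed$metabolite,
                           seed = derive_seed(seed, "enet"))
  scores <- compute_signature(model, cohort)
  scores_std <- as.numeric(scale(scores))
  val_baseline <- variance_explained(scores, cohort, cohort_label = "baseline")

  external <- simulate_cohort(
    modifyList_config(config, n_participants = external_n),
    derive_seed(seed, "external")
  )
  external <- apply_eligibility_filters(external)
  val_external <- variance_explained(compute_signature(model, external),
                                     external, cohort_label = "external")

  rep_cohort <- simulate_repeat_assessment(cohort, config,
                                           attenuation = repeat_attenuation,
                                           seed = derive_seed(seed, "repeat"))
  val_repeat <- variance_explained(compute_signature(model, rep_cohort),
                                   rep_cohort, cohort_label = "repeat")

  iecv <- internal_external_cv(cohort, n_cycles = iecv_cycles,
                               seed = derive_seed(seed, "iecv"))

  # prospective Cox models
  surv_cov <- default_survival_covariates()
  cn <- cohort %>% filter(.data$smoking_status %in% c("never", "current"))
  cn$current_smoking <- as.integer(cn$smoking_status == "current")
  fit_smoke <- fit_cox(cn, terms = c("current_smoking", surv_cov))
  hr_smoking <- hr_table(fit_smoke, "current_smoking")

  dat_sig <- cohort
  dat_sig$signature_sd <- scores_std
  dat_sig$signature_high <- as.integer(dichotomize_scores(scores) == "high")
  hr_sig_sd <- hr_table(fit_cox(dat_sig, terms = c("signature_sd", surv_cov)),
                        "signature_sd")
  hr_sig_high <- hr_table(fit_cox(dat_sig, terms = c("signature_high", surv_cov)),
                          "signature_high")

  mediation <- natural_effects(cohort, scores_std, n_boot = n_boot,
                               seed = derive_seed(seed, "mediation"))

  grs <- build_grs(as.matrix(cohort[attr(cohort, "snp_names")]),
                   attr(cohort, "grs_weights"),
                   ids = cohort$participant_id)
  interaction <- joint_interaction(cohort, dichotomize_scores(scores), grs)

  structure(list(
    seed = seed,
    mr_skipped = !run_mr,
    n_raw = nrow(cohort_raw),
    n_analysis = nrow(cohort),
    exclusions = attr(cohort, "exclusion_log"),
    n_events = sum(cohort$event),
    m_eff = eff$m_eff,
    alpha_adjusted = eff$alpha_adjusted,
    screen = screen,
    n_screened = nrow(selected),
    mr = mr,
    n_confirmed = nrow(confirmed),
    confirmed = confirmed,
    signature_model = model,
    n_signature = length(model$weights),
    validation = bind_rows(val_baseline, val_repeat, val_external),
    iecv = iecv,
    hr_smoking = hr_smoking,
    hr_signature_per_sd = hr_sig_sd,
    hr_signature_high = hr_sig_high,
    mediation = mediation,
    interaction = interaction
  ), class = "pipeline_report")
}

# modifyList for a classed config, revalidating through the constructor-set
# fields that matter downstream.
modifyList_config <- function(config, ...) {
  upd <- list(...)
  out <- unclass(config)
  for (nm in names(upd)) out[[nm]] <- upd[[nm]]
  out$n_participants <- as.integer(out$n_participants)
  class(out) <- "cohort_config"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  cohort: %d analysed (%d generated), %d events\n",
              x$n_analysis, x$n_raw, x$n_events))
  cat(sprintf("  screen: m_eff = %d (alpha %.2e); %d selected; %d confirmed%s; %d in signature\n",
              x$m_eff, x$alpha_adjusted, x$n_screened, x$n_confirmed,
              if (x$mr_skipped) " (MR stage skipped)" else " by MR",
              x$n_signature))
  v <- x$validation
  cat(sprintf("  signature R2 by smoking: baseline %.2f%%, repeat %.2f%%, external %.2f%%\n",
              100 * v$r2_smoking[1], 100 * v$r2_smoking[2], 100 * v$r2_smoking[3]))
  cat(sprintf("  IECV R2 range: %.2f%% - %.2f%%\n",
              100 * min(x$iecv$r2_smoking), 100 * max(x$iecv$r2_smoking)))
  cat(sprintf("  HR current vs never: %.2f (%.2f-%.2f)\n",
              x$hr_smoking$hr, x$hr_smoking$ci_low, x$hr_smoking$ci_high))
  cat(sprintf("  HR per SD signature: %.2f (%.2f-%.2f)\n",
              x$hr_signature_per_sd$hr, x$hr_signature_per_sd$ci_low,
              x$hr_signature_per_sd$ci_high))
  e <- x$mediation$estimates
  cat(sprintf("  mediation: total %.2f, NDE %.2f, NIE %.2f, mediated %.1f%%\n",
              e$hr_total, e$hr_nde, e$hr_nie, 100 * e$proportion_mediated))
  rh <- x$interaction$reri %>% filter(.data$grs_category == "high")
  cat(sprintf("  RERI (high GRS): %.2f (%.2f-%.2f); multiplicative LRT p = %.3f\n",
              rh$reri, rh$ci_low, rh$ci_high, x$interaction$multiplicative_lrt$p))
  invisible(x)
}

#' Flatten a pipeline report to its headline numbers
#'
#' @param report A `pipeline_report`.
#' @return A named list of scalar quantities (counts, HRs, proportion
#'   mediated in percent, RERI, R-squared values in percent).
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  v <- report$validation
  rh <- report$interaction$reri %>% filter(.data$grs_category == "high")
  e <- report$mediation$estimates
  list(
    n_analysis = report$n_analysis,
    n_events = report$n_events,
    m_eff = report$m_eff,
    n_screened = report$n_screened,
    n_confirmed = report$n_confirmed,
    n_signature_metabolites = report$n_signature,
    hr_current_vs_never = report$hr_smoking$hr,
    hr_signature_per_sd = report$hr_signature_per_sd$hr,
    hr_signature_high_vs_low = report$hr_signature_high$hr,
    hr_nde = e$hr_nde,
    hr_nie = e$hr_nie,
    proportion_mediated_pct = 100 * e$proportion_mediated,
    reri_high_grs = rh$reri,
    r2_smoking_baseline_pct = 100 * v$r2_smoking[v$cohort_label == "baseline"],
    r2_smoking_repeat_pct = 100 * v$r2_smoking[v$cohort_label == "repeat"],
    r2_smoking_external_pct = 100 * v$r2_smoking[v$cohort_label == "external"],
    r2_iecv_min_pct = 100 * min(report$iecv$r2_smoking),
    r2_iecv_max_pct = 100 * max(report$iecv$r2_smoking),
    multiplicative_lrt_p = report$interaction$multiplicative_lrt$p
  )
}
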