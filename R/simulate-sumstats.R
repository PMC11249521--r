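#' Simulate two-sample GWAS summary statistics
#'
#' Builds instrument-level summary statistics for smoking-initiation liability
#' (the exposure) and for each metabolite (the outcomes), with known true
#' causal effects and optionally planted pleiotropic outlier SNPs. For
#' non-outlier SNPs the outcome association is `true effect x exposure beta`
#' plus sampling noise at the stated standard error; outlier SNPs carry an
#' added pleiotropic offset of magnitude `pleiotropy_size` (random sign).
#'
#' By default each metabolite's true causal effect on the liability scale
#' equals its generative smoking effect, so screening and Mendelian
#' randomization agree in direction for truly smoking-driven metabolites.
#' A fraction of SNPs is reported with effect/other alleles swapped (and the
#' outcome beta negated) to exercise harmonization; strand-ambiguous allele
#' pairs are never generated.
#'
#' @param config A [cohort_config()]; supplies metabolite names and default
#'   true effects.
#' @param n_iv Number of instrument SNPs (default 94).
#' @param n_outliers Number of planted pleiotropic SNPs per metabolite.
#' @param pleiotropy_size Magnitude of the pleiotropic offset on the outcome
#'   beta scale.
#' @param seed Integer seed.
#' @param metabolites Metabolite names to generate outcomes for (default:
#'   all in the config).
#' @param true_effects Optional named vector of true causal effects per
#'   metabolite (per-SD outcome units per liability SD).
#' @param flip_fraction Fraction of outcome rows reported on swapped alleles.
#' @param se_exposure,se_outcome Per-SNP standard errors.
#' @return A list with tibbles `exposure` (snp, ea, nea, beta, se, p, n),
#'   `outcomes` (same columns plus `metabolite`, `is_planted_outlier`) and
#'   `truth` (`metabolite`, `true_effect`).
#' @export
simulate_gwas_sumstats <- function(config, n_iv = 94, n_outliers = 0,
                                   pleiotropy_size = 0, seed = 1,
                                   metabolites = NULL, true_effects = NULL,
                                   flip_fraction = 0.2,
                                   se_exposure = 0.003, se_outcome = 0.01) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_iv < 2) abort("n_iv must be >= 2 (IVW undefined for fewer)")
  if (n_outliers >= n_iv) abort("n_outliers must be < n_iv")
  st <- cohort_structure(config)
  if (is.null(metabolites)) metabolites <- st$met_names
  if (is.null(true_effects)) {
    true_effects <- setNames(config$beta_smoking_on_metabolites, st$met_names)
  }
  missing_te <- setdiff(metabolites, names(true_effects))
  if (length(missing_te) > 0) {
    abort(paste0("no true effect for: ", paste(head(missing_te, 3), collapse = ", ")))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  snp <- sprintf("rs%05d", sample.int(99999, n_iv))
  # non-palindromic allele pairs only
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- pairs[sample.int(nrow(pairs), n_iv, TRUE), , drop = FALSE]
  ea <- pick[, 1]; nea <- pick[, 2]

  beta_exp <- (abs(rnorm(n_iv, 0.018, 0.008)) + 0.004) * sample(c(-1, 1), n_iv, TRUE)
  se_exp <- rep(se_exposure, n_iv)
  exposure <- tibble(
    snp = snp, ea = ea, nea = nea,
    beta = beta_exp, se = se_exp,
    p = 2 * pnorm(-abs(beta_exp / se_exp)),
    n = 632802L
  )

  outcomes <- purrr::map(metabolites, function(m) {
    tau <- true_effects[[m]]
    is_out <- rep(FALSE, n_iv)
    if (n_outliers > 0) is_out[sample.int(n_iv, n_outliers)] <- TRUE
    offset <- ifelse(is_out, pleiotropy_size * sample(c(-1, 1), n_iv, TRUE), 0)
    b <- tau * beta_exp + offset + rnorm(n_iv, 0, se_outcome)
    flip <- runif(n_iv) < flip_fraction
    ea_out <- ifelse(flip, nea, ea)
    nea_out <- ifelse(flip, ea, nea)
    tibble(
      metabolite = m, snp = snp,
      ea = ea_out, nea = nea_out,
      beta = ifelse(flip, -b, b),
      se = rep(se_outcome, n_iv),
      p = 2 * pnorm(-abs(b / se_outcome)),
      n = 115078L,
      is_planted_outlier = is_out
    )
  }) %>% list_rbind()

  list(exposure = exposure,
       outcomes = outcomes,
       truth = tibble(metabolite = metabolites,
                      true_effect = unname(true_effects[metabolites])))
}
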