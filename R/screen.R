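#' Normalize a metabolite matrix
#'
#' Columns whose absolute sample skewness exceeds `skew_threshold` are
#' log-transformed (after adding half the minimum positive value when zeros
#' or negatives-free-but-zero values are present), then every column is
#' divided by its standard deviation. The transformation recipe is returned
#' so the identical preprocessing can be replayed on a new cohort.
#'
#' @param metabolites Numeric matrix (participants x metabolites) with column
#'   names, or a data frame of metabolite columns.
#' @param skew_threshold Absolute skewness above which a column is
#'   log-transformed (default 1).
#' @param prep Optional recipe from a previous call; when supplied the stored
#'   transformations and scale factors are applied unchanged (transfer mode).
#' @return A list with `metabolites` (the transformed matrix) and `prep`
#'   (a tibble recipe: `metabolite`, `log_transformed`, `offset`, `sd_scale`).
#' @export
prep_metabolites <- function(metabolites, skew_threshold = 1, prep = NULL) {
  X <- as.matrix(metabolites)
  if (nrow(X) < 2) abort("need at least 2 rows")
  if (is.null(colnames(X))) abort("metabolite columns must be named")

  if (is.null(prep)) {
    sds0 <- apply(X, 2, sd)
    if (any(sds0 == 0)) {
      abort(paste0("zero-variance metabolite column(s): ",
                   paste(colnames(X)[sds0 == 0], collapse = ", ")))
    }
    skew <- apply(X, 2, sample_skewness)
    log_tr <- abs(skew) > skew_threshold & apply(X, 2, function(x) all(x >= 0))
    offset <- vapply(seq_len(ncol(X)), function(j) {
      if (!log_tr[j]) return(0)
      if (any(X[, j] == 0)) min(X[X[, j] > 0, j]) / 2 else 0
    }, numeric(1))
    for (j in which(log_tr)) X[, j] <- log(X[, j] + offset[j])
    sd_scale <- apply(X, 2, sd)
    if (any(sd_scale == 0)) {
      abort(paste0("zero-variance metabolite column(s) after transform: ",
                   paste(colnames(X)[sd_scale == 0], collapse = ", ")))
    }
    prep <- tibble(metabolite = colnames(X),
                   log_transformed = unname(log_tr),
                   offset = offset,
                   sd_scale = unname(sd_scale))
  } else {
    prep <- prep[match(colnames(X), prep$metabolite), , drop = FALSE]
    if (anyNA(prep$metabolite)) abort("prep recipe missing some metabolites")
    for (j in which(prep$log_transformed)) X[, j] <- log(X[, j] + prep$offset[j])
  }
  X <- sweep(X, 2, prep$sd_scale, `/`)
  list(metabolites = X, prep = prep)
}

#' Effective number of tests from principal components
#'
#' Computes the smallest number of principal components of the metabolite
#' correlation matrix whose cumulative explained variance exceeds
#' `threshold`; the multiple-testing level is then `alpha / m_eff`, a
#' correlation-aware softening of Bonferroni.
#'
#' @param metabolites Standardized metabolite matrix.
#' @param threshold Cumulative explained-variance threshold in (0, 1)
#'   (default 0.99).
#' @param alpha Nominal significance level (default 0.05).
#' @return A list with `m_eff`, `cumulative_variance_threshold`,
#'   `alpha_adjusted`.
#' @export
effective_tests <- function(metabolites, threshold = 0.99, alpha = 0.05) {
  X <- as.matrix(metabolites)
  if (nrow(X) < 2) abort("need at least 2 rows")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cumvar <- cumsum(ev) / sum(ev)
  m_eff <- which(cumvar > threshold)[1]
  list(m_eff = as.integer(m_eff),
       cumulative_variance_threshold = threshold,
       alpha_adjusted = alpha / m_eff)
}

#' Per-metabolite smoking association screen
#'
#' Fits one ordinary least-squares model per metabolite with the prepped
#' metabolite as response and three-level smoking status plus covariates as
#' predictors, and extracts the requested smoking contrast. Variance
#' explained by smoking (`r2_smoking`) is the semi-partial R-squared:
#' full-model R-squared minus the R-squared of the covariate-only model.
#'
#' @param cohort Cohort tibble containing `smoking_status` and the covariates.
#' @param metabolites Prepped metabolite matrix (see [prep_metabolites()])
#'   with rows aligned to `cohort`.
#' @param contrast `"current_vs_never"` or `"former_vs_never"`.
#' @param covariates Character vector of covariate column names.
#' @return A tibble with one row per metabolite: `metabolite`, `contrast`,
#'   `beta`, `se`, `p`, `r2_smoking`, `r2_model`.
#' @export
screen_metabolites <- function(cohort, metabolites,
                               contrast = c("current_vs_never", "former_vs_never"),
                               covariates = default_screen_covariates()) {
  contrast <- match.arg(contrast)
  Y <- as.matrix(metabolites)
  stopifnot(nrow(Y) == nrow(cohort))
  if (!"smoking_status" %in% names(cohort)) abort("smoking_status column required")

  smoking <- factor(cohort$smoking_status, levels = c("never", "former", "current"))
  S <- smoking_indicators(smoking)
  Xc <- build_design(cohort, covariates)
  X <- cbind(Xc, S)

  fit <- ols_multi(X, Y)
  fit0 <- ols_multi(Xc, Y)
  term <- if (contrast == "current_vs_never") "smoking_current" else "smoking_former"
  j <- match(term, colnames(X))
  beta <- fit$coef[j, ]
  df <- nrow(Y) - ncol(X)
  sigma2 <- colSums(fit$residuals^2) / df
  se <- sqrt(sigma2 * fit$xtx_inv_diag[j])
  tval <- beta / se
  r2_full <- r2_from_residuals(Y, fit$residuals)
  r2_cov <- r2_from_residuals(Y, fit0$residuals)

  tibble(metabolite = colnames(Y),
         contrast = contrast,
         beta = unname(beta),
         se = unname(se),
         p = 2 * pt(-abs(tval), df),
         r2_smoking = pmax(r2_full - r2_cov, 0),
         r2_model = r2_full)
}

#' Default covariate set for the metabolite screen
#'
#' Age, sex, assessment center, education, deprivation, fasting time, BMI,
#' waist-to-hip ratio, physical activity and diet/alcohol items -- the
#' standard lifestyle adjustment set for metabolome-wide smoking models.
#'
#' @return Character vector of column names.
#' @export
default_screen_covariates <- function() {
  c("age", "sex", "center", "education", "deprivation", "fasting_hours",
    "bmi", "whr", "physical_activity", "alcohol", "coffee_cups", "tea_cups",
    "oily_fish")
}

#' Variance explained per covariate block
#'
#' Semi-partial R-squared of each covariate (and of smoking status): the drop
#' in model R-squared when that block alone is removed from the full model.
#'
#' @inheritParams screen_metabolites
#' @return A tibble `metabolite` x `term` with column `r2`.
#' @export
screen_r2_attribution <- function(cohort, metabolites,
                                  covariates = default_screen_covariates()) {
  Y <- as.matrix(metabolites)
  smoking <- factor(cohort$smoking_status, levels = c("never", "former", "current"))
  S <- smoking_indicators(smoking)
  blocks <- c(list(smoking_status = S),
              setNames(lapply(covariates, function(v) build_design(cohort, v,
                                                                   intercept = FALSE)),
                       covariates))
  Xfull <- do.call(cbind, c(list(`(Intercept)` = matrix(1, nrow(Y), 1)), blocks))
  r2_full <- r2_from_residuals(Y, ols_multi(Xfull, Y)$residuals)
  purrr::imap(blocks, function(B, nm) {
    keep <- setdiff(names(blocks), nm)
    Xr <- do.call(cbind, c(list(matrix(1, nrow(Y), 1)), blocks[keep]))
    r2_red <- r2_from_residuals(Y, ols_multi(Xr, Y)$residuals)
    tibble(metabolite = colnames(Y), term = nm, r2 = pmax(r2_full - r2_red, 0))
  }) %>% list_rbind()
}

#' Select metabolites passing the effective-tests threshold
#'
#' @param results Screen results from [screen_metabolites()].
#' @param eff Effective-tests object from [effective_tests()].
#' @return Tibble of selected rows with a `direction` column (+1/-1).
#' @export
select_significant <- function(results, eff) {
  if (nrow(results) == 0) abort("empty screen results")
  results %>%
    filter(.data$p < eff$alpha_adjusted) %>%
    mutate(direction = sign(.data$beta))
}
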