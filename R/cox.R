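#' Cox model on the attained-age time scale
#'
#' Fits a proportional-hazards model where age (not time on study) indexes
#' the risk sets: entry is delayed at the enrollment age (left truncation),
#' exit at the event or censoring age. The baseline hazard is stratified, by
#' default on 5-year entry-age bands crossed with sex, so age and sex are
#' controlled through stratification rather than covariates. Ties use the
#' Efron correction unless told otherwise.
#'
#' @param cohort Tibble with `entry_age`, `exit_age`, `event` and all model
#'   columns.
#' @param terms Character vector of right-hand-side terms (column names or
#'   expressions such as interactions `"a:b"`).
#' @param strata Character vector of stratification column names; the
#'   default `"age_sex_band"` builds 5-year entry-age bands crossed with sex
#'   when those columns exist.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param weights Optional numeric case weights.
#' @param age_band_width Width (years) of the entry-age strata bands.
#' @return The `coxph` fit, with the model data attached (`attr "data"`).
#' @export
fit_cox <- function(cohort, terms, strata = "age_sex_band",
                    ties = c("efron", "breslow"), weights = NULL,
                    age_band_width = 5) {
  ties <- match.arg(ties)
  stopifnot(all(c("entry_age", "exit_age", "event") %in% names(cohort)))
  if (any(cohort$exit_age <= cohort$entry_age)) {
    abort("exit_age must exceed entry_age for every row")
  }
  dat <- cohort
  if (identical(strata, "age_sex_band")) {
    band <- floor(dat$entry_age / age_band_width) * age_band_width
    if ("sex" %in% names(dat)) {
      dat$age_sex_band <- interaction(band, dat$sex, drop = TRUE)
    } else {
      dat$age_sex_band <- factor(band)
    }
  }
  rhs <- paste(c(terms,
                 if (length(strata) > 0)
                   paste0("strata(", paste(strata, collapse = ", "), ")")),
               collapse = " + ")
  fml <- as.formula(paste0("survival::Surv(entry_age, exit_age, event) ~ ", rhs))
  dat$.wt <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  fit <- survival::coxph(fml, data = dat, ties = ties, weights = dat$.wt,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 50))
  if (any(is.na(coef(fit)))) {
    abort(paste0("inestimable terms (separation or collinearity): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  attr(fit, "data") <- dat
  fit
}

#' Hazard-ratio table from a Cox fit
#'
#' `HR = exp(coef)` with Wald 95% confidence interval
#' `exp(coef +/- 1.96 se)` and two-sided Wald p-value.
#'
#' @param fit A `coxph` fit.
#' @param terms Optional coefficient names to report (default: all).
#' @return Tibble: `term`, `coef`, `se`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
hr_table <- function(fit, terms = NULL) {
  cf <- coef(fit)
  se <- setNames(sqrt(diag(vcov(fit))), names(cf))
  if (is.null(terms)) terms <- names(cf)
  unknown <- setdiff(terms, names(cf))
  if (length(unknown) > 0) {
    abort(paste0("unknown terms: ", paste(unknown, collapse = ", ")))
  }
  z <- qnorm(0.975)
  b <- unname(cf[terms])
  s <- unname(se[terms])
  tibble(term = terms, coef = b, se = s,
         hr = exp(b),
         ci_low = exp(b - z * s),
         ci_high = exp(b + z * s),
         p = 2 * pnorm(-abs(b / s)))
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param fit_full,fit_reduced Nested `coxph` fits on the same data and
#'   strata.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
cox_lrt <- function(fit_full, fit_reduced) {
  df <- length(coef(fit_full)) - length(coef(fit_reduced))
  if (df <= 0) abort("models are not nested (df <= 0)")
  stat <- 2 * (fit_full$loglik[2] - fit_reduced$loglik[2])
  tibble(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
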