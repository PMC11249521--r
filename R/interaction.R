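#' Weighted-allele genetic risk score with quintile categories
#'
#' `score_i = sum_k w_k g_ik` over risk-allele counts `g` in 0/1/2.
#' Participants are categorized into low (quintile 1), intermediate
#' (quintiles 2-4) and high (quintile 5) genetic risk; quintile ties are
#' broken by rank with a deterministic ordering on participant id.
#'
#' @param genotypes Integer matrix (participants x SNPs) with values 0/1/2
#'   and SNP column names.
#' @param weights Named nonnegative weights (effect sizes), names matching
#'   SNP columns.
#' @param ids Optional participant ids for deterministic tie-breaking
#'   (default: row order).
#' @return A `grs` object: `values`, `categories` (factor
#'   low/intermediate/high), `quintile_cutpoints`, `snp_weights`.
#' @export
build_grs <- function(genotypes, weights, ids = NULL) {
  G <- as.matrix(genotypes)
  missing_snps <- setdiff(names(weights), colnames(G))
  if (length(missing_snps) > 0) {
    abort(paste0("missing SNP columns: ", paste(missing_snps, collapse = ", ")))
  }
  if (!all(G[, names(weights)] %in% 0:2)) abort("genotype entries must be 0, 1 or 2")
  if (any(weights < 0)) warn("negative GRS weights: weights are assumed risk-aligned")
  values <- drop(G[, names(weights), drop = FALSE] %*% weights)
  n <- length(values)
  if (is.null(ids)) ids <- seq_len(n)
  rk <- order(order(values, ids))  # rank with deterministic tie-breaking
  lo <- floor(0.2 * n); hi <- ceiling(0.8 * n)
  categories <- factor(ifelse(rk <= lo, "low",
                              ifelse(rk > hi, "high", "intermediate")),
                       levels = c("low", "intermediate", "high"))
  cut_sorted <- sort(values)
  structure(list(values = values,
                 categories = categories,
                 quintile_cutpoints = c(cut_sorted[max(lo, 1)],
                                        cut_sorted[min(hi, n)]),
                 snp_weights = weights),
            class = "grs")
}

#' @export
print.grs <- function(x, ...) {
  cat("<grs> ", length(x$values), " participants; cutpoints ",
      paste(signif(x$quintile_cutpoints, 4), collapse = " / "), "\n", sep = "")
  print(table(x$categories))
  invisible(x)
}

#' Median split of signature scores
#'
#' @param scores Numeric scores.
#' @return Factor with levels low/high (high = above the median of the
#'   analysis sample).
#' @export
dichotomize_scores <- function(scores) {
  factor(ifelse(scores > median(scores), "high", "low"), levels = c("low", "high"))
}

#' Joint genetic-risk x signature hazard ratios with additive and
#' multiplicative interaction
#'
#' Fits one Cox model (attained-age scale) with five indicator terms for the
#' non-reference cells of the 3 x 2 (genetic risk category x signature
#' level) grid, reference = (low, low). Reports the per-cell hazard ratios
#' with events per cell, the relative excess risk due to interaction (RERI)
#' for the intermediate and high genetic-risk rows with delta-method CIs,
#' and the multiplicative-interaction likelihood-ratio test (main-effects
#' model vs model with the two product terms, df = 2).
#'
#' @param cohort Cohort tibble.
#' @param exposure_level Factor low/high (e.g. [dichotomize_scores()] of the
#'   signature, or a smoking dichotomy).
#' @param grs_category Factor low/intermediate/high from [build_grs()], or a
#'   `grs` object.
#' @param covariates Covariate column names for adjustment.
#' @param strata,age_band_width Passed to [fit_cox()].
#' @return An `interaction_fit` object; see [tidy.interaction_fit()].
#' @export
joint_interaction <- function(cohort, exposure_level, grs_category,
                              covariates = default_interaction_covariates(),
                              strata = "age_sex_band", age_band_width = 5) {
  if (inherits(grs_category, "grs")) grs_category <- grs_category$categories
  exposure_level <- factor(exposure_level, levels = c("low", "high"))
  grs_category <- factor(grs_category, levels = c("low", "intermediate", "high"))
  dat <- cohort
  dat$.grs <- grs_category
  dat$.exp <- exposure_level

  cells <- expand.grid(grs = levels(grs_category), exp = levels(exposure_level),
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$grs == "low" & cells$exp == "low"), ]
  cell_terms <- character(0)
  for (i in seq_len(nrow(cells))) {
    nm <- paste0("cell_", cells$grs[i], "_", cells$exp[i])
    dat[[nm]] <- as.integer(dat$.grs == cells$grs[i] & dat$.exp == cells$exp[i])
    cell_terms <- c(cell_terms, nm)
  }
  counts <- dat %>%
    group_by(.data$.grs, .data$.exp) %>%
    summarise(n = dplyr::n(), n_events = sum(.data$event), .groups = "drop")
  if (any(counts$n == 0)) abort("empty joint cell")
  if (any(counts$n_events == 0)) {
    warn("joint cell(s) with zero events; their HRs are unstable")
  }

  fit <- fit_cox(dat, terms = c(cell_terms, covariates), strata = strata,
                 age_band_width = age_band_width)
  ht <- hr_table(fit, cell_terms)
  joint <- bind_rows(
    tibble(term = "cell_low_low", coef = 0, se = 0, hr = 1,
           ci_low = NA_real_, ci_high = NA_real_, p = NA_real_),
    ht
  ) %>%
    mutate(grs_category = sub("^cell_([a-z]+)_.*$", "\\1", .data$term),
           signature_level = sub("^cell_[a-z]+_([a-z]+)$", "\\1", .data$term)) %>%
    left_join(counts, by = c(grs_category = ".grs", signature_level = ".exp"))

  # additive interaction per non-reference GRS row
  reri_tbl <- purrr::map(c("intermediate", "high"), function(g) {
    r <- reri_delta(fit,
                    term_11 = paste0("cell_", g, "_high"),
                    term_10 = paste0("cell_", g, "_low"),
                    term_01 = "cell_low_high")
    mutate(r, grs_category = g, .before = 1)
  }) %>% list_rbind()

  # multiplicative interaction: main effects vs main + products
  dat$.grs_int <- as.integer(dat$.grs == "intermediate")
  dat$.grs_high <- as.integer(dat$.grs == "high")
  dat$.exp_high <- as.integer(dat$.exp == "high")
  dat$.x_int <- dat$.grs_int * dat$.exp_high
  dat$.x_high <- dat$.grs_high * dat$.exp_high
  fit_main <- fit_cox(dat, terms = c(".grs_int", ".grs_high", ".exp_high",
                                     covariates),
                      strata = strata, age_band_width = age_band_width)
  fit_prod <- fit_cox(dat, terms = c(".grs_int", ".grs_high", ".exp_high",
                                     ".x_int", ".x_high", covariates),
                      strata = strata, age_band_width = age_band_width)
  lrt <- cox_lrt(fit_prod, fit_main)

  structure(list(joint_hr_table = joint,
                 reri = reri_tbl,
                 multiplicative_lrt = lrt,
                 fit = fit),
            class = "interaction_fit")
}

#' Default covariate set for gene-environment interaction models
#'
#' The interaction variant of the adjustment set: no ethnicity or family
#' history, with genotyping batch and 10 genetic principal components added.
#'
#' @return Character vector of column names.
#' @export
default_interaction_covariates <- function() {
  c("education", "deprivation", "bmi", "alcohol", "physical_activity",
    "coffee_cups", "tea_cups", "oily_fish", "genotyping_batch",
    sprintf("genetic_pc%02d", 1:10))
}

#' Relative excess risk due to interaction from hazard ratios
#'
#' `RERI = HR11 - HR10 - HR01 + 1`: the departure of the joint hazard ratio
#' from additivity of the two separate excess risks. Zero means exact
#' additivity.
#'
#' @param hr_11 Joint-exposure HR (both factors high).
#' @param hr_10,hr_01 Single-factor HRs against the double-reference cell.
#' @return The RERI point estimate.
#' @export
reri <- function(hr_11, hr_10, hr_01) {
  hr_11 - hr_10 - hr_01 + 1
}

#' RERI with delta-method confidence interval from a Cox fit
#'
#' Computes `RERI = exp(b11) - exp(b10) - exp(b01) + 1` from three named
#' log-HR coefficients of a fitted Cox model, with a normal-approximation CI
#' from the delta method: the gradient with respect to the three
#' coefficients is `(exp(b11), -exp(b10), -exp(b01))` and the variance is
#' the quadratic form with the coefficient covariance.
#'
#' @param fit A `coxph` fit containing the three terms.
#' @param term_11,term_10,term_01 Coefficient names for the joint and the
#'   two single-exposure cells.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `reri`, `se`, `ci_low`, `ci_high`.
#' @export
reri_delta <- function(fit, term_11, term_10, term_01, level = 0.95) {
  cf <- coef(fit)
  V <- vcov(fit)
  terms <- c(term_11, term_10, term_01)
  unknown <- setdiff(terms, names(cf))
  if (length(unknown) > 0) {
    abort(paste0("terms not in fit: ", paste(unknown, collapse = ", ")))
  }
  b <- cf[terms]
  est <- reri(exp(b[1]), exp(b[2]), exp(b[3]))
  grad <- c(exp(b[1]), -exp(b[2]), -exp(b[3]))
  se <- sqrt(drop(t(grad) %*% V[terms, terms] %*% grad))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(reri = unname(est), se = se,
         ci_low = unname(est) - z * se, ci_high = unname(est) + z * se)
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("<interaction_fit>\n")
  print(x$joint_hr_table %>%
          select("grs_category", "signature_level", "n_events", "hr",
                 "ci_low", "ci_high"))
  cat("RERI:\n"); print(x$reri)
  cat(sprintf("multiplicative LRT p = %.3g (df = %d)\n",
              x$multiplicative_lrt$p, x$multiplicative_lrt$df))
  invisible(x)
}

#' Tidy an interaction fit
#'
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @return The joint HR table as a tibble (one row per cell).
#' @export
tidy.interaction_fit <- function(x, ...) {
  x$joint_hr_table %>%
    select("grs_category", "signature_level", "n", "n_events", "hr",
           "ci_low", "ci_high", "p")
}

#' @rdname tidy.interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  high <- x$reri %>% filter(.data$grs_category == "high")
  tibble(reri_high = high$reri, reri_high_ci_low = high$ci_low,
         reri_high_ci_high = high$ci_high,
         multiplicative_lrt_p = x$multiplicative_lrt$p)
}
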