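#' Harmonize exposure and outcome summary statistics
#'
#' Matches SNPs by id, flips the outcome beta when the effect/other alleles
#' are swapped relative to the exposure file, and drops strand-ambiguous
#' (A/T, C/G) SNPs and SNPs whose alleles cannot be reconciled. Exclusions
#' are recorded in the `harmonization_log` attribute.
#'
#' @param exposure_stats,outcome_stats Tibbles with columns `snp`, `ea`,
#'   `nea`, `beta`, `se`, `p`, `n`.
#' @return A tibble of harmonized pairs with columns `snp`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (plus any extra outcome
#'   columns such as truth labels).
#' @export
harmonize_sumstats <- function(exposure_stats, outcome_stats) {
  req <- c("snp", "ea", "nea", "beta", "se")
  for (tb in list(exposure_stats, outcome_stats)) {
    if (!all(req %in% names(tb))) {
      abort(paste0("summary statistics need columns: ", paste(req, collapse = ", ")))
    }
  }
  palindromic <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  exp_pal <- palindromic(toupper(exposure_stats$ea), toupper(exposure_stats$nea))
  out_pal <- palindromic(toupper(outcome_stats$ea), toupper(outcome_stats$nea))

  ex <- exposure_stats[!exp_pal, ] %>%
    rename(ea_exp = "ea", nea_exp = "nea", beta_exposure = "beta",
           se_exposure = "se")
  ou <- outcome_stats[!out_pal, ] %>%
    rename(ea_out = "ea", nea_out = "nea", beta_outcome = "beta",
           se_outcome = "se")
  m <- dplyr::inner_join(
    ex %>% select("snp", "ea_exp", "nea_exp", "beta_exposure", "se_exposure"),
    ou %>% select(-dplyr::any_of(c("p", "n"))),
    by = "snp"
  )
  same <- toupper(m$ea_out) == toupper(m$ea_exp) &
    toupper(m$nea_out) == toupper(m$nea_exp)
  swapped <- toupper(m$ea_out) == toupper(m$nea_exp) &
    toupper(m$nea_out) == toupper(m$ea_exp)
  mismatched <- !(same | swapped)

  out <- m[!mismatched, , drop = FALSE]
  out$beta_outcome[swapped[!mismatched]] <- -out$beta_outcome[swapped[!mismatched]]
  out <- out %>%
    select(-"ea_out", -"nea_out") %>%
    rename(ea = "ea_exp", nea = "nea_exp")
  if (nrow(out) == 0) abort("no SNPs left after harmonization")

  attr(out, "harmonization_log") <- tibble(
    reason = c("palindromic_exposure", "palindromic_outcome",
               "unmatched", "allele_mismatch", "flipped"),
    n = c(sum(exp_pal), sum(out_pal),
          nrow(ex) - nrow(m), sum(mismatched), sum(swapped & !mismatched))
  )
  out
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_outcome / beta_exposure`; the standard error uses the
#' first-order delta approximation `se_outcome / |beta_exposure|`.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Per-SNP
#'   statistics (vectorized).
#' @return A tibble with `beta` and `se`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (any(beta_exposure == 0)) abort("zero exposure beta: Wald ratio undefined")
  tibble(beta = beta_outcome / beta_exposure,
         se = se_outcome / abs(beta_exposure))
}

#' Inverse-variance-weighted MR estimate
#'
#' Meta-analyses the per-SNP Wald ratios with weights `1 / se_i^2` (the
#' first-order Wald-ratio variances), which is identical to the slope of a
#' zero-intercept weighted regression of outcome betas on exposure betas with
#' weights `1 / se_outcome^2`. By default a multiplicative random-effects
#' variant is used: the fixed-effect standard error is inflated by
#' `sqrt(Q / (k - 1))` whenever Cochran's Q exceeds its degrees of freedom.
#' With a single SNP the estimate reduces to the Wald ratio.
#'
#' @param pairs Harmonized pairs from [harmonize_sumstats()].
#' @param method `"random"` (multiplicative, default) or `"fixed"`.
#' @return A one-row tibble: `n_snps_used`, `beta_ivw`, `se_ivw`, `p_ivw`,
#'   `q_statistic`.
#' @export
mr_ivw <- function(pairs, method = c("random", "fixed")) {
  method <- match.arg(method)
  k <- nrow(pairs)
  if (k < 1) abort("no harmonized pairs")
  wr <- wald_ratio(pairs$beta_exposure, pairs$se_exposure,
                   pairs$beta_outcome, pairs$se_outcome)
  w <- 1 / wr$se^2
  if (!any(is.finite(w))) abort("all IVW weights non-finite")
  beta <- sum(w * wr$beta) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  q <- sum(w * (wr$beta - beta)^2)
  se <- se_fe
  if (method == "random" && k > 1) {
    se <- se_fe * sqrt(max(q / (k - 1), 1))
  }
  tibble(n_snps_used = as.integer(k),
         beta_ivw = beta, se_ivw = se,
         p_ivw = 2 * pnorm(-abs(beta / se)),
         q_statistic = q)
}

#' MR-PRESSO global test, outlier detection and corrected estimate
#'
#' Simulation-based test for horizontal pleiotropy. The observed residual sum
#' of squares (each SNP's outcome beta against its leave-one-out IVW
#' prediction, inverse-variance weighted) is compared with `n_sim` replicates
#' drawn under the no-pleiotropy model (outcome betas normal around the
#' leave-one-out slope times the exposure betas at their stated standard
#' errors, exposure betas redrawn at theirs). The global p-value is the
#' simulated exceedance probability. Each SNP's observed weighted residual is
#' compared with its own simulated distribution; SNPs with
#' Bonferroni-adjusted empirical p below `outlier_alpha` are flagged, and the
#' IVW estimate is recomputed without them.
#'
#' @param pairs Harmonized pairs (at least 4 SNPs).
#' @param n_sim Number of null simulations (>= 100; default 1000).
#' @param outlier_alpha Per-family outlier test level (Bonferroni over SNPs).
#' @param seed Integer seed.
#' @return A list: `global_p`, `outlier_snps` (character), `outlier_p`
#'   (named vector), `beta_corrected` (one-row IVW tibble or `NULL` when no
#'   outliers are flagged).
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  k <- nrow(pairs)
  if (k < 4) abort("MR-PRESSO needs at least 4 SNPs")
  if (n_sim < 100) abort("n_sim must be >= 100")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  bx <- pairs$beta_exposure; sx <- pairs$se_exposure
  by <- pairs$beta_outcome; sy <- pairs$se_outcome
  w <- 1 / sy^2

  loo_resid2 <- function(bx, by) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    slope_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
    w * (by - slope_loo * bx)^2
  }
  obs <- loo_resid2(bx, by)
  rss_obs <- sum(obs)

  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  slope_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)

  bx_sim <- matrix(rnorm(k * n_sim, bx, sx), k, n_sim)
  by_sim <- matrix(rnorm(k * n_sim, slope_loo * bx, sy), k, n_sim)
  sxy_s <- colSums(w * bx_sim * by_sim)
  sxx_s <- colSums(w * bx_sim^2)
  slope_s <- sweep(-(w * bx_sim * by_sim), 2, sxy_s, `+`) /
    sweep(-(w * bx_sim^2), 2, sxx_s, `+`)
  resid_s <- w * (by_sim - slope_s * bx_sim)^2
  rss_sim <- colSums(resid_s)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  # raw exceedance proportion (may be exactly 0 for gross outliers), so the
  # Bonferroni-adjusted per-SNP test retains power at moderate n_sim
  outlier_p <- rowMeans(resid_s >= obs)
  names(outlier_p) <- pairs$snp
  flagged <- pairs$snp[outlier_p < outlier_alpha / k]

  beta_corrected <- NULL
  if (length(flagged) > 0 && k - length(flagged) >= 1) {
    beta_corrected <- mr_ivw(pairs[!pairs$snp %in% flagged, , drop = FALSE])
  }
  list(global_p = global_p,
       outlier_snps = flagged,
       outlier_p = outlier_p,
       beta_corrected = beta_corrected)
}

#' Run IVW + MR-PRESSO for every screened metabolite
#'
#' @param exposure_stats Exposure summary statistics tibble.
#' @param outcome_stats Long outcome tibble with a `metabolite` column.
#' @param metabolites Which metabolites to analyse (default: all present).
#' @param n_sim,outlier_alpha,seed Passed to [mr_presso()]; set `n_sim = 0`
#'   to skip the pleiotropy test.
#' @return A tibble with one row per metabolite: IVW fields plus
#'   `presso_global_p`, `n_outliers`, `outlier_snps` (list column),
#'   `beta_used`, `se_used`, `p_used` (outlier-corrected when available).
#' @export
mr_screen <- function(exposure_stats, outcome_stats, metabolites = NULL,
                      n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  if (is.null(metabolites)) metabolites <- unique(outcome_stats$metabolite)
  purrr::imap(setNames(metabolites, metabolites), function(m, nm) {
    ou <- outcome_stats %>% filter(.data$metabolite == m)
    pairs <- harmonize_sumstats(exposure_stats, ou %>% select(-"metabolite"))
    est <- mr_ivw(pairs)
    pg <- NA_real_; outliers <- character(0)
    used <- est
    if (n_sim > 0 && nrow(pairs) >= 4) {
      pr <- mr_presso(pairs, n_sim = n_sim, outlier_alpha = outlier_alpha,
                      seed = derive_seed(seed, m))
      pg <- pr$global_p
      outliers <- pr$outlier_snps
      if (!is.null(pr$beta_corrected)) used <- pr$beta_corrected
    }
    tibble(metabolite = m,
           n_snps_used = est$n_snps_used,
           beta_ivw = est$beta_ivw, se_ivw = est$se_ivw, p_ivw = est$p_ivw,
           q_statistic = est$q_statistic,
           presso_global_p = pg,
           n_outliers = length(outliers),
           outlier_snps = list(outliers),
           beta_used = used$beta_ivw, se_used = used$se_ivw,
           p_used = used$p_ivw)
  }) %>% list_rbind()
}

#' Confirm screened metabolites by MR direction consistency
#'
#' A metabolite is kept when its MR estimate (outlier-corrected when
#' available) points in the same direction as its baseline screen estimate
#' and its MR p-value is below `alpha`.
#'
#' @param screen_selected Output of [select_significant()] (needs
#'   `metabolite` and `direction`).
#' @param mr_estimates Output of [mr_screen()].
#' @param alpha MR significance level (default 0.05).
#' @return Tibble of confirmed metabolites with both estimates.
#' @export
confirm_metabolites <- function(screen_selected, mr_estimates, alpha = 0.05) {
  unmatched <- setdiff(screen_selected$metabolite, mr_estimates$metabolite)
  if (length(unmatched) > 0) {
    abort(paste0("no MR estimate for: ", paste(head(unmatched, 5), collapse = ", ")))
  }
  screen_selected %>%
    select("metabolite", screen_beta = "beta", "direction") %>%
    left_join(mr_estimates, by = "metabolite") %>%
    filter(sign(.data$beta_used) == .data$direction, .data$p_used < alpha)
}
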