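make_pairs <- function(k = 10, tau = 0.3, seed = 1, se_out = 0.01,
                       signed = TRUE) {
  set.seed(seed)
  bx <- runif(k, 0.01, 0.05) * (if (signed) sample(c(-1, 1), k, TRUE) else 1)
  tibble::tibble(snp = paste0("rs", seq_len(k)),
                 beta_exposure = bx, se_exposure = 0.003,
                 beta_outcome = tau * bx + rnorm(k, 0, se_out),
                 se_outcome = se_out)
}

test_that("harmonization matches, flips and filters alleles", {
  ex <- tibble::tibble(snp = c("rs1", "rs2", "rs3", "rs4"),
                       ea = c("A", "G", "A", "C"), nea = c("G", "A", "T", "A"),
                       beta = c(0.02, -0.01, 0.03, 0.015), se = 0.003,
                       p = 0.01, n = 1000)
  ou <- tibble::tibble(snp = c("rs1", "rs2", "rs3", "rs5"),
                       ea = c("A", "A", "A", "A"), nea = c("G", "G", "T", "G"),
                       beta = c(0.1, 0.2, 0.3, 0.4), se = 0.01,
                       p = 0.01, n = 1000)
  h <- harmonize_sumstats(ex, ou)
  # rs1 identical coding, rs2 swapped (beta negated), rs3 palindromic (A/T)
  # dropped, rs4/rs5 unmatched
  expect_equal(h$snp, c("rs1", "rs2"))
  expect_equal(h$beta_outcome, c(0.1, -0.2))
  log <- attr(h, "harmonization_log")
  expect_equal(log$n[log$reason == "palindromic_exposure"], 1)
  expect_equal(log$n[log$reason == "flipped"], 1)

  expect_error(harmonize_sumstats(ex[2, ], ou[3, ]), "no SNPs")
})

test_that("Wald ratio follows the delta rule", {
  wr <- wald_ratio(0.2, 0.003, 0.06, 0.01)
  expect_equal(wr$beta, 0.3)
  expect_equal(wr$se, 0.05)
  # symmetry under exposure sign flip
  wr2 <- wald_ratio(-0.2, 0.003, 0.06, 0.01)
  expect_equal(wr2$beta, -0.3)
  expect_equal(wr2$se, 0.05)
  expect_equal(wald_ratio(0.2, 0.003, 0, 0.01)$beta, 0)
  expect_error(wald_ratio(0, 0.003, 0.06, 0.01), "zero exposure")
})

test_that("IVW reduces to Wald for one SNP and averages known ratios", {
  p1 <- make_pairs(k = 1)
  est1 <- mr_ivw(p1)
  wr <- wald_ratio(p1$beta_exposure, p1$se_exposure,
                   p1$beta_outcome, p1$se_outcome)
  expect_equal(est1$beta_ivw, wr$beta)
  expect_equal(est1$se_ivw, wr$se)

  # ratios 0.1/0.2/0.3 with equal Wald SEs -> weighted mean 0.2
  p3 <- tibble::tibble(snp = c("a", "b", "c"),
                       beta_exposure = 1, se_exposure = 0.01,
                       beta_outcome = c(0.1, 0.2, 0.3), se_outcome = 0.1)
  expect_equal(mr_ivw(p3)$beta_ivw, 0.2)
})

test_that("IVW equals zero-intercept weighted least squares", {
  for (s in 1:20) {
    p <- make_pairs(k = sample(4:30, 1), tau = runif(1, -1, 1), seed = s,
                    se_out = runif(1, 0.005, 0.05))
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = p,
              weights = 1 / p$se_outcome^2)
    expect_equal(mr_ivw(p)$beta_ivw, unname(coef(wls)[1]), tolerance = 1e-10)
  }
})

test_that("IVW is invariant to SNP order and joint sign flips", {
  p <- make_pairs(k = 15, seed = 3)
  est <- mr_ivw(p)
  expect_equal(mr_ivw(p[sample(15), ]), est)
  flipped <- p
  flipped$beta_exposure <- -flipped$beta_exposure
  flipped$beta_outcome <- -flipped$beta_outcome
  expect_equal(mr_ivw(flipped)$beta_ivw, est$beta_ivw)
})

test_that("random-effect SE never undercuts fixed-effect SE", {
  p <- make_pairs(k = 20, seed = 5, se_out = 0.002)
  p$beta_outcome <- p$beta_outcome + rnorm(20, 0, 0.02)  # overdispersion
  fe <- mr_ivw(p, method = "fixed")
  re <- mr_ivw(p, method = "random")
  expect_gt(re$q_statistic / 19, 1)
  expect_gte(re$se_ivw, fe$se_ivw)
})

test_that("MR-PRESSO flags planted pleiotropic SNPs and corrects the estimate", {
  p <- make_pairs(k = 20, tau = 0.3, seed = 6, signed = FALSE)
  out_idx <- c(3, 11, 17)
  p$beta_outcome[out_idx] <- p$beta_outcome[out_idx] + 0.12
  pr <- mr_presso(p, n_sim = 500, seed = 2)
  expect_lt(pr$global_p, 0.05)
  expect_gte(length(intersect(pr$outlier_snps, p$snp[out_idx])), 2)
  # corrected estimate closer to the generating effect
  raw <- mr_ivw(p)$beta_ivw
  expect_lt(abs(pr$beta_corrected$beta_ivw - 0.3), abs(raw - 0.3))

  expect_error(mr_presso(p[1:3, ], n_sim = 500), "at least 4")
  expect_error(mr_presso(p, n_sim = 10), "n_sim")
})

test_that("MR-PRESSO global test is calibrated under the null", {
  ps <- vapply(1:40, function(s) {
    p <- make_pairs(k = 20, tau = 0.3, seed = 100 + s)
    mr_presso(p, n_sim = 200, seed = s)$global_p
  }, numeric(1))
  # p-values roughly uniform: no mass collapse at the low end
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
})

test_that("confirmation requires direction consistency and MR significance", {
  sel <- tibble::tibble(metabolite = c("m1", "m2", "m3"),
                        beta = c(0.3, 0.2, -0.25), direction = c(1, 1, -1))
  mr <- tibble::tibble(metabolite = c("m1", "m2", "m3"),
                       n_snps_used = 10L,
                       beta_ivw = c(0.28, -0.3, -0.2),
                       se_ivw = 0.05, p_ivw = c(1e-4, 1e-4, 0.2),
                       q_statistic = 9,
                       presso_global_p = 0.5, n_outliers = 0,
                       outlier_snps = list(character(0)),
                       beta_used = c(0.28, -0.3, -0.2), se_used = 0.05,
                       p_used = c(1e-4, 1e-4, 0.2))
  conf <- confirm_metabolites(sel, mr)
  # m2 wrong direction, m3 not significant
  expect_equal(conf$metabolite, "m1")
  expect_error(confirm_metabolites(dplyr::mutate(sel, metabolite = c("m1", "mX", "m3")), mr),
               "mX")
})

test_that("simulated summary statistics recover the planted causal effect", {
  cfg <- tiny_config()
  ss <- simulate_gwas_sumstats(cfg, n_iv = 94, seed = 4,
                               metabolites = "met_001")
  h <- harmonize_sumstats(ss$exposure,
                          dplyr::select(ss$outcomes, -"metabolite"))
  est <- mr_ivw(h)
  truth <- ss$truth$true_effect[1]
  expect_lt(abs(est$beta_ivw - truth), 3 * est$se_ivw + 0.05)
  expect_error(simulate_gwas_sumstats(cfg, n_iv = 1), "n_iv")
  expect_error(simulate_gwas_sumstats(cfg, n_iv = 5, n_outliers = 5),
               "n_outliers")
})
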