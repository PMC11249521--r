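test_that("GRS is the weighted allele sum with quintile categories", {
  g <- matrix(0L, 5, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_equal(build_grs(g, c(s1 = 0.3, s2 = 0.2))$values, rep(0, 5))
  g2 <- matrix(c(2L, 0L), 1, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_equal(build_grs(g2, c(s1 = 0.5, s2 = 0.4))$values, 1.0)

  set.seed(7)
  G <- matrix(rbinom(10000 * 4, 2, 0.3), 10000, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  grs <- build_grs(G, setNames(runif(4, 0.05, 0.2), paste0("s", 1:4)))
  frac <- prop.table(table(grs$categories))
  expect_equal(unname(frac[["low"]]), 0.2, tolerance = 0.001)
  expect_equal(unname(frac[["intermediate"]]), 0.6, tolerance = 0.001)
  expect_equal(unname(frac[["high"]]), 0.2, tolerance = 0.001)

  expect_error(build_grs(G, c(sX = 0.1)), "sX")
  expect_warning(build_grs(G, c(s1 = -0.1, s2 = 0.1, s3 = 0.1, s4 = 0.1)),
                 "negative")
})

test_that("median split halves the sample", {
  set.seed(9)
  grp <- dichotomize_scores(rnorm(1001))
  expect_lte(abs(sum(grp == "high") - sum(grp == "low")), 1)
})

test_that("RERI is the departure from hazard-ratio additivity", {
  # exact additive null
  expect_equal(reri(1.5 + 1.8 - 1, 1.5, 1.8), 0)
  # joint analysis of the insulin-resistance genetic score and the
  # metabolic signature: printed row recomputes exactly
  expect_equal(reri(1.79, 1.06, 1.48), 0.25)
})

test_that("both RERI code paths agree and the delta CI matches a parametric bootstrap", {
  cfg <- cohort_config(n_participants = 8000, n_metabolites = 10,
                       n_smoking_metabolites = 5, n_latent_factors = 3,
                       n_snps_grs = 8,
                       hazard_spec = hazard_cells(
                         rbind(c(1, 1.8), c(1.2, 2.1), c(1.5, 2.6))),
                       baseline_scale = 100)
  co <- simulate_cohort(cfg, seed = 79)
  ia <- joint_interaction(co, co$signature_group, co$grs_category,
                          covariates = character(0))

  # path 1: from the joint HR table; path 2: delta method on coefficients
  tab <- ia$joint_hr_table
  hr <- function(g, e) tab$hr[tab$grs_category == g & tab$signature_level == e]
  expect_equal(reri(hr("high", "high"), hr("high", "low"), hr("low", "high")),
               ia$reri$reri[ia$reri$grs_category == "high"], tolerance = 1e-12)

  # parametric bootstrap from the coefficient covariance
  fit <- ia$fit
  terms <- c("cell_high_high", "cell_high_low", "cell_low_high")
  V <- vcov(fit)[terms, terms]
  b <- coef(fit)[terms]
  set.seed(83)
  L <- chol(V)
  draws <- matrix(rnorm(2000 * 3), 2000, 3) %*% L
  draws <- sweep(draws, 2, b, `+`)
  reris <- exp(draws[, 1]) - exp(draws[, 2]) - exp(draws[, 3]) + 1
  bq <- quantile(reris, c(0.025, 0.975))
  row <- ia$reri[ia$reri$grs_category == "high", ]
  width <- row$ci_high - row$ci_low
  expect_lt(abs(row$ci_low - bq[[1]]), 0.1 * width)
  expect_lt(abs(row$ci_high - bq[[2]]), 0.1 * width)
})

test_that("planted joint-cell hazards are recovered within their CIs", {
  hrm <- rbind(c(1, 1.5), c(1.2, 1.8), c(1.6, 2.4))
  cfg <- cohort_config(n_participants = 30000, n_metabolites = 10,
                       n_smoking_metabolites = 5, n_latent_factors = 3,
                       n_snps_grs = 8, hazard_spec = hazard_cells(hrm),
                       baseline_scale = 100)
  co <- simulate_cohort(cfg, seed = 89)
  ia <- joint_interaction(co, co$signature_group, co$grs_category,
                          covariates = character(0))
  tab <- ia$joint_hr_table
  for (i in seq_len(nrow(tab))) {
    truth <- hrm[match(tab$grs_category[i], c("low", "intermediate", "high")),
                 match(tab$signature_level[i], c("low", "high"))]
    if (tab$grs_category[i] == "low" && tab$signature_level[i] == "low") next
    expect_gt(truth, tab$ci_low[i] * 0.999)
    expect_lt(truth, tab$ci_high[i] * 1.001)
  }
  expect_equal(tab$hr[tab$grs_category == "low" & tab$signature_level == "low"], 1)
})

test_that("a multiplicative generator shows positive RERI and a null product term", {
  # log-linear hazard in signature and GRS: multiplicative by construction,
  # so RERI = (HR10 - 1)(HR01 - 1) > 0 in expectation and the product-term
  # LRT is null
  cfg <- cohort_config(n_participants = 20000, n_metabolites = 10,
                       n_smoking_metabolites = 5, n_latent_factors = 3,
                       n_snps_grs = 8, baseline_scale = 100,
                       hazard_spec = hazard_loglinear(
                         theta_current = 0, theta_signature = 0.35,
                         theta_grs = 0.35, covariate_strength = 0))
  reris <- numeric(3); ps <- numeric(3)
  for (s in 1:3) {
    co <- simulate_cohort(cfg, seed = 90 + s)
    grs <- build_grs(as.matrix(co[attr(co, "snp_names")]),
                     attr(co, "grs_weights"), ids = co$participant_id)
    ia <- joint_interaction(co, dichotomize_scores(co$true_signature), grs,
                            covariates = character(0))
    reris[s] <- ia$reri$reri[ia$reri$grs_category == "high"]
    ps[s] <- ia$multiplicative_lrt$p
  }
  expect_gt(mean(reris), 0)
  expect_gt(mean(ps), 0.05)  # no spurious multiplicative interaction
})

test_that("delta-method CI width shrinks with sample size", {
  widths <- vapply(c(5000, 20000), function(n) {
    cfg <- cohort_config(n_participants = n, n_metabolites = 10,
                         n_smoking_metabolites = 5, n_latent_factors = 3,
                         n_snps_grs = 8, baseline_scale = 100,
                         hazard_spec = hazard_cells(
                           rbind(c(1, 1.8), c(1.2, 2), c(1.5, 2.3))))
    co <- simulate_cohort(cfg, seed = 97)
    ia <- joint_interaction(co, co$signature_group, co$grs_category,
                            covariates = character(0))
    row <- ia$reri[ia$reri$grs_category == "high", ]
    row$ci_high - row$ci_low
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.5)
})
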