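test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$exit_age, c$exit_age))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_participants = 0), "positive")
  expect_error(cohort_config(smoking_prevalence = c(never = 0.5, former = 0.4,
                                                    current = 0.4)), "sum")
  expect_error(tiny_config(former_attenuation = -1), "former_attenuation")
  expect_error(hazard_cells(rbind(c(2, 1.8), c(1.2, 2), c(1.5, 2.3))),
               "reference cell")
  expect_error(hazard_cells(matrix(1, 2, 2)), "3 x 2")
})

test_that("cohort satisfies its structural invariants", {
  co <- simulate_cohort(tiny_config(n = 1500), seed = 3)
  expect_true(all(co$exit_age > co$entry_age))
  expect_true(all(co$event %in% 0:1))
  snps <- attr(co, "snp_names")
  expect_true(all(as.matrix(co[snps]) %in% 0:2))
  expect_false(anyNA(co[metabolite_names(co)]))
})

test_that("smoking prevalence matches the configured marginals", {
  cfg <- cohort_config(n_participants = 50000, n_metabolites = 5,
                       n_smoking_metabolites = 2, n_latent_factors = 2,
                       n_snps_grs = 4)
  co <- simulate_cohort(cfg, seed = 5)
  p_hat <- prop.table(table(co$smoking_status))
  for (lvl in names(cfg$smoking_prevalence)) {
    p <- cfg$smoking_prevalence[[lvl]]
    se <- sqrt(p * (1 - p) / nrow(co))
    expect_lt(abs(p_hat[[lvl]] - p), 3 * se)
  }
})

test_that("genotype frequencies are Hardy-Weinberg consistent", {
  cfg <- tiny_config(n = 20000)
  co <- simulate_cohort(cfg, seed = 9)
  g <- as.matrix(co[attr(co, "snp_names")])
  # allele frequency and genotype distribution per SNP
  for (j in seq_len(ncol(g))) {
    q <- mean(g[, j]) / 2
    expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    observed <- tabulate(g[, j] + 1L, 3L) / nrow(g)
    expect_lt(max(abs(observed - expected)), 0.015)
  }
})

test_that("null smoking effects leave metabolites uncorrelated with smoking", {
  cfg <- tiny_config(n = 20000, beta_smoking_on_metabolites = rep(0, 12),
                     confounder_strength = 0)
  co <- simulate_cohort(cfg, seed = 21)
  cur <- as.integer(co$smoking_status == "current")
  cors <- vapply(metabolite_names(co),
                 function(m) cor(cur, co[[m]]), numeric(1))
  expect_lt(max(abs(cors)), 4 / sqrt(nrow(co)))
})

test_that("the configured direct smoking hazard is recovered by Cox", {
  cfg <- cohort_config(n_participants = 20000, n_metabolites = 6,
                       n_smoking_metabolites = 3, n_latent_factors = 2,
                       n_snps_grs = 6,
                       hazard_spec = hazard_loglinear(theta_current = log(1.7),
                                                      covariate_strength = 0))
  co <- simulate_cohort(cfg, seed = 42)
  cn <- dplyr::filter(co, smoking_status %in% c("never", "current"))
  cn$cur <- as.integer(cn$smoking_status == "current")
  ht <- hr_table(fit_cox(cn, terms = "cur"), "cur")
  expect_gt(1.7, ht$ci_low)
  expect_lt(1.7, ht$ci_high)
})

test_that("eligibility filtering removes exactly the union of flagged rows", {
  co <- simulate_cohort(tiny_config(n = 2000), seed = 13)
  filtered <- apply_eligibility_filters(co)
  flagged <- co$prevalent_diabetes | co$lipid_lowering_drug | co$missing_core_data
  expect_equal(nrow(filtered), nrow(co) - sum(flagged))
  log <- attr(filtered, "exclusion_log")
  expect_equal(log$n_excluded[log$flag == "any"], sum(flagged))
  expect_equal(log$n_excluded[log$flag == "prevalent_diabetes"],
               sum(co$prevalent_diabetes))

  # identity when nothing is flagged
  clean <- co
  clean$prevalent_diabetes <- FALSE
  clean$lipid_lowering_drug <- FALSE
  clean$missing_core_data <- FALSE
  expect_equal(nrow(apply_eligibility_filters(clean)), nrow(co))

  co$missing_core_data <- NULL
  expect_error(apply_eligibility_filters(co), "missing_core_data")
})

test_that("repeat assessment attenuates smoking effects as configured", {
  cfg <- tiny_config(n = 6000, m = 8, k = 4, lognormal_fraction = 0)
  co <- simulate_cohort(cfg, seed = 31)

  # identity case: no attenuation, no quitting, no fresh noise
  rep1 <- simulate_repeat_assessment(co, cfg, attenuation = 1, seed = 1,
                                     subset_fraction = 1, quit_probability = 0,
                                     noise_scale = 0)
  m <- metabolite_names(co)[1]
  base_means <- tapply(co[[m]], co$smoking_status, mean)
  rep_means <- tapply(rep1[[m]], rep1$smoking_status, mean)
  expect_lt(max(abs(base_means - rep_means)), 0.1)

  # half attenuation halves the screened smoking effect
  rep_half <- simulate_repeat_assessment(co, cfg, attenuation = 0.5, seed = 2,
                                         subset_fraction = 1,
                                         quit_probability = 0)
  pr_b <- prep_metabolites(co[metabolite_names(co)])
  pr_r <- prep_metabolites(rep_half[metabolite_names(rep_half)])
  sc_b <- screen_metabolites(co, pr_b$metabolites, "current_vs_never")
  sc_r <- screen_metabolites(rep_half, pr_r$metabolites, "current_vs_never")
  top <- which.max(abs(sc_b$beta))
  expect_lt(abs(sc_r$beta[top] - 0.5 * sc_b$beta[top]),
            2.5 * sqrt(sc_r$se[top]^2 + 0.25 * sc_b$se[top]^2))

  expect_error(simulate_repeat_assessment(co, cfg, attenuation = 2, seed = 1),
               "attenuation")
})
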