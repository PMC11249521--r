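test_that("preprocessing log-transforms skewed columns and unit-scales all", {
  set.seed(4)
  X <- cbind(gauss = rnorm(2000, 5, 2), lognorm = exp(rnorm(2000)))
  pr <- prep_metabolites(X, skew_threshold = 1)
  expect_false(pr$prep$log_transformed[pr$prep$metabolite == "gauss"])
  expect_true(pr$prep$log_transformed[pr$prep$metabolite == "lognorm"])
  expect_equal(unname(apply(pr$metabolites, 2, sd)), c(1, 1), tolerance = 1e-12)
  # skewness removed by the log transform
  skew_after <- apply(pr$metabolites, 2, smokesig:::sample_skewness)
  expect_lt(abs(skew_after[["lognorm"]]), 0.5)

  # recipe transfer applies identical transforms to new data
  pr2 <- prep_metabolites(X, prep = pr$prep)
  expect_equal(pr2$metabolites, pr$metabolites)
})

test_that("constant columns are rejected by name", {
  X <- cbind(ok = rnorm(50), flat = rep(3, 50))
  expect_error(prep_metabolites(X), "flat")
})

test_that("effective number of tests matches correlation structure", {
  set.seed(8)
  indep <- matrix(rnorm(2000 * 10), 2000, 10,
                  dimnames = list(NULL, paste0("m", 1:10)))
  expect_equal(effective_tests(indep)$m_eff, 10L)

  rank1 <- matrix(rep(rnorm(500), 10), 500, 10,
                  dimnames = list(NULL, paste0("m", 1:10)))
  expect_equal(effective_tests(rank1)$m_eff, 1L)

  # 42 independent blocks replicated to 60 columns -> m_eff = 42 and the
  # adjusted level is 0.05/42
  z <- matrix(rnorm(4000 * 42), 4000, 42)
  X <- z[, c(1:42, 1:18)] + matrix(rnorm(4000 * 60, 0, 0.02), 4000, 60)
  colnames(X) <- paste0("m", 1:60)
  eff <- effective_tests(X)
  expect_equal(eff$m_eff, 42L)
  expect_equal(eff$alpha_adjusted, 0.05 / 42)
  expect_equal(eff$alpha_adjusted, 1.19e-3, tolerance = 0.01)

  expect_error(effective_tests(indep, threshold = 1.2), "threshold")
})

test_that("m_eff decreases as inter-metabolite correlation grows", {
  set.seed(12)
  n <- 1500; m <- 20
  m_effs <- vapply(c(0, 0.5, 0.9), function(rho) {
    shared <- rnorm(n)
    X <- sqrt(rho) * matrix(shared, n, m) +
      sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    colnames(X) <- paste0("m", 1:m)
    effective_tests(X)$m_eff
  }, integer(1))
  expect_true(all(diff(m_effs) <= 0))
})

test_that("screen betas equal the Frisch-Waugh two-step oracle", {
  co <- simulate_cohort(tiny_config(n = 1200), seed = 17)
  pr <- prep_metabolites(co[metabolite_names(co)])
  covs <- c("age", "sex", "bmi")
  sc <- screen_metabolites(co, pr$metabolites, "current_vs_never",
                           covariates = covs)
  # oracle: residualize response and contrast on all other regressors, then
  # simple regression of residual on residual
  smoking <- co$smoking_status
  X_other <- cbind(smokesig:::build_design(co, covs),
                   former = as.integer(smoking == "former"))
  cur <- as.integer(smoking == "current")
  for (j in c(1, 5, 9)) {
    ry <- resid(lm.fit(X_other, pr$metabolites[, j]))
    rx <- resid(lm.fit(X_other, cbind(cur)))
    expect_equal(sc$beta[j], unname(coef(lm(ry ~ 0 + rx))[1]),
                 tolerance = 1e-10)
  }
})

test_that("screen recovers a planted effect and attributes its variance", {
  set.seed(30)
  n <- 20000
  cur <- rbinom(n, 1, 0.3)
  co <- tibble::tibble(
    smoking_status = factor(ifelse(cur == 1, "current", "never"),
                            levels = c("never", "former", "current")),
    age = rnorm(n, 55, 8)
  )
  M <- cbind(planted = 0.3 * cur + rnorm(n), null = rnorm(n))
  pr <- prep_metabolites(M)
  sc <- screen_metabolites(co, pr$metabolites, "current_vs_never",
                           covariates = "age")
  truth <- 0.3 / sd(M[, "planted"])
  expect_lt(abs(sc$beta[1] - truth), 2.5 * sc$se[1])
  # semi-partial R2: sanity and planted magnitude p(1-p) * beta^2 ~ 0.9%
  expect_true(all(sc$r2_smoking >= 0))
  expect_true(all(sc$r2_model >= sc$r2_smoking))
  expect_equal(unname(sc$r2_smoking[1]), 0.3 * 0.7 * truth^2, tolerance = 0.25)
  expect_lt(sc$r2_smoking[2], 0.001)
})

test_that("collinear covariates are reported", {
  co <- simulate_cohort(tiny_config(n = 300), seed = 2)
  co$bmi_copy <- co$bmi
  pr <- prep_metabolites(co[metabolite_names(co)])
  expect_error(
    screen_metabolites(co, pr$metabolites, covariates = c("bmi", "bmi_copy")),
    "bmi_copy"
  )
})

test_that("selection applies the adjusted threshold with direction", {
  res <- tibble::tibble(metabolite = c("a", "b", "c"),
                        contrast = "current_vs_never",
                        beta = c(0.4, -0.2, 0.1),
                        se = 0.1, p = c(1e-6, 0.5, 0.5),
                        r2_smoking = 0.01, r2_model = 0.1)
  eff <- list(m_eff = 42L, alpha_adjusted = 0.05 / 42)
  sel <- select_significant(res, eff)
  expect_equal(sel$metabolite, "a")
  expect_equal(sel$direction, 1)
  res$p <- rep(0.5, 3)
  expect_equal(nrow(select_significant(res, eff)), 0)
})

test_that("per-covariate variance attribution is coherent", {
  co <- simulate_cohort(tiny_config(n = 1500), seed = 19)
  pr <- prep_metabolites(co[metabolite_names(co)])
  attr_tbl <- screen_r2_attribution(co, pr$metabolites,
                                    covariates = c("age", "sex", "bmi"))
  expect_true(all(attr_tbl$r2 >= 0))
  expect_setequal(unique(attr_tbl$term),
                  c("smoking_status", "age", "sex", "bmi"))
})

test_that("the former-smoker contrast is an attenuated rerun of the screen", {
  cfg <- tiny_config(n = 8000, m = 8, k = 4, former_attenuation = 0.15)
  co <- simulate_cohort(cfg, seed = 91)
  pr <- prep_metabolites(co[metabolite_names(co)])
  cur <- screen_metabolites(co, pr$metabolites, "current_vs_never",
                            covariates = c("age", "sex"))
  frm <- screen_metabolites(co, pr$metabolites, "former_vs_never",
                            covariates = c("age", "sex"))
  top <- which.max(abs(cur$beta))
  expect_lt(abs(frm$beta[top] - 0.15 * cur$beta[top]),
            3 * sqrt(frm$se[top]^2 + 0.0225 * cur$se[top]^2))
  expect_lt(abs(frm$beta[top]), abs(cur$beta[top]))
})
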