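# Small shared configurations for fast tests.

tiny_config <- function(n = 800, m = 12, k = 6, ...) {
  cohort_config(n_participants = n, n_metabolites = m,
                n_smoking_metabolites = k, n_latent_factors = 4,
                n_snps_grs = 10, n_centers = 4,
                smoking_effect_mode = "sparse", ...)
}

# 30-row survival fixture with left truncation, a single binary covariate
# and no tied event ages; built deterministically.
small_survival_fixture <- function(seed = 11, n = 30) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  entry <- runif(n, 50, 60)
  u <- runif(n)
  tev <- 68 * ((entry / 68)^4 - log(u) * exp(-0.6 * x))^(1 / 4)
  exit <- pmin(tev, entry + 12)
  tibble::tibble(x = x, entry_age = entry,
                 exit_age = exit + seq_len(n) * 1e-7,  # break any exact ties
                 event = as.integer(tev <= entry + 12))
}

# Hand-written stratification-free Cox partial log-likelihood with delayed
# entry.
manual_cox_loglik <- function(beta, dat) {
  beta <- as.numeric(beta)
  ll <- 0
  for (i in which(dat$event == 1)) {
    t_i <- dat$exit_age[i]
    risk <- dat$entry_age < t_i & dat$exit_age >= t_i
    ll <- ll + dat$x[i] * beta - log(sum(exp(dat$x[risk] * beta)))
  }
  ll
}
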