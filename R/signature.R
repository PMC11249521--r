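#' Residualize metabolites on covariates
#'
#' Regresses each (prepped) metabolite on the covariate set by OLS and
#' returns standardized residuals (divided by the residual SD, so each column
#' has mean 0 and SD ~1). The per-metabolite coefficients and residual SDs
#' are stored so the identical residualization can be transferred to a new
#' cohort without refitting.
#'
#' @param cohort Cohort tibble containing the covariates.
#' @param metabolites Prepped metabolite matrix aligned to `cohort`.
#' @param covariates Covariate column names (default
#'   [default_residualization_covariates()]).
#' @param store Optional store from a previous call; when supplied its
#'   coefficients and residual SDs are applied unchanged (transfer mode).
#' @return A list: `residuals` (matrix), `store` (list with `covariates`,
#'   `coef` matrix, `resid_sd`).
#' @export
residualize_metabolites <- function(cohort, metabolites,
                                    covariates = default_residualization_covariates(),
                                    store = NULL) {
  Y <- as.matrix(metabolites)
  if (is.null(store)) {
    X <- build_design(cohort, covariates)
    fit <- ols_multi(X, Y)
    resid_sd <- apply(fit$residuals, 2, sd)
    if (any(resid_sd == 0)) {
      abort(paste0("zero residual variance: ",
                   paste(colnames(Y)[resid_sd == 0], collapse = ", ")))
    }
    res <- sweep(fit$residuals, 2, resid_sd, `/`)
    store <- list(covariates = covariates, coef = fit$coef, resid_sd = resid_sd)
  } else {
    X <- build_design(cohort, store$covariates)
    if (!identical(colnames(X), rownames(store$coef))) {
      miss <- setdiff(rownames(store$coef), colnames(X))
      if (length(miss) > 0) {
        abort(paste0("transfer design lacks columns: ", paste(miss, collapse = ", ")))
      }
      X <- X[, rownames(store$coef), drop = FALSE]
    }
    res <- sweep(Y - X %*% store$coef[, colnames(Y), drop = FALSE],
                 2, store$resid_sd[colnames(Y)], `/`)
  }
  list(residuals = res, store = store)
}

#' Default residualization covariates
#'
#' The variables that explain appreciable metabolite variance besides
#' smoking: age, sex, adiposity (BMI, WHR), alcohol, oily-fish intake and
#' fasting time.
#'
#' @return Character vector of column names.
#' @export
default_residualization_covariates <- function() {
  c("age", "sex", "bmi", "whr", "alcohol", "oily_fish", "fasting_hours")
}

#' Fit the smoking-related metabolic signature by elastic net
#'
#' Penalized least-squares regression of the 0/1 current-vs-never smoking
#' indicator on standardized metabolite residuals (former smokers are
#' excluded from training). The mixing parameter and penalty are chosen over
#' a grid by k-fold cross-validation minimizing mean squared error, with
#' folds stratified by smoking status and ties in CV error broken toward the
#' larger penalty (the sparser model). The model is then refit on all
#' training rows and zero-weight metabolites are dropped.
#'
#' @param residuals Standardized residual matrix from
#'   [residualize_metabolites()].
#' @param smoking Factor/character smoking status aligned to `residuals`
#'   (levels never/former/current).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param alpha_grid Elastic-net mixing values to search (default
#'   0.1 to 1 in steps of ~0.2; 0 = ridge, 1 = lasso).
#' @param lambda Optional fixed penalty; skips cross-validation when given.
#' @param family `"gaussian"` (penalized least squares, default) or
#'   `"binomial"`.
#' @param seed Integer seed controlling fold assignment.
#' @return A `signature_model` object: `weights` (named nonzero
#'   coefficients), `alpha_mix`, `lambda_penalty`, `prep`, `residualization`
#'   (filled by [build_signature()]), `training_meta`.
#' @export
fit_signature <- function(residuals, smoking, cv_folds = 10,
                          alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                          lambda = NULL, family = c("gaussian", "binomial"),
                          seed = 1) {
  family <- match.arg(family)
  smoking <- as.character(smoking)
  keep <- smoking %in% c("never", "current")
  X <- as.matrix(residuals)[keep, , drop = FALSE]
  y <- as.numeric(smoking[keep] == "current")
  if (length(unique(y)) < 2) abort("training response has a single class")
  if (length(alpha_grid) == 0 && is.null(lambda)) abort("empty tuning grid")

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  if (is.null(lambda)) {
    # response-stratified fold assignment, reproducible under the seed
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    cvs <- lapply(alpha_grid, function(a) {
      glmnet::cv.glmnet(X, y, family = family, alpha = a, foldid = foldid,
                        type.measure = "mse", standardize = FALSE)
    })
    # per alpha: best lambda (ties toward larger lambda = sparser model)
    best <- purrr::map(cvs, function(cv) {
      i <- which(cv$cvm <= min(cv$cvm) + 1e-12)[1]  # lambdas descend in glmnet
      list(lambda = cv$lambda[i], cvm = cv$cvm[i])
    })
    j <- which.min(vapply(best, `[[`, numeric(1), "cvm"))
    alpha_mix <- alpha_grid[j]
    lambda <- best[[j]]$lambda
  } else {
    alpha_mix <- alpha_grid[1]
  }

  fit <- glmnet::glmnet(X, y, family = family, alpha = alpha_mix,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-12)
  cf <- as.matrix(coef(fit))
  w <- setNames(cf[-1, 1], rownames(cf)[-1])
  w <- w[w != 0]
  if (length(w) == 0) abort("empty signature: the penalty removed every metabolite")

  structure(list(weights = w,
                 alpha_mix = alpha_mix,
                 lambda_penalty = lambda,
                 family = family,
                 prep = NULL,
                 residualization = NULL,
                 training_meta = list(n = length(y), seed = seed,
                                      cv_folds = cv_folds)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> ", length(x$weights), " metabolites (alpha = ",
      x$alpha_mix, ", lambda = ", signif(x$lambda_penalty, 4), ")\n", sep = "")
  invisible(x)
}

#' Build a transferable signature model from a cohort
#'
#' Convenience wrapper running the full training recipe on one cohort:
#' metabolite preprocessing, residualization on covariates, elastic-net fit
#' on current-vs-never smoking. The returned model carries the preprocessing
#' and residualization coefficients needed to score any cohort without
#' refitting.
#'
#' @param cohort Training cohort tibble.
#' @param metabolite_cols Metabolite column names (default from the cohort's
#'   attributes).
#' @param covariates Residualization covariates.
#' @param skew_threshold Passed to [prep_metabolites()].
#' @inheritParams fit_signature
#' @return A `signature_model` with `prep` and `residualization` filled.
#' @export
build_signature <- function(cohort, metabolite_cols = metabolite_names(cohort),
                            covariates = default_residualization_covariates(),
                            skew_threshold = 1, cv_folds = 10,
                            alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                            lambda = NULL, seed = 1) {
  pr <- prep_metabolites(cohort[metabolite_cols], skew_threshold = skew_threshold)
  rs <- residualize_metabolites(cohort, pr$metabolites, covariates = covariates)
  model <- fit_signature(rs$residuals, cohort$smoking_status,
                         cv_folds = cv_folds, alpha_grid = alpha_grid,
                         lambda = lambda, seed = seed)
  model$prep <- pr$prep
  model$residualization <- rs$store
  model
}

#' Score a cohort with a fitted signature model
#'
#' The signature is the weighted sum of the selected metabolites' residuals,
#' `sum_j w_j r_ij`. In transfer mode (the default) the training cohort's
#' preprocessing recipe and residualization coefficients are applied to the
#' new cohort unchanged; with `refit_residualization = TRUE` the covariate
#' regressions are refit locally (the weights are always transferred).
#' Scoring is deterministic given the model and cohort and never uses the
#' cohort's smoking or outcome data.
#'
#' @param model A `signature_model` from [build_signature()].
#' @param cohort Cohort tibble to score.
#' @param refit_residualization Refit covariate regressions on the new
#'   cohort instead of transferring coefficients.
#' @return Numeric vector of scores, one per row of `cohort`.
#' @export
compute_signature <- function(model, cohort, refit_residualization = FALSE) {
  stopifnot(inherits(model, "signature_model"))
  sel <- names(model$weights)
  missing_cols <- setdiff(sel, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks selected metabolites: ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  if (is.null(model$prep) || is.null(model$residualization)) {
    abort("model carries no preprocessing recipe; use build_signature()")
  }
  pr <- prep_metabolites(cohort[sel], prep = model$prep)
  if (refit_residualization) {
    rs <- residualize_metabolites(cohort, pr$metabolites,
                                  covariates = model$residualization$covariates)
  } else {
    rs <- residualize_metabolites(cohort, pr$metabolites,
                                  store = model$residualization)
  }
  drop(rs$residuals[, sel, drop = FALSE] %*% model$weights)
}

#' Variance of the signature explained by smoking
#'
#' Semi-partial R-squared of smoking status (two indicator contrasts) in an
#' OLS of the score on smoking plus covariates: full-model R-squared minus
#' the covariate-only R-squared.
#'
#' @param scores Numeric signature scores.
#' @param cohort Cohort tibble aligned to `scores`.
#' @param covariates Covariate column names.
#' @param cohort_label Label recorded in the result.
#' @return One-row tibble: `cohort_label`, `n`, `r2_smoking`.
#' @export
variance_explained <- function(scores, cohort,
                               covariates = default_residualization_covariates(),
                               cohort_label = "cohort") {
  if (sd(scores) == 0) abort("constant score vector")
  smoking <- factor(cohort$smoking_status, levels = c("never", "former", "current"))
  S <- smoking_indicators(smoking)
  Xc <- build_design(cohort, covariates)
  Y <- matrix(scores, ncol = 1, dimnames = list(NULL, "score"))
  r2_full <- r2_from_residuals(Y, ols_multi(cbind(Xc, S), Y)$residuals)
  r2_cov <- r2_from_residuals(Y, ols_multi(Xc, Y)$residuals)
  tibble(cohort_label = cohort_label, n = nrow(cohort),
         r2_smoking = max(unname(r2_full - r2_cov), 0))
}

#' Internal-external cross-validation of the signature
#'
#' Per cycle, assessment centers are randomly partitioned into a training and
#' a validation half; the full training recipe (preprocess, residualize,
#' elastic net) is run on the training centers and the held-out centers are
#' scored by pure transfer, recording the variance in the score explained by
#' smoking among the held-out participants.
#'
#' @param cohort Cohort tibble with a `center` column (>= 2 centers).
#' @param n_cycles Number of cycles (default 8).
#' @param seed Integer seed (controls center partitions and fold seeds).
#' @param covariates Residualization covariates.
#' @param ... Passed to [build_signature()].
#' @return A tibble with one row per cycle: `cycle`, `n_train_centers`,
#'   `n`, `r2_smoking`, `n_selected`.
#' @export
internal_external_cv <- function(cohort, n_cycles = 8, seed = 1,
                                 covariates = default_residualization_covariates(),
                                 ...) {
  centers <- unique(as.character(cohort$center))
  if (length(centers) < 2) abort("internal-external CV needs >= 2 centers")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)
  splits <- lapply(seq_len(n_cycles), function(i) {
    sample(centers, size = floor(length(centers) / 2))
  })
  purrr::imap(splits, function(train_centers, cycle) {
    train <- cohort %>% filter(as.character(.data$center) %in% train_centers)
    valid <- cohort %>% filter(!as.character(.data$center) %in% train_centers)
    if (length(unique(valid$smoking_status)) < 2) {
      abort(paste0("cycle ", cycle, ": single-class validation set"))
    }
    for (a in c("metabolite_names", "snp_names")) {
      attr(train, a) <- attr(cohort, a)
    }
    model <- build_signature(train, covariates = covariates,
                             seed = derive_seed(seed, paste0("iecv", cycle)), ...)
    scores <- compute_signature(model, valid)
    variance_explained(scores, valid, covariates = covariates,
                       cohort_label = paste0("cycle_", cycle)) %>%
      mutate(cycle = cycle, n_train_centers = length(train_centers),
             n_selected = length(model$weights)) %>%
      select("cycle", "n_train_centers", "n", "r2_smoking", "n_selected")
  }) %>% list_rbind()
}

#' Serialize / restore a signature model as JSON
#'
#' Round-trip is loss-free: weights, the preprocessing recipe, the
#' residualization coefficients and metadata are all preserved at full
#' precision.
#'
#' @param model A `signature_model`.
#' @param path File path to write to / read from.
#' @return `write_signature_model()` returns `path` invisibly;
#'   `read_signature_model()` returns the restored `signature_model`.
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  obj <- list(
    weights = as.list(model$weights),
    alpha_mix = model$alpha_mix,
    lambda_penalty = model$lambda_penalty,
    family = model$family,
    prep = model$prep,
    residualization = list(
      covariates = model$residualization$covariates,
      coef = list(rownames = rownames(model$residualization$coef),
                  colnames = colnames(model$residualization$coef),
                  values = as.vector(model$residualization$coef)),
      resid_sd = as.list(model$residualization$resid_sd)
    ),
    training_meta = model$training_meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- matrix(obj$residualization$coef$values,
                 nrow = length(obj$residualization$coef$rownames),
                 dimnames = list(obj$residualization$coef$rownames,
                                 obj$residualization$coef$colnames))
  structure(list(
    weights = unlist(obj$weights),
    alpha_mix = obj$alpha_mix,
    lambda_penalty = obj$lambda_penalty,
    family = obj$family,
    prep = as_tibble(obj$prep),
    residualization = list(covariates = obj$residualization$covariates,
                           coef = coef,
                           resid_sd = unlist(obj$residualization$resid_sd)),
    training_meta = obj$training_meta
  ), class = "signature_model")
}
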