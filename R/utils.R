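# Internal numerical helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from a single master seed, so individual stages can be re-run in isolation
#' while the end-to-end run stays reproducible.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  # cheap string hash (polynomial rolling, modulo a prime below 2^31)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483629)
}

# Sample skewness (moment estimator m3 / m2^{3/2}).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Multi-response OLS via a single QR decomposition.
# X: n x p design (with intercept), Y: n x m response matrix.
# Returns coefficients, residuals, and the diagonal of (X'X)^{-1}.
ols_multi <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("singular design matrix; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qrX, Y)
  fitted <- qr.fitted(qrX, Y)
  res <- Y - fitted
  Rinv <- backsolve(qr.R(qrX), diag(ncol(X)))
  xtx_inv_diag <- rowSums(Rinv^2)
  names(xtx_inv_diag) <- colnames(X)
  list(coef = coefs, residuals = res, fitted = fitted,
       xtx_inv_diag = xtx_inv_diag, rank = qrX$rank)
}

# Build a design matrix from a data frame and a covariate name list.
# Factors/characters are expanded by reference-level indicator coding
# (reference = first observed level).
build_design <- function(data, covariates, intercept = TRUE) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("covariates not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(covariates) == 0) {
    X <- matrix(1, nrow = nrow(data), ncol = 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  data <- as.data.frame(data[covariates])
  for (j in seq_along(data)) {
    if (is.character(data[[j]])) data[[j]] <- factor(data[[j]])
    if (is.factor(data[[j]])) data[[j]] <- droplevels(data[[j]])
  }
  # single-level factors are constants; the intercept absorbs them
  constant <- vapply(data, function(col) is.factor(col) && nlevels(col) < 2,
                     logical(1))
  covariates <- covariates[!constant]
  if (length(covariates) == 0) {
    return(matrix(1, nrow = nrow(data), ncol = 1,
                  dimnames = list(NULL, "(Intercept)")))
  }
  fml <- reformulate(vapply(covariates, function(v) paste0("`", v, "`"), ""))
  X <- model.matrix(fml, data = data)
  if (!intercept) X <- X[, -1, drop = FALSE]
  X
}

# R-squared of a fitted multi-response OLS given the response matrix.
r2_from_residuals <- function(Y, res) {
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  rss <- colSums(res^2)
  ifelse(tss > 0, 1 - rss / tss, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Indicator columns for smoking levels present in the data (never = reference).
smoking_indicators <- function(smoking) {
  smoking <- factor(smoking, levels = c("never", "former", "current"))
  S <- cbind(smoking_former = as.integer(smoking == "former"),
             smoking_current = as.integer(smoking == "current"))
  S[, colSums(S) > 0, drop = FALSE]
}
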