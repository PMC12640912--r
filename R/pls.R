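# Single-response PLS regression (NIPALS) with deflation.

#' Fit a single-response PLS regression
#'
#' Standardizes the predictor columns (z-score), centers the response, and
#' extracts latent components by NIPALS: each component's weight vector is
#' proportional to the feature-response covariances of the current deflated
#' matrices, making the model robust to multicollinearity. With
#' \code{n_components = rank(X)} on a full-rank problem the fit coincides
#' with ordinary least squares. If the response deflates to numerical zero
#' early, the component count is truncated (recorded in the fit).
#'
#' @param X numeric predictor matrix without missing values.
#' @param y numeric response.
#' @param n_components number of latent components,
#'   \code{1 <= n_components <= ncol(X)}.
#' @return a \code{pls_fit}: weights \code{W}, loadings \code{P}, response
#'   loadings \code{q}, raw-scale \code{coefficients} and \code{intercept},
#'   standardization constants, \code{fitted} values and
#'   \code{feature_names}.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y))
    stop_oculopls("missing_values", "X and y must be complete (impute first)")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    stop_oculopls("length_mismatch", "length(y) must equal nrow(X)")
  if (n_components < 1 || n_components > p)
    stop_oculopls("bad_components",
                  sprintf("n_components must be in [1, %d]", p))
  if (n < n_components + 2)
    stop_oculopls("too_few_rows", "need n >= n_components + 2")
  x_means <- colMeans(X)
  x_sds <- apply(X, 2L, stats::sd)
  if (any(x_sds == 0))
    stop_oculopls("constant_column", sprintf(
      "constant predictor column(s): %s",
      paste(colnames(X)[x_sds == 0], collapse = ", ")))
  E <- sweep(sweep(X, 2L, x_means), 2L, x_sds, "/")
  y_mean <- mean(y)
  f <- y - y_mean

  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  Tm <- matrix(0, n, n_components)
  used <- 0L
  for (k in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_k <- as.numeric(E %*% w)
    tt <- sum(t_k^2)
    if (tt < 1e-12) break
    p_k <- crossprod(E, t_k) / tt
    q_k <- sum(f * t_k) / tt
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k; Tm[, k] <- t_k
    E <- E - tcrossprod(t_k, p_k)
    f <- f - t_k * q_k
    used <- k
  }
  if (used == 0L)
    stop_oculopls("degenerate_fit", "response uncorrelated with predictors")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  B_std <- W %*% solve(crossprod(P, W), q)
  coefficients <- as.numeric(B_std) / x_sds
  intercept <- y_mean - sum(coefficients * x_means)
  fitted <- as.numeric(X %*% coefficients + intercept)
  structure(list(
    n_components = used, W = W, P = P, q = q,
    coefficients = stats::setNames(coefficients, colnames(X)),
    intercept = intercept,
    x_means = x_means, x_sds = x_sds, y_mean = y_mean,
    feature_names = colnames(X),
    fitted = fitted
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d latent component(s), %d feature(s)\n",
              x$n_components, length(x$feature_names)))
  invisible(x)
}

#' @export
coef.pls_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict from a PLS fit
#'
#' Affine map using the stored standardization constants and coefficients.
#' When \code{newdata} has column names they must match the training
#' features (order-insensitively).
#'
#' @param object a \code{pls_fit}.
#' @param newdata numeric matrix of predictors.
#' @param ... unused.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (anyNA(X))
    stop_oculopls("missing_values", "newdata contains missing values")
  if (!is.null(colnames(X))) {
    miss <- setdiff(object$feature_names, colnames(X))
    if (length(miss))
      stop_oculopls("name_mismatch", sprintf("newdata lacks feature(s): %s",
                                             paste(miss, collapse = ", ")))
    X <- X[, object$feature_names, drop = FALSE]
  } else if (ncol(X) != length(object$feature_names)) {
    stop_oculopls("dim_mismatch", "newdata column count mismatch")
  }
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' R-squared and adjusted R-squared
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1)} with \eqn{p} the
#' number of predictors.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param n_predictors predictor count \eqn{p}; requires
#'   \eqn{n > p + 1}.
#' @return list with \code{r2} and \code{r2_adjusted}.
#' @export
r2_and_adjusted <- function(y_true, y_pred, n_predictors) {
  if (length(y_true) != length(y_pred))
    stop_oculopls("length_mismatch", "y_true and y_pred lengths differ")
  n <- length(y_true)
  if (n <= n_predictors + 1)
    stop_oculopls("too_few_rows", "need n > n_predictors + 1")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop_oculopls("zero_variance", "y_true has zero variance")
  r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  list(r2 = r2,
       r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1))
}
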