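# Probabilistic PCA with missing data, fitted by EM.
#
# Model (on internally z-scored columns): x = W z + mu + eps, with
# z ~ N(0, I_q) and isotropic eps ~ N(0, sigma2 I). Missing entries are
# treated as latent alongside z; the E-step computes the exact posterior of
# (z, x_miss | x_obs) batched over rows sharing a missingness pattern, and
# the M-step updates (W, mu) jointly via the augmented-latent regression and
# sigma2 from the expected residual. The observed-data log-likelihood is
# tracked every iteration (it is provably non-decreasing under EM) and
# drives the relative-change stopping rule.

# group rows by missingness pattern; returns list of (rows, obs_cols)
.miss_patterns <- function(M) {
  key <- apply(M, 1L, function(r) paste(which(r), collapse = ","))
  idx <- split(seq_len(nrow(M)), key)
  lapply(idx, function(rows) list(rows = rows,
                                  obs = which(M[rows[1L], ])))
}

#' Fit a probabilistic PCA model to a matrix with missing entries
#'
#' @param X numeric matrix (participants x parameters) with \code{NA} for
#'   missing cells; every row and every column needs at least one observed
#'   value and no column may be constant on its observed entries.
#' @param rank number of latent components, \code{1 <= rank < min(dim(X))}.
#' @param tol relative observed-data log-likelihood change below which EM
#'   stops (default 1e-6).
#' @param max_iter maximum EM iterations (default 500); hitting it is
#'   reported via \code{converged = FALSE}, not an error.
#' @param seed unused by the deterministic SVD initialisation; kept so that
#'   callers can thread a seed uniformly.
#' @return a \code{ppca_model}: loading matrix \code{W}, mean vector
#'   \code{mu} (both on the standardized scale), noise variance
#'   \code{sigma2}, the column scalers, convergence info and the
#'   log-likelihood trace.
#' @export
fit_ppca <- function(X, rank, tol = 1e-6, max_iter = 500, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  M <- !is.na(X)
  if (any(rowSums(M) == 0))
    stop_oculopls("empty_row", "row(s) with no observed values")
  if (any(colSums(M) == 0))
    stop_oculopls("empty_column", "column(s) with no observed values")
  if (rank < 1 || rank >= min(n, d))
    stop_oculopls("bad_rank",
                  sprintf("rank must be in [1, %d)", min(n, d)))
  q <- as.integer(rank)

  col_mean <- colMeans(X, na.rm = TRUE)
  col_sd <- apply(X, 2L, stats::sd, na.rm = TRUE)
  col_sd[is.na(col_sd)] <- 0  # single observed entry
  if (any(col_sd == 0 & colSums(M) > 1))
    stop_oculopls("constant_column",
                  "constant column(s) on observed entries; drop them upstream")
  col_sd[col_sd == 0] <- 1
  Z <- sweep(sweep(X, 2L, col_mean), 2L, col_sd, "/")

  # init: truncated SVD of the zero(=mean)-imputed standardized matrix
  Z0 <- Z; Z0[!M] <- 0
  sv <- svd(Z0, nu = 0, nv = q)
  dq <- sv$d[seq_len(q)]
  W <- sv$v * rep(dq / sqrt(n), each = d)
  mu <- rep(0, d)
  sigma2 <- max((sum(Z0^2) - sum(dq^2)) / (n * d), 1e-4)

  pats <- .miss_patterns(M)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  delta <- NA_real_
  it <- 0L

  for (it in seq_len(max_iter)) {
    Szz <- matrix(0, q + 1L, q + 1L)
    Sxz <- matrix(0, d, q + 1L)
    Sxx <- numeric(d)
    ll <- 0
    for (pt in pats) {
      rows <- pt$rows; o <- pt$obs; m <- setdiff(seq_len(d), o)
      nr <- length(rows)
      Wo <- W[o, , drop = FALSE]
      A <- diag(sigma2, q) + crossprod(Wo)
      Ainv <- chol2inv(chol(A))
      Xo <- Z[rows, o, drop = FALSE]
      Xoc <- sweep(Xo, 2L, mu[o])
      B <- Xoc %*% Wo                      # nr x q
      Ez <- B %*% Ainv
      sum_Ez <- colSums(Ez)
      sum_Ezz <- nr * sigma2 * Ainv + crossprod(Ez)

      # observed-data log-likelihood of this pattern
      logdetC <- (length(o) - q) * log(sigma2) +
        determinant(A, logarithm = TRUE)$modulus[1]
      Q <- (sum(Xoc^2) - sum((B %*% Ainv) * B)) / sigma2
      ll <- ll - 0.5 * (nr * length(o) * log(2 * pi) + nr * logdetC + Q)

      # accumulate expected complete-data sufficient statistics
      Szz[seq_len(q), seq_len(q)] <- Szz[seq_len(q), seq_len(q)] + sum_Ezz
      Szz[q + 1L, seq_len(q)] <- Szz[q + 1L, seq_len(q)] + sum_Ez
      Szz[seq_len(q), q + 1L] <- Szz[seq_len(q), q + 1L] + sum_Ez
      Szz[q + 1L, q + 1L] <- Szz[q + 1L, q + 1L] + nr

      Sxz[o, seq_len(q)] <- Sxz[o, seq_len(q)] + crossprod(Xo, Ez)
      Sxz[o, q + 1L] <- Sxz[o, q + 1L] + colSums(Xo)
      Sxx[o] <- Sxx[o] + colSums(Xo^2)
      if (length(m)) {
        Wm <- W[m, , drop = FALSE]
        Xm_hat <- Ez %*% t(Wm) + rep(mu[m], each = nr)
        Sxz[m, seq_len(q)] <- Sxz[m, seq_len(q)] +
          outer(mu[m], sum_Ez) + Wm %*% sum_Ezz
        Sxz[m, q + 1L] <- Sxz[m, q + 1L] + colSums(Xm_hat)
        v_m <- sigma2 * (1 + rowSums((Wm %*% Ainv) * Wm))
        Sxx[m] <- Sxx[m] + colSums(Xm_hat^2) + nr * v_m
      }
    }
    ll_trace <- c(ll_trace, ll)

    # M-step
    Wt <- Sxz %*% chol2inv(chol(Szz))     # d x (q+1): [W mu]
    W <- Wt[, seq_len(q), drop = FALSE]
    mu <- Wt[, q + 1L]
    sigma2 <- max((sum(Sxx) - sum(Wt * Sxz)) / (n * d), 1e-12)

    delta <- abs(ll - ll_prev) / (abs(ll_prev) + 1e-12)
    if (is.finite(ll_prev) && delta < tol) { converged <- TRUE; break }
    ll_prev <- ll
  }

  structure(list(
    W = W, mu = mu, sigma2 = sigma2, rank = q,
    col_mean = col_mean, col_sd = col_sd, d = d,
    converged = converged, n_iterations = it, final_delta = delta,
    loglik_trace = ll_trace,
    colnames = colnames(X)
  ), class = "ppca_model")
}

#' @export
print.ppca_model <- function(x, ...) {
  cat(sprintf("<ppca_model> rank %d, %d parameters, sigma2 = %.4g, %s (%d EM iterations)\n",
              x$rank, x$d, x$sigma2,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Impute missing cells with a fitted PPCA model
#'
#' Observed cells pass through unchanged bit-for-bit; missing cells are
#' replaced by their posterior means under the model.
#'
#' @param model a \code{ppca_model} from [fit_ppca()].
#' @param X matrix with the same number of columns the model was fitted on.
#' @return list with \code{completed} (the filled matrix) and \code{report}
#'   (\code{n_cells_imputed}, \code{fraction_missing}, \code{rank_used},
#'   \code{cv_reconstruction_error} unset).
#' @export
ppca_impute <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop_oculopls("dim_mismatch",
                  sprintf("matrix has %d columns, model expects %d",
                          ncol(X), model$d))
  M <- !is.na(X)
  out <- X
  if (any(!M)) {
    Z <- sweep(sweep(X, 2L, model$col_mean), 2L, model$col_sd, "/")
    q <- model$rank
    for (pt in .miss_patterns(M)) {
      rows <- pt$rows; o <- pt$obs; m <- setdiff(seq_len(model$d), o)
      if (!length(m)) next
      nr <- length(rows)
      if (length(o)) {
        Wo <- model$W[o, , drop = FALSE]
        A <- diag(model$sigma2, q) + crossprod(Wo)
        Ez <- sweep(Z[rows, o, drop = FALSE], 2L, model$mu[o]) %*%
          Wo %*% chol2inv(chol(A))
      } else {
        Ez <- matrix(0, nr, q)
      }
      Zm <- Ez %*% t(model$W[m, , drop = FALSE]) + rep(model$mu[m], each = nr)
      out[rows, m] <- rep(model$col_mean[m], each = nr) +
        Zm * rep(model$col_sd[m], each = nr)
    }
  }
  report <- list(n_cells_imputed = sum(!M),
                 fraction_missing = mean(!M),
                 rank_used = model$rank,
                 cv_reconstruction_error = NA_real_)
  list(completed = out, report = report)
}

#' Choose the PPCA rank by held-out reconstruction
#'
#' For each of \code{n_folds} folds, masks an additional random 10% of the
#' observed cells, fits every candidate rank on the reduced matrix, and
#' scores it by RMSE on the held-out cells. Returns the rank minimising the
#' mean held-out RMSE; ties break to the smaller rank.
#'
#' @param X matrix with \code{NA} missing cells.
#' @param candidate_ranks integer vector of ranks to try.
#' @param n_folds number of masking folds (default 5).
#' @param seed integer seed for the fold masks.
#' @param tol,max_iter forwarded to [fit_ppca()].
#' @return list with \code{rank} and \code{cv_curve} (data frame
#'   \code{rank, rmse}).
#' @export
select_ppca_rank <- function(X, candidate_ranks, n_folds = 5, seed = 1L,
                             tol = 1e-5, max_iter = 200) {
  X <- as.matrix(X)
  candidate_ranks <- sort(unique(as.integer(candidate_ranks)))
  M <- !is.na(X)
  obs <- which(M)
  n_hold <- max(1L, round(0.1 * length(obs)))
  if (length(obs) - n_hold < length(candidate_ranks) + 2)
    stop_oculopls("too_few_cells", "not enough observed cells for folds")
  bad <- setdiff(candidate_ranks, seq_len(min(dim(X)) - 1L))
  if (length(bad))
    stop_oculopls("bad_rank", sprintf("invalid candidate rank(s): %s",
                                      paste(bad, collapse = ", ")))
  if (length(candidate_ranks) == 1L)
    return(list(rank = candidate_ranks,
                cv_curve = data.frame(rank = candidate_ranks,
                                      rmse = NA_real_)))
  err <- matrix(NA_real_, n_folds, length(candidate_ranks))
  for (f in seq_len(n_folds)) {
    hold <- with_seed(sub_seed(seed, "rank_cv", f),
                      sample(obs, n_hold))
    Xf <- X
    Xf[hold] <- NA_real_
    # never empty out a row or column
    Mf <- !is.na(Xf)
    fix <- hold[rowSums(Mf)[(hold - 1L) %% nrow(X) + 1L] == 0 |
                  colSums(Mf)[(hold - 1L) %/% nrow(X) + 1L] == 0]
    Xf[fix] <- X[fix]
    hold <- setdiff(hold, fix)
    for (k in seq_along(candidate_ranks)) {
      fit <- fit_ppca(Xf, candidate_ranks[k], tol = tol, max_iter = max_iter)
      comp <- ppca_impute(fit, Xf)$completed
      err[f, k] <- sqrt(mean((comp[hold] - X[hold])^2))
    }
  }
  curve <- data.frame(rank = candidate_ranks, rmse = colMeans(err))
  best <- curve$rank[which.min(curve$rmse)]  # which.min -> first = smallest
  list(rank = best, cv_curve = curve)
}
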