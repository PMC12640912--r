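# Model selection: correlation screening, BIC component selection under
# cross-validation, exhaustive feature-subset search.

# deterministic fold partition: a pure function of (n, n_folds, seed), so
# every subset evaluated in one search shares the same folds
.cv_folds <- function(n, n_folds, seed) {
  with_seed(sub_seed(seed, "cv_folds", n, n_folds),
            sample(rep(seq_len(n_folds), length.out = n)))
}

#' Select the PLS component count by cross-validated BIC
#'
#' For \eqn{k = 1..}\code{max_components}, accumulates
#' \eqn{PRESS_k = \sum} squared held-out residuals over a fixed seeded
#' \code{n_folds}-fold partition and scores
#' \eqn{BIC_k = n\,\ln(PRESS_k/n) + (k+1)\ln(n)}. Returns the minimising
#' \eqn{k} (ties to the smaller \eqn{k}) together with the per-\eqn{k}
#' curves.
#'
#' @param X complete predictor matrix.
#' @param y response.
#' @param max_components largest component count to consider
#'   (\code{<= ncol(X)}).
#' @param n_folds folds (default 10).
#' @param seed integer seed for the partition.
#' @return list with \code{n_components}, \code{bic}, \code{press} and
#'   \code{cv_r2} (each a length-\code{max_components} vector).
#' @export
bic_select_components <- function(X, y, max_components, n_folds = 10,
                                  seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds)
    stop_oculopls("too_few_rows", "need n >= n_folds")
  if (max_components > ncol(X))
    stop_oculopls("bad_components", "max_components exceeds feature count")
  fold <- .cv_folds(n, n_folds, seed)
  if (any((n - tabulate(fold, n_folds)) < 2))
    stop_oculopls("too_few_rows", "a fold leaves fewer than 2 training points")
  press <- as.numeric(cpp_cv_press(X, y, as.integer(fold),
                                   as.integer(max_components)))
  bic <- n * log(pmax(press, 1e-300) / n) +
    (seq_len(max_components) + 1) * log(n)
  k <- which.min(bic)  # which.min takes the first (= smallest k) on ties
  tss <- sum((y - mean(y))^2)
  list(n_components = k, bic = bic, press = press, cv_r2 = 1 - press / tss)
}

#' Rank features by absolute Spearman correlation with the response
#'
#' The screening step: parameters are ordered by \eqn{|\rho|} with the
#' outcome (computed on the complete, post-imputation matrix) and the top
#' \code{n_top} are returned. Ties break deterministically by parameter
#' name.
#'
#' @param X complete numeric matrix with named columns.
#' @param y response (no missing values).
#' @param n_top how many features to keep (default 20); all are returned if
#'   fewer are available.
#' @return character vector of feature names, strongest first.
#' @export
screen_features <- function(X, y, n_top = 20) {
  X <- as.matrix(X)
  if (length(y) < 3)
    stop_oculopls("too_few_pairs", "need >= 3 observations to screen")
  ry <- rank(y)
  rX <- apply(X, 2L, rank)
  rho <- suppressWarnings(as.numeric(stats::cor(ry, rX)))
  rho[is.na(rho)] <- 0  # zero-variance columns rank last
  ord <- order(-abs(rho), colnames(X))
  colnames(X)[ord][seq_len(min(n_top, ncol(X)))]
}

#' Exhaustive feature-subset search under cross-validated PLS
#'
#' Evaluates every nonempty subset of the candidate features
#' (\eqn{2^k - 1} subsets): each subset's latent-component count is chosen
#' by [bic_select_components()] (with \code{max_components =
#' min(|subset|, 10)}) on a fold partition shared across all subsets, and
#' the subset is scored by its cross-validated R-squared at that component
#' count. The winner maximises CV R-squared; ties break to fewer features,
#' then lexicographically by feature names. The final model is refit on the
#' full data with the winning subset and component count.
#'
#' @param X complete predictor matrix with named columns.
#' @param y response.
#' @param candidates character vector of candidate column names (at most
#'   \code{max_candidates_cap}).
#' @param n_folds folds (default 10).
#' @param seed integer seed for the shared partition.
#' @param max_candidates_cap guard on the combinatorial size (default 20,
#'   i.e. up to 1,048,575 subsets; lower it for desk-scale runs).
#' @param max_components_cap per-subset component bound (default 10).
#' @return list with \code{model} (a [fit_pls()] fit on the winning subset),
#'   and \code{trace} (\code{n_subsets_evaluated}, \code{best_subset},
#'   \code{n_components}, \code{best_criterion},
#'   \code{criterion_name = "cv_r2"}).
#' @export
exhaustive_subset_search <- function(X, y, candidates, n_folds = 10,
                                     seed = 1L, max_candidates_cap = 20,
                                     max_components_cap = 10) {
  X <- as.matrix(X)
  if (length(candidates) < 1)
    stop_oculopls("bad_candidates", "need at least one candidate")
  if (length(candidates) > max_candidates_cap)
    stop_oculopls("bad_candidates", sprintf(
      "%d candidates exceed the cap of %d", length(candidates),
      max_candidates_cap))
  miss <- setdiff(candidates, colnames(X))
  if (length(miss))
    stop_oculopls("name_mismatch", sprintf("candidate(s) not in X: %s",
                                           paste(miss, collapse = ", ")))
  n <- nrow(X)
  fold <- .cv_folds(n, n_folds, seed)
  Xc <- X[, candidates, drop = FALSE]
  name_rank <- rank(candidates, ties.method = "first")
  res <- cpp_subset_search(Xc, y, as.integer(fold),
                           as.integer(max_components_cap),
                           as.integer(name_rank))
  best <- candidates[res$columns]
  model <- fit_pls(X[, best, drop = FALSE], y, res$n_components)
  trace <- list(n_subsets_evaluated = res$n_subsets_evaluated,
                best_subset = best,
                n_components = res$n_components,
                best_criterion = res$cv_r2,
                criterion_name = "cv_r2")
  list(model = model, trace = trace)
}
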