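# Permutation nulls for group differences in Spearman rho and adjusted R2,
# and the paired comparison of true-age vs predicted-age correlations.
#
# "More extreme than the observed value" is implemented as the closed
# inequality |permuted| >= |observed|; optional add-one smoothing
# ((b + 1)/(M + 1)) is off by default so the reported p is the plain
# proportion. When the assignment space is small enough the null is
# enumerated exhaustively instead of sampled.

.rank_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

.perm_result <- function(statistic_name, observed, null_values, seed,
                         smoothing, n_discarded = 0L, exhaustive = FALSE,
                         note = NULL) {
  M <- length(null_values)
  b <- sum(abs(null_values) >= abs(observed) - 1e-12)
  p <- if (smoothing) (b + 1) / (M + 1) else b / M
  structure(list(
    statistic_name = statistic_name,
    observed_difference = observed,
    n_replicates = M,
    p_two_tailed = p,
    null_quantiles = stats::quantile(null_values, c(0.025, 0.5, 0.975),
                                     names = FALSE),
    seed = seed,
    n_discarded = n_discarded,
    exhaustive = exhaustive,
    note = note
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed difference = %+.4f\n", x$observed_difference))
  cat(sprintf("  null 2.5%%/50%%/97.5%% = %.4f / %.4f / %.4f\n",
              x$null_quantiles[1], x$null_quantiles[2], x$null_quantiles[3]))
  cat(sprintf("  two-tailed p = %.4g (%s, %d replicates)\n", x$p_two_tailed,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_replicates))
  if (!is.null(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

# all C(n, k) index subsets (used for exhaustive label enumeration)
.all_combn_small <- function(n, k) utils::combn(n, k)

#' Permutation test for a group difference in Spearman rho
#'
#' Observed statistic: \eqn{\rho_a - \rho_b}. Null: pool the (x, y) pairs,
#' reassign group labels preserving group sizes, recompute the difference.
#' Enumerated exhaustively over all label assignments when
#' \eqn{\binom{n_a+n_b}{n_a} \le} \code{exact_limit}, else sampled
#' \code{n_replicates} times. Replicates with degenerate ranks are discarded
#' and redrawn (counted in the result).
#'
#' @param x_a,y_a paired vectors for group a (complete pairs only are used).
#' @param x_b,y_b paired vectors for group b.
#' @param n_replicates label shuffles (default 1,000).
#' @param seed integer seed.
#' @param smoothing use add-one smoothing \eqn{(b+1)/(M+1)} (default
#'   \code{FALSE}: plain proportion).
#' @param exact_limit enumeration cap for the exhaustive path (default 5000).
#' @return a \code{permutation_result}.
#' @export
permute_rho_difference <- function(x_a, y_a, x_b, y_b, n_replicates = 1000,
                                   seed = 1L, smoothing = FALSE,
                                   exact_limit = 5000) {
  ka <- !is.na(x_a) & !is.na(y_a); x_a <- x_a[ka]; y_a <- y_a[ka]
  kb <- !is.na(x_b) & !is.na(y_b); x_b <- x_b[kb]; y_b <- y_b[kb]
  na <- length(x_a); nb <- length(x_b)
  if (na < 3 || nb < 3)
    stop_oculopls("too_few_pairs", "each group needs >= 3 complete pairs")
  obs <- .rank_rho(x_a, y_a) - .rank_rho(x_b, y_b)
  if (is.na(obs))
    stop_oculopls("zero_variance", "observed rho undefined in a group")
  x <- c(x_a, x_b); y <- c(y_a, y_b); n <- na + nb

  if (choose(n, na) <= exact_limit) {
    idx <- .all_combn_small(n, na)
    null_values <- apply(idx, 2L, function(ia) {
      .rank_rho(x[ia], y[ia]) - .rank_rho(x[-ia], y[-ia])
    })
    keep <- !is.na(null_values)
    return(.perm_result("spearman_rho_difference", obs, null_values[keep],
                        seed, smoothing, n_discarded = sum(!keep),
                        exhaustive = TRUE))
  }

  with_seed(seed, {
    null_values <- numeric(n_replicates)
    discarded <- 0L
    for (r in seq_len(n_replicates)) {
      repeat {
        ia <- sample.int(n, na)
        d <- .rank_rho(x[ia], y[ia]) - .rank_rho(x[-ia], y[-ia])
        if (!is.na(d)) break
        discarded <- discarded + 1L
        if (discarded > 100L * n_replicates)
          stop_oculopls("degenerate_permutation",
                        "could not draw non-degenerate replicates")
      }
      null_values[r] <- d
    }
    .perm_result("spearman_rho_difference", obs, null_values, seed,
                 smoothing, n_discarded = discarded)
  })
}

#' Permutation test for a group difference in adjusted R-squared
#'
#' Observed statistic: adjusted R2 of model a minus that of model b. Null:
#' pool the participants of both fits, shuffle the group labels preserving
#' sizes, refit the PLS coefficients within each pseudo-group using each
#' model's FIXED selected features and component count, and recompute the
#' adjusted R2 difference. Feature selection is deliberately not re-run per
#' replicate (noted in the result).
#'
#' @param model_a,model_b \code{oculopls} fits of the same outcome on the
#'   two cohorts.
#' @param n_replicates label shuffles (default 1,000).
#' @param seed integer seed.
#' @param smoothing as in [permute_rho_difference()].
#' @return a \code{permutation_result}.
#' @export
permute_r2_difference <- function(model_a, model_b, n_replicates = 1000,
                                  seed = 1L, smoothing = FALSE) {
  stopifnot(inherits(model_a, "oculopls"), inherits(model_b, "oculopls"))
  if (model_a$outcome != model_b$outcome)
    stop_oculopls("config_invalid", "models must share the outcome")
  obs <- model_a$r2_adjusted - model_b$r2_adjusted

  fa <- model_a$selected_features; ka <- model_a$n_components
  fb <- model_b$selected_features; kb <- model_b$n_components
  feats <- union(fa, fb)
  miss_a <- setdiff(feats, colnames(model_a$X))
  miss_b <- setdiff(feats, colnames(model_b$X))
  if (length(miss_a) || length(miss_b))
    stop_oculopls("name_mismatch",
                  "models' stored matrices do not cover both feature sets")
  Xp <- rbind(model_a$X[, feats, drop = FALSE],
              model_b$X[, feats, drop = FALSE])
  yp <- c(model_a$y, model_b$y)
  na <- length(model_a$y); n <- length(yp)
  ia_cols <- match(fa, feats); ib_cols <- match(fb, feats)
  pa <- length(fa); pb <- length(fb)

  adj <- function(r2, nn, p) 1 - (1 - r2) * (nn - 1) / (nn - p - 1)
  one_rep <- function(ia) {
    ya <- yp[ia]; yb <- yp[-ia]
    if (stats::sd(ya) == 0 || stats::sd(yb) == 0) return(NA_real_)
    r2a <- cpp_pls_insample_r2(Xp[ia, ia_cols, drop = FALSE], ya, ka)
    r2b <- cpp_pls_insample_r2(Xp[-ia, ib_cols, drop = FALSE], yb, kb)
    adj(r2a, na, pa) - adj(r2b, n - na, pb)
  }

  with_seed(seed, {
    null_values <- numeric(n_replicates)
    discarded <- 0L
    for (r in seq_len(n_replicates)) {
      repeat {
        d <- one_rep(sample.int(n, na))
        if (!is.na(d)) break
        discarded <- discarded + 1L
        if (discarded > 100L * n_replicates)
          stop_oculopls("degenerate_permutation",
                        "could not draw non-degenerate replicates")
      }
      null_values[r] <- d
    }
    .perm_result("adjusted_r2_difference", obs, null_values, seed, smoothing,
                 n_discarded = discarded,
                 note = "coefficients refit per replicate; feature selection fixed")
  })
}

#' Paired permutation test: true-age vs predicted-age correlation
#'
#' Observed statistic: \eqn{\rho(\mathrm{true\ age}, s) -
#' \rho(\mathrm{predicted\ age}, s)}. Null: independently per participant,
#' swap the (true, predicted) pair with probability 1/2 and recompute
#' (sign-flip exchangeability of the paired proxy). Enumerated over all
#' \eqn{2^n} swap patterns when feasible.
#'
#' @param age_true,age_predicted,score aligned per-participant vectors
#'   (rows with any \code{NA} dropped); need n >= 4.
#' @param n_replicates swaps (default 1,000).
#' @param seed integer seed.
#' @param smoothing as in [permute_rho_difference()].
#' @param exact_limit enumeration cap on \eqn{2^n} (default 5000).
#' @return a \code{permutation_result}.
#' @export
permute_paired_rho_difference <- function(age_true, age_predicted, score,
                                          n_replicates = 1000, seed = 1L,
                                          smoothing = FALSE,
                                          exact_limit = 5000) {
  keep <- !is.na(age_true) & !is.na(age_predicted) & !is.na(score)
  a <- age_true[keep]; b <- age_predicted[keep]; s <- score[keep]
  n <- length(s)
  if (n < 4)
    stop_oculopls("too_few_pairs", "need >= 4 aligned triples")
  obs <- .rank_rho(a, s) - .rank_rho(b, s)
  if (is.na(obs))
    stop_oculopls("zero_variance", "observed rho undefined")

  swap_diff <- function(sw) {
    aa <- ifelse(sw, b, a)
    bb <- ifelse(sw, a, b)
    .rank_rho(aa, s) - .rank_rho(bb, s)
  }

  if (2^n <= exact_limit) {
    null_values <- vapply(seq_len(2^n) - 1L, function(bits) {
      swap_diff(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0)
    }, numeric(1))
    keep2 <- !is.na(null_values)
    return(.perm_result("paired_rho_difference", obs, null_values[keep2],
                        seed, smoothing, n_discarded = sum(!keep2),
                        exhaustive = TRUE))
  }

  with_seed(seed, {
    null_values <- numeric(n_replicates)
    discarded <- 0L
    for (r in seq_len(n_replicates)) {
      repeat {
        d <- swap_diff(stats::runif(n) < 0.5)
        if (!is.na(d)) break
        discarded <- discarded + 1L
        if (discarded > 100L * n_replicates)
          stop_oculopls("degenerate_permutation",
                        "could not draw non-degenerate replicates")
      }
      null_values[r] <- d
    }
    .perm_result("paired_rho_difference", obs, null_values, seed, smoothing,
                 n_discarded = discarded)
  })
}
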