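# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths (and where possible the base
# helpers) used by the implementation under test.

# average ranks by counting, not by base rank()
oracle_rank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

# Pearson correlation from explicit sums
oracle_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  den <- sqrt(sum(am^2) * sum(bm^2))
  if (den == 0) return(NA_real_)
  sum(am * bm) / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# hand step-up BH: adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m),
                function(i) min(1, min(ps[i:m] * m / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mann-Whitney U and exact two-sided p by full enumeration of label
# assignments (valid with or without ties)
oracle_mwu_enum <- function(a, b) {
  na <- length(a); n <- na + length(b)
  pooled <- c(a, b)
  r <- oracle_rank(pooled)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  Us <- apply(idx, 2L, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  p <- min(1, 2 * min(mean(Us <= U_obs + 1e-9), mean(Us >= U_obs - 1e-9)))
  list(U = U_obs, p = p)
}

# R-level NIPALS prediction path (independent of the C++ core)
oracle_pls_path <- function(Xtr, ytr, Xte, kmax) {
  mx <- colMeans(Xtr)
  sx <- apply(Xtr, 2L, stats::sd); sx[sx == 0] <- 1
  E <- sweep(sweep(Xtr, 2L, mx), 2L, sx, "/")
  Te <- sweep(sweep(Xte, 2L, mx), 2L, sx, "/")
  my <- mean(ytr)
  f <- ytr - my
  preds <- matrix(my, nrow(Xte), kmax)
  acc <- rep(0, nrow(Xte))
  for (k in seq_len(kmax)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { preds[, k:kmax] <- acc + my; return(preds) }
    w <- w / nw
    tk <- drop(E %*% w); tt <- sum(tk^2)
    if (tt < 1e-12) { preds[, k:kmax] <- acc + my; return(preds) }
    pl <- drop(crossprod(E, tk)) / tt
    q <- sum(f * tk) / tt
    tte <- drop(Te %*% w)
    acc <- acc + tte * q
    preds[, k] <- acc + my
    E <- E - tcrossprod(tk, pl)
    f <- f - tk * q
    Te <- Te - tcrossprod(tte, pl)
  }
  preds
}

# brute-force best-subset enumeration with the same fold partition and the
# same selection criterion definitions, computed entirely in R
oracle_best_subset <- function(X, y, fold, kcap = 10) {
  p <- ncol(X); n <- nrow(X)
  tss <- sum((y - mean(y))^2)
  best <- NULL
  for (mask in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    kmax <- min(length(cols), kcap)
    press <- numeric(kmax)
    for (f in sort(unique(fold))) {
      te <- fold == f
      P <- oracle_pls_path(X[!te, cols, drop = FALSE], y[!te],
                           X[te, cols, drop = FALSE], kmax)
      press <- press + colSums((y[te] - P)^2)
    }
    bic <- n * log(press / n) + (seq_len(kmax) + 1) * log(n)
    k <- which.min(bic)
    r2 <- 1 - press[k] / tss
    key <- paste(sort(colnames(X)[cols]), collapse = ",")
    replace <- is.null(best) || r2 > best$r2 + 1e-12 ||
      (abs(r2 - best$r2) <= 1e-12 &&
         (length(cols) < length(best$cols) ||
            (length(cols) == length(best$cols) && key < best$key)))
    if (replace) best <- list(r2 = r2, cols = cols, k = k, key = key)
  }
  best$names <- colnames(X)[best$cols]
  best
}

# small hand-built cohort for I/O and validation tests
make_small_cohort <- function(n = 6, n_params = 4, seed = 1,
                              missing_cells = 0) {
  set.seed(seed)
  params <- sprintf("PS_p%02d", seq_len(n_params))
  X <- matrix(round(rnorm(n * n_params), 4), n, n_params,
              dimnames = list(NULL, params))
  if (missing_cells > 0) X[sample(length(X), missing_cells)] <- NA
  pp <- data.frame(
    id = sprintf("S%02d", seq_len(n)),
    group = "HC",
    sex = rep(c("male", "female"), length.out = n),
    age = round(runif(n, 20, 75), 1),
    MoCA = sample(20:30, n, replace = TRUE),
    TMTA = round(runif(n, 15, 60), 2),
    stringsAsFactors = FALSE)
  cohort_table(pp, X)
}
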