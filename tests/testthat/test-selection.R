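# Component selection by CV-BIC and the exhaustive subset search.

test_that("BIC curve implements n ln(PRESS/n) + (k+1) ln(n)", {
  set.seed(1)
  X <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] + rnorm(100, 0, 0.5)
  out <- bic_select_components(X, y, max_components = 3, seed = 9)
  expect_equal(out$bic,
               100 * log(out$press / 100) + (1:3 + 1) * log(100))
  # the stated arithmetic case: n = 100, PRESS = 50, k = 2
  expect_equal(100 * log(50 / 100) + (2 + 1) * log(100), -55.50,
               tolerance = 1e-3)
  expect_equal(out$cv_r2, 1 - out$press / sum((y - mean(y))^2))
})

test_that("CV PRESS matches an R-level fold-by-fold oracle", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X %*% runif(5, -1, 1) + rnorm(n, 0, 0.4)
  out <- bic_select_components(X, y, max_components = 4, n_folds = 5,
                               seed = 3)
  fold <- oculopls:::.cv_folds(n, 5, 3)
  press <- numeric(4)
  for (f in 1:5) {
    te <- fold == f
    P <- oracle_pls_path(X[!te, , drop = FALSE], y[!te],
                         X[te, , drop = FALSE], 4)
    press <- press + colSums((y[te] - P)^2)
  }
  expect_equal(out$press, press, tolerance = 1e-10)
})

test_that("BIC recovers two exact latent directions at high SNR", {
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 300
    Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
    t1 <- Q[, 1] * sqrt(n); t2 <- Q[, 2] * sqrt(n)
    X <- cbind(t1, t2) %*% matrix(rnorm(20), 2, 10)
    colnames(X) <- paste0("f", 1:10)
    y <- t1 - t2 + rnorm(n, 0, 0.1)
    bic_select_components(X, y, max_components = 6, seed = s)$n_components
  }, numeric(1))
  expect_gte(mean(hits == 2), 0.8)
})

test_that("BIC prefers one component for a pure-noise response", {
  picks <- vapply(1:15, function(s) {
    set.seed(s + 50)
    X <- matrix(rnorm(100 * 6), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
    bic_select_components(X, rnorm(100), max_components = 5,
                          seed = s)$n_components
  }, numeric(1))
  expect_gt(mean(picks == 1), 0.5)
})

test_that("screen_features orders by |rho| with name tie-breaks", {
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("PS_p%02d", 1:10)))
  y <- 2 * X[, 7] + rnorm(n, 0, 0.3)
  top <- screen_features(X, y, n_top = 3)
  expect_equal(top[1], "PS_p07")
  # fewer candidates than requested: all returned, sorted
  all10 <- screen_features(X, y, n_top = 20)
  expect_length(all10, 10L)
  ry <- rank(y)
  rhos <- abs(apply(X, 2, function(x) stats::cor(rank(x), ry)))
  expect_equal(all10, names(sort(-rhos)))
  # exact ties resolved alphabetically
  Xt <- cbind(b_dup = X[, 1], a_dup = X[, 1])
  expect_equal(screen_features(Xt, y, 2), c("a_dup", "b_dup"))
})

test_that("exhaustive search equals brute-force enumeration", {
  set.seed(5)
  for (p in c(3, 6)) {
    n <- 50
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("c%02d", 1:p)))
    y <- X[, 1] - 0.7 * X[, min(2, p)] + rnorm(n, 0, 0.5)
    res <- exhaustive_subset_search(X, y, colnames(X), n_folds = 5, seed = 6)
    expect_equal(res$trace$n_subsets_evaluated, 2^p - 1)
    fold <- oculopls:::.cv_folds(n, 5, 6)
    orc <- oracle_best_subset(X, y, fold, kcap = 10)
    expect_setequal(res$trace$best_subset, orc$names)
    expect_equal(res$trace$best_criterion, orc$r2, tolerance = 1e-10)
    expect_equal(res$trace$n_components, orc$k)
  }
})

test_that("a single candidate is selected unconditionally", {
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(40)
  res <- exhaustive_subset_search(X, y, "b", n_folds = 5, seed = 1)
  expect_equal(res$trace$best_subset, "b")
  expect_equal(res$trace$n_subsets_evaluated, 1)
  expect_error(exhaustive_subset_search(X, y, colnames(X), seed = 1,
                                        max_candidates_cap = 2),
               class = "oculopls_bad_candidates")
})

test_that("planted signal features are recovered among noise candidates", {
  # the planted pair is found essentially always; a few spurious extras can
  # ride along because any chance correlation present in the full sample
  # replicates across CV folds (an intrinsic property of the CV R2
  # criterion), so extras are checked on the median, not per run
  pair <- extras <- numeric(12)
  for (s in 1:12) {
    set.seed(s)
    n <- 300
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, sprintf("c%02d", 1:10)))
    y <- X[, 1] + 0.8 * X[, 2] + rnorm(n, 0, 0.25)
    sel <- exhaustive_subset_search(X, y, colnames(X),
                                    seed = s)$trace$best_subset
    pair[s] <- all(c("c01", "c02") %in% sel)
    extras[s] <- length(setdiff(sel, c("c01", "c02")))
  }
  expect_gte(mean(pair), 0.9)
  expect_lte(median(extras), 2)
})

test_that("the fold partition is a pure function of (n, n_folds, seed)", {
  f1 <- oculopls:::.cv_folds(100, 10, 5)
  f2 <- oculopls:::.cv_folds(100, 10, 5)
  expect_identical(f1, f2)
  expect_false(identical(f1, oculopls:::.cv_folds(100, 10, 6)))
  expect_equal(sort(unique(f1)), 1:10)
  expect_true(all(tabulate(f1, 10) == 10))
})
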