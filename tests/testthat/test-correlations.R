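# Rank correlation, FDR adjustment, task summaries, Mann-Whitney.

test_that("spearman_rho handles ties by average ranks", {
  r <- spearman_rho(c(1, 2, 3, 4, 5), c(5, 6, 7, 8, 7))
  expect_equal(r$rho, oracle_spearman(c(1, 2, 3, 4, 5), c(5, 6, 7, 8, 7)))
  expect_equal(r$rho, 0.8208, tolerance = 1e-4)
  expect_equal(r$n_pairs, 5L)
})

test_that("spearman_rho is invariant under monotone transforms and antisymmetric", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, base)
    expect_equal(spearman_rho(x, y^3)$rho, base)  # odd cube is monotone
    expect_equal(spearman_rho(x, -y)$rho, -base)
    expect_equal(spearman_rho(x, x^2 * sign(x))$rho, 1)  # monotone map of x
  }
})

test_that("spearman_rho matches the counting-rank oracle on tied data", {
  set.seed(22)
  for (i in 1:60) {
    n <- sample(4:9, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y))
  }
})

test_that("spearman_rho deletes pairwise and enforces preconditions", {
  r <- spearman_rho(c(1, 2, NA, 4, 5), c(2, NA, 3, 5, 6))
  expect_equal(r$n_pairs, 3L)
  expect_error(spearman_rho(c(1, 2), c(1, 2)), class = "oculopls_too_few_pairs")
  expect_error(spearman_rho(1:3, 1:4), class = "oculopls_length_mismatch")
  und <- spearman_rho(c(2, 2, 2, 2), c(1, 3, 2, 4))
  expect_false(und$defined)
  expect_true(is.na(und$rho))  # undefined, never coerced to 0
})

test_that("p-values: exact enumeration below n = 10, t approximation above", {
  # exact path: p is the proportion of permutations at least as extreme
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- spearman_rho(x, y)
  perms <- asplit(oculopls:::.all_perms(5), 1)
  rhos <- vapply(perms, function(pm) oracle_spearman(x, y[pm]), numeric(1))
  expect_equal(r$p_raw, mean(abs(rhos) >= abs(r$rho) - 1e-12))
  # t path matches the closed form
  set.seed(3); x <- rnorm(30); y <- x + rnorm(30)
  r <- spearman_rho(x, y)
  tt <- r$rho * sqrt((30 - 2) / (1 - r$rho^2))
  expect_equal(r$p_raw, 2 * stats::pt(-abs(tt), 28))
})

test_that("bh_adjust reproduces the hand step-up oracle", {
  got <- bh_adjust(c(0.01, 0.04, 0.03, 0.005), alpha = 0.05)
  expect_equal(got$p_adj, c(0.02, 0.04, 0.04, 0.02))
  expect_true(all(got$significant))
  expect_equal(bh_adjust(0.7)$p_adj, 0.7)        # single p unchanged
  all1 <- bh_adjust(rep(1, 5))
  expect_true(all(all1$p_adj == 1) && !any(all1$significant))
  expect_length(bh_adjust(numeric(0))$p_adj, 0L)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "oculopls_bad_pvalue")
})

test_that("bh_adjust is monotone along sorted p and idempotent", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:25, 1))
    adj <- bh_adjust(p)$p_adj
    expect_equal(adj, oracle_bh(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    again <- bh_adjust(adj)
    expect_identical(bh_adjust(p)$significant, again$significant)
  }
})

test_that("correlation_screen gives one row per parameter with family-wise BH", {
  g <- generate_cohort(hc_config(seed = 2))
  tab <- correlation_screen(g$cohort, "SDMT")
  expect_s3_class(tab, "correlation_table")
  expect_equal(nrow(tab), 199L)
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-12, na.rm = TRUE))
  ok <- !is.na(tab$p_raw)
  expect_equal(tab$p_adj[ok], oracle_bh(tab$p_raw[ok]))
  # planted informative parameters dominate the ranking
  inf <- g$truth$informative_param_ids
  top20 <- tab$parameter[order(-abs(tab$rho))][1:20]
  expect_gt(mean(top20 %in% inf), 0.8)
})

test_that("correlation_screen: an outcome-equal parameter has rho 1", {
  ch <- make_small_cohort(n = 12, n_params = 3, seed = 5)
  ch$oculo[, "PS_p01"] <- ch$participants$TMTA
  tab <- correlation_screen(ch, "TMTA")
  expect_equal(tab$rho[tab$parameter == "PS_p01"], 1)
  expect_error(correlation_screen(ch, "SDMT"),
               class = "oculopls_unknown_outcome")
})

test_that("sex-disaggregated screening returns one table per sex", {
  ch <- generate_cohort(hc_config(seed = 6))$cohort
  out <- correlation_screen(ch, "Age", disaggregate_by_sex = TRUE)
  expect_named(out, c("male", "female"))
  expect_true(all(out$male$n <= sum(ch$participants$sex == "male")))
  expect_true(all(out$female$n <= sum(ch$participants$sex == "female")))
})

test_that("task_average_abs_rho averages |rho| within tasks", {
  cat3 <- parameter_catalog(c("PS_a", "PS_b", "FIX_a"),
                            c("pro_saccade", "pro_saccade", "fixation"))
  tab <- data.frame(parameter = c("PS_a", "PS_b", "FIX_a"),
                    task = c("pro_saccade", "pro_saccade", "fixation"),
                    outcome = "MoCA",
                    rho = c(0.3, -0.5, -0.5),
                    n = 10L, p_raw = 0.5, p_adj = 0.5, significant = FALSE)
  out <- suppressWarnings(task_average_abs_rho(tab, cat3))
  expect_equal(out$mean_abs_rho[out$task == "pro_saccade"], 0.4)
  expect_equal(out$mean_abs_rho[out$task == "fixation"], 0.5)
  # undefined rho excluded with count
  tab$rho[2] <- NA
  out2 <- suppressWarnings(task_average_abs_rho(tab, cat3))
  expect_equal(out2$mean_abs_rho[out2$task == "pro_saccade"], 0.3)
  expect_equal(out2$n_undefined[out2$task == "pro_saccade"], 1L)
  # absent tasks warned about, not fabricated
  expect_warning(task_average_abs_rho(tab,
    parameter_catalog(c(tab$parameter, "OKN_x"),
                      c(tab$task, "okn"))), "okn")
})

test_that("mann_whitney_u matches enumeration and keeps U_a + U_b = n_a n_b", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_tailed, 1 / 3, tolerance = 1e-12)
  same <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$U, 4.5)  # n_a n_b / 2
  expect_equal(same$p_two_tailed, 1)
  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(5)
    ra <- mann_whitney_u(a, b)
    rb <- mann_whitney_u(b, a)
    expect_equal(ra$U + rb$U, 30)
    orc <- oracle_mwu_enum(a, b)
    expect_equal(ra$U, orc$U)
    expect_equal(ra$p_two_tailed, orc$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "oculopls_empty_group")
})
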