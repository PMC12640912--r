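# Synthetic cohort generator: preset structure, determinism, closed-form
# variance accounting, missingness machinery.

test_that("presets reproduce the study's demographic structure", {
  hc <- generate_cohort(hc_config(seed = 5))$cohort
  expect_equal(n_participants(hc), 204L)
  expect_true(all(hc$participants$age >= 18 & hc$participants$age <= 79))
  expect_equal(sum(hc$participants$sex == "male"), 120L)
  expect_equal(sum(hc$participants$sex == "female"), 84L)
  expect_equal(unname(outcome_n(hc)[c("MoCA", "SDMT", "HVLT")]),
               c(203L, 198L, 200L))

  pd <- generate_cohort(pd_config(seed = 5))$cohort
  expect_equal(n_participants(pd), 65L)
  expect_true(all(pd$participants$age >= 45 & pd$participants$age <= 89))
  expect_equal(sum(pd$participants$sex == "male"), 43L)
  expect_equal(sum(pd$participants$sex == "female"), 22L)
  expect_false("SDMT" %in% names(pd$participants))
  expect_equal(unname(outcome_n(pd)[c("MoCA", "TMTA", "TMTB", "HVLT", "COWAT")]),
               c(36L, 50L, 49L, 50L, 48L))
  expect_identical(validate_cohort(hc), character(0))
  expect_identical(validate_cohort(pd), character(0))
})

test_that("identical config gives a bit-identical cohort", {
  a <- generate_cohort(hc_config(seed = 42))
  b <- generate_cohort(hc_config(seed = 42))
  expect_identical(a$cohort$oculo, b$cohort$oculo)
  expect_identical(a$cohort$participants, b$cohort$participants)
  expect_identical(a$truth$latent_factor, b$truth$latent_factor)
  c2 <- generate_cohort(hc_config(seed = 43))
  expect_false(identical(a$cohort$oculo, c2$cohort$oculo))
})

test_that("theoretical R2 matches a large-n oracle regression on (g, age)", {
  cfg <- hc_config(seed = 7)
  cfg$n_participants <- 20000L
  cfg$sex_counts <- c(male = 10000L, female = 10000L)
  cfg$score_params$n_complete <- 20000L
  cfg$missing_block_rate <- 0
  cfg$missing_cell_rate <- 0
  # keep only the two scores checked; skip the expensive full block
  cfg$n_informative_params <- 2L
  g <- generate_cohort(cfg)
  pp <- g$cohort$participants
  # non-skewed scores: the skewed ones converge slowly in sample variance
  for (o in c("SDMT", "HVLT", "MoCA")) {
    fit <- stats::lm(pp[[o]] ~ g$truth$latent_factor + pp$age)
    emp_r2 <- summary(fit)$r.squared
    expect_lt(abs(emp_r2 - theoretical_r2(cfg, o)), 0.02)
  }
})

test_that("theoretical R2 is monotone in noise and zero without signal", {
  cfg <- hc_config()
  noisy <- cfg
  noisy$score_params$noise_sd <- 2 * noisy$score_params$noise_sd
  for (o in cfg$score_params$outcome)
    expect_lt(theoretical_r2(noisy, o), theoretical_r2(cfg, o))
  nullc <- null_config()
  for (o in nullc$score_params$outcome)
    expect_equal(theoretical_r2(nullc, o), 0)
  expect_error(theoretical_r2(cfg, "XYZ"), class = "oculopls_unknown_outcome")
})

test_that("age-score correlations recover the designed signs and sizes", {
  cfg <- hc_config(seed = 31)
  cfg$n_participants <- 2000L
  cfg$sex_counts <- c(male = 1000L, female = 1000L)
  cfg$score_params$n_complete <- 2000L
  ch <- generate_cohort(cfg)$cohort
  design <- cfg$score_params
  for (i in seq_len(nrow(design))) {
    r <- spearman_rho(ch$participants$age,
                      ch$participants[[design$outcome[i]]])
    expect_equal(sign(r$rho), sign(design$rho_age[i]),
                 label = design$outcome[i])
    expect_lt(abs(r$rho - design$rho_age[i]), 0.09,
              label = design$outcome[i])
  }
})

test_that("raising the coupling raises informative-parameter correlations", {
  mean_abs_rho <- function(kappa, seed) {
    cfg <- simulation_config(coupling_kappa = kappa, seed = seed,
                             missing_block_rate = 0, missing_cell_rate = 0)
    g <- generate_cohort(cfg)
    sdmt <- g$cohort$participants$SDMT
    mean(abs(apply(g$cohort$oculo[, g$truth$informative_param_ids], 2L,
                   function(x) spearman_rho(x, sdmt)$rho)))
  }
  reps <- 1:8
  m0 <- mean(vapply(reps, function(s) mean_abs_rho(0, s), numeric(1)))
  m1 <- mean(vapply(reps, function(s) mean_abs_rho(1, s), numeric(1)))
  m2 <- mean(vapply(reps, function(s) mean_abs_rho(2, s), numeric(1)))
  expect_lt(m0, m1)
  expect_lt(m1, m2)
})

test_that("zero-coupling cohorts carry no parameter-score association", {
  rhos <- vapply(1:6, function(s) {
    g <- generate_cohort(null_config(seed = s))
    sdmt <- g$cohort$participants$SDMT
    mean(abs(apply(g$cohort$oculo[, 1:30], 2L,
                   function(x) spearman_rho(x, sdmt)$rho)))
  }, numeric(1))
  # mean |rho| of null correlations at n = 204 is ~ sqrt(2/pi)/sqrt(n-1)
  expect_lt(abs(mean(rhos) - sqrt(2 / pi) / sqrt(203)), 0.01)
})

test_that("missingness scheme behaves at the boundary rates", {
  ch <- make_small_cohort(n = 6, n_params = 5, seed = 9)
  same <- apply_missingness(ch, 0, 0, seed = 1)
  expect_identical(same$oculo, ch$oculo)
  gone <- apply_missingness(ch, 1, 0, seed = 1)
  expect_true(all(is.na(gone$oculo)))
  expect_false(anyNA(gone$participants$MoCA))
  expect_error(apply_missingness(ch, -0.1, 0), class = "oculopls_config_invalid")
})

test_that("cell-wise missing fraction falls in the exact binomial interval", {
  set.seed(10)
  X <- matrix(rnorm(1000 * 10), 1000, 10,
              dimnames = list(NULL, sprintf("PS_p%02d", 1:10)))
  pp <- data.frame(id = sprintf("P%04d", 1:1000), group = "HC",
                   sex = "male", age = 40, stringsAsFactors = FALSE)
  ch <- cohort_table(pp, X)
  out <- apply_missingness(ch, 0, 0.1, seed = 77)
  n_missing <- sum(is.na(out$oculo))
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
})

test_that("block missingness drops whole task blocks", {
  set.seed(4)
  X <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(NULL, c(sprintf("PS_p%02d", 1:4),
                                      sprintf("SP_p%02d", 1:4))))
  pp <- data.frame(id = sprintf("P%03d", 1:200), group = "HC",
                   sex = "female", age = 50, stringsAsFactors = FALSE)
  ch <- cohort_table(pp, X)
  out <- apply_missingness(ch, 0.4, 0, seed = 123)
  for (tk in c("pro_saccade", "smooth_pursuit")) {
    cols <- which(ch$catalog$task == tk)
    frac <- rowMeans(is.na(out$oculo[, cols]))
    expect_true(all(frac %in% c(0, 1)))  # whole-block or untouched
  }
  expect_gt(sum(is.na(out$oculo)), 0)
  # deterministic given seed
  out2 <- apply_missingness(ch, 0.4, 0, seed = 123)
  expect_identical(out$oculo, out2$oculo)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(sex_counts = c(male = 10, female = 10),
                                 n_participants = 30),
               class = "oculopls_config_invalid")
  expect_error(simulation_config(coupling_kappa = -1),
               class = "oculopls_config_invalid")
  expect_error(simulation_config(n_informative_params = 500),
               class = "oculopls_config_invalid")
})
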