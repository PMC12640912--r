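# Synthetic cohort generator.
#
# Generative model, per participant i:
#   age_i  ~ truncated normal (resampled into the age range)
#   g_i    = alpha * z(age_i) + sqrt(1 - alpha^2) * eps_i,  eps_i ~ N(0, 1)
# g is a latent "neural integrity" factor, correlated with age (alpha = 0.5
# by default) but carrying independent individual variation.
#   informative parameter j:  x_ij = lambda_j * kappa * g_i + N(0, sd_x)
#   other parameters:         x_ij = N(0, sd_x)
#   score s:  s_i = intercept_s + beta_s * age_i + gamma_s * kappa * g_i
#                   + sd_s * noise_i
# with right-skewed standardized noise for the timed tests (TMTA/TMTB) and
# the anxiety inventory, then clipped into the legal score range and rounded
# for the integer-valued instruments. kappa scales the shared coupling: the
# healthy-control preset uses kappa = 1, the Parkinson's preset a larger
# value, reproducing the stronger oculomotor-cognition coupling in disease.

# Given targets on the total-variance-1 scale, solve for the couplings:
#   v + alpha u = rho_age      (age-score rank correlation target)
#   u + alpha v = s * sqrt(r2 / reliability)
# where u = gamma*kappa and v = beta*sd(age) in sd-of-score units, and
# `reliability` is the fraction of Var(g) recoverable from the oculomotor
# block. Returns (u, v, w) with w the residual noise sd.
.solve_score_coupling <- function(rho_age, r2, alpha, reliability) {
  s <- if (rho_age < 0) -1 else 1
  q <- s * sqrt(r2 / reliability)
  u <- (q - alpha * rho_age) / (1 - alpha^2)
  v <- (rho_age - alpha * q) / (1 - alpha^2)
  w2 <- 1 - (u^2 + v^2 + 2 * alpha * u * v)
  if (w2 <= 0)
    stop_oculopls("config_invalid",
                  "score coupling targets leave no residual variance")
  c(u = u, v = v, w = sqrt(w2))
}

# Frozen per-score design targets for the presets: marginal mean/sd, the
# age-score rank correlation and the population fraction of score variance an
# ideal oculomotor(+age) model explains in the healthy regime.
.SCORE_DESIGN <- data.frame(
  outcome = c("MoCA", "SDMT", "TMTA", "TMTB", "HVLT", "COWAT", "BAI"),
  mean    = c(26,     55,     30,     70,     26,     40,      9),
  sd      = c(2.3,    12,     10,     25,     5,      11,      7),
  rho_age = c(-0.128, -0.629, 0.4034, 0.3707, -0.4353, -0.1421, -0.2838),
  r2_pop  = c(0.095,  0.175,  0.15,   0.115,  0.155,   0.12,    0.105),
  skewed  = c(FALSE,  FALSE,  TRUE,   TRUE,   FALSE,  FALSE,   TRUE),
  integer = c(TRUE,   TRUE,   FALSE,  FALSE,  TRUE,   TRUE,    TRUE),
  stringsAsFactors = FALSE
)
.G_RELIABILITY <- 0.8  # assumed recoverable fraction of Var(g) from the block

# Right-skewed noise concentrates rank spacing, so the Spearman correlation
# of a skew-noised score runs ~25% above the linear correlation the solver
# targets; deflate those targets so the *rank* correlation matches the
# design value (factor measured once by simulation at n = 20,000).
.SKEW_RANK_DEFLATION <- 0.8

# build the (beta, gamma, noise_sd, intercept) table from the design targets,
# anchored on the healthy-control age distribution
.score_params_from_design <- function(design, alpha, age_mean, age_sd,
                                      age_range) {
  sd_age <- sqrt(.trunc_norm_var(age_mean, age_sd, age_range[1], age_range[2]))
  out <- design
  out$beta <- out$gamma <- out$noise_sd <- out$intercept <- NA_real_
  for (i in seq_len(nrow(design))) {
    rho_lin <- design$rho_age[i] *
      if (design$skewed[i]) .SKEW_RANK_DEFLATION else 1
    uvw <- .solve_score_coupling(rho_lin, design$r2_pop[i],
                                 alpha, .G_RELIABILITY)
    S <- design$sd[i]
    out$gamma[i] <- uvw[["u"]] * S          # per unit of kappa * g
    out$beta[i] <- uvw[["v"]] * S / sd_age  # per year of age
    out$noise_sd[i] <- uvw[["w"]] * S
    out$intercept[i] <- design$mean[i] - out$beta[i] * age_mean
  }
  out$shift <- 0
  out
}

#' Simulation configuration
#'
#' Assembles and validates the full parameter set of the generative model.
#' Most users want the frozen presets [hc_config()], [pd_config()] or
#' [null_config()].
#'
#' @param group \code{"HC"} or \code{"PD"} (cohort label).
#' @param n_participants cohort size.
#' @param age_range,age_mean_sd truncated-normal age distribution (years).
#' @param sex_counts named counts \code{c(male=, female=)}; must sum to
#'   \code{n_participants}.
#' @param coupling_kappa shared coupling strength multiplying both the
#'   oculomotor loadings and the score couplings; 0 decouples scores from the
#'   oculomotor block entirely.
#' @param alpha correlation between the latent factor and standardized age.
#' @param n_informative_params number of parameters loaded on the latent
#'   factor (the rest are pure noise).
#' @param noise_sd_params residual sd of every oculomotor parameter.
#' @param score_params data frame with one row per collected outcome and
#'   columns \code{outcome, beta, gamma, noise_sd, intercept, skewed,
#'   integer, shift, n_complete}.
#' @param missing_block_rate probability an entire participant-by-task block
#'   is dropped (structural missingness).
#' @param missing_cell_rate independent per-cell drop probability applied
#'   after block dropping.
#' @param catalog parameter catalog; default [default_catalog()].
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(group = "HC",
                              n_participants = 204,
                              age_range = c(18, 79),
                              age_mean_sd = c(40.2, 15),
                              sex_counts = c(male = 120, female = 84),
                              coupling_kappa = 1,
                              alpha = 0.5,
                              n_informative_params = 40,
                              noise_sd_params = 1,
                              score_params = NULL,
                              missing_block_rate = 0.05,
                              missing_cell_rate = 0.02,
                              catalog = default_catalog(),
                              seed = 1L) {
  if (!group %in% c("HC", "PD"))
    stop_oculopls("config_invalid", "group must be 'HC' or 'PD'")
  if (sum(sex_counts) != n_participants)
    stop_oculopls("config_invalid", "sex_counts must sum to n_participants")
  if (coupling_kappa < 0)
    stop_oculopls("config_invalid", "coupling_kappa must be non-negative")
  if (n_informative_params > nrow(catalog))
    stop_oculopls("config_invalid",
                  "n_informative_params exceeds catalog size")
  if (missing_block_rate < 0 || missing_block_rate > 1 ||
      missing_cell_rate < 0 || missing_cell_rate > 1)
    stop_oculopls("config_invalid", "missingness rates must be in [0, 1]")
  if (alpha < -1 || alpha > 1)
    stop_oculopls("config_invalid", "alpha must be in [-1, 1]")
  if (is.null(score_params)) {
    score_params <- .score_params_from_design(.SCORE_DESIGN, alpha,
                                              40.2, 15, c(18, 79))
    score_params$n_complete <- n_participants
  }
  structure(list(
    group = group, n_participants = n_participants,
    age_range = age_range, age_mean_sd = age_mean_sd,
    sex_counts = sex_counts, coupling_kappa = coupling_kappa,
    alpha = alpha, n_informative_params = n_informative_params,
    noise_sd_params = noise_sd_params, score_params = score_params,
    missing_block_rate = missing_block_rate,
    missing_cell_rate = missing_cell_rate,
    catalog = catalog, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Frozen cohort presets
#'
#' \code{hc_config()}: 204 healthy controls, ages 18-79 (40.2 +/- 15),
#' 120 male / 84 female, weak oculomotor-cognition coupling
#' (\code{kappa = 1}), all seven outcomes with realistic per-score
#' completion counts.
#'
#' \code{pd_config()}: 65 Parkinson's patients, ages 45-89 (64.1 +/- 8.4),
#' 43 male / 22 female, strong coupling (\code{kappa = 2.4}), outcomes
#' restricted to MoCA, TMTA, TMTB, HVLT and COWAT (SDMT and BAI are
#' collected in the healthy cohort only) with sparser completion, and
#' disease-shifted score means.
#'
#' \code{null_config()}: zero coupling and zero age slopes - scores and
#' oculomotor parameters are mutually independent noise; used for
#' calibration checks.
#'
#' @param seed integer seed.
#' @param n_participants cohort size (null preset only).
#' @return a [simulation_config()].
#' @export
hc_config <- function(seed = 1L) {
  sp <- .score_params_from_design(.SCORE_DESIGN, 0.5, 40.2, 15, c(18, 79))
  sp$n_complete <- c(MoCA = 203, SDMT = 198, TMTA = 203, TMTB = 203,
                     HVLT = 200, COWAT = 203, BAI = 203)[sp$outcome]
  simulation_config(group = "HC", score_params = sp, seed = seed)
}

#' @rdname hc_config
#' @export
pd_config <- function(seed = 1L) {
  sp <- .score_params_from_design(.SCORE_DESIGN, 0.5, 40.2, 15, c(18, 79))
  sp <- sp[sp$outcome %in% c("MoCA", "TMTA", "TMTB", "HVLT", "COWAT"), ]
  sp$shift <- c(MoCA = -2.5, TMTA = 15, TMTB = 40, HVLT = -4,
                COWAT = 0)[sp$outcome]
  sp$n_complete <- c(MoCA = 36, TMTA = 50, TMTB = 49, HVLT = 50,
                     COWAT = 48)[sp$outcome]
  simulation_config(group = "PD", n_participants = 65,
                    age_range = c(45, 89), age_mean_sd = c(64.1, 8.4),
                    sex_counts = c(male = 43, female = 22),
                    coupling_kappa = 2.45, score_params = sp, seed = seed)
}

#' @rdname hc_config
#' @export
null_config <- function(seed = 1L, n_participants = 204) {
  sp <- .score_params_from_design(.SCORE_DESIGN, 0.5, 40.2, 15, c(18, 79))
  sp$beta <- 0
  sp$gamma <- 0
  sp$intercept <- .SCORE_DESIGN$mean
  sp$n_complete <- n_participants
  nm <- round(n_participants * 120 / 204)
  simulation_config(group = "HC", n_participants = n_participants,
                    sex_counts = c(male = nm, female = n_participants - nm),
                    coupling_kappa = 0, score_params = sp,
                    missing_block_rate = 0, missing_cell_rate = 0,
                    seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the generative model in the config (see the package
#' vignette for the model), applies per-score completion counts and the
#' structural missingness scheme, and returns both the cohort and the
#' generative ground truth. Bit-reproducible given the config (including its
#' seed).
#'
#' @param config a [simulation_config()].
#' @return a list with elements \code{cohort} (a [cohort_table()]) and
#'   \code{truth} (latent factor, informative parameter ids, signed loadings
#'   and per-outcome theoretical R-squared).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    p <- nrow(config$catalog)
    age <- .rtruncnorm(n, config$age_mean_sd[1], config$age_mean_sd[2],
                       config$age_range[1], config$age_range[2])
    sex <- sample(rep(c("male", "female"), config$sex_counts))
    z <- if (n > 1) as.numeric(scale(age)) else 0
    g <- config$alpha * z + sqrt(1 - config$alpha^2) * stats::rnorm(n)

    inf_idx <- sort(sample.int(p, config$n_informative_params))
    lambda <- sample(c(-1, 1), config$n_informative_params, replace = TRUE) *
      stats::runif(config$n_informative_params, 0.5, 1)

    X <- matrix(stats::rnorm(n * p, 0, config$noise_sd_params), n, p,
                dimnames = list(NULL, config$catalog$parameter))
    if (config$coupling_kappa > 0 && length(inf_idx))
      X[, inf_idx] <- X[, inf_idx] +
        outer(g, lambda * config$coupling_kappa)

    sp <- config$score_params
    participants <- data.frame(
      id = sprintf("%s%03d", config$group, seq_len(n)),
      group = config$group, sex = sex, age = age,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sp))) {
      noise <- if (sp$skewed[i]) .rskew(n) else stats::rnorm(n)
      s <- sp$intercept[i] + sp$shift[i] + sp$beta[i] * age +
        sp$gamma[i] * config$coupling_kappa * g + sp$noise_sd[i] * noise
      rng <- .SCORE_RANGES[[sp$outcome[i]]]
      lo <- if (sp$outcome[i] %in% .STRICT_POSITIVE) 1 else rng[1]
      s <- pmax(s, lo)
      if (!is.na(rng[2])) s <- pmin(s, rng[2])
      if (sp$integer[i]) s <- round(s)
      n_miss <- n - min(sp$n_complete[i], n)
      if (n_miss > 0) s[sample.int(n, n_miss)] <- NA_real_
      participants[[sp$outcome[i]]] <- s
    }

    cohort <- cohort_table(participants, X, config$catalog)
    cohort <- apply_missingness(cohort, config$missing_block_rate,
                                config$missing_cell_rate,
                                seed = sub_seed(config$seed, "missingness"))
    r2 <- vapply(sp$outcome, function(o) theoretical_r2(config, o), numeric(1))
    truth <- structure(list(
      latent_factor = g,
      informative_param_ids = config$catalog$parameter[inf_idx],
      lambda = stats::setNames(lambda, config$catalog$parameter[inf_idx]),
      theoretical_r2 = r2
    ), class = "generative_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Population R-squared of the generative model
#'
#' Closed-form fraction of a score's variance explained by an ideal model
#' with access to the latent factor and age:
#' \deqn{R^2 = \frac{\beta^2 V_a + \gamma^2\kappa^2 +
#'   2\beta\gamma\kappa\alpha\sqrt{V_a}}{\beta^2 V_a + \gamma^2\kappa^2 +
#'   2\beta\gamma\kappa\alpha\sqrt{V_a} + \sigma_s^2}}
#' where \eqn{V_a} is the truncated-normal age variance and the cross term
#' reflects the built-in correlation \eqn{\alpha} between the latent factor
#' and standardized age (Var(g) = 1).
#'
#' @param config a [simulation_config()].
#' @param outcome outcome name present in \code{config$score_params}.
#' @return population R-squared in [0, 1].
#' @export
theoretical_r2 <- function(config, outcome) {
  sp <- config$score_params
  i <- match(outcome, sp$outcome)
  if (is.na(i))
    stop_oculopls("unknown_outcome",
                  sprintf("outcome '%s' not in config", outcome))
  Va <- .trunc_norm_var(config$age_mean_sd[1], config$age_mean_sd[2],
                        config$age_range[1], config$age_range[2])
  u <- sp$gamma[i] * config$coupling_kappa
  v <- sp$beta[i] * sqrt(Va)
  signal <- u^2 + v^2 + 2 * config$alpha * u * v
  signal / (signal + sp$noise_sd[i]^2)
}

#' Apply structural and cell-wise missingness to the oculomotor block
#'
#' For every participant-by-task pair the whole task block is dropped with
#' probability \code{block_rate} (structural missingness: an unusable task
#' recording); surviving cells are then dropped independently with
#' probability \code{cell_rate}. Demographics and clinical scores are never
#' masked. Deterministic given the seed.
#'
#' @param cohort a [cohort_table()].
#' @param block_rate,cell_rate probabilities in [0, 1].
#' @param seed integer seed.
#' @return the cohort with updated oculomotor matrix and mask.
#' @export
apply_missingness <- function(cohort, block_rate, cell_rate, seed = 1L) {
  if (block_rate < 0 || block_rate > 1 || cell_rate < 0 || cell_rate > 1)
    stop_oculopls("config_invalid", "rates must be in [0, 1]")
  n <- nrow(cohort$oculo)
  if (n == 0 || (block_rate == 0 && cell_rate == 0)) return(cohort)
  with_seed(seed, {
    X <- cohort$oculo
    tasks <- unique(cohort$catalog$task)
    if (block_rate > 0) {
      drop <- matrix(stats::runif(n * length(tasks)) < block_rate,
                     n, length(tasks), dimnames = list(NULL, tasks))
      for (tk in tasks) {
        cols <- which(cohort$catalog$task == tk)
        X[drop[, tk], cols] <- NA_real_
      }
    }
    if (cell_rate > 0) {
      obs <- which(!is.na(X))
      kill <- obs[stats::runif(length(obs)) < cell_rate]
      X[kill] <- NA_real_
    }
    cohort$oculo <- X
    cohort$mask <- !is.na(X)
    cohort
  })
}
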