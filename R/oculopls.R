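# The main modelling entry point: cohort -> screened, subset-selected,
# BIC-tuned PLS model of one clinical outcome.

#' Control parameters for [oculopls()]
#'
#' @param n_top how many parameters the correlation screen keeps (default
#'   20, the screening depth used throughout the package).
#' @param subset_cap cap on the candidate count entering the exhaustive
#'   subset search. The faithful full search over all 2^20 - 1 subsets of
#'   the screened parameters corresponds to \code{subset_cap = 20}; the
#'   default of 12 (4,095 subsets) keeps desk-scale runs fast and is
#'   announced with a message when it truncates the candidate list.
#' @param n_folds cross-validation folds for component selection and subset
#'   scoring (default 10).
#' @param max_components per-subset bound on latent components (default 10;
#'   the effective bound is \code{min(|subset|, max_components)}).
#' @param ppca_rank latent rank of the PPCA imputation model (default 6).
#' @param ppca_tol,ppca_max_iter EM stopping parameters for the imputation.
#' @return a list of class \code{oculopls_control}.
#' @export
oculopls_control <- function(n_top = 20, subset_cap = 12, n_folds = 10,
                             max_components = 10, ppca_rank = 6,
                             ppca_tol = 1e-5, ppca_max_iter = 150) {
  structure(list(n_top = n_top, subset_cap = subset_cap, n_folds = n_folds,
                 max_components = max_components, ppca_rank = ppca_rank,
                 ppca_tol = ppca_tol, ppca_max_iter = ppca_max_iter),
            class = "oculopls_control")
}

#' Fit an oculomotor PLS model of a clinical outcome
#'
#' The full modelling pipeline for one outcome: restrict to participants
#' with the outcome observed, impute missing oculomotor cells by PPCA,
#' screen the parameters most rank-correlated with the outcome, search all
#' feature subsets exhaustively (each subset's latent-component count chosen
#' by cross-validated BIC), and refit the winning subset on the full data.
#' When \code{include_age = TRUE}, age joins the candidate set after the
#' screen - it is always a candidate, never screened out.
#'
#' @param cohort a [cohort_table()].
#' @param outcome \code{"Age"} or a clinical score name present in the
#'   cohort.
#' @param include_age add chronological age as a candidate feature
#'   (incompatible with \code{outcome = "Age"}).
#' @param control an [oculopls_control()].
#' @param seed integer seed driving the cross-validation partitions.
#' @return an object of class \code{oculopls}; see
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals} and \code{plot} methods. Key fields:
#'   \code{selected_features}, \code{n_components}, \code{r2_insample},
#'   \code{r2_adjusted}, \code{r2_cv}, \code{spearman_pred_vs_true},
#'   \code{predictions}.
#' @export
oculopls <- function(cohort, outcome, include_age = FALSE,
                     control = oculopls_control(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (include_age && outcome == "Age")
    stop_oculopls("config_invalid",
                  "include_age is meaningless when modelling Age itself")
  y_all <- .outcome_vector(cohort, outcome)
  keep <- !is.na(y_all)
  n <- sum(keep)
  if (n < 3 * control$n_folds)
    stop_oculopls("too_few_rows", sprintf(
      "outcome '%s' observed for only %d participants", outcome, n))
  if (n < 10 * control$n_folds)
    warning(sprintf(
      "outcome '%s': n = %d is below the recommended 10 x n_folds = %d",
      outcome, n, 10 * control$n_folds))
  y <- y_all[keep]
  ids <- cohort$participants$id[keep]
  X <- cohort$oculo[keep, , drop = FALSE]

  # drop columns unusable after restriction (never observed, or constant)
  n_obs <- colSums(!is.na(X))
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  usable <- n_obs >= 2 & !is.na(sds) & sds > 0
  if (any(!usable))
    message(sprintf("dropping %d unusable parameter column(s) for '%s'",
                    sum(!usable), outcome))
  X <- X[, usable, drop = FALSE]

  ppca <- NULL
  imputation_report <- list(n_cells_imputed = 0L, fraction_missing = 0,
                            rank_used = NA_integer_,
                            cv_reconstruction_error = NA_real_)
  if (anyNA(X)) {
    rk <- min(control$ppca_rank, nrow(X) - 1L, ncol(X) - 1L)
    ppca <- fit_ppca(X, rank = rk, tol = control$ppca_tol,
                     max_iter = control$ppca_max_iter)
    imp <- ppca_impute(ppca, X)
    X <- imp$completed
    imputation_report <- imp$report
  }

  screened <- screen_features(X, y, control$n_top)
  candidates <- screened
  if (length(candidates) > control$subset_cap) {
    message(sprintf(
      "subset search capped at the top %d of %d screened candidates",
      control$subset_cap, length(candidates)))
    candidates <- candidates[seq_len(control$subset_cap)]
  }
  if (include_age) {
    X <- cbind(X, Age = cohort$participants$age[keep])
    candidates <- c(candidates, "Age")
  }

  search <- exhaustive_subset_search(
    X, y, candidates, n_folds = control$n_folds,
    seed = sub_seed(seed, "search", outcome),
    max_candidates_cap = length(candidates),
    max_components_cap = control$max_components)
  model <- search$model
  pred <- model$fitted
  p_model <- length(search$trace$best_subset)
  r2 <- r2_and_adjusted(y, pred, p_model)

  structure(list(
    outcome = outcome,
    group = if (length(unique(cohort$participants$group[keep])) == 1L)
      unique(cohort$participants$group[keep]) else "mixed",
    selected_features = search$trace$best_subset,
    n_components = model$n_components,
    r2_insample = r2$r2,
    r2_adjusted = r2$r2_adjusted,
    r2_cv = search$trace$best_criterion,
    spearman_pred_vs_true = spearman_rho(pred, y),
    predictions = data.frame(id = ids, true = y, predicted = pred,
                             stringsAsFactors = FALSE),
    include_age = include_age,
    seed = as.integer(seed),
    n = n,
    screened = screened,
    trace = search$trace,
    pls = model,
    ppca = ppca,
    imputation_report = imputation_report,
    X = X, y = y,
    control = control
  ), class = "oculopls")
}

#' @export
print.oculopls <- function(x, ...) {
  cat(sprintf("Oculomotor PLS model of %s (%s, n = %d)\n",
              x$outcome, x$group, x$n))
  cat(sprintf("  features: %d selected of %d screened%s; %d latent component(s)\n",
              length(x$selected_features), length(x$screened),
              if (x$include_age) " (+ age candidate)" else "",
              x$n_components))
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f, CV R2 = %.3f\n",
              x$r2_insample, x$r2_adjusted, x$r2_cv))
  s <- x$spearman_pred_vs_true
  cat(sprintf("  Spearman rho(pred, true) = %.4f (p = %.3g)\n", s$rho, s$p_raw))
  invisible(x)
}

#' @export
summary.oculopls <- function(object, ...) {
  print(object)
  cat("  selected features and raw-scale coefficients:\n")
  cf <- object$pls$coefficients
  for (f in names(cf))
    cat(sprintf("    %-12s %+.4f\n", f, cf[[f]]))
  cat(sprintf("  subset search: %s subsets evaluated, criterion %s = %.3f\n",
              format(object$trace$n_subsets_evaluated, big.mark = ","),
              object$trace$criterion_name, object$trace$best_criterion))
  if (object$imputation_report$n_cells_imputed > 0)
    cat(sprintf("  imputation: %d cells (%.1f%%) via rank-%d PPCA\n",
                object$imputation_report$n_cells_imputed,
                100 * object$imputation_report$fraction_missing,
                object$imputation_report$rank_used))
  invisible(object)
}

#' @export
coef.oculopls <- function(object, ...) coef(object$pls)

#' @export
fitted.oculopls <- function(object, ...) object$predictions$predicted

#' @export
residuals.oculopls <- function(object, ...) {
  object$predictions$true - object$predictions$predicted
}

#' Predict an outcome for new participants
#'
#' Accepts either a [cohort_table()] (missing oculomotor cells are imputed
#' with the PPCA model stored in the fit) or a complete numeric matrix
#' containing the selected feature columns.
#'
#' @param object an \code{oculopls} fit.
#' @param newdata cohort or matrix; defaults to the training predictions.
#' @param ... unused.
#' @export
predict.oculopls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions$predicted)
  if (inherits(newdata, "cohort_table")) {
    X <- newdata$oculo
    if (!is.null(object$ppca)) {
      X <- X[, object$ppca$colnames, drop = FALSE]
      if (anyNA(X)) X <- ppca_impute(object$ppca, X)$completed
    }
    if (object$include_age || "Age" %in% object$selected_features)
      X <- cbind(X, Age = newdata$participants$age)
    newdata <- X
  }
  predict(object$pls, newdata[, object$selected_features, drop = FALSE])
}

#' @export
plot.oculopls <- function(x, ...) {
  graphics::plot(x$predictions$true, x$predictions$predicted,
                 xlab = sprintf("observed %s", x$outcome),
                 ylab = sprintf("predicted %s", x$outcome),
                 main = sprintf("%s (%s): R2 = %.2f, adj R2 = %.2f",
                                x$outcome, x$group, x$r2_insample,
                                x$r2_adjusted), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare predicted-age and true-age correlations with clinical scores
#'
#' For each outcome, computes the Spearman correlation of the clinical score
#' with true chronological age and with the oculomotor-predicted age from a
#' fitted age model, on the overlapping participants.
#'
#' @param cohort the cohort the age model was trained on.
#' @param age_model an \code{oculopls} fit with \code{outcome = "Age"}.
#' @param outcomes character vector of score names.
#' @return data frame with \code{outcome, n, rho_true_age,
#'   rho_predicted_age} and the associated raw p-values.
#' @export
predicted_age_analysis <- function(cohort, age_model, outcomes) {
  stopifnot(inherits(age_model, "oculopls"))
  if (age_model$outcome != "Age")
    stop_oculopls("config_invalid", "age_model must have outcome 'Age'")
  idx <- match(age_model$predictions$id, cohort$participants$id)
  if (anyNA(idx))
    stop_oculopls("name_mismatch", "age model ids not found in cohort")
  out <- lapply(outcomes, function(o) {
    score <- .outcome_vector(cohort, o)[idx]
    ok <- !is.na(score)
    rt <- spearman_rho(age_model$predictions$true[ok], score[ok])
    rp <- spearman_rho(age_model$predictions$predicted[ok], score[ok])
    data.frame(outcome = o, n = sum(ok),
               rho_true_age = rt$rho, p_true_age = rt$p_raw,
               rho_predicted_age = rp$rho, p_predicted_age = rp$p_raw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
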