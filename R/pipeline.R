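# Full-analysis orchestration: simulate (or load) -> correlate -> model ->
# compare groups -> report.

.PIPELINE_OUTCOMES <- c("Age", "TMTA", "TMTB", "COWAT", "SDMT", "MoCA",
                        "HVLT", "BAI")

#' Pipeline configuration
#'
#' @param hc,pd cohort sources for the two groups: a [simulation_config()]
#'   (regenerated under the master seed), a [cohort_table()], or a path to a
#'   cohort CSV. \code{pd} may be \code{NULL} for a single-group run.
#' @param outcomes outcomes to model, a subset of
#'   \code{c("Age","TMTA","TMTB","COWAT","SDMT","MoCA","HVLT","BAI")}.
#' @param include_age also fit age-augmented models for the clinical scores.
#' @param control an [oculopls_control()] applied to every model.
#' @param n_replicates permutation replicates (default 1,000).
#' @param alpha two-tailed significance level in (0, 1).
#' @param master_seed master seed; every stage derives its own sub-seed from
#'   it (keyed by stage name, outcome and group), so adding an outcome never
#'   perturbs the others.
#' @param output_dir optional directory for tidy CSV/JSON outputs.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(hc = hc_config(), pd = pd_config(),
                            outcomes = .PIPELINE_OUTCOMES,
                            include_age = FALSE,
                            control = oculopls_control(subset_cap = 10,
                                                       n_top = 10),
                            n_replicates = 1000, alpha = 0.05,
                            master_seed = 1L, output_dir = NULL) {
  bad <- setdiff(outcomes, .PIPELINE_OUTCOMES)
  if (length(bad))
    stop_oculopls("config_invalid", sprintf("unknown outcome(s): %s",
                                            paste(bad, collapse = ", ")))
  if (alpha <= 0 || alpha >= 1)
    stop_oculopls("config_invalid", "alpha must be in (0, 1)")
  structure(list(hc = hc, pd = pd, outcomes = outcomes,
                 include_age = include_age, control = control,
                 n_replicates = n_replicates, alpha = alpha,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

.resolve_cohort <- function(src, master_seed, group) {
  if (is.null(src)) return(NULL)
  if (inherits(src, "cohort_table")) return(src)
  if (inherits(src, "simulation_config")) {
    src$seed <- sub_seed(master_seed, "simulate", group)
    return(generate_cohort(src)$cohort)
  }
  if (is.character(src)) return(read_cohort(src))
  stop_oculopls("config_invalid",
                "cohort source must be a config, cohort_table or path")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_oculopls("stage_failure", sprintf(
      "pipeline stage '%s' failed: %s (re-run with run_full_pipeline(config) after fixing)",
      name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, with deterministic stage-keyed sub-seeding from
#' \code{master_seed}: cohort acquisition, age-score correlations
#' (overall and sex-disaggregated), parameter-outcome correlation tables
#' with FDR control, one PLS model per outcome per group (plus optional
#' age-augmented variants), the predicted-age analysis with its paired
#' permutation tests, and the HC-vs-PD comparison table.
#'
#' @param config a [pipeline_config()].
#' @return a \code{report_bundle} list: \code{cohorts}, \code{age_score},
#'   \code{correlations}, \code{models} (per group, per outcome),
#'   \code{models_age_augmented}, \code{predicted_age}, \code{comparison},
#'   \code{manifest}.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ms <- config$master_seed
  cohorts <- .stage("simulate", list(
    HC = .resolve_cohort(config$hc, ms, "HC"),
    PD = .resolve_cohort(config$pd, ms, "PD")))
  cohorts <- Filter(Negate(is.null), cohorts)

  score_outcomes <- setdiff(config$outcomes, "Age")

  # age-score correlations (overall + per sex) for each cohort
  age_score <- .stage("age_score_correlations", lapply(cohorts, function(ch) {
    sc <- intersect(score_outcomes, names(ch$participants))
    do.call(rbind, lapply(sc, function(o) {
      y <- .outcome_vector(ch, o)
      r_all <- spearman_rho(ch$participants$age, y)
      rows <- data.frame(outcome = o, sex = "all", rho = r_all$rho,
                         n = r_all$n_pairs, p_raw = r_all$p_raw,
                         stringsAsFactors = FALSE)
      for (sx in c("male", "female")) {
        k <- ch$participants$sex == sx
        r <- spearman_rho(ch$participants$age[k], y[k])
        rows <- rbind(rows, data.frame(outcome = o, sex = sx, rho = r$rho,
                                       n = r$n_pairs, p_raw = r$p_raw))
      }
      rows
    }))
  }))

  # parameter-outcome correlation tables (BH within outcome, per group)
  correlations <- .stage("correlation_screen", lapply(cohorts, function(ch) {
    oc <- intersect(config$outcomes,
                    c("Age", intersect(score_outcomes, names(ch$participants))))
    stats::setNames(lapply(oc, function(o)
      correlation_screen(ch, o, alpha = config$alpha)), oc)
  }))

  fit_one <- function(ch, o, grp, augmented = FALSE) {
    suppressWarnings(suppressMessages(
      oculopls(ch, o, include_age = augmented, control = config$control,
               seed = sub_seed(ms, "model", grp, o,
                               if (augmented) "age" else ""))))
  }
  # the chronological-age model is fit in the neurologically intact group
  # only; disease-group models cover the clinical scores
  models <- .stage("models", lapply(names(cohorts), function(grp) {
    ch <- cohorts[[grp]]
    oc <- intersect(config$outcomes,
                    c(if (grp == "HC") "Age",
                      intersect(score_outcomes, names(ch$participants))))
    stats::setNames(lapply(oc, function(o) fit_one(ch, o, grp)), oc)
  }))
  names(models) <- names(cohorts)

  models_aug <- NULL
  if (config$include_age) {
    models_aug <- .stage("age_augmented_models", lapply(names(cohorts),
      function(grp) {
        ch <- cohorts[[grp]]
        oc <- intersect(score_outcomes, names(ch$participants))
        stats::setNames(lapply(oc, function(o) fit_one(ch, o, grp, TRUE)), oc)
      }))
    names(models_aug) <- names(cohorts)
  }

  # predicted-age analysis on the HC cohort
  predicted_age <- NULL
  if ("Age" %in% config$outcomes && "HC" %in% names(cohorts)) {
    predicted_age <- .stage("predicted_age", {
      am <- models$HC$Age
      sc <- intersect(score_outcomes, names(cohorts$HC$participants))
      tab <- predicted_age_analysis(cohorts$HC, am, sc)
      tab$p_perm <- vapply(sc, function(o) {
        idx <- match(am$predictions$id, cohorts$HC$participants$id)
        s <- .outcome_vector(cohorts$HC, o)[idx]
        permute_paired_rho_difference(
          am$predictions$true, am$predictions$predicted, s,
          n_replicates = config$n_replicates,
          seed = sub_seed(ms, "paired_perm", o))$p_two_tailed
      }, numeric(1))
      tab
    })
  }

  bundle <- structure(list(
    cohorts = cohorts,
    age_score = age_score,
    correlations = correlations,
    models = models,
    models_age_augmented = models_aug,
    predicted_age = predicted_age,
    comparison = NULL,
    manifest = list(
      master_seed = ms,
      outcomes = config$outcomes,
      n_replicates = config$n_replicates,
      alpha = config$alpha,
      control = unclass(config$control),
      package_version = as.character(utils::packageVersion("oculopls")),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "report_bundle")

  if (length(cohorts) == 2L)
    bundle$comparison <- .stage("compare_groups",
                                compare_groups_report(bundle, config))

  if (!is.null(config$output_dir)) .write_bundle(bundle, config$output_dir)
  bundle
}

#' HC-vs-PD comparison table
#'
#' For every outcome modelled in both groups: the two adjusted R-squared
#' values with the permutation p for their difference, the two
#' Spearman(predicted, true) correlations with the permutation p for their
#' difference, and the Mann-Whitney U comparison of the raw score
#' distributions with BH-corrected p-values across outcomes. Per-task mean
#' absolute correlations for both groups are attached as
#' \code{attr(, "task_summary")}.
#'
#' @param bundle a \code{report_bundle} with models for both groups.
#' @param config the [pipeline_config()] used (replicates, alpha, seed).
#' @return a data frame, one row per shared outcome.
#' @export
compare_groups_report <- function(bundle, config = pipeline_config()) {
  if (!all(c("HC", "PD") %in% names(bundle$models)))
    stop_oculopls("missing_group", "both group models are required")
  ms <- config$master_seed
  shared <- setdiff(intersect(names(bundle$models$HC),
                              names(bundle$models$PD)), "Age")
  rows <- lapply(shared, function(o) {
    ma <- bundle$models$HC[[o]]; mb <- bundle$models$PD[[o]]
    rho_p <- permute_rho_difference(
      ma$predictions$predicted, ma$predictions$true,
      mb$predictions$predicted, mb$predictions$true,
      n_replicates = config$n_replicates,
      seed = sub_seed(ms, "rho_perm", o))
    r2_p <- permute_r2_difference(ma, mb,
                                  n_replicates = config$n_replicates,
                                  seed = sub_seed(ms, "r2_perm", o))
    mwu <- mann_whitney_u(.outcome_vector(bundle$cohorts$HC, o),
                          .outcome_vector(bundle$cohorts$PD, o))
    data.frame(outcome = o,
               hc_adj_r2 = ma$r2_adjusted, pd_adj_r2 = mb$r2_adjusted,
               p_perm_r2 = r2_p$p_two_tailed,
               hc_rho_pred = ma$spearman_pred_vs_true$rho,
               pd_rho_pred = mb$spearman_pred_vs_true$rho,
               p_perm_rho = rho_p$p_two_tailed,
               mwu_U = mwu$U, mwu_p_raw = mwu$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bh_adjust(out$mwu_p_raw, config$alpha)
  out$mwu_p_adj <- adj$p_adj
  out$mwu_significant <- adj$significant

  task_summary <- do.call(rbind, lapply(names(bundle$cohorts), function(grp) {
    do.call(rbind, lapply(shared, function(o) {
      tab <- bundle$correlations[[grp]][[o]]
      if (is.null(tab)) return(NULL)
      ts <- task_average_abs_rho(tab, bundle$cohorts[[grp]]$catalog)
      ts$group <- grp
      ts
    }))
  }))
  attr(out, "task_summary") <- task_summary
  out
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (grp in names(bundle$age_score))
    utils::write.csv(bundle$age_score[[grp]],
                     file.path(dir, sprintf("age_score_%s.csv", grp)),
                     row.names = FALSE)
  for (grp in names(bundle$correlations))
    for (o in names(bundle$correlations[[grp]]))
      utils::write.csv(bundle$correlations[[grp]][[o]],
                       file.path(dir, sprintf("correlations_%s_%s.csv", grp, o)),
                       row.names = FALSE)
  model_rows <- do.call(rbind, lapply(names(bundle$models), function(grp)
    do.call(rbind, lapply(bundle$models[[grp]], function(m)
      data.frame(group = grp, outcome = m$outcome, n = m$n,
                 n_features = length(m$selected_features),
                 n_components = m$n_components,
                 r2 = m$r2_insample, r2_adjusted = m$r2_adjusted,
                 r2_cv = m$r2_cv,
                 rho_pred_true = m$spearman_pred_vs_true$rho)))))
  utils::write.csv(model_rows, file.path(dir, "model_reports.csv"),
                   row.names = FALSE)
  for (grp in names(bundle$models))
    for (m in bundle$models[[grp]])
      utils::write.csv(m$predictions,
                       file.path(dir, sprintf("predictions_%s_%s.csv",
                                              grp, m$outcome)),
                       row.names = FALSE)
  if (!is.null(bundle$predicted_age))
    utils::write.csv(bundle$predicted_age,
                     file.path(dir, "predicted_age.csv"), row.names = FALSE)
  if (!is.null(bundle$comparison)) {
    utils::write.csv(bundle$comparison, file.path(dir, "group_comparison.csv"),
                     row.names = FALSE)
    ts <- attr(bundle$comparison, "task_summary")
    if (!is.null(ts))
      utils::write.csv(ts, file.path(dir, "task_correlation_summary.csv"),
                       row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
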