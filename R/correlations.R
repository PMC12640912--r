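# Rank correlations, FDR control, per-task summaries, group comparisons.

# all permutations of 1..n as a matrix (n! x n); used for exact small-n p
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with average ranks
#'
#' Computes Spearman's rho as the Pearson correlation of the
#' average-rank-transformed vectors, after pairwise deletion of incomplete
#' pairs. The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom for
#' \eqn{n \ge 10}, and exact enumeration over all \eqn{n!} rank permutations
#' below that. A zero-variance rank vector yields an explicit undefined
#' result (\code{defined = FALSE}), never a silent 0.
#'
#' @param x,y numeric vectors of equal length; \code{NA}s deleted pairwise.
#' @return a \code{correlation_result} list: \code{rho}, \code{n_pairs},
#'   \code{p_raw}, \code{p_adj} (unset), \code{significant} (unset),
#'   \code{defined}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_oculopls("length_mismatch", "x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop_oculopls("too_few_pairs",
                  sprintf("need >= 3 complete pairs, got %d", n))
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(structure(list(rho = NA_real_, n_pairs = n, p_raw = NA_real_,
                          p_adj = NA_real_, significant = NA,
                          defined = FALSE),
                     class = "correlation_result"))
  }
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  } else {
    perms <- .all_perms(n)
    ryp <- matrix(ry[perms], nrow(perms), n)
    rhos <- as.numeric((ryp %*% (rx - mean(rx)))) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  structure(list(rho = rho, n_pairs = n, p_raw = p, p_adj = NA_real_,
                 significant = NA, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined)
    cat(sprintf("Spearman rho: undefined (zero rank variance), n = %d\n",
                x$n_pairs))
  else
    cat(sprintf("Spearman rho = %.4f, n = %d, p = %.4g%s\n", x$rho, x$n_pairs,
                x$p_raw,
                if (!is.na(x$p_adj)) sprintf(", p_adj = %.4g", x$p_adj) else ""))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: sorted ascending,
#' \eqn{p^{adj}_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and mapped
#' back to input order. Delegates to \code{stats::p.adjust(method = "BH")};
#' significance flags are \code{p_adj <= alpha}.
#'
#' @param p numeric vector of raw p-values in [0, 1] (\code{NA} allowed and
#'   propagated).
#' @param alpha FDR level (default 0.05).
#' @return list with \code{p_adj} and logical \code{significant}.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0)
    return(list(p_adj = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_oculopls("bad_pvalue", "p-values must be in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = !is.na(p_adj) & p_adj <= alpha)
}

# resolve an outcome name ("Age" or a score column) to a numeric vector
.outcome_vector <- function(cohort, outcome) {
  if (outcome == "Age") return(cohort$participants$age)
  if (!outcome %in% names(cohort$participants))
    stop_oculopls("unknown_outcome",
                  sprintf("outcome '%s' absent from cohort", outcome))
  cohort$participants[[outcome]]
}

#' Correlate every oculomotor parameter with an outcome
#'
#' One Spearman correlation per catalog parameter against the outcome
#' (\code{"Age"} or a clinical score), with pairwise deletion per parameter
#' (so each row can have its own n), and Benjamini-Hochberg adjustment across
#' the parameter family within this one outcome. Undefined correlations
#' (zero rank variance or fewer than 3 pairs) are kept as \code{NA} rows and
#' excluded from the BH family.
#'
#' @param cohort a [cohort_table()].
#' @param outcome outcome name.
#' @param disaggregate_by_sex if \code{TRUE}, return a list with one table
#'   per sex.
#' @param alpha FDR level.
#' @return a \code{correlation_table} data frame with columns
#'   \code{parameter, task, outcome, rho, n, p_raw, p_adj, significant}; or a
#'   named list of two such tables when disaggregated.
#' @export
correlation_screen <- function(cohort, outcome, disaggregate_by_sex = FALSE,
                               alpha = 0.05) {
  if (disaggregate_by_sex) {
    out <- lapply(c(male = "male", female = "female"), function(sx) {
      keep <- cohort$participants$sex == sx
      sub <- cohort
      sub$participants <- sub$participants[keep, , drop = FALSE]
      sub$oculo <- sub$oculo[keep, , drop = FALSE]
      sub$mask <- sub$mask[keep, , drop = FALSE]
      correlation_screen(sub, outcome, FALSE, alpha)
    })
    return(out)
  }
  y <- .outcome_vector(cohort, outcome)
  if (sum(!is.na(y)) < 3)
    stop_oculopls("too_few_pairs",
                  sprintf("outcome '%s' observed for < 3 participants", outcome))
  res <- lapply(seq_len(ncol(cohort$oculo)), function(j) {
    x <- cohort$oculo[, j]
    n_ok <- sum(!is.na(x) & !is.na(y))
    if (n_ok < 3)
      return(list(rho = NA_real_, n_pairs = n_ok, p_raw = NA_real_,
                  defined = FALSE))
    spearman_rho(x, y)
  })
  tab <- data.frame(
    parameter = colnames(cohort$oculo),
    task = cohort$catalog$task[match(colnames(cohort$oculo),
                                     cohort$catalog$parameter)],
    outcome = outcome,
    rho = vapply(res, function(r) r$rho, numeric(1)),
    n = vapply(res, function(r) as.integer(r$n_pairs), integer(1)),
    p_raw = vapply(res, function(r) r$p_raw, numeric(1)),
    stringsAsFactors = FALSE)
  adj <- bh_adjust(tab$p_raw, alpha)
  tab$p_adj <- adj$p_adj
  tab$significant <- ifelse(is.na(tab$p_raw), NA, adj$significant)
  attr(tab, "alpha") <- alpha
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

#' Mean absolute correlation per oculomotor task
#'
#' Summarises a correlation table into one row per task: the mean of
#' \code{|rho|} over that task's parameters, with undefined correlations
#' excluded and counted. Tasks without any parameter in the table are absent
#' from the summary (with a warning).
#'
#' @param table a \code{correlation_table} from [correlation_screen()].
#' @param catalog the matching [parameter_catalog()].
#' @return data frame with \code{task, outcome, mean_abs_rho, n_parameters,
#'   n_undefined}.
#' @export
task_average_abs_rho <- function(table, catalog) {
  if (!all(table$parameter %in% catalog$parameter))
    stop_oculopls("unknown_parameter",
                  "correlation table contains parameters absent from catalog")
  task <- catalog$task[match(table$parameter, catalog$parameter)]
  present <- intersect(unique(catalog$task), unique(task))
  absent <- setdiff(unique(catalog$task), present)
  if (length(absent))
    warning(sprintf("task(s) with zero parameters omitted: %s",
                    paste(absent, collapse = ", ")))
  out <- do.call(rbind, lapply(present, function(tk) {
    rows <- table[task == tk, , drop = FALSE]
    ok <- !is.na(rows$rho)
    data.frame(task = tk,
               outcome = rows$outcome[1],
               mean_abs_rho = if (any(ok)) mean(abs(rows$rho[ok])) else NA_real_,
               n_parameters = sum(ok),
               n_undefined = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The U statistic uses
#' average ranks for ties. The p-value is exact (full enumeration of the
#' rank-sum distribution) when there are no ties and
#' \eqn{\binom{n_a+n_b}{n_a}} is at most \code{exact_threshold}; otherwise
#' the normal approximation with tie correction and continuity correction is
#' used. Delegates to \code{stats::wilcox.test}.
#'
#' @param a,b numeric vectors (non-empty; \code{NA}s dropped).
#' @param exact_threshold enumeration-size cap for the exact path.
#' @return list with \code{U} (for group \code{a}), \code{p_two_tailed},
#'   \code{n_a}, \code{n_b}, \code{method}.
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 1e6) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop_oculopls("empty_group", "both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && choose(length(a) + length(b), length(a)) <= exact_threshold
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_two_tailed = wt$p.value,
       n_a = length(a), n_b = length(b),
       method = if (exact) "exact" else "normal approximation")
}
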