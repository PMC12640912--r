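# Cohort container: participants x (demographics + scores + oculomotor block)

#' Construct a cohort table
#'
#' The central data container: an ordered participant table (id, group, sex,
#' age and the clinical outcome columns), an oculomotor parameter matrix with
#' \code{NA} for missing cells, the parameter catalog, and an explicit
#' observation mask (\code{TRUE} = observed).
#'
#' @param participants data frame with columns \code{id}, \code{group}
#'   (\code{"HC"}/\code{"PD"}), \code{sex} (\code{"male"}/\code{"female"}),
#'   \code{age}, and any subset of [OUTCOME_NAMES].
#' @param oculo numeric matrix, one row per participant, one column per
#'   catalog parameter; \code{NA} marks missing cells.
#' @param catalog a [parameter_catalog()]; defaults to inference from
#'   \code{colnames(oculo)}.
#' @return an object of class \code{cohort_table}.
#' @export
cohort_table <- function(participants, oculo, catalog = NULL) {
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  req <- c("id", "group", "sex", "age")
  miss <- setdiff(req, names(participants))
  if (length(miss))
    stop_oculopls("schema", sprintf("participants lack column(s): %s",
                                    paste(miss, collapse = ", ")))
  oculo <- as.matrix(oculo)
  storage.mode(oculo) <- "double"
  if (is.null(catalog)) catalog <- infer_catalog(colnames(oculo))
  if (nrow(oculo) != nrow(participants))
    stop_oculopls("schema", "oculo row count differs from participant count")
  if (!identical(sort(colnames(oculo)), sort(catalog$parameter)))
    stop_oculopls("unknown_parameter",
                  "oculo columns do not match the catalog parameter set")
  oculo <- oculo[, catalog$parameter, drop = FALSE]  # catalog order
  rownames(oculo) <- participants$id
  structure(list(
    participants = participants,
    oculo = oculo,
    catalog = catalog,
    mask = !is.na(oculo)
  ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  sc <- intersect(OUTCOME_NAMES, names(x$participants))
  cat(sprintf("<cohort_table> %d participants, %d oculomotor parameters\n",
              nrow(x$participants), ncol(x$oculo)))
  if (nrow(x$participants)) {
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s=%d", names(table(x$participants$group)),
                              table(x$participants$group)), collapse = ", ")))
    cat(sprintf("  oculomotor cells observed: %.1f%%\n", 100 * mean(x$mask)))
  }
  cat(sprintf("  outcomes: %s\n", paste(sc, collapse = ", ")))
  invisible(x)
}

#' Number of participants
#' @param cohort a \code{cohort_table}.
#' @export
n_participants <- function(cohort) nrow(cohort$participants)

#' Per-outcome available sample sizes
#'
#' @param cohort a \code{cohort_table}.
#' @return named integer vector: non-missing count per outcome column present.
#' @export
outcome_n <- function(cohort) {
  sc <- intersect(OUTCOME_NAMES, names(cohort$participants))
  vapply(sc, function(s) sum(!is.na(cohort$participants[[s]])), integer(1))
}

# CSV I/O -------------------------------------------------------------------

.MISSING_TOKENS <- c("", "na", "nan")

#' Read a cohort CSV
#'
#' Expects a header with \code{id,group,sex,age}, any subset of the outcome
#' columns ([OUTCOME_NAMES]), and oculomotor parameter columns. Empty cells
#' (and \code{NA}/\code{NaN}, case-insensitive) become missing values in the
#' oculomotor mask. Without a catalog, tasks are inferred from the column
#' prefix convention; with a catalog, every parameter column must be
#' registered in it (unknown numeric columns are an error, not silently
#' treated as parameters).
#'
#' @param path CSV file path.
#' @param catalog optional [parameter_catalog()].
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, catalog = NULL) {
  if (!file.exists(path))
    stop_oculopls("unreadable_file", sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  req <- c("id", "group", "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_oculopls("schema", sprintf("cohort CSV lacks column(s): %s",
                                    paste(miss, collapse = ", ")))
  score_cols <- intersect(OUTCOME_NAMES, names(df))
  param_cols <- setdiff(names(df), c(req, score_cols))
  if (!is.null(catalog)) {
    unknown <- setdiff(param_cols, catalog$parameter)
    if (length(unknown))
      stop_oculopls("unknown_parameter", sprintf(
        "column(s) not in catalog and not a known outcome: %s",
        paste(unknown, collapse = ", ")))
    param_cols <- intersect(catalog$parameter, param_cols)
    catalog <- parameter_catalog(
      catalog$parameter[catalog$parameter %in% param_cols],
      catalog$task[catalog$parameter %in% param_cols])
  }

  if (anyDuplicated(df$id))
    stop_oculopls("duplicate_id", sprintf(
      "duplicate participant id(s): %s",
      paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  bad_grp <- setdiff(unique(df$group), c("HC", "PD"))
  if (nrow(df) && length(bad_grp))
    stop_oculopls("bad_token", sprintf("unknown group token(s): %s",
                                       paste(bad_grp, collapse = ", ")))
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (nrow(df) && length(bad_sex))
    stop_oculopls("bad_token", sprintf("unknown sex token(s): %s",
                                       paste(bad_sex, collapse = ", ")))

  to_num <- function(x, col) {
    x <- trimws(x)
    x[tolower(x) %in% .MISSING_TOKENS] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad))
      stop_oculopls("non_numeric", sprintf(
        "non-numeric value '%s' in column %s", x[which(bad)[1L]], col))
    out
  }

  participants <- data.frame(id = df$id, group = df$group, sex = df$sex,
                             age = to_num(df$age, "age"),
                             stringsAsFactors = FALSE)
  for (s in score_cols) participants[[s]] <- to_num(df[[s]], s)

  oculo <- matrix(NA_real_, nrow(df), length(param_cols),
                  dimnames = list(df$id, param_cols))
  for (p in param_cols) oculo[, p] <- to_num(df[[p]], p)
  cohort_table(participants, oculo, catalog)
}

#' Write a cohort CSV
#'
#' Stable column order: \code{id,group,sex,age}, outcomes (in [OUTCOME_NAMES]
#' order), then oculomotor parameters in catalog order. Missing values are
#' written as empty cells. UTF-8, comma-delimited, '.' decimal.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  sc <- intersect(OUTCOME_NAMES, names(cohort$participants))
  out <- cbind(cohort$participants[, c("id", "group", "sex", "age", sc),
                                   drop = FALSE],
               as.data.frame(cohort$oculo, optional = TRUE))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_oculopls("unwritable_path",
                  sprintf("cannot write cohort CSV to %s: %s",
                          path, conditionMessage(ok)))
  invisible(path)
}

# Validation ----------------------------------------------------------------

#' Validate a cohort against the domain invariants
#'
#' Checks id uniqueness, positive age, legal score ranges (MoCA 0-30,
#' SDMT 0-110, BAI 0-63, TMTA/TMTB strictly positive seconds, HVLT/COWAT
#' non-negative), group/sex tokens and mask consistency. Issues are returned
#' as data, never raised: the result is a character vector, empty iff all
#' invariants hold, with each issue naming the participant, field and rule.
#'
#' @param cohort a [cohort_table()].
#' @return character vector of issue descriptions (length 0 when valid).
#' @export
validate_cohort <- function(cohort) {
  issues <- character(0)
  pp <- cohort$participants
  dup <- unique(pp$id[duplicated(pp$id)])
  for (d in dup)
    issues <- c(issues, sprintf("id %s: duplicate participant id", d))
  bad_grp <- which(!pp$group %in% c("HC", "PD"))
  for (i in bad_grp)
    issues <- c(issues, sprintf("id %s: group '%s' not in {HC, PD}",
                                pp$id[i], pp$group[i]))
  bad_sex <- which(!pp$sex %in% c("male", "female"))
  for (i in bad_sex)
    issues <- c(issues, sprintf("id %s: sex '%s' not in {male, female}",
                                pp$id[i], pp$sex[i]))
  bad_age <- which(!is.na(pp$age) & pp$age <= 0)
  for (i in bad_age)
    issues <- c(issues, sprintf("id %s: age %g violates age > 0",
                                pp$id[i], pp$age[i]))
  for (s in intersect(OUTCOME_NAMES, names(pp))) {
    rng <- .SCORE_RANGES[[s]]
    v <- pp[[s]]
    lo_ok <- if (s %in% .STRICT_POSITIVE) v > rng[1] else v >= rng[1]
    hi_ok <- if (is.na(rng[2])) TRUE else v <= rng[2]
    bad <- which(!is.na(v) & !(lo_ok & hi_ok))
    rule <- if (is.na(rng[2])) {
      if (s %in% .STRICT_POSITIVE) sprintf("%s > 0", s) else sprintf("%s >= 0", s)
    } else sprintf("%s in [%g, %g]", s, rng[1], rng[2])
    for (i in bad)
      issues <- c(issues, sprintf("id %s: %s = %g violates range %s",
                                  pp$id[i], s, v[i], rule))
  }
  if (!identical(dim(cohort$mask), dim(cohort$oculo)))
    issues <- c(issues, "mask: shape differs from oculomotor matrix")
  else if (!identical(unname(cohort$mask), unname(!is.na(cohort$oculo))))
    issues <- c(issues, "mask: inconsistent with missing oculomotor values")
  issues
}
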