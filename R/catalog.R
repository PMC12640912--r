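#' @useDynLib oculopls, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed domain vocabulary ---------------------------------------------------

#' Oculomotor task labels
#'
#' The five eye-tracking tasks from which oculomotor parameters are derived.
#' @export
OCULO_TASKS <- c("fixation", "pro_saccade", "anti_saccade",
                 "smooth_pursuit", "okn")

.TASK_PREFIX <- c(fixation = "FIX", pro_saccade = "PS", anti_saccade = "AS",
                  smooth_pursuit = "SP", okn = "OKN")

#' Clinical outcome columns
#'
#' The fixed set of clinical/cognitive outcome measures a cohort may carry:
#' global cognition (MoCA), processing speed (SDMT), attention and
#' set-shifting (TMTA/TMTB, seconds), verbal memory (HVLT), verbal fluency
#' (COWAT) and anxiety (BAI).
#' @export
OUTCOME_NAMES <- c("MoCA", "SDMT", "TMTA", "TMTB", "HVLT", "COWAT", "BAI")

# Legal score ranges; NA bound = unbounded above.
.SCORE_RANGES <- list(
  MoCA  = c(0, 30),
  SDMT  = c(0, 110),
  BAI   = c(0, 63),
  TMTA  = c(0, NA),   # strictly positive seconds, checked as > 0
  TMTB  = c(0, NA),
  HVLT  = c(0, NA),   # >= 0
  COWAT = c(0, NA)
)
.STRICT_POSITIVE <- c("TMTA", "TMTB")

# classed, message-bearing errors so callers can discriminate failure modes
stop_oculopls <- function(subclass, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("oculopls_", subclass), "oculopls_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Parameter catalog ---------------------------------------------------------

#' Build a parameter catalog
#'
#' A catalog registers every oculomotor parameter name together with the task
#' it was measured in. It is a plain data frame with columns \code{parameter}
#' and \code{task} and class \code{"parameter_catalog"}.
#'
#' @param parameter character vector of unique parameter names.
#' @param task character vector of task labels, one of [OCULO_TASKS].
#' @return a \code{parameter_catalog} data frame.
#' @export
parameter_catalog <- function(parameter, task) {
  parameter <- as.character(parameter)
  task <- as.character(task)
  if (length(parameter) != length(task))
    stop_oculopls("catalog_invalid", "parameter and task lengths differ")
  if (anyDuplicated(parameter))
    stop_oculopls("catalog_invalid", sprintf(
      "duplicate parameter names in catalog: %s",
      paste(unique(parameter[duplicated(parameter)]), collapse = ", ")))
  bad <- setdiff(unique(task), OCULO_TASKS)
  if (length(bad))
    stop_oculopls("catalog_invalid",
                  sprintf("unknown task label(s): %s", paste(bad, collapse = ", ")))
  structure(data.frame(parameter = parameter, task = task,
                       stringsAsFactors = FALSE),
            class = c("parameter_catalog", "data.frame"))
}

#' Default 199-parameter catalog
#'
#' The default registry of 199 oculomotor parameters spanning the five tasks
#' (30 fixation, 60 pro-saccade, 45 anti-saccade, 38 smooth-pursuit, 26 OKN).
#' Parameter names follow the task-prefix convention
#' (\code{FIX_}, \code{PS_}, \code{AS_}, \code{SP_}, \code{OKN_}).
#'
#' @return a \code{parameter_catalog} with 199 rows.
#' @export
default_catalog <- function() {
  counts <- c(fixation = 30, pro_saccade = 60, anti_saccade = 45,
              smooth_pursuit = 38, okn = 26)
  task <- rep(names(counts), counts)
  parameter <- unlist(lapply(names(counts), function(tk)
    sprintf("%s_p%02d", .TASK_PREFIX[[tk]], seq_len(counts[[tk]]))),
    use.names = FALSE)
  parameter_catalog(parameter, task)
}

#' Infer a catalog from parameter names
#'
#' Maps each column name to a task via its prefix (\code{FIX_}, \code{PS_},
#' \code{AS_}, \code{SP_}, \code{OKN_}).
#'
#' @param names character vector of parameter column names.
#' @return a \code{parameter_catalog}.
#' @export
infer_catalog <- function(names) {
  pref <- toupper(sub("_.*$", "", names))
  task_of <- names(.TASK_PREFIX)[match(pref, .TASK_PREFIX)]
  if (anyNA(task_of))
    stop_oculopls("unknown_parameter", sprintf(
      "cannot infer task for column(s): %s (no FIX_/PS_/AS_/SP_/OKN_ prefix)",
      paste(names[is.na(task_of)], collapse = ", ")))
  parameter_catalog(names, task_of)
}

#' Read / write a catalog CSV
#'
#' Sidecar catalog files are two-column CSVs (\code{parameter,task}).
#'
#' @param path file path.
#' @return \code{read_catalog}: a \code{parameter_catalog}.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path))
    stop_oculopls("unreadable_file", sprintf("catalog file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("parameter", "task") %in% names(df)))
    stop_oculopls("catalog_invalid",
                  "catalog CSV must have columns 'parameter' and 'task'")
  parameter_catalog(df$parameter, df$task)
}

#' @rdname read_catalog
#' @param catalog a \code{parameter_catalog}.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog)[, c("parameter", "task")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
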