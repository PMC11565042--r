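#' Trial-level score tables
#'
#' A `trial_table` is the universal input of the package: one row per
#' observed trial, keyed by participant, condition and trial index, with a
#' single finite score per trial (an ERP time-window mean amplitude in
#' microvolts, or a per-epoch spectral power value). Trial counts may differ
#' across participants and conditions (ragged tables are legal); a missing
#' trial is simply absent, never stored as a sentinel.
#'
#' @param participant character vector of participant identifiers.
#' @param condition character vector of condition labels.
#' @param trial integer vector of positive trial indices, ordinal within
#'   each participant-by-condition cell.
#' @param value numeric vector of finite trial scores.
#'
#' @return An object of class `trial_table`: a data frame with columns
#'   `participant`, `condition`, `trial`, `value`, sorted by participant,
#'   condition, trial.
#' @examples
#' tt <- trial_table(
#'   participant = c("P1", "P1", "P2"),
#'   condition   = c("A", "A", "A"),
#'   trial       = c(1L, 2L, 1L),
#'   value       = c(0.5, 1.5, 2.0)
#' )
#' trials(tt, "P1", "A")
#' @export
trial_table <- function(participant, condition, trial, value) {
  n <- length(value)
  if (length(participant) != n || length(condition) != n || length(trial) != n)
    stop("participant, condition, trial and value must have equal lengths")
  tab <- data.frame(
    participant = as.character(participant),
    condition = as.character(condition),
    trial = as.integer(trial),
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$participant, tab$condition, tab$trial), , drop = FALSE]
  rownames(tab) <- NULL
  out <- structure(tab, class = c("trial_table", "data.frame"))
  issues <- validate_trial_table(out)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("invalid trial table: ", paste(errs$message, collapse = "; "))
  out
}

#' @export
print.trial_table <- function(x, ...) {
  cells <- unique(x[, c("participant", "condition")])
  cat(sprintf(
    "Trial table: %d trials, %d participants, %d condition(s), %d cells\n",
    nrow(x), length(unique(x$participant)),
    length(unique(x$condition)), nrow(cells)
  ))
  cnt <- table(paste(x$participant, x$condition, sep = "\r"))
  cat(sprintf("Trials per cell: %d-%d (median %g)\n",
              min(cnt), max(cnt), stats::median(as.numeric(cnt))))
  if (nrow(x) > 0L) {
    cat("First rows:\n")
    print(utils::head(as.data.frame(x), 6L))
  }
  invisible(x)
}

#' Extract one participant-by-condition cell
#'
#' Returns the trial values of one participant under one condition in
#' ascending trial-index order.
#'
#' @param table a [trial_table()].
#' @param participant participant identifier.
#' @param condition condition label.
#' @return Numeric vector of trial values (possibly empty).
#' @export
trials <- function(table, participant, condition) {
  stopifnot(inherits(table, "trial_table"))
  sel <- table$participant == participant & table$condition == condition
  v <- table$value[sel]
  v[order(table$trial[sel])]
}

#' List of per-participant trial vectors for one condition
#'
#' @param table a [trial_table()].
#' @param condition condition label.
#' @return Named list (by participant) of numeric trial-value vectors in
#'   trial-index order.
#' @keywords internal
condition_cells <- function(table, condition) {
  sel <- table$condition == condition
  if (!any(sel)) stop("condition not present in table: ", condition)
  sub <- table[sel, , drop = FALSE]
  sub <- sub[order(sub$participant, sub$trial), , drop = FALSE]
  split(sub$value, sub$participant)
}

#' Conditions present in a trial table
#' @param table a [trial_table()].
#' @return Character vector of condition labels.
#' @export
conditions <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  sort(unique(table$condition))
}

#' Validate a trial table
#'
#' Checks the trial-table invariants and returns a report instead of
#' raising: duplicate (participant, condition, trial) keys and non-finite
#' values are errors; participants whose trial count in some condition falls
#' below the smallest requested subsample size are warnings, so downstream
#' exclusions are announced before any resampling runs.
#'
#' @param table a `trial_table` (or a plain data frame with its columns).
#' @param min_trials optional positive integer: smallest subsample size the
#'   caller intends to request; cells with fewer trials draw a warning.
#' @return A data frame of class `validation_report` with columns
#'   `severity` (`"error"`/`"warning"`), `code`, `message`, `participant`,
#'   `condition`, `trial`. Zero rows means the table is clean.
#' @examples
#' tt <- trial_table(rep("P1", 3), rep("A", 3), 1:3, c(1, 2, 3))
#' validate_trial_table(tt)                 # no issues
#' validate_trial_table(tt, min_trials = 5) # warning: only 3 trials
#' @export
validate_trial_table <- function(table, min_trials = NULL) {
  issues <- list()
  add <- function(severity, code, message, participant = NA, condition = NA,
                  trial = NA) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      participant = as.character(participant),
      condition = as.character(condition),
      trial = as.integer(trial), stringsAsFactors = FALSE
    )
  }

  key <- paste(table$participant, table$condition, table$trial, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) {
    add("error", "duplicate_key",
        sprintf("duplicate trial key (%s, %s, %d)",
                table$participant[i], table$condition[i], table$trial[i]),
        table$participant[i], table$condition[i], table$trial[i])
  }
  bad <- which(!is.finite(table$value))
  for (i in bad) {
    add("error", "nonfinite_value",
        sprintf("non-finite value at (%s, %s, %d)",
                table$participant[i], table$condition[i], table$trial[i]),
        table$participant[i], table$condition[i], table$trial[i])
  }
  badidx <- which(is.na(table$trial) | table$trial < 1L)
  for (i in badidx) {
    add("error", "bad_trial_index",
        sprintf("trial index must be a positive integer at (%s, %s)",
                table$participant[i], table$condition[i]),
        table$participant[i], table$condition[i], table$trial[i])
  }

  if (!is.null(min_trials)) {
    cnt <- stats::aggregate(value ~ participant + condition, data = table,
                            FUN = length)
    low <- cnt[cnt$value < min_trials, , drop = FALSE]
    for (i in seq_len(nrow(low))) {
      add("warning", "below_min_subsample",
          sprintf(
            "participant %s has %d trial(s) in condition %s, below the smallest requested subsample size %d; it will be excluded there",
            low$participant[i], low$value[i], low$condition[i],
            as.integer(min_trials)),
          low$participant[i], low$condition[i])
    }
  }

  out <- if (length(issues)) do.call(rbind, issues) else data.frame(
    severity = character(), code = character(), message = character(),
    participant = character(), condition = character(), trial = integer(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Validation report: no issues\n")
  } else {
    cat(sprintf("Validation report: %d error(s), %d warning(s)\n",
                sum(x$severity == "error"), sum(x$severity == "warning")))
    print(as.data.frame(x))
  }
  invisible(x)
}
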