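#' Read a trial-level score table from delimited text
#'
#' The canonical interchange is a long CSV with one row per trial and
#' columns `participant,condition,trial,value`. A wide layout is accepted as
#' a convenience: one row per participant-by-condition pair, whose first two
#' columns identify the pair and whose remaining columns hold trial scores
#' left-to-right as trial index 1..k. Blank wide cells mean "trial absent"
#' (never zero — zero is a legal amplitude) and their index positions are
#' preserved.
#'
#' @param path path to a delimited text file with a header row (UTF-8).
#' @param layout `"long"` (default) or `"wide"`.
#' @param delimiter field delimiter, default `","`.
#' @param columns optional named character vector remapping file column
#'   names onto the canonical names, e.g.
#'   `c(participant = "subj", condition = "cond", trial = "epoch", value = "uV")`.
#'   For wide layout only `participant` and `condition` apply.
#' @return A [trial_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant,condition,trial,value",
#'              "P1,A,1,0.5", "P1,A,2,1.5", "P2,A,1,2.0"), f)
#' read_trial_table(f)
#' @export
read_trial_table <- function(path, layout = c("long", "wide"),
                             delimiter = ",", columns = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (layout == "long") {
    names(raw) <- remap_columns(names(raw), columns,
                                c("participant", "condition", "trial", "value"))
    need <- c("participant", "condition", "trial", "value")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    val <- parse_numeric(raw$value, path, "value")
    tri <- parse_numeric(raw$trial, path, "trial")
    if (any(tri != floor(tri) | tri < 1))
      stop("trial indices must be positive integers in ", path)
    key <- paste(raw$participant, raw$condition, tri, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1L]
      stop(sprintf("duplicate (participant, condition, trial) = (%s, %s, %s)",
                   raw$participant[i], raw$condition[i], raw$trial[i]))
    }
    trial_table(raw$participant, raw$condition, as.integer(tri), val)
  } else {
    names(raw)[1:2] <- remap_columns(names(raw)[1:2], columns,
                                     c("participant", "condition"))
    if (ncol(raw) < 3L)
      stop("wide layout needs at least one trial column after participant and condition")
    if (!identical(names(raw)[1:2], c("participant", "condition")))
      stop("missing required column(s): ",
           paste(setdiff(c("participant", "condition"), names(raw)[1:2]),
                 collapse = ", "))
    k <- ncol(raw) - 2L
    recs <- vector("list", nrow(raw))
    for (i in seq_len(nrow(raw))) {
      cells <- trimws(as.character(raw[i, -(1:2)]))
      present <- which(!is.na(cells) & nzchar(cells))
      if (!length(present)) next
      recs[[i]] <- data.frame(
        participant = raw$participant[i], condition = raw$condition[i],
        trial = present,
        value = parse_numeric(cells[present], path,
                              sprintf("row %d", i + 1L)),
        stringsAsFactors = FALSE
      )
    }
    recs <- do.call(rbind, recs)
    if (is.null(recs)) stop("no trial values found in ", path)
    if (anyDuplicated(paste(raw$participant, raw$condition, sep = "\r"))) {
      stop("duplicate (participant, condition) row in wide file ", path)
    }
    trial_table(recs$participant, recs$condition, recs$trial, recs$value)
  }
}

remap_columns <- function(have, map, canonical) {
  if (is.null(map)) return(have)
  for (canon in intersect(names(map), canonical)) {
    hit <- which(have == map[[canon]])
    if (length(hit) == 1L) have[hit] <- canon
  }
  have
}

parse_numeric <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric %s cell ('%s') in %s (entry %d)",
                 what, x[bad[1L]], path, bad[1L]))
  v
}

#' Write a long-format trial table to CSV
#'
#' Inverse of [read_trial_table()] for the long layout; writing then reading
#' reproduces the identical record set.
#'
#' @param table a [trial_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  lines <- c("participant,condition,trial,value",
             sprintf("%s,%s,%d,%s", table$participant, table$condition,
                     table$trial, format_num(table$value)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write metric result rows to CSV
#'
#' Serializes reliability, effect-size or SME summaries in a stable schema:
#' header `metric,condition,contrast,scope,n_trials,n_iterations,
#' n_participants,estimate,ci_low,ci_high`; `scope` is `overall` or
#' `subsample` and `n_trials` is empty on overall rows. Numbers carry at
#' least six significant digits and the output is byte-identical for
#' identical inputs.
#'
#' @param results a data frame of result rows (see [as.data.frame.qc_curve()])
#'   or an object with such an `as.data.frame` method. All rows must share
#'   one metric kind.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  cols <- c("metric", "condition", "contrast", "scope", "n_trials",
            "n_iterations", "n_participants", "estimate", "ci_low", "ci_high")
  for (m in setdiff(cols, names(df))) df[[m]] <- NA
  if (nrow(df) > 0L && length(unique(df$metric)) > 1L)
    stop("result rows must share one metric kind")
  df <- df[, cols, drop = FALSE]
  num <- function(x) ifelse(is.na(x), "", format_num(x))
  chr <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- paste(cols, collapse = ",")
  if (nrow(df) > 0L) {
    lines <- c(lines, sprintf(
      "%s,%s,%s,%s,%s,%s,%s,%s,%s,%s",
      chr(df$metric), chr(df$condition), chr(df$contrast), chr(df$scope),
      ifelse(is.na(df$n_trials), "", sprintf("%d", as.integer(df$n_trials))),
      ifelse(is.na(df$n_iterations), "",
             sprintf("%d", as.integer(df$n_iterations))),
      ifelse(is.na(df$n_participants), "",
             sprintf("%d", as.integer(df$n_participants))),
      num(df$estimate), num(df$ci_low), num(df$ci_high)
    ))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# 8 significant digits, locale-independent, no scientific-notation drift
format_num <- function(x) {
  out <- formatC(x, digits = 8L, format = "g", flag = "")
  trimws(out)
}
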