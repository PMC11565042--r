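#' Analytic standardized measurement error
#'
#' The standard error of one participant's trial-level score: the sample
#' (k-1) standard deviation across that participant's trials divided by the
#' square root of the number of trials N. Scale-equivariant
#' (`asme(c * x) = |c| * asme(x)`) and translation-invariant; zero exactly
#' when all trials are identical.
#'
#' @param values numeric vector of one participant's trial values
#'   (length >= 2).
#' @return Non-negative scalar.
#' @examples
#' asme(1:5)      # sqrt(2.5)/sqrt(5) = 0.7071068
#' asme(c(0, 2))  # 1
#' @export
asme <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 trials for aSME")
  stats::sd(values) / sqrt(n)
}

#' Bootstrapped standardized measurement error
#'
#' Estimates the same standard error by bootstrapping: `iterations`
#' resamples of size N are drawn with replacement from the participant's
#' trials, the mean of each resample is recorded, and the bSME is the
#' standard deviation (k-1 over the draws) of that sampling distribution
#' of the mean.
#'
#' Because the bootstrap resamples from the empirical distribution, its
#' large-B limit is `asme(values) * sqrt((N - 1) / N)` — the population-
#' style SD of the data — not [asme()] itself; the factor is a property of
#' the estimator, left uncorrected so the two can cross-validate each
#' other.
#'
#' @param values numeric vector of trial values (length >= 2).
#' @param iterations number of bootstrap resamples B (>= 2).
#' @return Non-negative scalar.
#' @examples
#' set.seed(1)
#' bsme(c(0, 2), iterations = 10000)  # near sqrt(0.5) = 0.7071
#' @export
bsme <- function(values, iterations = 1000L) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 trials for bSME")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 2L) stop("iterations must be >= 2")
  draws <- matrix(values[sample.int(n, n * iterations, replace = TRUE)],
                  nrow = n)
  stats::sd(colMeans(draws))
}

#' Standardized measurement error per participant and condition
#'
#' Computes the analytic and bootstrapped SME for every
#' participant-by-condition cell with at least 2 trials; smaller cells are
#' skipped with one warning each. Accepts only trial-level single scores
#' (mean-amplitude-type measures): trials are treated as exchangeable
#' numbers, with no waveform, peak or latency input path.
#'
#' @param table a [trial_table()].
#' @param bootstrap_iterations bootstrap resamples per cell for the bSME;
#'   set to `NULL` to skip the bootstrap and report aSME only.
#' @param seed master seed for the bootstrap.
#' @param ci_level confidence level used by [summary.sme_table()].
#' @return An object of class `c("sme_table", "data.frame")` with columns
#'   `participant`, `condition`, `n_trials`, `sd`, `asme`, `bsme`,
#'   `bsme_iterations`. Methods: `print`, `summary`, `plot`.
#' @examples
#' tt <- trial_table(rep(c("P1", "P2"), each = 3),
#'                   rep("A", 6), rep(1:3, 2), c(1, 2, 3, 2, 2, 2))
#' sme(tt, bootstrap_iterations = 200, seed = 1)
#' @export
sme <- function(table, bootstrap_iterations = 1000L, seed = 0L,
                ci_level = 0.95) {
  stopifnot(inherits(table, "trial_table"))
  rows <- list()
  for (cond in conditions(table)) {
    cells <- condition_cells(table, cond)
    for (id in names(cells)) {
      v <- cells[[id]]
      if (length(v) < 2L) {
        warning(sprintf(
          "participant %s has %d trial(s) in condition %s: SME skipped",
          id, length(v), cond))
        next
      }
      b <- NA_real_
      if (!is.null(bootstrap_iterations)) {
        set.seed(derive_seed(seed, "sme", cond, id))
        b <- bsme(v, bootstrap_iterations)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = id, condition = cond, n_trials = length(v),
        sd = stats::sd(v), asme = asme(v), bsme = b,
        bsme_iterations = if (is.null(bootstrap_iterations)) NA_integer_
                          else as.integer(bootstrap_iterations),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    participant = character(), condition = character(),
    n_trials = integer(), sd = numeric(), asme = numeric(),
    bsme = numeric(), bsme_iterations = integer(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, ci_level = ci_level,
            class = c("sme_table", "data.frame"))
}

#' @export
print.sme_table <- function(x, ...) {
  cat(sprintf("SME records: %d participant-condition cell(s)\n", nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Group summaries of SME records
#'
#' Averages the per-participant SMEs within groups (by default per
#' condition) and attaches a t-interval on the between-participant
#' variability of the aSME: `mean +/- t * sd / sqrt(m)` at the stored
#' confidence level.
#'
#' @param object an [sme()] table.
#' @param by grouping column(s), default `"condition"`.
#' @param ci_level confidence level; defaults to the level stored on the
#'   table.
#' @param ... unused.
#' @return A data frame of class `sme_summary` with columns the grouping
#'   keys plus `n_participants`, `mean_asme`, `mean_bsme`, `ci_low`,
#'   `ci_high`. Groups with fewer than 2 records are skipped with a
#'   warning (no CI is defined).
#' @export
summary.sme_table <- function(object, by = "condition", ci_level = NULL, ...) {
  if (is.null(ci_level)) ci_level <- attr(object, "ci_level")
  if (is.null(ci_level)) ci_level <- 0.95
  groups <- split(seq_len(nrow(object)),
                  interaction(object[, by, drop = FALSE], drop = TRUE,
                              lex.order = TRUE))
  rows <- list()
  for (g in groups) {
    m <- length(g)
    if (m < 2L) {
      warning("group with fewer than 2 SME records skipped: ",
              paste(unlist(object[g[1L], by, drop = TRUE]), collapse = "/"))
      next
    }
    a <- object$asme[g]
    half <- stats::qt(1 - (1 - ci_level) / 2, df = m - 1) *
      stats::sd(a) / sqrt(m)
    key <- object[g[1L], by, drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(key, data.frame(
      n_participants = m,
      mean_asme = mean(a),
      mean_bsme = mean(object$bsme[g]),
      ci_low = mean(a) - half,
      ci_high = mean(a) + half,
      stringsAsFactors = FALSE
    ))
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) stop("no group had >= 2 SME records")
  rownames(out) <- NULL
  class(out) <- c("sme_summary", "data.frame")
  out
}

#' Write SME records to CSV
#'
#' Schema: `participant,condition,n_trials,sd,asme,bsme,bsme_iterations`;
#' byte-identical output for identical inputs.
#'
#' @param records an [sme()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sme <- function(records, path) {
  stopifnot(inherits(records, "sme_table"))
  num <- function(x) ifelse(is.na(x), "", format_num(x))
  lines <- c("participant,condition,n_trials,sd,asme,bsme,bsme_iterations",
             if (nrow(records) > 0L) sprintf(
               "%s,%s,%d,%s,%s,%s,%s",
               records$participant, records$condition, records$n_trials,
               num(records$sd), num(records$asme), num(records$bsme),
               ifelse(is.na(records$bsme_iterations), "",
                      sprintf("%d", records$bsme_iterations))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
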