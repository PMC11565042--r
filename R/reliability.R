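#' Spearman-Brown correction of a split-half correlation
#'
#' Steps a half-length reliability coefficient up to the full test length:
#' `r_full = 2 * r_half / (1 + r_half)`. The map is monotone increasing on
#' (-1, 1] and fixes 0 and 1. Negative inputs are passed through unchanged
#' (no clamping at 0): truncation would bias the mean of a resampling
#' distribution, so negative corrected coefficients are reported as
#' computed.
#'
#' @param r_half numeric vector of half-test correlations in \[-1, 1\];
#'   exactly -1 is undefined (division by zero).
#' @return Corrected full-length reliability coefficient(s).
#' @examples
#' spearman_brown(0.5)   # 0.6666667
#' spearman_brown(c(0, 1))
#' @export
spearman_brown <- function(r_half) {
  bad <- !is.na(r_half) & abs(r_half) > 1
  if (any(bad)) stop("r_half must lie in [-1, 1]")
  if (any(!is.na(r_half) & r_half == -1))
    stop("r_half = -1 gives an undefined correction (division by zero)")
  2 * r_half / (1 + r_half)
}

# Eligible cells for a subsample size (or for overall scope, n = NA:
# any cell that can be split, i.e. >= 2 trials).
eligible_cells <- function(cells, n) {
  need <- if (is.na(n)) 2L else n
  cells[vapply(cells, length, 1L) >= need]
}

#' One split-half reliability iteration
#'
#' For each eligible participant, subsamples `n` trials without replacement
#' (or takes the participant's full, possibly ragged, trial set when
#' `n = NA`), splits them uniformly at random into two near-equal bins,
#' and averages each bin. The two per-participant mean vectors are
#' Pearson-correlated across participants and the correlation is stepped up
#' with [spearman_brown()].
#'
#' @param table a [trial_table()].
#' @param condition condition label.
#' @param n subsample size, or `NA` for overall scope (all trials).
#' @return One corrected split-half coefficient, or `NA` when either bin
#'   vector has zero variance across participants (undefined correlation).
#' @export
split_half_estimate <- function(table, condition, n = NA) {
  cells <- condition_cells(table, condition)
  cells <- eligible_cells(cells, n)
  split_half_estimate_cells(cells, n)
}

split_half_estimate_cells <- function(cells, n) {
  p <- length(cells)
  if (p < 3L)
    stop("need at least 3 eligible participants for a split-half correlation")
  halves <- vapply(cells, function(v) {
    k <- if (is.na(n)) length(v) else n
    sample_bin_means(v, k)
  }, numeric(2L))
  a <- halves[1L, ]
  b <- halves[2L, ]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  r <- stats::cor(a, b)
  if (r == -1) return(NA_real_)
  spearman_brown(r)
}

#' Split-half internal-consistency reliability of trial-level scores
#'
#' Estimates how consistently a trial-level EEG/ERP measure ranks
#' participants, overall and as a function of the number of trials. Each
#' iteration subsamples trials without replacement (for grid sizes), splits
#' them randomly into two bins per participant, averages the bins,
#' Pearson-correlates the two half means across participants and applies
#' the Spearman-Brown correction; the iteration distribution is summarized
#' by its mean and percentile confidence interval.
#'
#' Participants with fewer than `n` trials are excluded at that grid point
#' (eligibility is fixed across iterations, and `n_participants` is
#' reported per point); grid points with fewer than 3 eligible participants
#' are flagged unavailable rather than aborting the curve. Overall scope
#' uses each participant's full, possibly ragged, trial set. Iterations
#' with an undefined correlation (zero variance in a half-mean vector) are
#' dropped from the summary and counted.
#'
#' @param table a [trial_table()].
#' @param condition condition label; defaults to the only condition present.
#' @param grid integer vector of subsample sizes (see [resample_config()]),
#'   or `NULL` for the overall estimate only.
#' @param iterations number of resampling iterations B.
#' @param seed master seed.
#' @param ci_level confidence level of the percentile intervals.
#' @param overall compute the overall (all-trials) estimate, default TRUE.
#' @param average `"arithmetic"` (default) averages corrected coefficients;
#'   `"fisher"` averages on the Fisher-z scale and back-transforms.
#' @param config optionally a ready [resample_config()]; overrides
#'   `grid`/`iterations`/`seed`/`ci_level`.
#' @return An object of class `c("reliability_curve", "qc_curve")` with
#'   components `metric`, `condition`, `overall` (a `resample_summary` or
#'   `NULL`), `curve` (list of per-n summaries; unavailable points carry
#'   `available = FALSE`), `config` and `average`. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @examples
#' spec <- synthetic_spec(n_subjects = 40, trials = 20, mu = 1,
#'                        sigma_b = 1, sigma_w = 2, seed = 7)
#' tt <- generate_trial_table(spec)
#' rel <- reliability(tt, grid = c(5, 10, 20), iterations = 100, seed = 1)
#' rel
#' @export
reliability <- function(table, condition = NULL, grid = NULL,
                        iterations = 1000L, seed = 0L, ci_level = 0.95,
                        overall = TRUE,
                        average = c("arithmetic", "fisher"),
                        config = NULL) {
  average <- match.arg(average)
  if (is.null(config))
    config <- resample_config(iterations, seed, grid, ci_level)
  condition <- resolve_condition(table, condition)
  cells <- condition_cells(table, condition)

  res <- list(metric = "reliability", condition = condition,
              overall = NULL, curve = list(), config = config,
              average = average)

  scopes <- c(if (overall) NA_integer_, config$grid)
  for (n in scopes) {
    elig <- eligible_cells(cells, n)
    label <- if (is.na(n)) "overall" else n
    if (length(elig) < 3L) {
      if (is.na(n))
        stop("need at least 3 participants with >= 2 trials for overall reliability")
      res$curve[[as.character(n)]] <- unavailable_point(n, length(elig))
      next
    }
    set.seed(derive_seed(config$seed, "reliability", condition, label))
    draws <- vapply(seq_len(config$iterations), function(b) {
      split_half_estimate_cells(elig, n)
    }, numeric(1L))
    s <- summarize_draws(draws, config, n_trials = n,
                         n_participants = length(elig))
    if (average == "fisher") s$estimate <- fisher_mean(s$draws)
    if (is.na(n)) res$overall <- s else res$curve[[as.character(n)]] <- s
  }
  structure(res, class = c("reliability_curve", "qc_curve"))
}

fisher_mean <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

unavailable_point <- function(n, n_participants) {
  structure(list(n_trials = n, n_iterations = 0L, n_dropped = 0L,
                 n_participants = as.integer(n_participants),
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 draws = NULL, available = FALSE),
            class = "resample_summary")
}

resolve_condition <- function(table, condition) {
  if (!is.null(condition)) {
    if (!condition %in% table$condition)
      stop("condition not present in table: ", condition)
    return(condition)
  }
  conds <- conditions(table)
  if (length(conds) != 1L)
    stop("table has several conditions; specify one of: ",
         paste(conds, collapse = ", "))
  conds
}

point_available <- function(s) is.null(s$available) || isTRUE(s$available)

#' @export
print.qc_curve <- function(x, ...) {
  cat(sprintf("%s (%s)\n", metric_title(x$metric), contrast_label(x)))
  if (!is.null(x$overall)) {
    cat("Overall: ")
    print(x$overall)
  }
  for (s in x$curve) {
    if (point_available(s)) {
      print(s)
    } else {
      cat(sprintf("n = %d: unavailable (%d eligible participant(s))\n",
                  s$n_trials, s$n_participants))
    }
  }
  invisible(x)
}

metric_title <- function(metric) {
  switch(metric,
         reliability = "Split-half reliability (Spearman-Brown corrected)",
         effect_size = "Within-subject effect size (Cohen's d)",
         metric)
}

contrast_label <- function(x) {
  if (!is.null(x$contrast)) x$contrast else paste("condition", x$condition)
}

#' @export
summary.qc_curve <- function(object, ...) as.data.frame(object)

#' Flatten a metric curve to result rows
#'
#' Produces the stable row schema consumed by [write_results()]: one row
#' for the overall estimate (empty `n_trials`) and one per grid point.
#'
#' @param x a `qc_curve` (reliability or effect-size result).
#' @param ... unused.
#' @return A data frame with columns `metric`, `condition`, `contrast`,
#'   `scope`, `n_trials`, `n_iterations`, `n_participants`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
as.data.frame.qc_curve <- function(x, ...) {
  row <- function(s, scope) data.frame(
    metric = x$metric,
    condition = if (!is.null(x$condition)) x$condition else NA_character_,
    contrast = if (!is.null(x$contrast)) x$contrast else NA_character_,
    scope = scope,
    n_trials = if (scope == "overall") NA_integer_ else s$n_trials,
    n_iterations = s$n_iterations,
    n_participants = s$n_participants,
    estimate = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high,
    stringsAsFactors = FALSE
  )
  rows <- list()
  if (!is.null(x$overall)) rows[[1L]] <- row(x$overall, "overall")
  for (s in x$curve) rows[[length(rows) + 1L]] <- row(s, "subsample")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
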