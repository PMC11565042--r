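#' Resampling configuration
#'
#' Shared settings for the iterative subsampling procedures: the number of
#' iterations B (the field convention is 1000-5000; default 1000), a master
#' seed, the grid of subsample sizes n (the classic choice is 5 to 100 in
#' increments of 5), and the confidence level of the percentile intervals.
#'
#' @param iterations positive integer B, number of resampling iterations.
#' @param seed non-negative integer master seed.
#' @param grid strictly increasing integer vector of subsample sizes, every
#'   entry at least 2 (a split needs two non-empty bins). May be `NULL` when
#'   only overall estimates are wanted.
#' @param ci_level confidence level in (0, 1), default 0.95.
#' @return An object of class `resample_config`.
#' @examples
#' resample_config(iterations = 1000, seed = 1, grid = seq(5, 40, by = 5))
#' @export
resample_config <- function(iterations = 1000L, seed = 0L, grid = NULL,
                            ci_level = 0.95) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be a positive integer")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  if (!is.null(grid)) {
    grid <- as.integer(grid)
    if (any(is.na(grid)) || any(grid < 2L))
      stop("every grid entry must be an integer >= 2")
    if (is.unsorted(grid, strictly = TRUE))
      stop("grid must be strictly increasing")
  }
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie strictly between 0 and 1")
  structure(list(iterations = iterations, seed = seed, grid = grid,
                 ci_level = ci_level),
            class = "resample_config")
}

#' @export
print.resample_config <- function(x, ...) {
  cat(sprintf("Resample config: B = %d, seed = %d, ci_level = %g\n",
              x$iterations, x$seed, x$ci_level))
  if (!is.null(x$grid))
    cat("Grid:", paste(x$grid, collapse = ", "), "\n")
  invisible(x)
}

# Deterministic 31-bit sub-seed from the master seed and context tokens, so
# each (metric, condition, n) block has its own stream and adding a grid
# point does not perturb the draws of other points.
derive_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(tokens)) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

#' Subsample trials without replacement
#'
#' Draws exactly `n` distinct trials uniformly without replacement from one
#' participant-by-condition cell, emulating a shorter experiment. A cell
#' with fewer than `n` trials returns `NULL` (the exclusion marker): the
#' participant is dropped from every iteration at that subsample size rather
#' than padded or resampled with replacement, which would change the
#' estimand.
#'
#' @param values numeric vector of one cell's trial values.
#' @param n number of trials to draw (positive integer).
#' @return Numeric vector of length `n`, or `NULL` when the cell is too
#'   small.
#' @export
subsample_trials <- function(values, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  k <- length(values)
  if (k < n) return(NULL)
  values[sample.int(k, n)]
}

#' Randomly split trial values into two near-equal bins
#'
#' Partitions the input uniformly at random into bins of sizes
#' `floor(k/2)` and `ceiling(k/2)`.
#'
#' @param values numeric vector of at least 2 trial values.
#' @return List with components `a` and `b`, the two bins.
#' @export
split_into_bins <- function(values) {
  k <- length(values)
  if (k < 2L) stop("need at least 2 values to split")
  ka <- k %/% 2L
  idx <- sample.int(k, ka)
  list(a = values[idx], b = values[-idx])
}

# One subsample-then-split step for a cell, returning the two bin means.
# sample.int(k, n) is a uniformly random ordered draw without replacement,
# so taking the first floor(n/2) positions as bin A is exactly the
# subsample + uniform split of the two-step procedure in a single call.
sample_bin_means <- function(values, n) {
  k <- length(values)
  idx <- sample.int(k, n)
  ka <- n %/% 2L
  c(mean(values[idx[seq_len(ka)]]), mean(values[idx[(ka + 1L):n]]))
}

#' Percentile confidence interval of a resampling distribution
#'
#' Empirical quantiles at (1-level)/2 and 1-(1-level)/2 with linear
#' interpolation between order statistics (quantile q sits at fractional
#' position 1 + q(B-1) in the sorted draws; `stats::quantile` type 7). For
#' the default level 0.95 these are the 2.5th and 97.5th percentiles of the
#' iteration distribution.
#'
#' @param draws numeric vector of at least 2 per-iteration estimates.
#' @param level confidence level in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' percentile_ci(0:4, 0.95)  # c(0.1, 3.9)
#' @export
percentile_ci <- function(draws, level = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 1L) stop("draws must be non-empty")
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  alpha <- (1 - level) / 2
  unname(stats::quantile(draws, c(alpha, 1 - alpha), type = 7L,
                         names = FALSE))
}

#' Summarize per-iteration draws
#'
#' Collapses a resampling distribution to its arithmetic mean and
#' percentile confidence interval.
#'
#' @param draws numeric vector of per-iteration estimates; `NA` entries
#'   (undefined iterations) are dropped and counted.
#' @param config a [resample_config()] (supplies `ci_level`).
#' @param n_trials subsample size for this summary, or `NA` for overall
#'   scope.
#' @param n_participants number of participants used.
#' @param keep_draws retain the draw vector in the summary (default TRUE).
#' @return An object of class `resample_summary` with fields `n_trials`,
#'   `n_iterations` (valid draws), `n_dropped` (undefined iterations),
#'   `n_participants`, `estimate`, `ci_low`, `ci_high`, and optionally
#'   `draws`.
#' @export
summarize_draws <- function(draws, config, n_trials = NA_integer_,
                            n_participants = NA_integer_, keep_draws = TRUE) {
  ok <- draws[!is.na(draws)]
  if (!length(ok)) stop("no defined draws to summarize")
  ci <- percentile_ci(ok, config$ci_level)
  structure(list(
    n_trials = n_trials,
    n_iterations = length(ok),
    n_dropped = length(draws) - length(ok),
    n_participants = as.integer(n_participants),
    estimate = mean(ok),
    ci_low = ci[1L],
    ci_high = ci[2L],
    draws = if (keep_draws) ok else NULL
  ), class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  scope <- if (is.na(x$n_trials)) "overall" else paste0("n = ", x$n_trials)
  cat(sprintf("%s: %.4f [%.4f, %.4f] (B = %d, participants = %d%s)\n",
              scope, x$estimate, x$ci_low, x$ci_high, x$n_iterations,
              x$n_participants,
              if (x$n_dropped > 0)
                sprintf(", %d undefined iteration(s) dropped", x$n_dropped)
              else ""))
  invisible(x)
}
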