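#' One-sample Cohen's d against a baseline constant
#'
#' Standardized mean difference of per-participant scores from a constant
#' `mu0`: `d = (mean(scores) - mu0) / sd(scores)` with the sample (k-1)
#' standard deviation. Positive values mean the scores exceed the baseline.
#' The matching one-sample t statistic `t = d * sqrt(k)` is returned
#' alongside.
#'
#' @param scores numeric vector of per-participant mean values (length >= 2).
#' @param mu0 baseline constant, default 0 (scores are assumed
#'   baseline-corrected).
#' @return List with components `d` and `t`.
#' @examples
#' cohens_d_one_sample(c(1, 2, 3))  # d = 2, t = 2*sqrt(3)
#' @export
cohens_d_one_sample <- function(scores, mu0 = 0) {
  k <- length(scores)
  if (k < 2L) stop("need at least 2 scores")
  s <- stats::sd(scores)
  if (s == 0) stop("zero standard deviation: effect size undefined")
  d <- (mean(scores) - mu0) / s
  list(d = d, t = d * sqrt(k))
}

#' Paired Cohen's d between two conditions
#'
#' Standardized mean difference of two participant-aligned score vectors,
#' `d = (mean1 - mean2) / s` with the pooled standard deviation
#' `s = sqrt((s1^2 + s2^2) / 2)` (average-variance pooling of the two
#' condition vectors). The paired t statistic
#' `mean(diff) / (sd(diff) / sqrt(k))` is reported alongside; note it
#' standardizes by the difference-score SD, not by `s`.
#'
#' The difference-score standardizer `d_z = mean(diff) / sd(diff)` is
#' available via `standardizer = "dz"`; the two are not interchangeable.
#'
#' @param scores_1,scores_2 numeric vectors of per-participant means,
#'   aligned by participant, equal length >= 2.
#' @param standardizer `"pooled"` (default) or `"dz"`.
#' @return List with components `d` and `t`.
#' @examples
#' cohens_d_paired(c(2, 4, 6), c(1, 3, 5))  # d = 0.5
#' @export
cohens_d_paired <- function(scores_1, scores_2,
                            standardizer = c("pooled", "dz")) {
  standardizer <- match.arg(standardizer)
  k <- length(scores_1)
  if (k != length(scores_2))
    stop("scores must be participant-aligned vectors of equal length")
  if (k < 2L) stop("need at least 2 participant pairs")
  dif <- scores_1 - scores_2
  sdif <- stats::sd(dif)
  s <- switch(standardizer,
    pooled = sqrt((stats::var(scores_1) + stats::var(scores_2)) / 2),
    dz = sdif
  )
  if (s == 0) stop("zero pooled standard deviation: effect size undefined")
  d <- mean(dif) / s
  t <- if (sdif == 0) NA_real_ else mean(dif) / (sdif / sqrt(k))
  list(d = d, t = t)
}

# Per-participant all-trials means for the conditions of a contrast,
# participant-aligned (paired contrasts keep only participants present in
# both conditions).
contrast_scores <- function(cells1, cells2) {
  if (is.null(cells2))
    return(list(s1 = vapply(cells1, mean, 0), s2 = NULL))
  ids <- intersect(names(cells1), names(cells2))
  list(s1 = vapply(cells1[ids], mean, 0),
       s2 = vapply(cells2[ids], mean, 0))
}

#' Within-subject effect size, overall and by trial count
#'
#' Computes Cohen's d for a condition against a baseline constant
#' (one-sample) or between two conditions (paired, pooled-SD
#' standardizer), overall and across a grid of subsampled trial counts.
#'
#' For each grid size n and iteration, n trials are drawn without
#' replacement per participant in each involved condition, averaged to
#' per-participant scores, and d is computed; the iteration distribution
#' is summarized by its mean and percentile confidence interval. Paired
#' eligibility requires at least n trials in both conditions. The overall
#' estimate is deterministic (all trials per participant); its confidence
#' interval is obtained by resampling participants with replacement
#' `iterations` times, an interpretation documented in the package
#' vignette.
#'
#' @param table a [trial_table()].
#' @param condition condition label (defaults to the only one present).
#' @param condition2 second condition for a paired contrast, or `NULL`
#'   (default) for a one-sample contrast against `baseline`.
#' @param baseline baseline constant for one-sample contrasts, default 0.
#' @param grid,iterations,seed,ci_level,config as in [reliability()].
#' @param overall compute the overall estimate, default TRUE.
#' @return An object of class `c("effect_size_curve", "qc_curve")` with
#'   components `metric`, `condition`, `contrast` (e.g. `"A_vs_baseline(0)"`
#'   or `"A_vs_B"`), `overall`, `curve`, `t_overall` (t statistic of the
#'   all-trials computation), `boot_draws`, `config`.
#' @examples
#' spec <- synthetic_spec(n_subjects = 40, trials = 20, mu = 0.5,
#'                        sigma_b = 1, sigma_w = 2, seed = 7)
#' tt <- generate_trial_table(spec)
#' effect_size(tt, grid = c(5, 10), iterations = 100, seed = 1)
#' @export
effect_size <- function(table, condition = NULL, condition2 = NULL,
                        baseline = 0, grid = NULL, iterations = 1000L,
                        seed = 0L, ci_level = 0.95, overall = TRUE,
                        config = NULL) {
  if (is.null(config))
    config <- resample_config(iterations, seed, grid, ci_level)
  condition <- resolve_condition(table, condition)
  cells1 <- condition_cells(table, condition)
  cells2 <- NULL
  paired <- !is.null(condition2)
  if (paired) {
    cells2 <- condition_cells(table, condition2)
    contrast <- paste0(condition, "_vs_", condition2)
  } else {
    contrast <- sprintf("%s_vs_baseline(%g)", condition, baseline)
  }

  res <- list(metric = "effect_size", condition = condition,
              contrast = contrast, overall = NULL, curve = list(),
              t_overall = NA_real_, boot_draws = NULL, config = config)

  if (overall) {
    sc <- contrast_scores(cells1, cells2)
    est <- if (paired) cohens_d_paired(sc$s1, sc$s2)
           else cohens_d_one_sample(sc$s1, baseline)
    k <- length(sc$s1)
    if (k < 2L) stop("need at least 2 participants for an overall effect size")
    set.seed(derive_seed(config$seed, "effect_size", contrast, "overall"))
    boot <- vapply(seq_len(config$iterations), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      out <- tryCatch({
        if (paired) cohens_d_paired(sc$s1[idx], sc$s2[idx])$d
        else cohens_d_one_sample(sc$s1[idx], baseline)$d
      }, error = function(e) NA_real_)
      out
    }, numeric(1L))
    s <- summarize_draws(boot, config, n_trials = NA_integer_,
                         n_participants = k, keep_draws = FALSE)
    s$estimate <- est$d  # deterministic all-trials point estimate
    res$overall <- s
    res$t_overall <- est$t
    res$boot_draws <- boot
  }

  for (n in config$grid) {
    e1 <- eligible_cells(cells1, n)
    ids <- names(e1)
    if (paired) ids <- intersect(ids, names(eligible_cells(cells2, n)))
    if (length(ids) < 2L) {
      res$curve[[as.character(n)]] <- unavailable_point(n, length(ids))
      next
    }
    c1 <- cells1[ids]
    c2 <- if (paired) cells2[ids]
    set.seed(derive_seed(config$seed, "effect_size", contrast, n))
    draws <- vapply(seq_len(config$iterations), function(b) {
      m1 <- vapply(c1, function(v) mean(v[sample.int(length(v), n)]), 0)
      tryCatch({
        if (paired) {
          m2 <- vapply(c2, function(v) mean(v[sample.int(length(v), n)]), 0)
          cohens_d_paired(m1, m2)$d
        } else cohens_d_one_sample(m1, baseline)$d
      }, error = function(e) NA_real_)
    }, numeric(1L))
    res$curve[[as.character(n)]] <-
      summarize_draws(draws, config, n_trials = n,
                      n_participants = length(ids))
  }
  structure(res, class = c("effect_size_curve", "qc_curve"))
}
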