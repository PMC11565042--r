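#' Variance-components specification for synthetic trial-level data
#'
#' Describes the generating model used to simulate trial-level scores with
#' known ground truth: for subject i and condition c, the true score is
#' `theta_ic = mu_c + b_i` with a subject effect `b_i ~ N(0, sigma_b^2)`
#' shared across conditions, and each trial adds independent noise
#' `e ~ N(0, sigma_w^2)`. The single-trial reliability is
#' `rho = sigma_b^2 / (sigma_b^2 + sigma_w^2)`, and every package metric
#' has a closed-form oracle under this model ([expected_reliability()],
#' [expected_effect_size()], [expected_asme()]).
#'
#' A heavy-tailed trial-noise option (`noise = "t"`, scaled to SD
#' `sigma_w`) is available for robustness checks; the oracles for the
#' second-moment quantities still hold, but it is off by default.
#'
#' @param n_subjects number of subjects.
#' @param trials trials per subject-condition cell: a single integer, or
#'   `c(min, max)` for ragged counts drawn uniformly per cell.
#' @param mu grand mean per condition: a scalar recycled over `conditions`,
#'   or a named vector keyed by condition.
#' @param sigma_b between-subject SD (>= 0).
#' @param sigma_w within-subject (trial-noise) SD (>= 0).
#' @param conditions character vector of condition labels, default `"A"`.
#' @param seed generator seed.
#' @param noise `"gaussian"` (default) or `"t"`.
#' @param t_df degrees of freedom of the scaled-t noise (> 2), default 5.
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_subjects = 200, trials = 40, mu = 0.5,
#'                        sigma_b = 1, sigma_w = 2, seed = 42)
#' expected_reliability(spec, 20)   # 0.8333
#' @export
synthetic_spec <- function(n_subjects, trials, mu = 0, sigma_b = 1,
                           sigma_w = 1, conditions = "A", seed = 0L,
                           noise = c("gaussian", "t"), t_df = 5) {
  noise <- match.arg(noise)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects must be a positive integer")
  trials <- as.integer(trials)
  if (length(trials) == 1L) trials <- c(trials, trials)
  if (length(trials) != 2L || any(is.na(trials)) || any(trials < 1L) ||
      trials[1L] > trials[2L])
    stop("trials must be a positive integer or an increasing (min, max) pair")
  if (sigma_b < 0 || sigma_w < 0) stop("sigma_b and sigma_w must be >= 0")
  if (noise == "t" && t_df <= 2)
    stop("t_df must exceed 2 so the noise SD is finite")
  if (is.null(names(mu))) {
    mu <- rep_len(as.numeric(mu), length(conditions))
    names(mu) <- conditions
  } else if (!all(conditions %in% names(mu))) {
    stop("mu must name every condition")
  }
  structure(list(n_subjects = n_subjects, trials = trials,
                 mu = mu[conditions], sigma_b = sigma_b, sigma_w = sigma_w,
                 conditions = conditions, seed = as.integer(seed),
                 noise = noise, t_df = t_df),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  tr <- if (x$trials[1L] == x$trials[2L]) as.character(x$trials[1L])
        else sprintf("%d-%d (ragged)", x$trials[1L], x$trials[2L])
  cat(sprintf(
    "Synthetic spec: %d subjects, %s trials/cell, sigma_b = %g, sigma_w = %g, %s noise\n",
    x$n_subjects, tr, x$sigma_b, x$sigma_w, x$noise))
  cat("Conditions:",
      paste(sprintf("%s (mu = %g)", x$conditions, x$mu), collapse = ", "),
      "\n")
  if (x$sigma_b > 0 || x$sigma_w > 0)
    cat(sprintf("Single-trial reliability rho = %.4f\n",
                single_trial_reliability(x)))
  invisible(x)
}

#' Single-trial reliability of a synthetic spec
#' @param spec a [synthetic_spec()].
#' @return `rho = sigma_b^2 / (sigma_b^2 + sigma_w^2)`.
#' @export
single_trial_reliability <- function(spec) {
  if (spec$sigma_b == 0 && spec$sigma_w == 0)
    stop("rho undefined when sigma_b and sigma_w are both 0")
  spec$sigma_b^2 / (spec$sigma_b^2 + spec$sigma_w^2)
}

#' Generate a trial table from a synthetic spec
#'
#' Deterministic per seed. Subject effects are shared across conditions,
#' so between-condition null contrasts produce positively correlated
#' per-participant scores, exercising the paired analysis path
#' realistically.
#'
#' @param spec a [synthetic_spec()].
#' @return A [trial_table()].
#' @export
generate_trial_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ids <- sprintf("S%03d", seq_len(spec$n_subjects))
  b <- stats::rnorm(spec$n_subjects, 0, spec$sigma_b)
  rows <- vector("list", spec$n_subjects * length(spec$conditions))
  j <- 0L
  for (i in seq_len(spec$n_subjects)) {
    for (cond in spec$conditions) {
      k <- if (spec$trials[1L] == spec$trials[2L]) spec$trials[1L]
           else sample(spec$trials[1L]:spec$trials[2L], 1L)
      e <- if (spec$noise == "gaussian") {
        stats::rnorm(k, 0, spec$sigma_w)
      } else {
        stats::rt(k, df = spec$t_df) * spec$sigma_w /
          sqrt(spec$t_df / (spec$t_df - 2))
      }
      j <- j + 1L
      rows[[j]] <- data.frame(
        participant = ids[i], condition = cond, trial = seq_len(k),
        value = spec$mu[[cond]] + b[i] + e, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  trial_table(df$participant, df$condition, df$trial, df$value)
}

#' @rdname generate_trial_table
#' @param object a [synthetic_spec()].
#' @param nsim unused (one table per call).
#' @param seed optional seed overriding the spec's.
#' @param ... unused.
#' @export
simulate.synthetic_spec <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seed <- as.integer(seed)
  generate_trial_table(object)
}

#' Closed-form oracle: expected split-half reliability at n trials
#'
#' The Spearman-Brown prophecy of the variance-components model:
#' `R(n) = n * rho / (1 + (n - 1) * rho)` with
#' `rho = sigma_b^2 / (sigma_b^2 + sigma_w^2)`. `R(1) = rho`, and
#' `R(n) -> 1` as `n` grows whenever `rho > 0`.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of trials (vectorized).
#' @return Expected reliability in \[0, 1\].
#' @export
expected_reliability <- function(spec, n) {
  rho <- single_trial_reliability(spec)
  n * rho / (1 + (n - 1) * rho)
}

#' Closed-form oracle: expected one-sample effect size at n trials
#'
#' Under the generating model, per-participant n-trial means are
#' distributed `N(mu_c, sigma_b^2 + sigma_w^2 / n)`, so the expected
#' one-sample Cohen's d versus 0 is
#' `d(n) = mu_c / sqrt(sigma_b^2 + sigma_w^2 / n)`; its magnitude grows
#' with n towards `mu_c / sigma_b`.
#'
#' @param spec a [synthetic_spec()].
#' @param condition condition label, default the first.
#' @param n number of trials (vectorized).
#' @return Expected Cohen's d.
#' @export
expected_effect_size <- function(spec, condition = spec$conditions[1L], n) {
  den <- sqrt(spec$sigma_b^2 + spec$sigma_w^2 / n)
  if (any(den == 0)) stop("effect-size oracle undefined: zero denominator")
  spec$mu[[condition]] / den
}

#' Closed-form oracle: expected analytic SME at n trials
#'
#' Expected aSME of an n-trial cell is approximately `sigma_w / sqrt(n)`
#' (exact for the squared quantity; the SD itself carries a small-sample
#' bias factor that vanishes as n grows).
#'
#' @param spec a [synthetic_spec()].
#' @param n number of trials (vectorized).
#' @return Expected aSME (>= 0).
#' @export
expected_asme <- function(spec, n) {
  spec$sigma_w / sqrt(n)
}
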