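# Small fixtures built in code, shared across test files.

# Long-format table: each participant's trials listed per condition.
make_table <- function(cells) {
  # cells: named list participant -> named list condition -> numeric values
  rows <- list()
  for (p in names(cells)) {
    for (cond in names(cells[[p]])) {
      v <- cells[[p]][[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, condition = cond, trial = seq_along(v), value = v,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  trial_table(df$participant, df$condition, df$trial, df$value)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Independent oracle for the 2-trials-per-participant split-half design:
# with exactly 2 trials each, every bin holds a single trial, so the 2^P
# equally likely bin assignments can be enumerated exhaustively. Undefined
# assignments (zero variance or r = -1) are dropped, mirroring the
# estimator's treatment of undefined iterations.
exhaustive_two_trial_mean <- function(pairs) {
  p <- length(pairs)
  vals <- c()
  for (mask in 0:(2^p - 1)) {
    pick <- as.integer(intToBits(mask))[seq_len(p)]
    a <- mapply(function(pr, s) pr[1L + s], pairs, pick)
    b <- mapply(function(pr, s) pr[2L - s], pairs, pick)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r == -1) next
    vals <- c(vals, 2 * r / (1 + r))
  }
  mean(vals)
}

# Balanced single-condition table -> subjects x trials score matrix.
score_matrix <- function(tt) {
  df <- as.data.frame(tt)
  df <- df[order(df$participant, df$trial), ]
  k <- length(unique(df$trial))
  matrix(df$value, ncol = k, byrow = TRUE)
}

# Cronbach's alpha from a subjects x trials score matrix, computed from
# the covariance matrix (independent of the split-half machinery).
cronbach_alpha <- function(m) {
  k <- ncol(m)
  S <- stats::cov(m)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}
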