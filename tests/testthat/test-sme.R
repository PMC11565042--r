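test_that("analytic SME matches direct computation and its invariances", {
  expect_equal(asme(1:5), sqrt(2.5) / sqrt(5))
  expect_equal(asme(c(3, 3, 3)), 0)
  expect_equal(asme(c(0, 2)), 1)
  expect_error(asme(1), "at least 2")

  set.seed(4)
  v <- rnorm(12)
  expect_equal(asme(3 * v), 3 * asme(v))       # scale equivariance
  expect_equal(asme(-2 * v), 2 * asme(v))
  expect_equal(asme(v + 10), asme(v))          # translation invariance
})

test_that("bootstrapped SME converges to its exhaustive limit", {
  expect_equal(bsme(c(7, 7, 7), 100), 0)
  expect_error(bsme(1, 100), "at least 2")
  expect_error(bsme(c(1, 2), 1), ">= 2")

  # exhaustive bootstrap of [0, 2]: resample means {0,1,1,2}/4, SD sqrt(0.5)
  set.seed(6)
  expect_equal(bsme(c(0, 2), 20000), sqrt(0.5), tolerance = 0.02)

  # large-B identity: bsme -> asme * sqrt((N-1)/N)
  set.seed(7)
  for (i in 1:5) {
    v <- rnorm(15, sd = runif(1, 0.5, 3))
    lim <- asme(v) * sqrt(14 / 15)
    expect_equal(bsme(v, 5000), lim, tolerance = lim * 0.06)
  }
})

test_that("SME tables cover every eligible cell and skip singletons", {
  tt <- make_table(list(P1 = list(A = c(1, 2, 3)), P2 = list(A = c(2, 2)),
                        P3 = list(A = c(0, 4)), P4 = list(A = 5)))
  expect_warning(rec <- sme(tt, bootstrap_iterations = 100, seed = 1),
                 "P4")
  expect_identical(nrow(rec), 3L)
  expect_false("P4" %in% rec$participant)
  # per-cell recomputation oracle
  for (i in seq_len(nrow(rec))) {
    v <- trials(tt, rec$participant[i], rec$condition[i])
    expect_equal(rec$asme[i], stats::sd(v) / sqrt(length(v)))
    expect_equal(rec$sd[i], stats::sd(v))
    expect_identical(rec$n_trials[i], length(v))
  }
  # invariant: asme = 0 iff all trials identical
  expect_equal(rec$asme[rec$participant == "P2"], 0)

  # deterministic under a fixed seed
  rec2 <- suppressWarnings(sme(tt, bootstrap_iterations = 100, seed = 1))
  expect_equal(as.data.frame(rec), as.data.frame(rec2))

  # aSME-only mode
  rec3 <- suppressWarnings(sme(tt, bootstrap_iterations = NULL))
  expect_true(all(is.na(rec3$bsme)))
})

test_that("group summaries average member records with a t-interval", {
  rec <- structure(data.frame(
    participant = paste0("P", 1:5),
    condition = c("A", "A", "A", "B", "B"),
    n_trials = 10L, sd = 1,
    asme = c(0.4, 0.5, 0.6, 0.2, 0.4),
    bsme = c(0.38, 0.48, 0.58, 0.19, 0.39),
    bsme_iterations = 100L, stringsAsFactors = FALSE
  ), ci_level = 0.95, class = c("sme_table", "data.frame"))
  gs <- summary(rec)
  expect_identical(nrow(gs), 2L)
  expect_equal(gs$mean_asme, c(0.5, 0.3))
  expect_equal(gs$mean_bsme, c(0.48, 0.29))
  expect_identical(gs$n_participants, c(3L, 2L))
  half <- stats::qt(0.975, 2) * stats::sd(c(0.4, 0.5, 0.6)) / sqrt(3)
  expect_equal(gs$ci_low[1L], 0.5 - half)
  expect_equal(gs$ci_high[1L], 0.5 + half)

  # identical members give a zero-width interval
  same <- rec
  same$asme <- 0.5
  gs2 <- summary(same)
  expect_equal(gs2$ci_low[1L], 0.5)
  expect_equal(gs2$ci_high[1L], 0.5)
})

test_that("mean aSME tracks sigma_w / sqrt(n) on synthetic data", {
  spec <- synthetic_spec(n_subjects = 150, trials = 25, mu = 0, sigma_b = 1,
                         sigma_w = 2, seed = 14)
  tt <- generate_trial_table(spec)
  rec <- sme(tt, bootstrap_iterations = NULL)
  expect_equal(mean(rec$asme), expected_asme(spec, 25), tolerance = 0.05)
})

test_that("SME CSVs follow the schema deterministically", {
  tt <- make_table(list(P1 = list(A = c(1, 2, 3)), P2 = list(A = c(0, 4))))
  rec <- sme(tt, bootstrap_iterations = 50, seed = 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_sme(rec, f1); write_sme(rec, f2)
  expect_identical(readLines(f1)[1L],
    "participant,condition,n_trials,sd,asme,bsme,bsme_iterations")
  expect_identical(readLines(f1), readLines(f2))
})
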