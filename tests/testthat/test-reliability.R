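test_that("Spearman-Brown correction matches direct substitution", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(-1 / 3), -1)
  expect_error(spearman_brown(-1), "undefined")
  expect_error(spearman_brown(1.2), "\\[-1, 1\\]")
  # monotone increasing on the domain
  r <- seq(-0.9, 1, by = 0.01)
  expect_true(all(diff(spearman_brown(r)) > 0))
})

test_that("single split-half iterations behave at the boundaries", {
  const <- make_table(list(P1 = list(A = rep(1, 4)),
                           P2 = list(A = rep(2, 4)),
                           P3 = list(A = rep(3, 4))))
  set.seed(1)
  # bins are identical to the participant constants -> r_half = r_full = 1
  expect_equal(split_half_estimate(const, "A", n = 4), 1)
  expect_equal(split_half_estimate(const, "A"), 1)  # overall scope

  two <- make_table(list(P1 = list(A = c(1, 2)), P2 = list(A = c(3, 4))))
  expect_error(split_half_estimate(two, "A"), "3 eligible")

  # zero between-participant variance -> undefined-correlation marker
  flat <- make_table(list(P1 = list(A = c(5, 5)), P2 = list(A = c(5, 5)),
                          P3 = list(A = c(5, 5))))
  expect_true(is.na(split_half_estimate(flat, "A")))
})

test_that("Monte-Carlo split-half mean converges to the exhaustive oracle", {
  pairs <- list(P1 = c(0.3, 1.1), P2 = c(2.0, 2.6), P3 = c(4.2, 3.5))
  oracle <- exhaustive_two_trial_mean(pairs)
  tt <- make_table(lapply(pairs, function(v) list(A = v)))
  rel <- reliability(tt, "A", grid = NULL, iterations = 4000, seed = 5)
  expect_equal(rel$overall$estimate, oracle, tolerance = 0.02)
})

test_that("noise-free synthetic data yields perfect reliability at every n", {
  spec <- synthetic_spec(n_subjects = 12, trials = 20, mu = 1, sigma_b = 1,
                         sigma_w = 0, seed = 3)
  tt <- generate_trial_table(spec)
  rel <- reliability(tt, grid = c(5, 10), iterations = 20, seed = 1)
  expect_equal(rel$overall$estimate, 1)
  for (s in rel$curve) expect_equal(s$estimate, 1)
})

test_that("reliability curves recover the prophecy closed form and rise with n", {
  spec <- synthetic_spec(n_subjects = 200, trials = 40, mu = 0, sigma_b = 1,
                         sigma_w = 2, seed = 11)
  tt <- generate_trial_table(spec)
  rel <- reliability(tt, grid = c(5, 10, 20, 40), iterations = 300, seed = 2)
  est <- vapply(rel$curve, function(s) s$estimate, 0)
  expect_lt(max(abs(est - expected_reliability(spec, c(5, 10, 20, 40)))),
            0.05)
  expect_true(all(diff(est) > -0.01))  # monotone up to Monte-Carlo noise
})

test_that("eligibility is fixed per grid point and gaps are flagged", {
  tt <- make_table(list(P1 = list(A = rnorm(8)), P2 = list(A = rnorm(8)),
                        P3 = list(A = rnorm(8)), P4 = list(A = rnorm(8))))
  rel <- reliability(tt, grid = c(5, 10), iterations = 30, seed = 4)
  expect_identical(rel$curve[["5"]]$n_participants, 4L)
  expect_true(isFALSE(rel$curve[["10"]]$available))
  expect_true(is.na(rel$curve[["10"]]$estimate))
  df <- as.data.frame(rel)
  expect_identical(nrow(df), 3L)  # overall + two grid rows
  expect_identical(df$scope, c("overall", "subsample", "subsample"))
})

test_that("identical seeds reproduce results; Fisher averaging is close", {
  spec <- synthetic_spec(n_subjects = 30, trials = 12, mu = 0, sigma_b = 1,
                         sigma_w = 1, seed = 9)
  tt <- generate_trial_table(spec)
  r1 <- reliability(tt, grid = c(4, 8), iterations = 50, seed = 21)
  r2 <- reliability(tt, grid = c(4, 8), iterations = 50, seed = 21)
  expect_equal(as.data.frame(r1), as.data.frame(r2))

  rf <- reliability(tt, grid = NULL, iterations = 200, seed = 21,
                    average = "fisher")
  ra <- reliability(tt, grid = NULL, iterations = 200, seed = 21)
  expect_equal(rf$overall$estimate, ra$overall$estimate, tolerance = 0.05)
  expect_false(identical(rf$overall$estimate, ra$overall$estimate))
})
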