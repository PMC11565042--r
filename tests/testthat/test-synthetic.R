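test_that("degenerate specs generate exactly what they promise", {
  spec0 <- synthetic_spec(n_subjects = 5, trials = 4, mu = 1, sigma_b = 0,
                          sigma_w = 0, seed = 1)
  tt0 <- generate_trial_table(spec0)
  expect_true(all(tt0$value == 1))
  expect_identical(nrow(tt0), 20L)

  spec <- synthetic_spec(n_subjects = 50, trials = 20,
                         conditions = c("A", "B"), seed = 2)
  tt <- generate_trial_table(spec)
  expect_identical(sum(tt$condition == "A"), 1000L)  # 50 x 20 per condition
  expect_identical(sum(tt$condition == "B"), 1000L)

  expect_error(synthetic_spec(0, 10), "positive")
  expect_error(synthetic_spec(10, c(5, 3)), "increasing")
  expect_error(synthetic_spec(10, 10, sigma_b = -1), ">= 0")
  expect_error(single_trial_reliability(spec0), "undefined")
})

test_that("generated moments match the variance-components model", {
  spec <- synthetic_spec(n_subjects = 500, trials = 20, mu = 0, sigma_b = 1,
                         sigma_w = 2, seed = 31)
  tt <- generate_trial_table(spec)
  cells <- split(tt$value, tt$participant)
  means <- vapply(cells, mean, 0)
  withins <- vapply(cells, stats::var, 0)
  expect_equal(stats::var(means), 1 + 4 / 20, tolerance = 0.1 * (1 + 0.2))
  expect_equal(mean(withins), 4, tolerance = 0.4)
})

test_that("generation is deterministic per seed and ragged counts respect the range", {
  spec <- synthetic_spec(n_subjects = 20, trials = c(5, 15), seed = 7)
  t1 <- generate_trial_table(spec)
  t2 <- simulate(spec)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  cnt <- table(t1$participant)
  expect_true(all(cnt >= 5 & cnt <= 15))
  expect_gt(length(unique(as.integer(cnt))), 1L)

  t3 <- simulate(spec, seed = 8)
  expect_false(identical(t1$value, t3$value))
})

test_that("subject effects are shared across conditions", {
  spec <- synthetic_spec(n_subjects = 300, trials = 30, mu = c(A = 0, B = 0),
                         sigma_b = 1, sigma_w = 1, conditions = c("A", "B"),
                         seed = 17)
  tt <- generate_trial_table(spec)
  mA <- vapply(condition_cells <- split(tt$value[tt$condition == "A"],
                                        tt$participant[tt$condition == "A"]),
               mean, 0)
  mB <- vapply(split(tt$value[tt$condition == "B"],
                     tt$participant[tt$condition == "B"]), mean, 0)
  # cor of n-trial means across conditions ~ sigma_b^2/(sigma_b^2+sigma_w^2/n)
  expect_gt(stats::cor(mA, mB[names(mA)]), 0.9)
})

test_that("closed-form oracles evaluate correctly", {
  spec <- synthetic_spec(n_subjects = 10, trials = 40, mu = 0.5, sigma_b = 1,
                         sigma_w = 2, seed = 1)
  expect_equal(single_trial_reliability(spec), 0.2)
  expect_equal(expected_reliability(spec, 20), 5 / 6)
  expect_equal(expected_reliability(spec, 1), 0.2)
  expect_equal(expected_effect_size(spec, n = 4), 0.5 / sqrt(2),
               tolerance = 1e-9)
  expect_equal(expected_asme(spec, 16), 0.5)
  expect_equal(expected_asme(spec, 4), 1)

  pure <- synthetic_spec(10, 10, mu = 1, sigma_b = 1, sigma_w = 0)
  expect_equal(expected_reliability(pure, c(1, 7)), c(1, 1))
  expect_equal(expected_effect_size(pure, n = 3), 1)
  noiseonly <- synthetic_spec(10, 10, sigma_b = 0, sigma_w = 1)
  expect_equal(expected_reliability(noiseonly, c(1, 50)), c(0, 0))
})

test_that("heavy-tailed noise keeps the promised second moments", {
  spec <- synthetic_spec(n_subjects = 400, trials = 20, mu = 0, sigma_b = 0,
                         sigma_w = 2, seed = 23, noise = "t", t_df = 5)
  tt <- generate_trial_table(spec)
  expect_equal(stats::sd(tt$value), 2, tolerance = 0.15)
  expect_error(synthetic_spec(10, 10, noise = "t", t_df = 2), "exceed 2")
})
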