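intervals_of <- function(k, dur) {
  out <- data.frame(k = k, duration = dur)
  class(out) <- c("coalescent_intervals_cb", "data.frame")
  attr(out, "depth") <- sum(dur)
  out
}

test_that("classic skyline applies the k(k-1)/2 moment estimator per interval", {
  expect_equal(classic_skyline(intervals_of(2, 0.4))$Ne_u, 0.4)
  est <- classic_skyline(intervals_of(c(5, 2), c(0.2, 0.1)))
  expect_equal(est$Ne_u, c(10 * 0.2, 1 * 0.1))
  expect_equal(attr(est, "K"), 2)
})

test_that("epsilon = 0 reproduces the classic skyline exactly", {
  set.seed(111)
  tr <- simulate_kingman_tree(20, 0.02)
  ci <- coalescent_intervals(tr)
  expect_equal(generalized_skyline(ci, 0)$Ne_u, classic_skyline(ci)$Ne_u)
})

test_that("full pooling yields the single-parameter MLE", {
  ci <- intervals_of(c(4, 3, 2), c(0.1, 0.2, 0.5))
  est <- generalized_skyline(ci, epsilon = 10)
  expect_equal(attr(est, "K"), 1)
  expect_equal(unique(est$Ne_u), (6 * 0.1 + 3 * 0.2 + 1 * 0.5) / 3)
})

test_that("pooling two intervals gives the hand-computed composite MLE", {
  ci <- intervals_of(c(3, 2), c(0.1, 0.4))
  est <- generalized_skyline(ci, epsilon = 10)
  expect_equal(unique(est$Ne_u), (3 * 0.1 + 1 * 0.4) / 2)
  expect_equal(unique(est$Ne_u), 0.35)
})

test_that("classic skyline matches the ape reference implementation", {
  set.seed(112)
  for (rep in 1:4) {
    tr <- simulate_kingman_tree(15, 0.03)
    ours <- classic_skyline(coalescent_intervals(tr))
    ref <- ape::skyline(tr)
    expect_equal(ours$Ne_u, ref$population.size, tolerance = 1e-9)
  }
})

test_that("AIC selection favours pooling on constant-size trees", {
  set.seed(113)
  pooled_less <- vapply(1:100, function(i) {
    tr <- simulate_kingman_tree(15, 0.02)
    ci <- coalescent_intervals(tr)
    sel <- aic_select_epsilon(ci)
    c(K = attr(sel$skyline, "K"),
      aic_best = attr(sel$skyline, "AIC"),
      aic_classic = attr(classic_skyline(ci), "AIC"))
  }, numeric(3))
  expect_gt(mean(pooled_less["K", ] < 14), 0.9)
  # with 0 in the grid, the minimised AIC can never exceed the classic one
  expect_true(all(pooled_less["aic_best", ] <= pooled_less["aic_classic", ] + 1e-9))
})

test_that("AIC epsilon selection handles degenerate grids and ties", {
  ci <- intervals_of(2, 0.7)
  sel <- aic_select_epsilon(ci, c(0, 0.1, 0.5))
  expect_equal(sel$epsilon, 0) # all give K = 1, tie broken to smallest epsilon
  expect_equal(sel$skyline$Ne_u, 0.7)
  sel0 <- aic_select_epsilon(coalescent_intervals(simulate_kingman_tree(8, 0.01)),
                             epsilon_grid = 0)
  expect_equal(attr(sel0$skyline, "epsilon"), 0)
})

test_that("skyline amplitude is the max/min ratio with scale invariance", {
  est <- generalized_skyline(intervals_of(c(3, 2), c(0.2, 0.2)), 0)
  expect_equal(skyline_amplitude(est), max(est$Ne_u) / min(est$Ne_u))
  est2 <- est
  est2$Ne_u <- est$Ne_u * 7
  expect_equal(skyline_amplitude(est2), skyline_amplitude(est))
  flat <- generalized_skyline(intervals_of(c(3, 2), c(0.1, 0.3)), 10)
  expect_equal(skyline_amplitude(flat), 1)
})

test_that("the fully pooled skyline recovers the simulated constant size", {
  set.seed(114)
  est <- vapply(1:200, function(i) {
    ci <- coalescent_intervals(simulate_kingman_tree(10, 0.01))
    unique(generalized_skyline(ci, epsilon = sum(ci$duration) + 1)$Ne_u)
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.01), 3 * se)
})
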