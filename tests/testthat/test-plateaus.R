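test_that("a constant series produces no confident boundary", {
  set.seed(1)
  cp <- bcp_posterior(rnorm(100, 0.02, 0.002), seed = 1)
  expect_true(all(cp$boundaries$prob < 0.5))
  pl <- extract_plateaus(cp)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$start_win, 1L)
  expect_equal(pl$end_win, 100L)
})

test_that("an exactly constant series returns prior-level probabilities", {
  cp <- bcp_posterior(rep(0.02, 50), seed = 1)
  expect_true(all(cp$boundaries$prob <= 0.2))
  expect_equal(cp$windows$post_mean, rep(0.02, 50))
})

test_that("a single step is located within two windows", {
  set.seed(2)
  x <- c(rnorm(50, 0.027, 0.002), rnorm(50, 0.008, 0.002))
  cp <- bcp_posterior(x, seed = 2)
  expect_lte(abs(which.max(cp$boundaries$prob) - 50), 2)
  expect_gt(max(cp$boundaries$prob), 0.9)
  # posterior mean tracks the two levels
  expect_lt(abs(mean(cp$windows$post_mean[1:45]) - 0.027), 0.003)
  expect_lt(abs(mean(cp$windows$post_mean[56:100]) - 0.008), 0.003)
})

test_that("segmentation is invariant to affine rescaling of the series", {
  set.seed(3)
  x <- c(rnorm(40, 1, 0.3), rnorm(40, 3, 0.3))
  cp1 <- bcp_posterior(x, seed = 7)
  cp2 <- bcp_posterior(5 * x - 2, seed = 7)
  expect_equal(cp1$boundaries$prob, cp2$boundaries$prob, tolerance = 1e-12)
})

test_that("with p0 -> 0 the posterior mean collapses to the global mean", {
  set.seed(4)
  x <- c(rnorm(30, 1, 0.5), rnorm(30, 1.3, 0.5))
  cp <- bcp_posterior(x, p0 = 1e-9, seed = 4)
  expect_lt(max(abs(cp$windows$post_mean - mean(x))), 1e-6)
  expect_true(all(cp$boundaries$prob == 0))
})

test_that("a three-level series yields three ordered plateaus", {
  set.seed(5)
  x <- c(rnorm(210, 0.0232, 0.002), rnorm(30, 0.0164, 0.002),
         rnorm(20, 0.0095, 0.002))
  cp <- bcp_posterior(x, seed = 5)
  pl <- extract_plateaus(cp, mu = MU)
  expect_equal(nrow(pl), 3)
  expect_lte(abs(pl$end_win[1] - 210), 2)
  expect_lte(abs(pl$end_win[2] - 240), 2)
  expect_true(all(diff(pl$mean_div) < 0))
  expect_true(all(diff(pl$t_hat) < 0))  # split times follow divergence order
})

test_that("segments shorter than min_windows merge into the closer neighbour", {
  cp <- list(windows = tibble::tibble(index = 1:20,
                                      value = c(rep(1, 9), 1.05, rep(2, 10)),
                                      post_mean = NA),
             boundaries = tibble::tibble(after_index = 1:19, prob = 0))
  cp$boundaries$prob[c(9, 10)] <- 1  # isolates window 10 (value 1.05)
  class(cp) <- "bcp_result"
  pl <- extract_plateaus(cp, min_windows = 5)
  expect_equal(nrow(pl), 2)
  expect_equal(pl$end_win[1], 10L)  # short segment joined the left plateau
})

test_that("deterministic binary segmentation recovers a noise-free step", {
  x <- c(rep(0.027, 50), rep(0.008, 30))
  expect_equal(binseg_boundaries(x), 50L)
  expect_equal(binseg_boundaries(rep(0.01, 40)), integer(0))
})

test_that("landscape boundary recovery is reliable across replicates", {
  cfg <- sim_config()
  hits <- vapply(1:20, function(i) {
    land <- simulate_h_landscape(cfg, seed = 100 + i)
    cp <- bcp_posterior(land$h, seed = 200 + i)
    pl <- extract_plateaus(cp)
    bnd <- pl$end_win[-nrow(pl)]
    truth <- attr(land, "boundaries")
    all(vapply(truth, function(b) any(abs(bnd - b) <= 2), logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
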