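test_that("tanh threshold rule matches direct scalar evaluation", {
  # zero maps to zero for any parameters
  expect_identical(aldtf_threshold(0, 1, 1), 0)
  expect_identical(aldtf_threshold(0, 0.3, 7), 0)
  # alpha = 0 halves every coefficient (tanh(0) = 0)
  expect_equal(aldtf_threshold(2, 1, 0), 1.0)
  expect_equal(aldtf_threshold(c(-4, 0.2), 1, 0), c(-2, 0.1))
  # direct high-precision evaluation: (2/2) * (tanh(1) + 1)
  expect_equal(aldtf_threshold(2, 1, 1), 1.7615941559557649, tolerance = 1e-12)
  expect_equal(aldtf_threshold(-2, 1, 1), -1.7615941559557649, tolerance = 1e-12)
  # layer_rule interface is equivalent
  expect_identical(
    aldtf_threshold(c(1, 2, 3), layer_rule(2, 1, 1)),
    aldtf_threshold(c(1, 2, 3), 1, 1)
  )
})

test_that("tanh rule approaches hard thresholding for large alpha", {
  expect_equal(aldtf_threshold(3, 1, 1e8), hard_threshold(3, 1), tolerance = 1e-6)
  expect_equal(aldtf_threshold(0.5, 1, 1e8), hard_threshold(0.5, 1), tolerance = 1e-6)
  w <- seq(-5, 5, by = 0.037)
  w <- w[abs(abs(w) - 1) >= 1e-2] # stay away from the threshold boundary
  expect_equal(aldtf_threshold(w, 1, 1e8), hard_threshold(w, 1), tolerance = 1e-6)
})

test_that("tanh rule is a continuous, odd, monotone shrinker", {
  grid <- seq(-10, 10, length.out = 4001L)
  for (par in list(c(0.5, 0.2), c(1, 1), c(2, 8), c(0, 3))) {
    out <- aldtf_threshold(grid, par[1], par[2])
    expect_true(all(abs(out) <= abs(grid) + 1e-15)) # shrinkage
    expect_identical(aldtf_threshold(-grid, par[1], par[2]), -out) # odd, exact
    expect_true(all(diff(out) >= -1e-12)) # monotone in w
    # fixed point w/2 at the threshold for every alpha
    expect_equal(aldtf_threshold(par[1], par[1], par[2]), par[1] / 2)
  }
  # no jump at the threshold, unlike the hard rule
  eps <- 10^seq(-3, -8)
  gap <- abs(aldtf_threshold(1 + eps, 1, 5) - aldtf_threshold(1 - eps, 1, 5))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 1e-6)
})

test_that("soft and hard thresholding follow their definitions", {
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_identical(soft_threshold(c(-3, 0.4, 2.2), 0), c(-3, 0.4, 2.2))
  expect_equal(hard_threshold(2, 1), 2)
  expect_equal(hard_threshold(1, 1), 0) # boundary excluded
  expect_identical(hard_threshold(c(-3, 0.4, 2.2), 0), c(-3, 0.4, 2.2))
})

test_that("threshold functions reject invalid input", {
  expect_error(aldtf_threshold(c(1, NA), 1, 1), "finite")
  expect_error(aldtf_threshold(1, -0.1, 1), "threshold")
  expect_error(aldtf_threshold(1, 1, -2), "tuning")
  expect_error(soft_threshold(1, -1), "threshold")
  expect_error(hard_threshold(Inf, 1), "finite")
  expect_error(layer_rule(0, 1, 1), "level")
})
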