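test_that("metrics match hand-computed values", {
  x <- c(1, 1, 1, 1)
  yin <- c(1, 1, 1, -1)
  yout <- c(1, 1, 1, 0)
  expect_equal(snr(x, yout), 10 * log10(4), tolerance = 1e-12) # 6.0206 dB
  expect_equal(rmse(x, yout), 0.5)
  expect_equal(prd(x, yout), 50)
  expect_equal(sinad(x, yin, yout), 10 * log10(1 / 0.5), tolerance = 1e-12) # 3.0103 dB
})

test_that("degenerate and sentinel cases behave as documented", {
  x <- c(1, 2, 3)
  expect_identical(snr(x, x), Inf)
  expect_equal(rmse(x, x), 0)
  expect_equal(prd(x, x), 0)
  expect_equal(snr(x, numeric(3)), 0) # ratio exactly 1
  expect_error(snr(numeric(4), c(1, 2, 3, 4)), "zero")
  expect_error(snr(x, c(1, 2)), "length mismatch")
  expect_error(sinad(x, x, x), "undefined")
  # yout = x but yin differs: finite, driven by Pd alone
  expect_true(is.finite(sinad(x, x + 1, x)))
})

test_that("metric identities hold on random triples", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    x <- stats::rnorm(n)
    yin <- x + stats::rnorm(n)
    yout <- x + 0.3 * stats::rnorm(n)
    # snr and prd are two views of the same error ratio
    expect_equal(snr(x, yout), -20 * log10(prd(x, yout) / 100), tolerance = 1e-9)
    # rmse^2 * n recovers the summed squared error
    expect_equal(rmse(x, yout)^2 * n, sum((x - yout)^2), tolerance = 1e-9)
    # scale behavior
    expect_equal(rmse(2 * x, 2 * yout), 2 * rmse(x, yout), tolerance = 1e-12)
    expect_equal(prd(2 * x, 2 * yout), prd(x, yout), tolerance = 1e-12)
    expect_equal(sinad(2 * x, 2 * yin, 2 * yout), sinad(x, yin, yout),
                 tolerance = 1e-12)
    # permutation covariance
    p <- sample(n)
    expect_equal(snr(x[p], yout[p]), snr(x, yout), tolerance = 1e-12)
    expect_equal(sinad(x[p], yin[p], yout[p]), sinad(x, yin, yout),
                 tolerance = 1e-12)
  }
})

test_that("delta metrics follow the output-minus-input convention", {
  set.seed(22)
  x <- stats::rnorm(200)
  yin <- x + 0.5 * stats::rnorm(200)
  r0 <- delta_metrics(x, yin, yin)
  expect_equal(r0$delta_snr_db, 0)
  expect_equal(r0$delta_sinad_db, 0)
  r1 <- delta_metrics(x, yin, x)
  expect_identical(r1$delta_snr_db, Inf)
  yout <- x + 0.2 * stats::rnorm(200)
  r <- delta_metrics(x, yin, yout)
  # independent recomputation from the definitions
  expect_equal(r$delta_snr_db, snr(x, yout) - snr(x, yin), tolerance = 1e-12)
  expect_equal(r$delta_sinad_db,
               sinad(x, yin, yout) - sinad(x, yin, yin), tolerance = 1e-12)
  expect_equal(r$ps, mean(x^2))
  expect_gte(r$pn, 0)
  expect_gte(r$pd, 0)
})
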