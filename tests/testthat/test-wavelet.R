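# Frozen reference decomposition computed independently with PyWavelets
# (wavedec, bior6.8, symmetric mode, level 2) on a fixed random signal.
pywt_x <- c(1.028857, 1.64192, 1.14672, -0.97318, -1.3928, 0.067196, 0.861351, 0.509187, 1.810286, 0.750843, 0.63976, -0.731323, -1.107717, 1.484406, 0.048912, 0.81152, -1.376423, -0.436371, -1.291092, -0.775679, 0.903063, -1.480581, -0.534093, 0.163789, -0.66847, -0.25229, -0.221862, 0.418139, -0.431255, 0.272261, 0.056819, 0.424569)
pywt_cD1 <- c(-0.391198307526793, 0.574763538478325, -0.704124890354328, 0.449190894806425, -0.37354213716358, 0.583472957955969, -0.535118314349267, 0.847441161059457, 0.422521107818148, 0.276806050512088, -1.50477852265882, -0.895362230524666, -0.880688542897533, 0.476499174674407, 1.39426392539804, -0.77004297507663, -0.0497453139801924, -0.55136879253696, -0.347905653474867, -0.0922392252089375, 0.199799710906257, 0.602252370081545, 0.150622875763792, 0.509359835727315)
pywt_cD2 <- c(2.28145673224767, 0.139478199096848, 1.67227136202545, -0.726637550763845, 0.321084638195887, -1.5246565250317, -0.995885245235795, -0.847379229209295, 0.443194620791489, -1.87141626034945, 0.778996143798031, 0.526236246504725, -0.166380599437412, -0.00145709439410618, 0.359910964894153, 0.231069644602459, -0.424920090677524, -0.242220302666724, 0.186200467981432, -0.0442105044095469)
pywt_cA2 <- c(0.816798746440822, 0.595087864329269, 2.17249290825588, -0.558203708416048, 1.91857854532775, -0.706659947530951, 3.21695237256072, -1.09001724415402, 2.19537348711623, -0.0787741039910724, -0.634834384668785, -1.15372265018594, -0.675860557872752, 0.0978160823497305, 0.548411803155613, -0.163437520586032, -0.689822126341624, 0.346745637838764, 0.423413183960139, -0.339920203337529)

test_that("decomposition agrees with an independent reference implementation", {
  d <- dwt_decompose(pywt_x, levels = 2)
  expect_equal(d$details[[1]], pywt_cD1, tolerance = 1e-12)
  expect_equal(d$details[[2]], pywt_cD2, tolerance = 1e-12)
  expect_equal(d$approximation, pywt_cA2, tolerance = 1e-12)
})

test_that("decomposition has the expected structure", {
  s <- sampled_signal(stats::rnorm(500), fs = 100)
  d <- dwt_decompose(s, levels = 4)
  expect_s3_class(d, "wavelet_decomposition")
  expect_length(d$details, 4)
  expect_equal(d$levels, 4L)
  expect_equal(d$n, 500L)
  # band lengths follow floor((n + filter - 1) / 2) per level
  fl <- wavelet_filters("bior6.8")$length
  n <- 500L
  for (j in 1:4) {
    expect_length(d$details[[j]], (n + fl - 1L) %/% 2L)
    n <- (n + fl - 1L) %/% 2L
  }
  expect_length(d$approximation, n)
})

test_that("perfect reconstruction holds across lengths and depths", {
  set.seed(5)
  for (n in c(256, 500, 1000, 4096)) {
    x <- stats::rnorm(n)
    for (lev in 1:5) {
      y <- dwt_reconstruct(dwt_decompose(x, levels = lev))
      expect_lt(max(abs(y - x)), 1e-8)
    }
  }
})

test_that("a constant signal puts all energy in the approximation", {
  d <- dwt_decompose(rep(2.5, 300), levels = 3)
  for (j in 1:3) expect_lt(max(abs(d$details[[j]])), 1e-8)
  d$details <- lapply(d$details, function(v) numeric(length(v)))
  expect_lt(max(abs(dwt_reconstruct(d) - 2.5)), 1e-8)
})

test_that("the inverse transform is linear", {
  set.seed(6)
  x <- stats::rnorm(400)
  d <- dwt_decompose(x, levels = 3)
  d$details <- lapply(d$details, function(v) v / 2)
  d$approximation <- d$approximation / 2
  expect_lt(max(abs(dwt_reconstruct(d) - x / 2)), 1e-8)
})

test_that("sampling-rate metadata survives the round trip", {
  s <- sampled_signal(stats::rnorm(256), fs = 360, label = "probe")
  y <- dwt_reconstruct(dwt_decompose(s, levels = 2))
  expect_s3_class(y, "sampled_signal")
  expect_equal(y$fs, 360)
})

test_that("tampered coefficients and infeasible depths are rejected", {
  d <- dwt_decompose(stats::rnorm(128), levels = 2)
  d$details[[1]] <- d$details[[1]][-1]
  expect_error(dwt_reconstruct(d), "inconsistent")
  expect_error(dwt_decompose(stats::rnorm(4), levels = 8), "maximum feasible depth")
  expect_error(dwt_decompose(stats::rnorm(100), wavelet = "db4"), "unknown wavelet")
  expect_equal(dwt_max_levels(4096), 7L)
})
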