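test_that("mean lifetime is the amplitude-weighted component average", {
  expect_equal(mean_lifetime(biexp_params(1, 500, 2500)), 500)
  expect_equal(mean_lifetime(biexp_params(0.5, 400, 2400)), 1400)
  # convexity: tau1 <= tau_m <= tau2 for random valid parameter draws
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1); t1 <- runif(1, 100, 1000); t2 <- runif(1, t1, 5000)
    tm <- mean_lifetime(biexp_params(a, t1, t2))
    expect_true(t1 <= tm + 1e-12 && tm <= t2 + 1e-12)
  }
})

test_that("intensity integration is the plain bin sum", {
  expect_equal(integrate_intensity(rep(1, 256)), 256)
  expect_equal(integrate_intensity(numeric(64)), 0)
  set.seed(2)
  x <- rpois(100, 7)
  expect_equal(integrate_intensity(x), sum(x))
})

test_that("model_decay reduces to a pure exponential under a delta IRF", {
  irf <- delta_irf()
  p <- biexp_params(1, 800, 800, C = 0, amplitude = 1000)
  m <- model_decay(p, irf)
  tc <- (seq_len(256) - 0.5) * default_bw
  ref <- exp(-tc / 800)
  expect_equal(m / m[1], ref / ref[1], tolerance = 1e-6)
})

test_that("model_decay signal counts sum to the amplitude", {
  irf <- test_irf()
  for (a in c(0.2, 0.7, 1)) {
    p <- biexp_params(a, 300, 2600, C = 0, amplitude = 5e4)
    expect_equal(sum(model_decay(p, irf)), 5e4, tolerance = 1e-6 * 5e4)
  }
  # with background: total = amplitude + n_bins * C
  p <- biexp_params(0.6, 300, 2600, C = 2, amplitude = 1e4)
  expect_equal(sum(model_decay(p, irf)), 1e4 + 256 * 2, tolerance = 1e-2)
})

test_that("convolution matches a brute-force oracle and shifts the peak", {
  p <- biexp_params(0.75, 400, 2500, C = 0.3, amplitude = 1e4)
  irf <- test_irf(t0 = 1200, fwhm = 250)
  m <- model_decay(p, irf)
  # brute-force circular convolution oracle
  tc <- (seq_len(256) - 0.5) * default_bw
  f <- p$alpha1 * exp(-tc / 400) / (1 - exp(-256 * default_bw / 400)) +
    p$alpha2 * exp(-tc / 2500) / (1 - exp(-256 * default_bw / 2500))
  conv <- sapply(seq_len(256), function(i)
    sum(f[((i - seq_len(256)) %% 256) + 1] * irf$values))
  ref <- conv / sum(conv) * 1e4 + 0.3
  expect_equal(m, ref, tolerance = 1e-8)

  # a later IRF peak delays the decay peak
  md <- model_decay(p, delta_irf())
  expect_gt(which.max(m), which.max(md))

  # away from the rising edge an integer-bin IRF delay is a pure shift;
  # centre the Gaussian on a bin centre so the delay is a whole number
  # of bins (25) relative to the delta IRF in bin 1
  nb <- 25L
  mg <- model_decay(biexp_params(0.75, 400, 2500, C = 0, amplitude = 1e4),
                    test_irf(t0 = (nb + 0.5) * default_bw, fwhm = 60))
  md0 <- model_decay(biexp_params(0.75, 400, 2500, C = 0,
                                  amplitude = 1e4), delta_irf())
  aligned <- mg[(seq_len(256) - 1 + nb) %% 256 + 1]
  sel <- seq_len(256) > 4 * 60 / default_bw & md0 > 0.01 * max(md0)
  expect_lt(max(abs(aligned[sel] - md0[sel]) / md0[sel]), 0.02)
})

test_that("spatial_bin matches the brute-force neighbourhood oracle", {
  set.seed(3)
  for (rep in 1:50) {
    d <- c(sample(4:16, 1), sample(4:16, 1), sample(c(8, 16, 32), 1))
    arr <- array(as.numeric(rpois(prod(d), 3)), dim = d)
    r <- sample(0:1, 1)
    expect_equal(spatial_bin(arr, r), brute_bin(arr, r))
  }
})

test_that("spatial_bin identity, border truncation and validation", {
  arr <- array(1, dim = c(3, 3, 4))
  expect_identical(spatial_bin(arr, 0), arr)
  b <- spatial_bin(arr, 1)
  expect_equal(b[2, 2, 1], 9)
  expect_equal(b[1, 1, 1], 4)  # corner: truncated neighbourhood
  expect_equal(b[1, 2, 1], 6)  # edge
  expect_error(spatial_bin(arr, 2), "radius")
})

test_that("threshold_mask uses a >= comparison on the peak bin", {
  arr <- array(0, dim = c(1, 2, 4))
  arr[1, 1, 2] <- 49; arr[1, 2, 3] <- 50
  m <- threshold_mask(arr, 50)
  expect_identical(as.vector(m), c(FALSE, TRUE))
  expect_true(all(threshold_mask(arr, 0)))
  expect_error(threshold_mask(arr, -1), "non-negative")
})

test_that("noiseless monoexponential decay is recovered essentially exactly", {
  irf <- delta_irf()
  truth <- biexp_params(1, 2000, 2000, C = 0, amplitude = 5e4)
  obs <- model_decay(truth, irf)
  f <- fit_pixel(obs, irf, fit_config("NADPH"))
  expect_true(f$converged)
  expect_lt(abs(f$tau_m - 2000) / 2000, 0.001)
  # effectively monoexponential: either one component vanishes or the
  # two lifetimes coincide
  expect_true(f$params$alpha1 > 0.99 || f$params$alpha1 < 0.01 ||
                abs(f$params$tau2 - f$params$tau1) / 2000 < 0.01)
  expect_lt(f$chi2_red, 1e-4)
})

test_that("component exchange before sorting yields identical reports", {
  irf <- test_irf()
  truth <- biexp_params(0.7, 400, 2500, C = 0, amplitude = 5e4)
  obs <- model_decay(truth, irf)
  f1 <- fit_pixel(obs, irf, fit_config("NADPH",
                                       init = list(alpha1 = 0.7,
                                                   tau1 = 300,
                                                   tau2 = 2000)))
  # swapped initialization: start with the long component as "component 1"
  f2 <- fit_pixel(obs, irf, fit_config("NADPH",
                                       init = list(alpha1 = 0.3,
                                                   tau1 = 2000,
                                                   tau2 = 300)))
  expect_equal(f1$params$tau1, f2$params$tau1, tolerance = 1e-3)
  expect_equal(f1$params$tau2, f2$params$tau2, tolerance = 1e-3)
  expect_equal(f1$params$alpha1, f2$params$alpha1, tolerance = 1e-4)
  expect_true(f1$params$tau1 <= f1$params$tau2)
})

test_that("degenerate decays are flagged, never NaN", {
  irf <- test_irf()
  f <- fit_pixel(numeric(256), irf)
  expect_false(f$converged)
  expect_true(is.na(f$tau_m))
  expect_error(fit_pixel(numeric(100), irf), "length")
})

test_that("noisy biexponential recovery: tau_m within a few percent", {
  irf <- test_irf()
  truth <- biexp_params(0.75, 400, 2500, C = 0.05, amplitude = 5e4)
  m <- model_decay(truth, irf)
  tm_true <- mean_lifetime(truth)  # 925 ps
  expect_equal(tm_true, 0.75 * 400 + 0.25 * 2500)
  ests <- sapply(1:40, function(i) {
    set.seed(100 + i)
    f <- fit_pixel(rpois(256, m), irf, fit_config("NADPH"))
    c(tm = f$tau_m, a1 = f$params$alpha1, conv = f$converged,
      t1 = f$params$tau1, t2 = f$params$tau2)
  })
  expect_true(all(ests["conv", ] == 1))
  expect_lt(median(abs(ests["tm", ] - tm_true)) / tm_true, 0.03)
  expect_lt(median(abs(ests["a1", ] - 0.75)), 0.05)
  # convexity for every converged fit
  expect_true(all(ests["t1", ] <= ests["tm", ] + 1e-9 &
                    ests["tm", ] <= ests["t2", ] + 1e-9))
})

test_that("fit_image on a noiseless field reproduces ground truth", {
  irf <- test_irf()
  tr <- manual_truths(cx = 12, cy = 12, ax = 5, ay = 5, photons = 1200,
                      background = 0.05)
  sc <- render_field(tr, irf, small_optics(), seed = 1, noise = FALSE)
  fm <- fit_image(sc$nadph, irf, fit_config("NADPH"))
  tm_true <- 0.75 * 400 + 0.25 * 2500
  inside <- sc$mask == 1L & fm$valid
  expect_gt(sum(inside), 20)
  rel <- abs(fm$tau_m[inside] - tm_true) / tm_true
  expect_lt(max(rel), 0.005)
})

test_that("a threshold above the global maximum yields an empty fit map", {
  irf <- test_irf()
  tr <- manual_truths(cx = 12, cy = 12, photons = 500)
  sc <- render_field(tr, irf, small_optics(), seed = 2)
  expect_warning(
    fm <- fit_image(sc$nadph, irf,
                    fit_config("NADPH", min_peak_counts = 1e9)),
    "threshold")
  expect_equal(sum(fm$valid), 0)
  expect_true(all(is.na(fm$tau_m)))
})
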