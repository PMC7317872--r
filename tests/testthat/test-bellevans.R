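test_that("forward Bell-Evans force has the exact logarithmic identities", {
  p <- bell_evans_params(tau0 = 1.86, x_beta = 0.55, kBT = 4.11)
  # argument exactly 1 -> zero force
  expect_equal(bell_evans_force(p$kBT / (p$x_beta * p$tau0), p), 0)
  # argument e -> kBT/x_beta
  expect_equal(bell_evans_force(exp(1) * p$kBT / (p$x_beta * p$tau0), p),
               p$kBT / p$x_beta, tolerance = 1e-12)
  # below threshold clamps at zero, not negative
  expect_equal(bell_evans_force(0.5 * p$kBT / (p$x_beta * p$tau0), p), 0)
})

test_that("rupture-force sampler matches the quadrature CDF and the analytic mode", {
  # mode check at the strong-state parameters and the loading rate at which
  # the tether contour-length distribution was characterized
  p <- bell_evans_params(tau0 = 1224.2, x_beta = 0.31, kBT = 4.11)
  f <- sample_rupture_forces(p, loading_rate = 13841, n = 1e5, seed = 42)
  d <- stats::density(f, adjust = 1.8, n = 4096)
  # parabolic refinement of the log-density around the kernel peak: the
  # wide kernel keeps the variance down and the local fit removes most of
  # the smoothing-induced shift of the skewed peak
  i <- which.max(d$y)
  win <- abs(d$x - d$x[i]) < 1.2 * d$bw
  cf <- stats::coef(stats::lm(log(d$y[win]) ~ stats::poly(d$x[win], 2,
                                                          raw = TRUE)))
  mode_hat <- -cf[[2]] / (2 * cf[[3]])
  expect_lt(abs(mode_hat - analytic_mode(1224.2, 0.31, 4.11, 13841)), 1)
  expect_lt(abs(mode_hat - bell_evans_force(13841, p)), 1)

  # KS statistic vs the quadrature oracle across lifetimes spanning 1-2000 s
  for (tau0 in c(1, 50, 2000)) {
    pp <- bell_evans_params(tau0 = tau0, x_beta = 0.4, kBT = 4.11)
    ff <- sort(sample_rupture_forces(pp, 5000, 1e5, seed = tau0))
    cdf <- quadrature_rupture_cdf(stats::quantile(ff, seq(0.01, 0.99, by = 0.02)),
                                  tau0, 0.4, 4.11, 5000)
    ks <- max(abs(cdf - seq(0.01, 0.99, by = 0.02)))
    expect_lt(ks, 0.01)
  }
})

test_that("deep thermal regime puts the sampled mode at vanishing force", {
  # koff*kBT/(x_beta*r) >> 1: most ruptures occur before force builds up
  p <- bell_evans_params(tau0 = 1e-4, x_beta = 0.5, kBT = 4.11)
  f <- sample_rupture_forces(p, loading_rate = 10, n = 2e4, seed = 1)
  expect_lt(stats::median(f), 1)
  expect_equal(bell_evans_force(10, p), 0)
})

test_that("sampling is reproducible for a fixed seed and validates inputs", {
  p <- bell_evans_params(1.86, 0.55)
  expect_identical(sample_rupture_forces(p, 1e4, 100, seed = 7),
                   sample_rupture_forces(p, 1e4, 100, seed = 7))
  expect_error(sample_rupture_forces(p, -5, 10), "positive")
  expect_error(sample_rupture_forces(p, 1e4, 0), "n")
})

test_that("Bell-Evans fit inverts noiseless data exactly and obeys the log law", {
  p <- bell_evans_params(tau0 = 1.86, x_beta = 0.55, kBT = 4.11)
  vF <- 10^seq(3, 5.2, length.out = 7)
  pts <- data.frame(vF = vF, Fmp = bell_evans_force(vF, p))
  fit <- fit_bell_evans(pts, kBT = 4.11)
  expect_equal(fit$tau0, 1.86, tolerance = 1e-8)
  expect_equal(fit$x_beta, 0.55, tolerance = 1e-8)
  # doubling every loading rate raises each predicted force by (kBT/xb)*ln 2
  f2 <- bell_evans_force(2 * vF, p) - bell_evans_force(vF, p)
  expect_equal(f2, rep(4.11 / 0.55 * log(2), 7), tolerance = 1e-12)
  # unphysical negative slope errors out
  bad <- data.frame(vF = vF, Fmp = rev(pts$Fmp))
  expect_error(fit_bell_evans(bad), "slope")
})

test_that("self-consistent loading rate is a fixed point of the compliance correction", {
  tether <- fjc_params()
  pull <- pulling_config(v = 2000)
  p <- bell_evans_params(1.86, 0.55)
  r <- self_consistent_loading_rate(p, pull, tether)
  expect_equal(r$vF, effective_loading_rate(r$F_mode, pull, tether),
               tolerance = 1e-6)
  expect_equal(r$F_mode, bell_evans_force(r$vF, p), tolerance = 1e-6)
  expect_lt(r$vF, pull$kc * pull$v)
})
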