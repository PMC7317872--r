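test_that("Scott's rule bin width is 3.49*sd*n^(-1/3), linear in sd", {
  set.seed(1)
  x <- stats::rnorm(1000)
  expect_equal(scott_bin_width(x), 3.49 * stats::sd(x) * 0.1)
  z <- c(-1, 0, 1, 2, -2, 0.5, -0.5, 0)
  expect_equal(scott_bin_width(z), 3.49 * stats::sd(z) / 2)
  expect_equal(scott_bin_width(10 * z), 10 * scott_bin_width(z))
  expect_error(scott_bin_width(rep(1, 10)), "degenerate")
  expect_error(scott_bin_width(1), "at least 2")
})

test_that("fit_fjc recovers the tether from a noiseless curve and ignores flat noise", {
  tether <- fjc_params(58.7, 0.7)
  cv <- make_force_curve(tether, pulling_config(v = 2000, noise_sd = 0), 70,
                         seed = 1)
  f <- fit_fjc(cv, noise_sd = 0.5)
  expect_false(f$no_event)
  expect_lt(abs(f$params$Lc - 58.7) / 58.7, 0.005)
  expect_lt(f$residual, 0.5)
  expect_equal(f$F_rupture, 70, tolerance = 0.01)
  # pure-noise baseline: classified no-event
  set.seed(2)
  flat <- force_curve(seq(0, 120, length.out = 400),
                      stats::rnorm(400, 0, 5), v = 2000, kc = 20,
                      sampling_rate = 6000)
  expect_true(fit_fjc(flat, noise_sd = 5)$no_event)
})

test_that("event selection keeps single ruptures, rejects doubles, and recovers planted forces", {
  tether <- fjc_params()
  pull <- pulling_config(v = 2000, noise_sd = 5)
  mix <- two_state_mixture()
  curves <- make_dfs_dataset(mix, tether, list(pull), n_per_speed = 120,
                             event_fraction = 1, seed = 31)
  ev <- select_single_events(curves, noise_sd = 5)
  expect_gt(nrow(ev), 100)
  man <- attr(curves, "manifest")
  m <- merge(ev, man, by = "id")
  frac <- mean(abs(m$F_rupture_pN - m$planted_force_pN) < 3 * 5)
  expect_gte(frac, 0.95)

  # a curve with two rupture drops violates the single-molecule criterion
  c1 <- make_force_curve(fjc_params(30, 0.7), pull, 55, seed = 32)
  c2 <- make_force_curve(fjc_params(58.7, 0.7), pull, 70, seed = 33)
  double <- force_curve(c(c1$extension, c1$extension[length(c1$extension)] +
                            c2$extension),
                        c(c1$force, c2$force), v = 2000, kc = 20,
                        sampling_rate = 6000, id = "double")
  expect_equal(nrow(select_single_events(list(double), noise_sd = 5)), 0)
})

test_that("event yield and the false-positive rate match the single-molecule regime", {
  tether <- fjc_params()
  mix <- two_state_mixture()
  pulls <- list(pulling_config(v = 2000), pulling_config(v = 7500))
  curves <- make_dfs_dataset(mix, tether, pulls, n_per_speed = 250,
                             event_fraction = 0.08, seed = 34)
  ev <- select_single_events(curves, noise_sd = 5)
  yield <- nrow(ev) / length(curves)
  expect_gte(yield, 0.05)
  expect_lte(yield, 0.10)

  # pure-noise retractions: false positives must stay below 0.5%
  set.seed(35)
  blanks <- lapply(1:300, function(i) {
    force_curve(seq(0, 120, length.out = 700),
                stats::rnorm(700, 0, 5), v = 2000, kc = 20,
                sampling_rate = 6000, id = paste0("blank", i))
  })
  fp <- nrow(select_single_events(blanks, noise_sd = 5)) / 300
  expect_lt(fp, 0.005)
})

test_that("force-distribution fitting finds the planted components and guards against overfitting", {
  kBT <- 4.11
  low <- bell_evans_params(1.86, 0.55, kBT)
  high <- bell_evans_params(1224.2, 0.31, kBT)
  f_low <- sample_rupture_forces(low, 14000, 800, seed = 41)
  f_high <- sample_rupture_forces(high, 34000, 800, seed = 42)

  fit1 <- fit_force_distribution(f_low, n_components = 1)
  d <- stats::density(f_low, n = 2048)
  expect_lt(abs(fit1$components$Fmp - d$x[which.max(d$y)]), 1.5)

  fit2 <- fit_force_distribution(c(f_low, f_high), n_components = 2)
  expect_equal(fit2$n_components, 2)
  # the LSQ Gaussian mean of a skewed first-passage histogram sits a few
  # piconewtons below the analytic mode; allow for that known offset
  expect_lt(abs(fit2$components$Fmp[1] - analytic_mode(1.86, 0.55, kBT, 14000)), 5)
  expect_lt(abs(fit2$components$Fmp[2] - analytic_mode(1224.2, 0.31, kBT, 34000)), 6)

  # two components requested on unimodal data: must fall back, not split
  expect_warning(funi <- fit_force_distribution(f_low, n_components = 2),
                 "falling back")
  expect_equal(funi$n_components, 1)

  # posterior state assignment splits a well-separated mixture cleanly
  states <- assign_states(c(f_low, f_high), fit2)
  expect_gt(mean(states[1:800] == 1), 0.97)
  expect_gt(mean(states[801:1600] == 2), 0.97)

  expect_error(fit_force_distribution(f_low[1:10], 1), "30")
})

test_that("a single-state dataset analysed against the mixture overlays the low-force component", {
  # the weak state measured alone lands on the low-force component of the
  # two-state mixture: same generator state, same analysis window
  kBT <- 4.11
  tether <- fjc_params()
  pull <- pulling_config(v = 2000)
  low <- bell_evans_params(1.86, 0.55, kBT)
  r <- self_consistent_loading_rate(low, pull, tether, kBT)
  f_alone <- sample_rupture_forces(low, r$vF, 600, seed = 51)
  mixed <- c(f_alone,
             sample_rupture_forces(bell_evans_params(1224.2, 0.31, kBT),
                                   self_consistent_loading_rate(
                                     bell_evans_params(1224.2, 0.31, kBT),
                                     pull, tether, kBT)$vF, 600, seed = 52))
  f1 <- fit_force_distribution(f_alone, 1)
  f2 <- fit_force_distribution(mixed, 2)
  expect_lt(abs(f1$components$Fmp - f2$components$Fmp[1]), 2.5)
})
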