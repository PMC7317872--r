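test_that("simulated force curves are self-consistent with the FJC they sample", {
  tether <- fjc_params()
  pull <- pulling_config(v = 2000, noise_sd = 0)
  cv <- make_force_curve(tether, pull, rupture_force = 80, seed = 1)
  # noiseless curve: the force at any pre-rupture extension equals the FJC
  # inversion at that extension
  pre <- which(cv$force > 1 & cv$extension < 0.99 * tether$Lc)
  i <- pre[length(pre)]
  expect_equal(cv$force[i], fjc_force(cv$extension[i], tether),
               tolerance = 1e-6)
  # last above-baseline sample carries the planted rupture force
  i_last <- max(which(cv$force > 40))
  expect_equal(cv$force[i_last], 80, tolerance = 1e-9)
  expect_true(all(diff(cv$extension) >= 0))
})

test_that("noisy curves carry the rupture force within the noise", {
  tether <- fjc_params()
  pull <- pulling_config(v = 2000, noise_sd = 5)
  errs <- vapply(1:40, function(i) {
    cv <- make_force_curve(tether, pull, 70, seed = i)
    max(cv$force[max(which(stats::runmed(cv$force, 3) > 35))]) - 70
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3)
  expect_true(all(abs(errs) < 4 * 5))
})

test_that("generators are bit-identical under a fixed seed", {
  tether <- fjc_params()
  pull <- pulling_config(v = 5000)
  c1 <- make_force_curve(tether, pull, 60, seed = 3)
  c2 <- make_force_curve(tether, pull, 60, seed = 3)
  expect_identical(c1$force, c2$force)
  mix <- two_state_mixture()
  d1 <- make_dfs_dataset(mix, tether, list(pull), 10, seed = 4)
  d2 <- make_dfs_dataset(mix, tether, list(pull), 10, seed = 4)
  expect_identical(lapply(d1, `[[`, "force"), lapply(d2, `[[`, "force"))
  t1 <- make_fret_traces(0.6, 5, seed = 5)
  t2 <- make_fret_traces(0.6, 5, seed = 5)
  expect_identical(t1[[3]]$acceptor, t2[[3]]$acceptor)
  s1 <- make_se_scans(se_ground_truth(), seed = 6)
  s2 <- make_se_scans(se_ground_truth(), seed = 6)
  expect_identical(s1[[2]]$A, s2[[2]]$A)
  x1 <- make_saxs_profile(sphere_model(), seed = 7)
  x2 <- make_saxs_profile(sphere_model(), seed = 7)
  expect_identical(x1$I, x2$I)
  a1 <- make_anisotropy_decay(0.3, 0.4, 0.5, 0.6, 10, seed = 8)
  a2 <- make_anisotropy_decay(0.3, 0.4, 0.5, 0.6, 10, seed = 8)
  expect_identical(a1$I_parallel, a2$I_parallel)
})

test_that("dfs dataset respects the event fraction and mixture structure", {
  tether <- fjc_params()
  mix <- two_state_mixture()
  pulls <- list(pulling_config(v = 2000), pulling_config(v = 7500))
  curves <- make_dfs_dataset(mix, tether, pulls, n_per_speed = 150,
                             event_fraction = 0.08, seed = 9)
  man <- attr(curves, "manifest")
  expect_equal(nrow(man), 300)
  frac <- mean(!is.na(man$planted_force_pN))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.15)
  expect_error(make_dfs_dataset(mix, tether, list(), 10), "non-empty")
  expect_error(make_dfs_dataset(mix, tether, pulls, 10, event_fraction = 0),
               "event_fraction")
})

test_that("FRET traces conserve total intensity and honour degenerate efficiencies", {
  traces <- make_fret_traces(0.45, n_traces = 8, I_total = 500,
                             bg_donor = 50, bg_acceptor = 50, seed = 10)
  bleach <- attr(traces, "bleach_frame")
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    pre <- seq_len(max(bleach[i] - 1, 1))
    tot <- mean(tr$donor[pre] + tr$acceptor[pre]) - 100
    expect_lt(abs(tot - 500) / 500, 0.1)
  }
  # E_true = 0: acceptor sits at background throughout
  dark <- make_fret_traces(0, n_traces = 3, seed = 11)
  for (tr in dark) {
    expect_lt(abs(mean(tr$acceptor) - tr$bg_acceptor), 5)
  }
  expect_error(make_fret_traces(1.2, 5), "E_true")
})

test_that("anisotropy generator reproduces the model identities", {
  t <- seq(0, 30, by = 0.05)
  d <- make_anisotropy_decay(0.32, 0.4, 0.5, 0.6, 10, t_grid = t,
                             noise_sd = 0, seed = 1)
  rt <- anisotropy_curve(d)
  # r(0) = r0*(A1+A2)
  expect_equal(rt$r[1], 0.32 * (0.4 + 0.6), tolerance = 1e-9)
  # single-exponential case: ln r linear in t with slope -1/phi1
  d1 <- make_anisotropy_decay(0.3, 1, 2, 0, 1, t_grid = t, noise_sd = 0)
  r1 <- anisotropy_curve(d1)
  slope <- stats::coef(stats::lm(log(r1$r) ~ r1$t))[[2]]
  expect_equal(slope, -1 / 2, tolerance = 1e-8)
})

test_that("SE scans obey mass action, flatten at zero speed, and share ground truth across speeds", {
  truth <- se_ground_truth()
  sp <- species_params()
  scans <- make_se_scans(truth, noise_sd = 0)
  crefs <- attr(scans, "c_ref")
  for (k in seq_along(scans)) {
    sc <- scans[[k]]
    sig <- reduced_buoyant_term(sp, sc$omega, sc$T_K)
    cm <- crefs[k] * exp(sig * (sc$r^2 - sc$meniscus^2) / 2)
    cd <- (crefs[k]^2 / truth$KD) * exp(2 * sig * (sc$r^2 - sc$meniscus^2) / 2)
    # mass action holds at every radius by construction
    expect_equal(cd, cm^2 / truth$KD, tolerance = 1e-12)
    # and the profile decomposes into exactly these two species
    expect_equal(sc$A, sp$eps_l * (cm + 2 * cd), tolerance = 1e-10)
    expect_true(all(diff(sc$A) > 0))
  }
  # omega = 0: flat profile at the loading absorbance
  flat <- make_se_scans(se_ground_truth(speeds_rpm = 0), noise_sd = 0)
  expect_lt(diff(range(flat[[1]]$A)), 1e-10)
  expect_equal(mean(flat[[1]]$A), truth$eps_l *
                 (crefs_flat <- attr(flat, "c_ref")[1]) +
                 2 * truth$eps_l * crefs_flat^2 / truth$KD, tolerance = 1e-9)
  # KD -> infinity: ideal single-species exponential in r^2
  mono <- make_se_scans(se_ground_truth(KD = 1e6), noise_sd = 0)
  sc <- mono[[3]]
  sig <- reduced_buoyant_term(sp, sc$omega, sc$T_K)
  fitl <- stats::lm(log(sc$A) ~ I(sc$r^2 / 2))
  expect_equal(stats::coef(fitl)[[2]], sig, tolerance = 1e-6)
  expect_error(se_ground_truth(vbar = 1.1), "float")
})

test_that("sphere profile approaches I0 at low q and carries its noise level in sigma", {
  m <- sphere_model(R = 3, I0 = 7, q_grid = seq(0.005, 2, by = 0.005),
                    noise_frac = 0)
  prof <- make_saxs_profile(m)
  expect_equal(prof$I[1], 7, tolerance = 1e-3)
  noisy <- make_saxs_profile(sphere_model(R = 3, noise_frac = 0.01), seed = 2)
  ref <- make_saxs_profile(sphere_model(R = 3, noise_frac = 0))
  z <- (noisy$I - ref$I) / noisy$sigma
  expect_lt(abs(stats::sd(z) - 1), 0.15)
})
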