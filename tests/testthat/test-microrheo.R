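test_that("MSD matches closed forms and the exhaustive pairwise oracle", {
  t <- seq(0, 9.9, by = 0.1)
  # stationary particle: zero at all lags
  still <- particle_track(1, t, rep(2, length(t)), rep(-1, length(t)))
  cv <- compute_msd(still, min_pairs = 1)
  expect_true(all(cv$msd == 0))

  # ballistic track x = v t: msd(tau) = v^2 tau^2 exactly
  v <- 1.7
  ball <- particle_track(1, t, v * t, rep(0, length(t)))
  cb <- compute_msd(ball, min_pairs = 1)
  expect_equal(cb$msd, v^2 * cb$tau^2, tolerance = 1e-10)

  # arbitrary 3-particle fixture: exact equality with the brute-force
  # double loop over all frame pairs
  set.seed(31)
  tracks <- lapply(1:3, function(p) {
    particle_track(p, seq(0, 4.9, by = 0.1), cumsum(rnorm(50)),
                   cumsum(rnorm(50)))
  })
  fast <- compute_msd(tracks, max_lag_fraction = 0.25, min_pairs = 1)
  slow <- msd_oracle(tracks, max_lag = 12)
  expect_equal(fast$tau, slow$tau, tolerance = 1e-12)
  expect_equal(fast$msd, slow$msd, tolerance = 1e-12)
})

test_that("MSD input validation enforces sampling and pair-count rules", {
  expect_error(compute_msd(list()), "no tracks")
  expect_error(particle_track(1, c(0, 0.1, 0.3), 1:3, 1:3), "irregular")
  tr <- particle_track(1, c(0, 0.1, 0.3), 1:3, 1:3, allow_irregular = TRUE)
  expect_s3_class(tr, "particle_track")
  # lags with fewer pairs than the minimum are dropped
  short <- particle_track(1, seq(0, 0.5, by = 0.1), 1:6, 1:6)
  cv <- compute_msd(list(short), max_lag_fraction = 1, min_pairs = 4)
  expect_lte(max(cv$tau), 0.2 + 1e-12)  # lags 1-2 have >= 4 pairs
})

test_that("log-slope diagnostics classify free, anomalous and arrested probes", {
  # flat (plateaued) curve has slope 0
  flat <- structure(list(tau = c(0.1, 0.2, 0.4, 0.8), msd = rep(0.05, 4),
                         n_pairs = rep(100, 4), cure_time = NA),
                    class = "msd_curve")
  expect_equal(msd_log_slope(flat), 0, tolerance = 1e-12)

  # seeded Brownian ensemble: slope about 1
  tr <- generate_tracks("brownian", n_particles = 60, n_frames = 400,
                        dt = 0.1, d = 0.1, seed = 8)
  s <- msd_log_slope(compute_msd(tr), fit_window = c(0.1, 1))
  expect_lt(abs(s - 1), 0.05)

  # subdiffusive generator with alpha = 0.5 recovers its exponent
  trs <- generate_tracks("subdiffusive", n_particles = 100, n_frames = 300,
                         dt = 0.1, d = 0.1, alpha = 0.5, seed = 9)
  ss <- msd_log_slope(compute_msd(trs), fit_window = c(0.1, 2))
  expect_lt(abs(ss - 0.5), 0.05)

  expect_error(msd_log_slope(structure(list(tau = 1:2, msd = 1:2),
                                       class = "msd_curve")), "3 lags")
  bad <- structure(list(tau = c(1, 2, 3), msd = c(1, 0, 2)),
                   class = "msd_curve")
  expect_error(msd_log_slope(bad), "positive")
})

test_that("trajectory generator reproduces its configured transport laws", {
  # 2D free diffusion: MSD(1 s) = 4 D tau = 0.4 within 10%
  tr <- generate_tracks("brownian", n_particles = 100, n_frames = 1000,
                        dt = 0.1, d = 0.1, seed = 2)
  cv <- compute_msd(tr)
  m1 <- cv$msd[which.min(abs(cv$tau - 1))]
  expect_lt(abs(m1 - 0.4) / 0.4, 0.10)

  # arrested probes plateau at the configured amplitude within 10%
  ta <- generate_tracks("arrested", n_particles = 150, n_frames = 400,
                        dt = 0.1, plateau = 0.1, relax_time = 0.5, seed = 3)
  ca <- compute_msd(ta)
  plateau_est <- mean(ca$msd[ca$tau > 5])
  expect_lt(abs(plateau_est - 0.1) / 0.1, 0.10)

  # determinism and validation
  a <- generate_tracks("brownian", n_particles = 2, n_frames = 50, seed = 4)
  b <- generate_tracks("brownian", n_particles = 2, n_frames = 50, seed = 4)
  expect_identical(a, b)
  expect_error(generate_tracks("subdiffusive", alpha = 1.5), "exponent")
})

test_that("Brownian log-slope tightens toward 1 with ensemble size", {
  dev_for <- function(n) {
    tr <- generate_tracks("brownian", n_particles = n, n_frames = 300,
                          dt = 0.1, d = 0.1, seed = 21)
    abs(msd_log_slope(compute_msd(tr), fit_window = c(0.1, 1)) - 1)
  }
  expect_lt(dev_for(200), dev_for(10) + 0.02)
  expect_lt(dev_for(200), 0.03)
})

test_that("sigmoidal gel-point fit recovers the logistic midpoint", {
  # noiseless logistic: exact self-fit
  clean <- synth_relaxation_series(noise_sd = 0, midpoint = 8.0,
                                   cure_times = seq(2, 14, by = 1))
  f <- fit_gelation_sigmoid(clean$cure_time, clean$slope)
  expect_equal(f$t_gel, 8.0, tolerance = 1e-4)
  expect_equal(f$plateau, 0.03, tolerance = 1e-4)

  # noisy recovery at the reported uncertainty scale
  errs <- vapply(1:10, function(s) {
    d <- synth_relaxation_series(midpoint = 8.1, noise_sd = 0.05, seed = s)
    fit_gelation_sigmoid(d$cure_time, d$slope)$t_gel - 8.1
  }, numeric(1))
  expect_true(all(abs(errs) < 0.4))

  # constant series: no transition
  expect_error(fit_gelation_sigmoid(1:6, rep(0.5, 6)), "no gel point")
})

test_that("time-cure superposition recovers the constructed gel point", {
  fam <- synth_msd_family(n = 0.6, t_c = 7.5)
  res <- time_cure_superposition(fam)
  expect_lt(abs(res$t_gel - 7.5) / 7.5, 0.15)
  expect_lt(abs(res$n_c - 0.6), 0.05)
  # reference curves carry zero shift
  sf <- res$shift_factors
  pre_ref <- sf[sf$branch == "pre", ]
  expect_equal(pre_ref$log_a[which.max(pre_ref$cure_time)], 0)
  expect_equal(pre_ref$log_b[which.max(pre_ref$cure_time)], 0)

  # order invariance
  res2 <- time_cure_superposition(rev(fam))
  expect_equal(res2$t_gel, res$t_gel, tolerance = 1e-12)
  expect_equal(res2$n_c, res$n_c, tolerance = 1e-9)

  # identical curves: no divergence to locate
  same <- lapply(1:10, function(i) {
    structure(list(tau = fam[[1]]$tau, msd = fam[[1]]$msd,
                   n_pairs = fam[[1]]$n_pairs, cure_time = i),
              class = "msd_curve")
  })
  expect_error(time_cure_superposition(same), "superposition error")
})
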