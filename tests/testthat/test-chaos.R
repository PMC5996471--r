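test_that("correlation sum counts pairs exactly as the literal double loop", {
  # two points at distance 1
  two <- rbind(c(0, 0), c(1, 0))
  cs_wide <- correlation_sum(two, radii = c(0.5, 2), theiler = 0)
  expect_equal(cs_wide$c_values, c(0, 1))

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    m <- sample(1:5, 1)
    w <- sample(0:3, 1)
    pts <- matrix(rnorm(n * m), n)
    radii <- sort(runif(8, 0.1, 4))
    got <- correlation_sum(pts, radii = radii, theiler = w)
    expect_identical(got$c_values, corr_sum_oracle(pts, radii, w))
  }
})

test_that("correlation sum is monotone and saturates at the attractor diameter", {
  tr <- embed_delay(as.matrix(generate_map_series(
    signal_spec("henon", 500, seed = 2)))[, 1], m = 2, lag = 1)
  diam <- max(stats::dist(unclass(tr)))
  cs <- correlation_sum(tr, radii = exp(seq(log(1e-3), log(diam + 1),
                                            length.out = 30)),
                        theiler = 0)
  expect_true(all(diff(cs$c_values) >= 0))
  expect_equal(cs$c_values[30], 1)
  expect_true(all(cs$c_values <= 1))
})

test_that("scaling-region fit recovers the dimension of geometric sets", {
  # uniform points on a 1-D segment embedded in 3-D
  set.seed(5)
  n <- 4000
  dir3 <- c(1, 2, -1) / sqrt(6)
  line <- outer(runif(n), dir3)
  cd_line <- estimate_cd(correlation_sum(line, theiler = 0))
  expect_gt(cd_line$cd, 0.85)
  expect_lt(cd_line$cd, 1.15)
  expect_gt(cd_line$r_squared, 0.99)

  square <- cbind(runif(n), runif(n))
  cd_sq <- estimate_cd(correlation_sum(square, theiler = 0))
  expect_gt(cd_sq$cd, 1.75)
  expect_lt(cd_sq$cd, 2.15)

  # explicit fit bounds are honoured
  cs <- correlation_sum(square, theiler = 0)
  cd_b <- estimate_cd(cs, fit_lo_r = cs$radii[5], fit_hi_r = cs$radii[15])
  expect_equal(cd_b$n_fit_points, 11)
  expect_error(estimate_cd(cs, fit_lo_r = 100, fit_hi_r = 200), "usable")
})

test_that("white noise fills the embedding space (no low-dimensional scaling)", {
  w <- generate_flow_series(signal_spec("white_noise", 6000, 500,
                                        list(sd = 10), seed = 9))
  cd <- correlation_dimension(w, m = 10, lag = 1)
  expect_gt(cd$cd, 3)
})

test_that("Rosenstein LLE matches the analytic exponent of the logistic map", {
  x <- generate_map_series(signal_spec("logistic", 5000, seed = 11))
  fit <- lyapunov_max(x, m = 2, lag = 1)
  expect_lt(abs(fit$lle - log(2)), 0.1)
  # independent derivative-sum oracle: lambda = <ln |f'(x)|> = ln 2
  xv <- as.matrix(x)[, 1]
  oracle <- mean(log(abs(4 - 8 * xv)))
  expect_lt(abs(fit$lle - oracle), 0.1)

  # determinism: identical epochs give identical fits
  fit2 <- lyapunov_max(x, m = 2, lag = 1)
  expect_identical(fit$lle, fit2$lle)
})

test_that("periodic signals do not diverge: LLE is at most 0.01 per step", {
  s <- sine_epoch(3000, 100, freq = 4)
  fit <- lyapunov_max(s, m = 2, lag = 6)
  expect_lte(fit$lle, 0.01)
})

test_that("CD and LLE are invariant to amplitude scaling", {
  e <- generate_normal_epoch(signal_spec("normal_eeg", 3000, 500, seed = 6))
  v <- as.matrix(e)[, 1]
  cd1 <- correlation_dimension(v, m = 5, lag = 2)
  cd2 <- correlation_dimension(3.7 * v, m = 5, lag = 2)
  expect_equal(cd1$cd, cd2$cd, tolerance = 1e-6)
  ll1 <- lyapunov_max(v, m = 5, lag = 2)
  ll2 <- lyapunov_max(3.7 * v, m = 5, lag = 2)
  expect_equal(ll1$lle, ll2$lle, tolerance = 1e-6)
})

test_that("per-epoch features are deterministic and ordered by complexity", {
  tp <- bandpass(generate_triphasic_epoch(
    signal_spec("enceph_eeg", 6000, 500, seed = 31)))
  ne <- bandpass(generate_normal_epoch(
    signal_spec("normal_eeg", 6000, 500, seed = 32)))
  f_tp <- chaos_features(tp, epoch_id = "tw")
  f_ne <- chaos_features(ne, epoch_id = "broadband")
  expect_lt(f_tp$cd, f_ne$cd)
  f_tp2 <- chaos_features(tp, epoch_id = "tw")
  expect_identical(f_tp$cd, f_tp2$cd)
  expect_identical(f_tp$lle, f_tp2$lle)
  # config snapshot recorded for provenance
  expect_equal(f_tp$config$m, 10L)
  expect_equal(f_tp$config$theiler, 10L)
})

test_that("multi-channel epochs reduce to the mean of per-channel features", {
  sp <- signal_spec("enceph_eeg", 3000, 500, list(channels = 2L), seed = 12)
  e <- generate_triphasic_epoch(sp)
  expect_equal(ncol(as.matrix(e)), 2)
  f <- chaos_features(e, m = 5)
  f1 <- chaos_features(eeg_epoch(as.matrix(e)[, 1], 500), m = 5)
  f2 <- chaos_features(eeg_epoch(as.matrix(e)[, 2], 500), m = 5)
  expect_equal(f$cd, (f1$cd + f2$cd) / 2, tolerance = 1e-12)
  expect_equal(f$lle, (f1$lle + f2$lle) / 2, tolerance = 1e-12)
})
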