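test_that("logistic map generator respects the bounded regime and its invariant density", {
  expect_error(generate_map_series(signal_spec("logistic", 100,
                                               params = list(rate = 4.2))),
               "rate")
  # x0 = 0.5 maps to 1 and then to the absorbing point 0
  expect_error(generate_map_series(signal_spec("logistic", 100,
                                               params = list(x0 = 0.5))),
               "fixed point")
  x <- as.matrix(generate_map_series(signal_spec("logistic", 5000,
                                                 seed = 11)))[, 1]
  expect_true(all(x >= 0 & x <= 1))
  # invariant density of the rate-4 map is symmetric about 1/2
  expect_gt(mean(x), 0.45)
  expect_lt(mean(x), 0.55)
})

test_that("Henon orbits stay bounded and generators are deterministic", {
  spec <- signal_spec("henon", 5000, seed = 5)
  x <- as.matrix(generate_map_series(spec))[, 1]
  expect_true(all(abs(x) < 2))
  y <- as.matrix(generate_map_series(spec))[, 1]
  expect_identical(x, y)
})

test_that("sine and white-noise generators match their closed-form moments", {
  s <- sine_epoch(20000, 100, freq = 7, amplitude = 50)
  expect_equal(rms(s), 50 / sqrt(2), tolerance = 0.01)
  w <- generate_flow_series(signal_spec("white_noise", 10000, 500,
                                        list(sd = 10), seed = 21))
  expect_equal(sd(as.matrix(w)), 10, tolerance = 0.05)
  expect_error(signal_spec("sine", 100, sampling_rate = 0), "positive")
})

test_that("Lorenz integration is accurate under step halving and shows sensitive dependence", {
  # short model horizon: over long horizons chaotic error amplification,
  # not integrator accuracy, dominates any twin-trajectory comparison
  base <- list(init = c(1, 1, 20), burn_time = 0, sample_dt = 0.01)
  a <- as.matrix(generate_flow_series(signal_spec("lorenz", 1000, 500,
                                                  c(base, max_step = 0.005))))
  b <- as.matrix(generate_flow_series(signal_spec("lorenz", 1000, 500,
                                                  c(base, max_step = 0.0025))))
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.01)
  # twin orbits separated by 1e-8 in x diverge to macroscopic distance
  c1 <- as.matrix(generate_flow_series(signal_spec("lorenz", 2000, 500,
                                                   list(init = c(1, 1, 20)))))
  c2 <- as.matrix(generate_flow_series(signal_spec("lorenz", 2000, 500,
                                                   list(init = c(1 + 1e-8, 1, 20)))))
  expect_gt(max(abs(c1 - c2)), 1)
})

test_that("triphasic epochs have the required morphology, rate and spectrum", {
  expect_error(generate_triphasic_epoch(
    signal_spec("enceph_eeg", 6000, 500, list(amplitude_uv = 60))), "70")
  expect_error(generate_triphasic_epoch(
    signal_spec("enceph_eeg", 6000, 500, list(rate_hz = 2.5))), "\\[1, 2\\]")
  e <- generate_triphasic_epoch(signal_spec("enceph_eeg", 6000, 500,
                                            list(rate_hz = 1.5,
                                                 amplitude_uv = 100,
                                                 noise_sd_uv = 5),
                                            seed = 3))
  v <- as.matrix(e)[, 1]
  # 1.5 complexes/s x 12 s = 18 stereotyped complexes
  peaks <- which(v > 50)
  complexes <- sum(diff(c(-1000, peaks)) > 0.3 * 500)
  expect_equal(complexes, 18)
  expect_gt(max(abs(v)), 85)
  expect_lt(max(abs(v)), 115)
  sp <- spec.pgram(v, taper = 0, plot = FALSE, detrend = TRUE)
  f_peak <- 500 * sp$freq[which.max(sp$spec)]
  expect_gte(f_peak, 1)
  expect_lte(f_peak, 2)
})

test_that("normal-like epochs are broadband, band-limited and reproducible", {
  spec <- signal_spec("normal_eeg", 6000, 500, seed = 4)
  e <- generate_normal_epoch(spec)
  expect_identical(as.matrix(e), as.matrix(generate_normal_epoch(spec)))
  v <- as.matrix(e)[, 1]
  sp <- spec.pgram(v, taper = 0, plot = FALSE, detrend = TRUE)
  f <- 500 * sp$freq
  expect_gt(sum(sp$spec[f >= 0.5 & f <= 60]) / sum(sp$spec), 0.95)
  # power spread over octave bands: no single octave holds > 60%
  octaves <- cut(f, c(0.5, 1, 2, 4, 8, 16, 32, 64), right = FALSE)
  share <- tapply(sp$spec, octaves, sum)
  share <- share[!is.na(share)] / sum(share, na.rm = TRUE)
  expect_lt(max(share), 0.60)
  expect_gte(sum(share > 0.05), 3)
})

test_that("cohorts are balanced, deterministic and jittered within groups", {
  coh <- generate_cohort(4, seed = 7, n_samples = 1500)
  expect_length(coh$epochs, 8)
  expect_equal(unname(table(coh$labels)), c(4L, 4L), ignore_attr = TRUE)
  durations <- vapply(coh$epochs, n_samples, integer(1))
  expect_true(all(durations == 1500))
  coh2 <- generate_cohort(4, seed = 7, n_samples = 1500)
  for (i in seq_along(coh$epochs))
    expect_identical(as.matrix(coh$epochs[[i]]), as.matrix(coh2$epochs[[i]]))
  # per-epoch jitter produces within-group variability
  amps <- vapply(coh$specs[coh$labels == "encephalopathy"],
                 function(s) s$params$amplitude_uv, numeric(1))
  expect_gt(diff(range(amps)), 0)
})

test_that("low-complexity epochs score lower CD than high-complexity ones", {
  coh <- generate_cohort(8, seed = 3)
  ft <- cohort_features(coh)
  med <- tapply(ft$cd, ft$label, median)
  expect_lt(med[["encephalopathy"]], med[["normal"]])
})
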