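test_that("delay embedding satisfies the count contract and coordinate rule", {
  tr <- embed_delay(1:10, m = 3, lag = 1)
  expect_equal(nrow(tr), 8)
  expect_equal(ncol(tr), 3)

  # direct substitution: series (1..5), m = 2, lag = 2
  tr2 <- embed_delay(1:5, m = 2, lag = 2)
  expect_equal(unclass(tr2), cbind(c(3, 4, 5), c(1, 2, 3)),
               ignore_attr = TRUE)

  # m = 1 reduces to the original series
  x <- rnorm(50)
  expect_equal(as.numeric(embed_delay(x, m = 1, lag = 5)), x)

  expect_error(embed_delay(1:5, m = 3, lag = 3), "too short")

  # property: n_points = N - (m-1) lag over random valid triples
  set.seed(42)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    m <- sample(1:8, 1)
    lag <- sample(1:5, 1)
    if (N <= (m - 1) * lag) next
    tr <- embed_delay(rnorm(N), m = m, lag = lag)
    expect_equal(nrow(tr), N - (m - 1) * lag)
    expect_equal(ncol(tr), m)
  }
})

test_that("autocorrelation delay finds the quarter period of oscillations", {
  p <- 40
  s <- sine_epoch(4000, 1, freq = 1 / p)
  expect_lte(abs(delay_autocorr(s, max_lag = 100) - p / 4), 1)

  # white noise: autocorrelation ~ 0 beyond lag 0, so the first crossing
  # is geometric with p = 1/2 -- typically 1 or 2, always early
  crossings <- vapply(1:20, function(s) delay_autocorr(
    generate_flow_series(signal_spec("white_noise", 10000, 1, seed = s)),
    max_lag = 50), integer(1))
  expect_lte(median(crossings), 2)
  expect_true(all(crossings <= 8))

  alt <- rep(c(1, -1), 50)
  expect_equal(delay_autocorr(alt, max_lag = 10), 1L)

  expect_error(delay_autocorr(rep(1, 100), 10), "constant")
})

test_that("histogram mutual information behaves like an information measure", {
  set.seed(7)
  x <- rnorm(10000)
  # I(X;X) equals the histogram entropy of X
  px <- tabulate(pmin(floor((x - min(x)) / diff(range(x)) * 16) + 1, 16),
                 16) / length(x)
  h <- -sum(px[px > 0] * log(px[px > 0]))
  expect_equal(histogram_mi(x, x, 16), h, tolerance = 1e-12)

  # affine scaling of the inputs leaves MI unchanged
  y <- rnorm(10000)
  expect_equal(histogram_mi(x, y, 16), histogram_mi(2.5 * x - 7, y, 16),
               tolerance = 1e-10)
})

test_that("mutual-information delay finds the first minimum", {
  w <- generate_flow_series(signal_spec("white_noise", 10000, 1, seed = 2))
  res <- delay_mutual_information(w, max_lag = 20, n_bins = 16)
  expect_true(all(res$mi < 0.05))  # independent lagged copies

  # narrowband oscillation, period 100: the joint density decorrelates at
  # the quarter period, so the first minimum lands near lag 25. (A pure
  # noiseless sine is degenerate for histogram MI: its arcsine marginal
  # makes the curve oscillate with bin-occupancy artifacts.)
  set.seed(2)
  s <- 50 * sin(2 * pi * (0:5999) / 100) + rnorm(6000, 0, 15)
  res2 <- delay_mutual_information(s, max_lag = 60)
  expect_gte(res2$lag, 20)
  expect_lte(res2$lag, 30)

  expect_error(delay_mutual_information(rep(2, 100), 10), "constant")
})

test_that("false nearest neighbours separate low-dimensional signals from noise", {
  hx <- generate_map_series(signal_spec("henon", 5000, seed = 5))
  res <- fnn_dimension(hx, lag = 1, max_m = 6)
  expect_lte(res$m, 3)
  expect_lt(res$fractions[2], 0.02)

  # limit cycle sampled at an incommensurate frequency (a commensurate one
  # collapses the orbit onto a handful of exactly repeated points, leaving
  # the nearest-neighbour relation degenerate)
  s <- generate_flow_series(signal_spec("sine", 3000, 100,
                                        list(amplitude = 50, freq_hz = 4.7,
                                             phase = 0.3)))
  res_s <- fnn_dimension(s, lag = 5, max_m = 6)
  expect_equal(res_s$m, 2L)

  w <- generate_flow_series(signal_spec("white_noise", 3000, 1, seed = 3))
  expect_warning(res_w <- fnn_dimension(w, lag = 1, max_m = 6), "threshold")
  expect_true(all(res_w$fractions > 0.10))

  # fractions non-increasing in m for deterministic low-dimensional inputs
  expect_true(all(diff(res$fractions) < 0.02))
  expect_true(all(diff(res_s$fractions) < 0.02))
})
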