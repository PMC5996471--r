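# Shared fixtures and small oracles used across the test files.

rms <- function(x) sqrt(mean(as.matrix(x)^2))

sine_epoch <- function(n, fs, freq, amplitude = 50, phase = 0) {
  generate_flow_series(signal_spec("sine", n, fs,
                                   list(amplitude = amplitude,
                                        freq_hz = freq, phase = phase)))
}

# Literal double-loop correlation sum: fraction of ordered pairs (i, j),
# i != j, |i - j| > theiler, with squared distance <= r^2. Independent of
# the compiled path (plain R loops, squared-distance comparison).
corr_sum_oracle <- function(pts, radii, theiler = 0) {
  n <- nrow(pts)
  counts <- numeric(length(radii))
  n_adm <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i <= theiler) next
    d2 <- sum((pts[i, ] - pts[j, ])^2)
    n_adm <- n_adm + 1
    counts <- counts + (d2 <= radii^2)
  }
  counts / n_adm
}

# Exhaustive two-sided Mann-Whitney p: enumerate U over every assignment
# of n1 pooled observations to group a, p = P(|U - mu| >= |u_obs - mu|).
mw_enum_p <- function(a, b) {
  n1 <- length(a); nt <- n1 + length(b)
  r <- rank(c(a, b))
  mu <- n1 * (nt - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(nt, n1), 2, function(s) sum(r[s])) -
    n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Cohort feature tables are expensive (hundreds of 6000-sample epochs), so
# they are computed once per test run and shared between test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

cohort_features_cached <- function(n_per_group, seed) {
  cached(sprintf("feat_%d_%d", n_per_group, seed), {
    coh <- generate_cohort(n_per_group, seed = seed)
    pc <- preprocess_config()
    filtered <- lapply(coh$epochs, bandpass, config = pc)
    cohort_features(filtered, labels = as.character(coh$labels))
  })
}
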