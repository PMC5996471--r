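#' Specification of a synthetic signal
#'
#' A `signal_spec` describes one synthetic signal completely: which
#' generator (`kind`), how many samples, the sampling rate, generator
#' parameters and the RNG seed. Identical specs always produce
#' bit-identical signals.
#'
#' Supported kinds: `"logistic"`, `"henon"` (discrete maps with nominal
#' sampling rate 1), `"lorenz"`, `"sine"`, `"white_noise"` (flows/noise),
#' `"normal_eeg"` (broadband high-complexity surrogate) and `"enceph_eeg"`
#' (low-complexity surrogate dominated by 1-2 Hz triphasic waves).
#'
#' @param kind One of the supported generator kinds.
#' @param n_samples Number of samples to emit (>= 1).
#' @param sampling_rate Sampling rate in Hz (positive; 1 for maps).
#' @param params Named list of kind-specific parameters; unset entries take
#'   the documented defaults.
#' @param seed Integer RNG seed.
#' @return A list of class `signal_spec`.
#' @seealso [generate_signal()]
#' @export
signal_spec <- function(kind, n_samples, sampling_rate = 1,
                        params = list(), seed = 1L) {
  kinds <- c("logistic", "henon", "lorenz", "sine", "white_noise",
             "normal_eeg", "enceph_eeg")
  kind <- match.arg(kind, kinds)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(list(kind = kind, n_samples = as.integer(n_samples),
                 sampling_rate = as.numeric(sampling_rate),
                 params = params, seed = as.integer(seed)),
            class = "signal_spec")
}

param_or <- function(spec, name, default) {
  if (!is.null(spec$params[[name]])) spec$params[[name]] else default
}

#' Generate a synthetic signal from a spec
#'
#' Dispatches on `spec$kind` to the matching generator
#' ([generate_map_series()], [generate_flow_series()],
#' [generate_triphasic_epoch()] or [generate_normal_epoch()]).
#'
#' @param spec A [signal_spec()].
#' @return An [eeg_epoch()].
#' @examples
#' e <- generate_signal(signal_spec("sine", 1000, 100,
#'                                  list(amplitude = 50, freq_hz = 10)))
#' sqrt(mean(as.matrix(e)^2))  # ~ 50 / sqrt(2)
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  switch(spec$kind,
         logistic = ,
         henon = generate_map_series(spec),
         lorenz = ,
         sine = ,
         white_noise = generate_flow_series(spec),
         enceph_eeg = generate_triphasic_epoch(spec),
         normal_eeg = generate_normal_epoch(spec))
}

#' Iterated-map series (logistic, Henon)
#'
#' Emits the scalar observable of a discrete-time chaotic map after a
#' burn-in of at least 100 iterations, as an epoch with nominal sampling
#' rate 1. Logistic parameters: `rate` (growth rate, default 4) and
#' optional `x0` in (0, 1); orbits that hit an absorbing fixed point during
#' burn-in are rejected. Henon parameters: `a` (1.4), `b` (0.3) and
#' optional initial conditions; unbounded orbits are rejected.
#'
#' @param spec A [signal_spec()] with kind `"logistic"` or `"henon"`.
#' @param burn_in Iterations discarded before emitting samples (>= 100).
#' @return An [eeg_epoch()] with sampling rate 1.
#' @export
generate_map_series <- function(spec, burn_in = 100L) {
  stopifnot(inherits(spec, "signal_spec"),
            spec$kind %in% c("logistic", "henon"))
  if (burn_in < 100) stop("burn_in must be at least 100 iterations")
  n <- spec$n_samples
  if (spec$kind == "logistic") {
    rate <- param_or(spec, "rate", 4)
    if (rate <= 0 || rate > 4)
      stop("logistic rate must be in (0, 4]: orbits escape [0, 1] otherwise")
    x <- param_or(spec, "x0", NULL)
    if (is.null(x)) x <- with_seed(spec$seed, runif(1, 0.05, 0.95))
    fixed <- 1 - 1 / rate
    out <- numeric(n)
    total <- burn_in + n
    for (i in seq_len(total)) {
      if (x <= 0 || x >= 1 || x == fixed)
        stop("degenerate logistic orbit: trajectory hit a fixed point; ",
             "choose a different x0")
      x <- rate * x * (1 - x)
      if (i > burn_in) out[i - burn_in] <- x
    }
    return(eeg_epoch(out, 1, source_id = sprintf("logistic(rate=%g,seed=%d)",
                                                 rate, spec$seed)))
  }
  a <- param_or(spec, "a", 1.4)
  b <- param_or(spec, "b", 0.3)
  xy <- with_seed(spec$seed, runif(2, -0.1, 0.1))
  x <- param_or(spec, "x0", xy[1])
  y <- param_or(spec, "y0", xy[2])
  out <- numeric(n)
  total <- burn_in + n
  for (i in seq_len(total)) {
    xn <- 1 - a * x * x + y
    y <- b * x
    x <- xn
    if (!is.finite(x) || abs(x) > 1e6)
      stop("Henon orbit diverged: parameters outside the bounded regime")
    if (i > burn_in) out[i - burn_in] <- x
  }
  eeg_epoch(out, 1, source_id = sprintf("henon(a=%g,b=%g,seed=%d)",
                                        a, b, spec$seed))
}

# Lorenz x/y/z trajectory sampled every `sample_dt` time units, integrated
# with fixed-step RK4 at an internal step <= max_step.
lorenz_trajectory <- function(n_out, sample_dt = 0.03, seed = 1L,
                              sigma = 10, rho = 28, beta = 8 / 3,
                              init = NULL, burn_time = 20,
                              max_step = 0.005) {
  substeps <- max(1L, as.integer(ceiling(sample_dt / max_step)))
  dt <- sample_dt / substeps
  if (is.null(init))
    init <- with_seed(seed, c(runif(1, -10, 10), runif(1, -10, 10),
                              runif(1, 10, 30)))
  burn <- as.integer(ceiling(burn_time / dt))
  cpp_lorenz(sigma, rho, beta, init[1], init[2], init[3],
             dt, n_out, substeps, burn)
}

#' Flow and noise series (Lorenz, sine, white noise)
#'
#' `"lorenz"` integrates the Lorenz system (`sigma` 10, `rho` 28, `beta`
#' 8/3 by default) with a fixed-step RK4 scheme and emits the x-coordinate;
#' `sample_dt` (default 0.03 time units) is the model time between emitted
#' samples and the internal step is at most `max_step` (default 0.005, small
#' enough that halving changes the emitted samples by well under 1% RMS).
#' `"sine"` emits `amplitude * sin(2 pi freq_hz t + phase)`; `"white_noise"`
#' emits i.i.d. Gaussian samples with standard deviation `sd`. Lorenz
#' extras: `init` (length-3 initial state, default drawn from the seed),
#' `burn_time` (model time discarded before emitting, default 20) and
#' `max_step` (internal step bound).
#'
#' @param spec A [signal_spec()] with kind `"lorenz"`, `"sine"` or
#'   `"white_noise"`.
#' @return An [eeg_epoch()] at `spec$sampling_rate`.
#' @export
generate_flow_series <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"),
            spec$kind %in% c("lorenz", "sine", "white_noise"))
  n <- spec$n_samples
  fs <- spec$sampling_rate
  if (spec$kind == "sine") {
    amp <- param_or(spec, "amplitude", 50)
    f <- param_or(spec, "freq_hz", 10)
    phase <- param_or(spec, "phase", NULL)
    if (is.null(phase)) phase <- with_seed(spec$seed, runif(1, 0, 2 * pi))
    t <- (seq_len(n) - 1) / fs
    return(eeg_epoch(amp * sin(2 * pi * f * t + phase), fs,
                     source_id = sprintf("sine(%g Hz)", f)))
  }
  if (spec$kind == "white_noise") {
    sdv <- param_or(spec, "sd", 10)
    x <- with_seed(spec$seed, rnorm(n, 0, sdv))
    return(eeg_epoch(x, fs, source_id = sprintf("white_noise(sd=%g)", sdv)))
  }
  traj <- lorenz_trajectory(
    n, sample_dt = param_or(spec, "sample_dt", 0.03), seed = spec$seed,
    sigma = param_or(spec, "sigma", 10), rho = param_or(spec, "rho", 28),
    beta = param_or(spec, "beta", 8 / 3),
    init = param_or(spec, "init", NULL),
    burn_time = param_or(spec, "burn_time", 20),
    max_step = param_or(spec, "max_step", 0.005))
  eeg_epoch(traj[, 1], fs, source_id = sprintf("lorenz(seed=%d)", spec$seed))
}

# One triphasic complex: negative lobe, dominant positive lobe (~2x), and a
# trailing negative lobe, built from smooth Gaussian bumps. Lobe widths and
# spacing are free morphology parameters with documented defaults.
triphasic_complex <- function(t, center, amplitude, w_pos = 0.12,
                              w_neg = 0.07, offset = 0.18) {
  amplitude * exp(-0.5 * ((t - center) / w_pos)^2) -
    0.5 * amplitude * exp(-0.5 * ((t - center + offset) / w_neg)^2) -
    0.5 * amplitude * exp(-0.5 * ((t - center - offset) / w_neg)^2)
}

#' Encephalopathy-like epoch dominated by triphasic waves
#'
#' Generates the low-complexity surrogate: a periodic train of stereotyped
#' triphasic complexes (a dominant positive deflection preceded and
#' followed by smaller negative deflections) at `rate_hz` complexes per
#' second, peak amplitude `amplitude_uv`, over low-amplitude Gaussian
#' background noise. Triphasic waves in encephalopathy run at 1-2 Hz with
#' amplitudes above 70 microvolts, and the generator rejects parameters
#' outside that morphology.
#'
#' @param spec A [signal_spec()] with kind `"enceph_eeg"`. Parameters:
#'   `rate_hz` (default 1.5, must lie in \[1, 2\]), `amplitude_uv` (default
#'   100, must exceed 70), `noise_sd_uv` (default 5), lobe shape `w_pos`,
#'   `w_neg`, `offset` (seconds), and `channels` (default 1; extra channels
#'   share the waveform with independent noise).
#' @return An [eeg_epoch()].
#' @export
generate_triphasic_epoch <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"), spec$kind == "enceph_eeg")
  rate <- param_or(spec, "rate_hz", 1.5)
  amp <- param_or(spec, "amplitude_uv", 100)
  noise_sd <- param_or(spec, "noise_sd_uv", 5)
  channels <- param_or(spec, "channels", 1L)
  if (rate < 1 || rate > 2)
    stop("triphasic rate_hz must lie in [1, 2] Hz")
  if (amp <= 70)
    stop("triphasic amplitude_uv must exceed 70 microvolts")
  fs <- spec$sampling_rate
  n <- spec$n_samples
  t <- (seq_len(n) - 1) / fs
  duration <- n / fs
  k <- floor(duration * rate + 1e-9)
  centers <- (seq_len(k) - 0.5) / rate
  wave <- rowSums(vapply(centers, function(cc)
    triphasic_complex(t, cc, amp,
                      w_pos = param_or(spec, "w_pos", 0.12),
                      w_neg = param_or(spec, "w_neg", 0.07),
                      offset = param_or(spec, "offset", 0.18)),
    numeric(n)))
  noise <- with_seed(spec$seed, matrix(rnorm(n * channels, 0, noise_sd), n))
  eeg_epoch(wave + noise, fs,
            source_id = sprintf("enceph_eeg(rate=%g,amp=%g,seed=%d)",
                                rate, amp, spec$seed))
}

#' Normal-like broadband high-complexity epoch
#'
#' Generates the high-complexity surrogate for normal awake EEG: several
#' incommensurate-frequency rhythms spread across the 0.5-60 Hz band
#' (delta/theta/alpha/beta/gamma analogues), a chaotic Lorenz component and
#' broadband noise, the latter two band-limited to 0.5-60 Hz; overall scale
#' is tens of microvolts and no single octave band dominates the spectrum.
#'
#' @param spec A [signal_spec()] with kind `"normal_eeg"`. Parameters:
#'   `rhythm_freqs` (Hz, default c(2.3, 6.1, 10.7, 19.3, 37.1)),
#'   `rhythm_amps` (microvolts, default c(14, 12, 16, 9, 6)),
#'   `noise_sd_uv` (default 8), `chaos_sd_uv` (default 8) and `channels`
#'   (default 1; extra channels share the deterministic components with
#'   independent noise).
#' @return An [eeg_epoch()].
#' @export
generate_normal_epoch <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"), spec$kind == "normal_eeg")
  fs <- spec$sampling_rate
  n <- spec$n_samples
  freqs <- param_or(spec, "rhythm_freqs", c(2.3, 6.1, 10.7, 19.3, 37.1))
  amps <- param_or(spec, "rhythm_amps", c(14, 12, 16, 9, 6))
  noise_sd <- param_or(spec, "noise_sd_uv", 8)
  chaos_sd <- param_or(spec, "chaos_sd_uv", 8)
  channels <- param_or(spec, "channels", 1L)
  stopifnot(length(freqs) == length(amps))
  t <- (seq_len(n) - 1) / fs
  with_seed(spec$seed, {
    phases <- runif(length(freqs), 0, 2 * pi)
    rhythms <- as.numeric(
      vapply(seq_along(freqs),
             function(i) amps[i] * sin(2 * pi * freqs[i] * t + phases[i]),
             numeric(n)) %*% rep(1, length(freqs)))
    lx <- lorenz_trajectory(n, sample_dt = 0.03,
                            init = c(runif(1, -10, 10), runif(1, -10, 10),
                                     runif(1, 10, 30)))[, 1]
    chaos <- (lx - mean(lx)) / sd(lx) * chaos_sd
    noise <- matrix(rnorm(n * channels, 0, noise_sd), n)
    bp <- preprocess_config(0.5, min(60, fs / 2 - 1))
    chaos_f <- as.matrix(bandpass(eeg_epoch(chaos, fs), bp))[, 1]
    noise_f <- apply(noise, 2, function(ch)
      as.matrix(bandpass(eeg_epoch(ch, fs), bp))[, 1])
    eeg_epoch(rhythms + chaos_f + noise_f, fs,
              source_id = sprintf("normal_eeg(seed=%d)", spec$seed))
  })
}

#' Balanced synthetic cohort of normal and encephalopathy-like epochs
#'
#' Generates `n_per_group` epochs per group with per-epoch seeds derived
#' deterministically from `seed` and per-epoch parameters jittered by
#' +/-10% (uniform) around the generator defaults, so rank-based group
#' tests see within-group variability. The group sizes, 12-second epoch
#' length and 500 Hz sampling rate mirror a clinical case-control design.
#'
#' @param n_per_group Number of epochs in each group (>= 1).
#' @param seed Master integer seed.
#' @param n_samples Samples per epoch (default 6000 = 12 s at 500 Hz).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param channels Channels per epoch (default 1).
#' @return An object of class `eeg_cohort`: list with `epochs` (list of
#'   [eeg_epoch()]), `labels` (factor, levels `normal`/`encephalopathy`)
#'   and `specs` (the per-epoch [signal_spec()]s).
#' @examples
#' coh <- generate_cohort(3, seed = 42, n_samples = 1000)
#' table(coh$labels)
#' @export
generate_cohort <- function(n_per_group, seed = 1L, n_samples = 6000,
                            sampling_rate = 500, channels = 1L) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  n_total <- 2L * n_per_group
  draws <- with_seed(seed, list(
    seeds = sample.int(2147483646L, n_total),
    jitter = matrix(runif(n_total * 8, 0.9, 1.1), n_total)))
  labels <- factor(rep(c("normal", "encephalopathy"), each = n_per_group),
                   levels = c("normal", "encephalopathy"))
  specs <- vector("list", n_total)
  epochs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    j <- draws$jitter[i, ]
    if (labels[i] == "normal") {
      specs[[i]] <- signal_spec(
        "normal_eeg", n_samples, sampling_rate,
        params = list(rhythm_amps = c(14, 12, 16, 9, 6) * j[1:5],
                      noise_sd_uv = 8 * j[6], chaos_sd_uv = 8 * j[7],
                      channels = channels),
        seed = draws$seeds[i])
    } else {
      # clamp the jittered rate to the 1-2 Hz triphasic band
      specs[[i]] <- signal_spec(
        "enceph_eeg", n_samples, sampling_rate,
        params = list(rate_hz = min(2, max(1, 1.5 * j[1])),
                      amplitude_uv = 100 * j[2], noise_sd_uv = 5 * j[3],
                      channels = channels),
        seed = draws$seeds[i])
    }
    epochs[[i]] <- generate_signal(specs[[i]])
  }
  structure(list(epochs = epochs, labels = labels, specs = specs,
                 seed = as.integer(seed)),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d epochs (%s), %d samples @ %g Hz, seed %d\n",
              length(x$epochs),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              n_samples(x$epochs[[1]]), x$epochs[[1]]$sampling_rate,
              x$seed))
  invisible(x)
}

format_params <- function(params) {
  paste(vapply(names(params), function(k)
    sprintf("%s=%s", k, paste(sprintf("%.10g", as.numeric(params[[k]])),
                              collapse = "|")), character(1)),
    collapse = ";")
}

#' Write a cohort as text epochs plus a manifest
#'
#' Writes one delimited text file per epoch under `dir/epochs/` and a CSV
#' manifest (`manifest.csv`: path, label, seed, kind, params) readable by
#' [read_epoch_text()] / `read.csv()`.
#'
#' @param cohort An `eeg_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  epdir <- file.path(dir, "epochs")
  dir.create(epdir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$epochs)
  rel <- sprintf("epochs/epoch_%04d.txt", seq_len(n))
  for (i in seq_len(n))
    write_epoch_text(cohort$epochs[[i]], file.path(dir, rel[i]))
  manifest <- data.frame(
    path = rel,
    label = as.character(cohort$labels),
    seed = vapply(cohort$specs, function(s) s$seed, integer(1)),
    kind = vapply(cohort$specs, function(s) s$kind, character(1)),
    sampling_rate = vapply(cohort$specs, function(s) s$sampling_rate,
                           numeric(1)),
    params = vapply(cohort$specs, function(s) format_params(s$params),
                    character(1)),
    stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
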