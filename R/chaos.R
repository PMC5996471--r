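#' Correlation sum over a grid of radii
#'
#' For each radius r, the fraction of admissible point pairs of the
#' trajectory whose Euclidean distance is at most r. Pairs closer in time
#' than the Theiler window are excluded from both numerator and
#' denominator; `theiler = 0` gives the literal all-pairs correlation sum.
#' By default radii are 24 log-spaced values between the 1st and 50th
#' percentile of a deterministic subsample of admissible pairwise
#' distances, which brackets the scaling region of interest.
#'
#' @param traj An `embedded_traj` from [embed_delay()], or any numeric
#'   matrix of points (rows = points).
#' @param radii Strictly increasing positive radii, or `NULL` for the
#'   automatic grid.
#' @param theiler Theiler exclusion window in samples (>= 0).
#' @param n_radii Number of radii in the automatic grid.
#' @return An object of class `corr_sum`: `radii`, `c_values`, `n_pairs`
#'   (admissible pair count), `n_points`, `theiler`.
#' @export
correlation_sum <- function(traj, radii = NULL, theiler = 0L,
                            n_radii = 24L) {
  pts <- as_point_matrix(traj)
  n <- nrow(pts)
  theiler <- as.integer(theiler)
  if (theiler < 0) stop("theiler must be >= 0")
  if (n - theiler < 2) stop("no admissible pairs under this Theiler window")
  if (is.null(radii)) radii <- default_radii(pts, theiler, n_radii)
  radii <- as.numeric(radii)
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing")
  res <- cpp_correlation_counts(pts, radii, theiler)
  if (res$n_pairs < 1) stop("no admissible pairs under this Theiler window")
  structure(list(radii = radii, c_values = res$counts / res$n_pairs,
                 n_pairs = res$n_pairs, n_points = n, theiler = theiler),
            class = "corr_sum")
}

# Deterministic (RNG-free) radii grid: systematic subsample of points,
# percentiles of the admissible pairwise distances.
default_radii <- function(pts, theiler, n_radii = 24L, max_ref = 120L) {
  n <- nrow(pts)
  idx <- unique(round(seq(1, n, length.out = min(n, max_ref))))
  dd <- as.matrix(stats::dist(pts[idx, , drop = FALSE]))
  sep <- abs(outer(idx, idx, "-"))
  dv <- dd[upper.tri(dd) & sep > theiler]
  dv <- dv[dv > 0]
  if (length(dv) < 2) stop("degenerate trajectory: all sampled distances zero")
  q <- quantile(dv, c(0.01, 0.5), names = FALSE)
  if (q[1] <= 0) q[1] <- min(dv)
  exp(seq(log(q[1]), log(q[2]), length.out = n_radii))
}

#' @export
print.corr_sum <- function(x, ...) {
  cat(sprintf("<corr_sum> %d radii in [%.4g, %.4g], %d points, theiler %d\n",
              length(x$radii), min(x$radii), max(x$radii), x$n_points,
              x$theiler))
  invisible(x)
}

#' Correlation dimension from the scaling region of a correlation sum
#'
#' Fits the least-squares slope of log C(r) versus log r over the linear
#' scaling region. By default the region is chosen automatically as the
#' contiguous window of at least `min_run` radii, within the radii whose
#' C(r) lies in `c_range`, that maximises the linear-fit R-squared;
#' explicit bounds override the search. The slope is the correlation
#' dimension estimate.
#'
#' @param curve A `corr_sum` from [correlation_sum()].
#' @param fit_lo_r,fit_hi_r Optional explicit radius bounds for the fit.
#' @param c_range C(r) values admitted to the automatic search (default
#'   `c(1e-3, 0.5)`, away from the depleted small-r and saturated large-r
#'   ends).
#' @param min_run Minimum number of radii in the fitted window.
#' @return An object of class `cd_fit`: `cd` (the slope), `fit_lo_r`,
#'   `fit_hi_r`, `r_squared`, `n_fit_points`, plus the input curve.
#' @export
estimate_cd <- function(curve, fit_lo_r = NULL, fit_hi_r = NULL,
                        c_range = c(1e-3, 0.5), min_run = 6L) {
  stopifnot(inherits(curve, "corr_sum"))
  r <- curve$radii
  cv <- curve$c_values
  if (!is.null(fit_lo_r) || !is.null(fit_hi_r)) {
    lo <- if (is.null(fit_lo_r)) -Inf else fit_lo_r
    hi <- if (is.null(fit_hi_r)) Inf else fit_hi_r
    use <- which(r >= lo & r <= hi & cv > 0)
    if (length(use) < 3) stop("fewer than 3 usable radii in the fit region")
    win <- c(use[1], use[length(use)])
  } else {
    mask <- cv >= c_range[1] & cv <= c_range[2] & cv > 0
    win <- best_loglog_window(log(r), log(pmax(cv, .Machine$double.xmin)),
                              mask, min_run)
    if (is.null(win)) stop("fewer than 3 usable radii in the scaling region")
  }
  sel <- win[1]:win[2]
  fit <- ls_line(log(r[sel]), log(cv[sel]))
  structure(list(cd = fit$slope, fit_lo_r = r[win[1]], fit_hi_r = r[win[2]],
                 r_squared = fit$r_squared, n_fit_points = length(sel),
                 intercept = fit$intercept, curve = curve),
            class = "cd_fit")
}

# Best-R^2 contiguous window of length >= min_run inside masked runs; falls
# back to the longest run when no run reaches min_run (>= 3 points).
best_loglog_window <- function(lx, ly, mask, min_run) {
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- NULL; best_key <- c(-Inf, -Inf)
  for (k in which(runs$values)) {
    a0 <- starts[k]; b0 <- ends[k]
    len <- b0 - a0 + 1
    if (len < min_run) next
    for (a in a0:(b0 - min_run + 1)) for (b in (a + min_run - 1):b0) {
      f <- ls_line(lx[a:b], ly[a:b])
      key <- c(f$r_squared, b - a)
      if (key[1] > best_key[1] + 1e-12 ||
          (abs(key[1] - best_key[1]) <= 1e-12 && key[2] > best_key[2])) {
        best_key <- key; best <- c(a, b)
      }
    }
  }
  if (is.null(best)) {
    k <- which(runs$values & runs$lengths >= 3)
    if (length(k) == 0) return(NULL)
    k <- k[which.max(runs$lengths[k])]
    best <- c(starts[k], ends[k])
  }
  best
}

#' Grassberger-Procaccia correlation dimension of a scalar series
#'
#' Convenience front end: delay-embeds the series ([embed_delay()]),
#' computes the correlation sum ([correlation_sum()]) and fits the scaling
#' region ([estimate_cd()]). The defaults m = 10, lag = 1 are the settings
#' used for 12 s / 500 Hz EEG epochs; `theiler = NULL` applies the
#' `lag * m` exclusion window (set 0 for the literal all-pairs sum).
#'
#' @param x An [eeg_epoch()] (single channel) or numeric vector.
#' @param m Embedding dimension.
#' @param lag Embedding delay in samples.
#' @param theiler Theiler window; `NULL` for `lag * m`.
#' @param radii,n_radii Passed to [correlation_sum()].
#' @param ... Passed to [estimate_cd()].
#' @return A `cd_fit` (see [estimate_cd()]).
#' @examples
#' x <- generate_map_series(signal_spec("henon", 3000, seed = 7))
#' fit <- correlation_dimension(x, m = 2, lag = 1)
#' coef(fit)  # near the Henon attractor's correlation dimension ~1.2
#' @export
correlation_dimension <- function(x, m = 10L, lag = 1L, theiler = NULL,
                                  radii = NULL, n_radii = 24L, ...) {
  traj <- embed_delay(x, m = m, lag = lag)
  if (is.null(theiler)) theiler <- as.integer(lag) * as.integer(m)
  curve <- correlation_sum(traj, radii = radii, theiler = theiler,
                           n_radii = n_radii)
  fit <- estimate_cd(curve, ...)
  fit$m <- as.integer(m); fit$lag <- as.integer(lag)
  fit
}

#' @export
print.cd_fit <- function(x, ...) {
  cat(sprintf("Correlation dimension: %.4f\n", x$cd))
  cat(sprintf("  scaling region: r in [%.4g, %.4g] (%d radii), R^2 = %.4f\n",
              x$fit_lo_r, x$fit_hi_r, x$n_fit_points, x$r_squared))
  invisible(x)
}

#' @export
coef.cd_fit <- function(object, ...) c(cd = object$cd)

#' @export
plot.cd_fit <- function(x, ...) {
  r <- x$curve$radii; cv <- x$curve$c_values
  ok <- cv > 0
  plot(log10(r[ok]), log10(cv[ok]), xlab = "log10 r", ylab = "log10 C(r)",
       main = sprintf("Correlation sum (CD = %.3f)", x$cd), ...)
  sel <- r >= x$fit_lo_r & r <= x$fit_hi_r
  points(log10(r[sel]), log10(cv[sel]), pch = 19)
  # refit in log10 for the display line (slope is base-invariant)
  f <- ls_line(log10(r[sel]), log10(cv[sel]))
  abline(f$intercept, f$slope, lty = 2)
  invisible(x)
}

#' Largest Lyapunov exponent by the Rosenstein method
#'
#' Delay-embeds the series, pairs every state point with its nearest
#' neighbour at temporal separation greater than `mean_period`, and tracks
#' the mean log-divergence `y(i) = (1/dt) <ln d_j(i)>` of the surviving
#' pairs over `i = 0..max_steps` steps. The largest Lyapunov exponent is
#' the least-squares slope of y(i) over the initial linear region; by
#' default the fitted region starts at step 0 and ends at the step
#' maximising the linear-fit R-squared (at least 5 steps), before the curve
#' saturates at the attractor diameter.
#'
#' @param x An [eeg_epoch()] (single channel) or numeric vector.
#' @param m Embedding dimension.
#' @param lag Embedding delay in samples.
#' @param dt Time per sample (1 gives the exponent per sample step).
#' @param mean_period Temporal exclusion for the neighbour search, in
#'   samples; `NULL` estimates it as the reciprocal of the power-spectrum
#'   mean frequency.
#' @param max_steps Steps tracked; `NULL` gives `min(100, N/10)`.
#' @param fit_range Optional explicit `c(first, last)` step range for the
#'   slope fit (steps count from 0).
#' @return An object of class `lle_fit`: `lle`, `fit_lo_step`,
#'   `fit_hi_step`, `r_squared`, `mean_period`, and `curve` (steps, y
#'   values, pair counts, dt).
#' @examples
#' x <- generate_map_series(signal_spec("logistic", 2000, seed = 3))
#' fit <- lyapunov_max(x, m = 2, lag = 1)
#' coef(fit)  # near ln 2 = 0.693 for the rate-4 logistic map
#' @export
lyapunov_max <- function(x, m = 10L, lag = 1L, dt = 1,
                         mean_period = NULL, max_steps = NULL,
                         fit_range = NULL) {
  xv <- as_signal_vector(x)
  traj <- embed_delay(xv, m = m, lag = lag)
  n_pts <- nrow(traj)
  if (is.null(mean_period)) mean_period <- spectral_mean_period(xv)
  mean_period <- min(as.integer(mean_period), max(1L, n_pts %/% 10L))
  if (mean_period >= n_pts - 1)
    stop("no admissible neighbours: series too short for this mean_period")
  if (is.null(max_steps))
    max_steps <- min(100L, max(10L, length(xv) %/% 10L))
  max_steps <- min(as.integer(max_steps), n_pts - 2L)
  res <- cpp_rosenstein(unclass(traj), mean_period, max_steps)
  keep <- which(!is.na(res$y) & res$n_pairs > 0)
  if (length(keep) < 5) stop("no admissible neighbours to track")
  keep <- seq_len(max(keep))  # curve is contiguous from step 0
  y <- res$y[keep] / dt
  steps <- keep - 1L
  if (is.null(fit_range)) {
    win <- c(0L, best_initial_end(steps, y, min_len = 5L))
  } else {
    win <- as.integer(fit_range)
    if (win[1] < 0 || win[2] > max(steps) || win[2] - win[1] < 2)
      stop("fit_range outside the divergence curve")
  }
  sel <- which(steps >= win[1] & steps <= win[2])
  fit <- ls_line(steps[sel], y[sel])
  structure(list(lle = fit$slope, fit_lo_step = win[1],
                 fit_hi_step = win[2], r_squared = fit$r_squared,
                 mean_period = mean_period,
                 curve = list(steps = steps, y = y,
                              n_pairs = res$n_pairs[keep], dt = dt),
                 m = as.integer(m), lag = as.integer(lag)),
            class = "lle_fit")
}

# Reciprocal of the power-spectrum mean frequency, in samples.
spectral_mean_period <- function(x) {
  sp <- spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  mf <- sum(sp$freq * sp$spec) / sum(sp$spec)
  max(1L, as.integer(round(1 / mf)))
}

# Largest end b such that the fit over steps 0..b maximises R^2 (ties to
# the longer window): the initial linear region, anchored at the start of
# the divergence curve.
best_initial_end <- function(steps, y, min_len = 5L) {
  K <- max(steps)
  if (K < min_len - 1) return(K)
  r2 <- vapply((min_len - 1):K, function(b) {
    sel <- steps <= b
    ls_line(steps[sel], y[sel])$r_squared
  }, numeric(1))
  cand <- (min_len - 1):K
  cand[max(which(r2 >= max(r2) - 1e-9))]
}

#' @export
print.lle_fit <- function(x, ...) {
  cat(sprintf("Largest Lyapunov exponent: %.4f per unit time (dt = %g)\n",
              x$lle, x$curve$dt))
  cat(sprintf("  fit over steps %d..%d, R^2 = %.4f, mean period %d samples\n",
              x$fit_lo_step, x$fit_hi_step, x$r_squared, x$mean_period))
  invisible(x)
}

#' @export
coef.lle_fit <- function(object, ...) c(lle = object$lle)

#' @export
plot.lle_fit <- function(x, ...) {
  plot(x$curve$steps, x$curve$y, xlab = "step i",
       ylab = "mean log divergence y(i)",
       main = sprintf("Rosenstein divergence (LLE = %.4f)", x$lle), ...)
  sel <- x$curve$steps >= x$fit_lo_step & x$curve$steps <= x$fit_hi_step
  f <- ls_line(x$curve$steps[sel], x$curve$y[sel])
  abline(f$intercept, f$slope, lty = 2)
  invisible(x)
}

#' Chaotic feature pair (CD, LLE) of an epoch
#'
#' Runs [correlation_dimension()] and [lyapunov_max()] on each channel of a
#' preprocessed epoch with shared embedding settings and reduces
#' multi-channel results by the configured rule (default: mean over
#' channels). This is the per-epoch feature extractor feeding the group
#' comparison and the classifier.
#'
#' @param epoch An [eeg_epoch()].
#' @param m,lag,theiler,dt Embedding and divergence settings (defaults
#'   m = 10, lag = 1, Theiler window `m * lag`, dt = 1).
#' @param channel_reduce `"mean"` (average per-channel features) or
#'   `"first"` (use channel 1 only).
#' @param epoch_id Identifier carried into the result.
#' @return An object of class `chaos_features`: `cd`, `cd_r2`, `lle`,
#'   `lle_r2`, `epoch_id`, `config`.
#' @export
chaos_features <- function(epoch, m = 10L, lag = 1L, theiler = NULL,
                           dt = 1, channel_reduce = c("mean", "first"),
                           epoch_id = "") {
  channel_reduce <- match.arg(channel_reduce)
  stopifnot(inherits(epoch, "eeg_epoch"))
  nch <- if (channel_reduce == "first") 1L else ncol(epoch$samples)
  per <- lapply(seq_len(nch), function(ch) {
    xv <- as_signal_vector(epoch, ch)
    cd <- tryCatch(correlation_dimension(xv, m = m, lag = lag,
                                         theiler = theiler),
                   error = function(e)
                     stop("epoch '", epoch_id, "' channel ", ch, ": ",
                          conditionMessage(e), call. = FALSE))
    ll <- tryCatch(lyapunov_max(xv, m = m, lag = lag, dt = dt),
                   error = function(e)
                     stop("epoch '", epoch_id, "' channel ", ch, ": ",
                          conditionMessage(e), call. = FALSE))
    c(cd$cd, cd$r_squared, ll$lle, ll$r_squared)
  })
  v <- colMeans(do.call(rbind, per))
  structure(list(cd = v[1], cd_r2 = v[2], lle = v[3], lle_r2 = v[4],
                 epoch_id = as.character(epoch_id),
                 config = list(m = as.integer(m), lag = as.integer(lag),
                               theiler = if (is.null(theiler))
                                 as.integer(m) * as.integer(lag)
                               else as.integer(theiler),
                               dt = dt, channel_reduce = channel_reduce)),
            class = "chaos_features")
}

#' @export
print.chaos_features <- function(x, ...) {
  cat(sprintf("<chaos_features> CD = %.4f (R^2 %.3f), LLE = %.4f (R^2 %.3f)\n",
              x$cd, x$cd_r2, x$lle, x$lle_r2))
  invisible(x)
}

#' Feature table for a whole cohort
#'
#' Applies [chaos_features()] to every epoch of a cohort and returns a
#' plain data frame, one row per epoch.
#'
#' @param cohort An `eeg_cohort` from [generate_cohort()], or a plain list
#'   of epochs with a parallel `labels` argument.
#' @param labels Optional per-epoch labels when `cohort` is a bare list.
#' @param ... Passed to [chaos_features()].
#' @return A data frame with columns `epoch_id`, `label`, `cd`, `cd_r2`,
#'   `lle`, `lle_r2`.
#' @export
cohort_features <- function(cohort, labels = NULL, ...) {
  if (inherits(cohort, "eeg_cohort")) {
    epochs <- cohort$epochs
    labels <- as.character(cohort$labels)
  } else {
    epochs <- cohort
    if (is.null(labels)) labels <- rep(NA_character_, length(epochs))
  }
  rows <- lapply(seq_along(epochs), function(i) {
    f <- chaos_features(epochs[[i]], epoch_id = sprintf("epoch_%04d", i), ...)
    data.frame(epoch_id = f$epoch_id, label = labels[i], cd = f$cd,
               cd_r2 = f$cd_r2, lle = f$lle, lle_r2 = f$lle_r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
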