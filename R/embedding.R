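#' Delay embedding of a scalar series
#'
#' Reconstructs an m-dimensional state-space trajectory from a scalar time
#' series by the method of delays: point k has coordinates
#' `(x_k, x_{k-lag}, ..., x_{k-(m-1)lag})`, for k from `(m-1)*lag + 1` to N,
#' giving `N - (m-1)*lag` points. Any consistent coordinate order yields the
#' same geometry; this one keeps the newest sample first.
#'
#' @param x An [eeg_epoch()] (single channel used) or numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param lag Time delay in samples (>= 1).
#' @return A numeric matrix of class `embedded_traj` (rows = state points,
#'   columns = coordinates) with attributes `m` and `lag`.
#' @examples
#' embed_delay(1:5, m = 2, lag = 2)  # points (3,1), (4,2), (5,3)
#' @export
embed_delay <- function(x, m = 10L, lag = 1L) {
  x <- as_signal_vector(x)
  m <- as.integer(m); lag <- as.integer(lag)
  if (m < 1 || lag < 1) stop("m and lag must be >= 1")
  N <- length(x)
  span <- (m - 1L) * lag
  if (N <= span)
    stop(sprintf("series too short: need more than (m-1)*lag = %d samples, got %d",
                 span, N))
  idx <- seq.int(span + 1L, N)
  pts <- vapply(0L:(m - 1L), function(k) x[idx - k * lag],
                numeric(length(idx)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  structure(pts, class = "embedded_traj", m = m, lag = lag)
}

#' @export
print.embedded_traj <- function(x, ...) {
  cat(sprintf("<embedded_traj> %d points in %d dimensions (lag %d)\n",
              nrow(x), attr(x, "m"), attr(x, "lag")))
  invisible(x)
}

# Accept an embedded_traj or a plain point matrix (rows = points).
as_point_matrix <- function(traj) {
  if (inherits(traj, "embedded_traj")) return(unclass(traj))
  if (is.matrix(traj) && is.numeric(traj)) return(traj)
  stop("expected an embedded_traj or a numeric point matrix")
}

#' Delay estimate from the autocorrelation zero crossing
#'
#' Returns the smallest lag at which the sample autocorrelation is <= 0
#' (the first sign change), the classical rule of thumb for the embedding
#' delay. If no crossing occurs within `max_lag`, returns `max_lag` with a
#' warning.
#'
#' @param x An [eeg_epoch()] or numeric vector.
#' @param max_lag Largest lag searched (must be < N/2).
#' @return Integer lag.
#' @export
delay_autocorr <- function(x, max_lag = 100L) {
  x <- as_signal_vector(x)
  if (sd(x) == 0) stop("constant signal: autocorrelation undefined")
  if (max_lag >= length(x) / 2) stop("max_lag must be below N/2")
  ac <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)[-1]
  hit <- which(ac <= 0)
  if (length(hit) == 0) {
    warning("no autocorrelation zero crossing within max_lag; returning max_lag")
    return(as.integer(max_lag))
  }
  as.integer(hit[1])
}

#' Histogram mutual information between two samples
#'
#' Mutual information in nats from a joint histogram with `n_bins`
#' equal-width bins per axis over each sample's observed range:
#' `sum p_ij * log(p_ij / (p_i p_j))`. Equal-width binning over the range
#' makes the estimate invariant to affine amplitude scaling.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of bins per axis (>= 2).
#' @return Mutual information in nats (>= 0 up to estimation error).
#' @export
histogram_mi <- function(x, y, n_bins = 16L) {
  stopifnot(length(x) == length(y), n_bins >= 2)
  bin_idx <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) stop("zero-variance input: binning undefined")
    i <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
    pmin.int(i, n_bins)
  }
  bx <- bin_idx(x); by <- bin_idx(y)
  joint <- matrix(tabulate(bx + n_bins * (by - 1L), nbins = n_bins^2),
                  n_bins) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  ref <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / ref[nz]))
}

#' Delay estimate from the first minimum of mutual information
#'
#' Computes histogram mutual information between the series and its lagged
#' copy for lags `1..max_lag` and returns the first local minimum (the
#' smallest lag k with `mi[k] < mi[k-1]` and `mi[k] <= mi[k+1]`). If the
#' curve is monotone over the searched range, returns `max_lag` with a
#' warning.
#'
#' @param x An [eeg_epoch()] or numeric vector.
#' @param max_lag Largest lag searched (< N/2).
#' @param n_bins Histogram bins per axis (default 16).
#' @return A list with `lag` (selected delay), `lags` and `mi` (the full
#'   curve, nats), and `n_bins`.
#' @export
delay_mutual_information <- function(x, max_lag = 100L, n_bins = 16L) {
  x <- as_signal_vector(x)
  if (sd(x) == 0) stop("constant signal: mutual information undefined")
  if (max_lag >= length(x) / 2) stop("max_lag must be below N/2")
  n <- length(x)
  lags <- seq_len(max_lag)
  mi <- vapply(lags, function(l)
    histogram_mi(x[seq_len(n - l)], x[(1 + l):n], n_bins), numeric(1))
  sel <- NA_integer_
  for (k in seq_len(max_lag)) {
    prev <- if (k == 1) Inf else mi[k - 1]
    nxt <- if (k == max_lag) Inf else mi[k + 1]
    if (mi[k] < prev && mi[k] <= nxt) { sel <- k; break }
  }
  if (is.na(sel)) {
    warning("mutual information monotone over searched lags; returning max_lag")
    sel <- max_lag
  }
  list(lag = as.integer(sel), lags = lags, mi = mi,
       n_bins = as.integer(n_bins))
}

#' Minimal embedding dimension by false nearest neighbours
#'
#' For each m in `1..max_m`, finds every point's nearest neighbour in the
#' m-dimensional embedding (excluding temporal neighbours within the
#' Theiler window) and flags it false when adding the (m+1)-th coordinate
#' either stretches the pair by more than `rtol` times its m-dimensional
#' distance or beyond `atol` attractor sizes (Kennel's two tests, with the
#' standard thresholds as defaults). Returns the smallest m whose false
#' fraction drops below `threshold`, or the minimising m with a warning.
#'
#' @param x An [eeg_epoch()] or numeric vector.
#' @param lag Embedding delay in samples.
#' @param max_m Largest dimension tried (>= 2).
#' @param rtol Distance-ratio threshold (default 15).
#' @param atol Attractor-size threshold (default 2).
#' @param theiler Theiler exclusion window; `NULL` uses `lag * m` per m.
#' @param threshold False-neighbour fraction below which m is accepted.
#' @return A list with `m` (selected dimension), `fractions` (per-m false
#'   fractions) and `dims`.
#' @export
fnn_dimension <- function(x, lag = 1L, max_m = 10L, rtol = 15, atol = 2,
                          theiler = NULL, threshold = 0.01) {
  x <- as_signal_vector(x)
  if (max_m < 2) stop("max_m must be >= 2")
  if (length(x) <= (max_m + 1L) * lag + 1L)
    stop("series too short to embed at max_m + 1 dimensions")
  frac <- cpp_fnn(x, as.integer(lag), as.integer(max_m), rtol, atol,
                  if (is.null(theiler)) -1L else as.integer(theiler))
  dims <- seq_len(max_m)
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok) > 0) {
    m_sel <- ok[1]
  } else {
    warning("false-neighbour fraction never fell below the threshold; ",
            "returning the minimising dimension")
    m_sel <- which.min(frac)
  }
  list(m = as.integer(m_sel), fractions = as.numeric(frac), dims = dims)
}
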