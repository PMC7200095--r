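# Predictor set for one window of tri-axial samples: per-axis moments,
# three-axis posture/intensity summaries (q, pitch, roll, ODBA) and the
# one-sided FFT magnitude spectrum of each axis. Moment conventions are
# population (divide-by-n) throughout; kurtosis is the plain standardized
# 4th central moment (3 for a normal sample), not excess.

#' Per-axis moment statistics of a sample window
#'
#' Computes mean, standard deviation, inverse coefficient of variation
#' (mean/sd), variance, skewness and kurtosis with population (divide-by-n)
#' definitions. For a constant window (sd = 0), `inv_cv`, `skewness` and
#' `kurtosis` are undefined; they are mapped to the sentinel 0 so that
#' feature vectors stay finite on deep-rest windows.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Named numeric vector: `mean`, `sd`, `inv_cv`, `variance`,
#'   `skewness`, `kurtosis`.
#' @examples
#' axis_moments(c(1, 2, 3, 4))
#' @export
axis_moments <- function(samples) {
  if (length(samples) < 2)
    stop("insufficient data: need at least 2 samples")
  n <- length(samples)
  m <- mean(samples)
  d <- samples - m
  v <- sum(d^2) / n
  s <- sqrt(v)
  if (s > 0) {
    skw <- sum(d^3) / n / s^3
    krt <- sum(d^4) / n / s^4
    icv <- m / s
  } else {
    skw <- 0; krt <- 0; icv <- 0
  }
  c(mean = m, sd = s, inv_cv = icv, variance = v,
    skewness = skw, kurtosis = krt)
}

#' Overall dynamic body acceleration of a window
#'
#' The static component of each axis is its window mean; the dynamic
#' component is the residual. ODBA is the mean over samples of the summed
#' absolute dynamic components of the three axes — a standard proxy for
#' movement intensity.
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return Non-negative scalar; 0 for a constant window.
#' @examples
#' odba(rep(1, 10), rep(0, 10), rep(0, 10))  # 0
#' @export
odba <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("shape error: axes must have equal length")
  mean(abs(x - mean(x)) + abs(y - mean(y)) + abs(z - mean(z)))
}

#' Posture angles (pitch and roll) of a window
#'
#' Derived from the static (gravitational) component, i.e. the per-axis
#' window means, under the collar axis convention x = sway, y = surge,
#' z = heave: pitch = atan2(mean_y, sqrt(mean_x^2 + mean_z^2)) and
#' roll = atan2(mean_x, sqrt(mean_y^2 + mean_z^2)), both in degrees.
#' Alternative sign/offset conventions differ only by transformations the
#' classifiers absorb.
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return Named numeric vector `pitch`, `roll` in degrees.
#' @examples
#' pitch_roll(0, 0, 1)  # gravity on the heave axis: pitch = roll = 0
#' @export
pitch_roll <- function(x, y, z) {
  mx <- mean(x); my <- mean(y); mz <- mean(z)
  if (mx == 0 && my == 0 && mz == 0)
    stop("undefined orientation: all-zero mean acceleration vector")
  deg <- 180 / pi
  c(pitch = atan2(my, sqrt(mx^2 + mz^2)) * deg,
    roll = atan2(mx, sqrt(my^2 + mz^2)) * deg)
}

#' Mean vector magnitude (q) of a window
#'
#' Mean over samples of the Euclidean norm sqrt(x^2 + y^2 + z^2).
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @examples
#' q_stat(3, 4, 0)  # 5
#' @export
q_stat <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("shape error: axes must have equal length")
  mean(sqrt(x^2 + y^2 + z^2))
}

#' One-sided FFT magnitude spectrum of a window
#'
#' Unnormalized magnitudes of the discrete Fourier transform, one-sided
#' including the DC bin: length `floor(w/2) + 1` for window length `w`.
#' No taper is applied; the spectrum preserves the within-window temporal
#' structure that the summary moments discard.
#'
#' @param samples Numeric vector of length `w`.
#' @return Numeric vector of `floor(w/2) + 1` magnitudes (bin 0 = DC).
#' @examples
#' sp <- fft_spectrum(sin(2 * pi * 3 * (0:31) / 32))
#' which.max(sp[-1])  # dominant bin 3
#' @export
fft_spectrum <- function(samples) {
  w <- length(samples)
  Mod(stats::fft(samples))[seq_len(w %/% 2 + 1)]
}

#' Names of the full predictor set for a given window length
#'
#' The column order is frozen: per-axis moments (x, y, z blocks of mean,
#' sd, inv_cv, variance, skewness, kurtosis), then q, pitch, roll, odba,
#' then the FFT magnitude blocks fft_x_0.., fft_y_0.., fft_z_0... For
#' w = 79 this yields 18 + 4 + 3*40 = 142 predictors.
#'
#' @param w Window length (samples per axis).
#' @return Character vector of predictor names.
#' @export
feature_names <- function(w) {
  mom <- c("mean", "sd", "inv_cv", "variance", "skewness", "kurtosis")
  nf <- w %/% 2 + 1
  c(paste0(rep(c("x", "y", "z"), each = 6), "_", mom),
    "q", "pitch", "roll", "odba",
    paste0("fft_x_", seq_len(nf) - 1),
    paste0("fft_y_", seq_len(nf) - 1),
    paste0("fft_z_", seq_len(nf) - 1))
}

#' Compute the full predictor vector for one window
#'
#' @param window Numeric matrix with columns `x`, `y`, `z` (one row per
#'   sample) or a list with elements `x`, `y`, `z`.
#' @return Named numeric vector in the order of [feature_names()]; finite
#'   for all finite input (degenerate windows use the sentinel rules of
#'   [axis_moments()]).
#' @export
featurize <- function(window) {
  if (is.list(window) && !is.data.frame(window))
    window <- cbind(x = window$x, y = window$y, z = window$z)
  window <- as.matrix(window)
  if (nrow(window) < 2) stop("window length must be >= 2")
  x <- window[, 1]; y <- window[, 2]; z <- window[, 3]
  out <- c(axis_moments(x), axis_moments(y), axis_moments(z),
           q_stat(x, y, z), pitch_roll(x, y, z), odba(x, y, z),
           fft_spectrum(x), fft_spectrum(y), fft_spectrum(z))
  names(out) <- feature_names(nrow(window))
  out
}

# Vectorized feature computation for all step-1..k windows of one burst.
# mat: n x 3 sample matrix; offsets: 0-based window starts; w: window size.
# Returns a (length(offsets) x n_features) matrix. Hot path for expand().
featurize_windows <- function(mat, offsets, w) {
  nw <- length(offsets)
  nf_fft <- w %/% 2 + 1
  res <- matrix(NA_real_, nw, 22 + 3 * nf_fft)
  idx <- outer(seq_len(w), offsets, "+")  # w x nw (offsets are 0-based)
  per_axis <- function(v) {
    X <- matrix(v[idx], w, nw)
    m <- colMeans(X)
    D <- X - rep(m, each = w)
    v2 <- colMeans(D^2)
    s <- sqrt(v2)
    ok <- s > 0
    icv <- ifelse(ok, m / s, 0)
    skw <- ifelse(ok, colMeans(D^3) / s^3, 0)
    krt <- ifelse(ok, colMeans(D^4) / s^4, 0)
    list(X = X, D = D, mom = cbind(m, s, icv, v2, skw, krt))
  }
  ax <- lapply(1:3, function(j) per_axis(mat[, j]))
  res[, 1:6] <- ax[[1]]$mom
  res[, 7:12] <- ax[[2]]$mom
  res[, 13:18] <- ax[[3]]$mom
  mx <- ax[[1]]$mom[, 1]; my <- ax[[2]]$mom[, 1]; mz <- ax[[3]]$mom[, 1]
  res[, 19] <- colMeans(sqrt(ax[[1]]$X^2 + ax[[2]]$X^2 + ax[[3]]$X^2))
  deg <- 180 / pi
  res[, 20] <- atan2(my, sqrt(mx^2 + mz^2)) * deg
  res[, 21] <- atan2(mx, sqrt(my^2 + mz^2)) * deg
  res[, 22] <- colMeans(abs(ax[[1]]$D) + abs(ax[[2]]$D) + abs(ax[[3]]$D))
  for (j in 1:3) {
    sp <- Mod(stats::mvfft(ax[[j]]$X))[seq_len(nf_fft), , drop = FALSE]
    res[, 22 + (j - 1) * nf_fft + seq_len(nf_fft)] <- t(sp)
  }
  colnames(res) <- feature_names(w)
  res
}
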