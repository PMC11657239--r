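#' Signal vector magnitude of tri-axial samples
#'
#' SVM collapses a tri-axial sample to the orientation-robust scalar
#' `sqrt(ax^2 + ay^2 + az^2)`. Applied elementwise to vectors; the same
#' formula serves accelerometer (m/s^2) and gyroscope (deg/s) axes.
#'
#' @param ax,ay,az Per-axis values (vectors of equal length).
#' @return Numeric vector of Euclidean norms.
#' @export
#' @examples
#' compute_svm(3, 4, 0)  # 5
compute_svm <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop("non-finite input to compute_svm")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Build an SVM series from an IMU recording
#'
#' @param rec An `imu_recording`.
#' @param source `"accel"` (m/s^2) or `"gyro"` (deg/s).
#' @return An `svm_series`: the scalar magnitude per sample on the
#'   recording's time base, carrying the sampling rate and processing flags.
#' @export
svm_from_recording <- function(rec, source = c("accel", "gyro")) {
  source <- match.arg(source)
  s <- rec$samples
  values <- if (source == "accel") compute_svm(s$ax, s$ay, s$az)
            else compute_svm(s$gx, s$gy, s$gz)
  svm_series(values, sample_rate_hz = rec$sample_rate_hz, source = source)
}

#' @rdname svm_from_recording
#' @param values Numeric vector of magnitudes.
#' @param sample_rate_hz Sampling rate of the series.
#' @param normalized Whether the series has been z-scored.
#' @param filter_spec Record of filter parameters already applied (or NULL).
#' @export
svm_series <- function(values, sample_rate_hz, source = "accel",
                       normalized = FALSE, filter_spec = NULL) {
  if (!normalized && any(values < 0))
    stop("raw SVM values must be non-negative")
  structure(list(values = as.numeric(values),
                 sample_rate_hz = sample_rate_hz,
                 source = source,
                 normalized = normalized,
                 filter_spec = filter_spec),
            class = "svm_series")
}

#' @export
print.svm_series <- function(x, ...) {
  cat(sprintf("<svm_series> %s, %d samples @ %g Hz%s%s\n",
              x$source, length(x$values), x$sample_rate_hz,
              if (!is.null(x$filter_spec)) ", filtered" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

# reflect-pad a series by p samples on each side (mirror without repeating
# the edge sample), to suppress start/end filter transients
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1)
  c(x[(p + 1):2], x, x[(n - 1):(n - p)])
}

#' Low-pass filter an SVM series
#'
#' Removes high-intensity noise while preserving the dominant gait
#' periodicity (gait energy sits below ~6 Hz). Default is a zero-phase
#' Butterworth low-pass (order-2 filter run forward and backward, i.e. a
#' 4th-order effective response) at 6 Hz; a centred moving average is
#' available as a simple linear alternative. Reflect padding keeps the
#' output the same length as the input and protects the first and last
#' gait cycles from edge transients.
#'
#' @param series An `svm_series`.
#' @param type `"butterworth"` or `"moving_average"`.
#' @param cutoff_hz Low-pass cutoff (Hz), Butterworth only.
#' @param order Effective filter order (even; forward-backward halves it).
#' @param window Moving-average window length (odd, samples).
#' @return A filtered `svm_series` of identical length.
#' @export
filter_svm <- function(series, type = c("butterworth", "moving_average"),
                       cutoff_hz = 6, order = 4, window = 5) {
  type <- match.arg(type)
  x <- series$values
  n <- length(x)
  if (type == "butterworth") {
    w <- cutoff_hz / (series$sample_rate_hz / 2)
    if (w <= 0 || w >= 1)
      stop("cutoff_hz must lie strictly inside (0, Nyquist)")
    if (order %% 2 != 0) stop("order must be even for zero-phase filtering")
    # transient length scales with 1/cutoff; pad generously so forward-
    # backward filtering settles inside the reflected margins
    pad <- max(3 * order, ceiling(3 * series$sample_rate_hz / cutoff_hz))
    if (n <= pad) stop("series too short for the requested filter")
    bf <- signal::butter(order / 2, w, type = "low")
    xp <- reflect_pad(x, pad)
    yp <- signal::filtfilt(bf, xp)
    y <- yp[(pad + 1):(pad + n)]
    spec <- list(type = type, cutoff_hz = cutoff_hz, order = order)
  } else {
    if (window %% 2 != 1) stop("window must be odd")
    if (n <= window) stop("series shorter than the moving-average window")
    half <- (window - 1) / 2
    xp <- reflect_pad(x, half)
    y <- as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))
    y <- y[(half + 1):(half + n)]
    spec <- list(type = type, window = window)
  }
  if (!series$normalized) y <- pmax(y, 0)  # filter undershoot below the SVM floor
  svm_series(y, series$sample_rate_hz, series$source,
             normalized = series$normalized, filter_spec = spec)
}

#' Z-score an SVM series
#'
#' Per-recording normalization to mean 0 and (population) standard
#' deviation 1. The pipeline order is fixed as filter, then normalize.
#'
#' @param series An `svm_series`.
#' @return Normalized `svm_series`.
#' @export
normalize_svm <- function(series) {
  x <- series$values
  s <- sd_pop(x)
  if (s == 0) stop("cannot normalize a zero-variance series")
  out <- series
  out$values <- (x - mean(x)) / s
  out$normalized <- TRUE
  out
}
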