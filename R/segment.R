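#' Segment a filtered SVM series into gait cycles
#'
#' Cycle boundaries are successive prominent SVM peaks (peak-to-peak, i.e.
#' one step of the lumbar magnitude signal). Peaks must have topographic
#' prominence of at least `prominence_factor` times the series' population
#' SD and be separated by at least `min_peak_sep_s`. Cycles whose duration
#' falls outside `[min_duration_s, max_duration_s]` are dropped (and
#' counted, see the `dropped` attribute), never merged.
#'
#' @param series A filtered (and typically normalized) `svm_series`.
#' @param recording Optional `imu_recording` supplying the `distance_m`
#'   channel; without it `start_distance_m` is `NA`.
#' @param min_peak_sep_s Minimum peak separation (s).
#' @param prominence_factor Prominence threshold as a multiple of the
#'   series SD.
#' @param min_duration_s,max_duration_s Plausible stride-duration bounds (s).
#' @return A `gait_cycles` object: a list with `cycles` (data.frame of
#'   `start_idx`, `end_idx` half-open sample indices, `start_distance_m`,
#'   `duration_s`), `values` (list of per-cycle SVM slices), and counts of
#'   detected/dropped cycles.
#' @export
segment_cycles <- function(series, recording = NULL,
                           min_peak_sep_s = 0.4, prominence_factor = 0.5,
                           min_duration_s = 0.4, max_duration_s = 2.5) {
  x <- series$values
  fs <- series$sample_rate_hz
  s <- sd_pop(x)
  peaks <- if (s == 0) integer(0) else
    find_peaks_cpp(x, as.integer(round(min_peak_sep_s * fs)),
                   prominence_factor * s)
  if (length(peaks) < 4)
    stop("insufficient gait: fewer than 3 cycles detected")
  start_idx <- peaks[-length(peaks)]
  end_idx <- peaks[-1]
  duration_s <- (end_idx - start_idx) / fs
  ok <- duration_s >= min_duration_s & duration_s <= max_duration_s
  dropped <- sum(!ok)
  start_idx <- start_idx[ok]; end_idx <- end_idx[ok]
  duration_s <- duration_s[ok]
  if (length(start_idx) < 3)
    stop("insufficient gait: fewer than 3 cycles within duration bounds")
  start_distance_m <- if (!is.null(recording))
    recording$samples$distance_m[start_idx] else rep(NA_real_, length(start_idx))
  cycles <- data.frame(start_idx = start_idx, end_idx = end_idx,
                       start_distance_m = start_distance_m,
                       duration_s = duration_s)
  values <- lapply(seq_len(nrow(cycles)),
                   function(i) x[start_idx[i]:(end_idx[i] - 1L)])
  structure(list(cycles = cycles, values = values,
                 n_detected = length(peaks) - 1L, n_dropped = dropped,
                 sample_rate_hz = fs),
            class = "gait_cycles")
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat(sprintf("<gait_cycles> %d cycles (%d detected, %d dropped), mean stride %.3f s\n",
              nrow(x$cycles), x$n_detected, x$n_dropped,
              mean(x$cycles$duration_s)))
  invisible(x)
}

#' SVM slice of one gait cycle
#'
#' @param cycles A `gait_cycles` object.
#' @param i Cycle index.
#' @return Numeric vector of the cycle's SVM values.
#' @export
cycle_values <- function(cycles, i) cycles$values[[i]]

#' Distance bin of a gait cycle
#'
#' Walks are analysed in fixed-width distance increments (200 m by default,
#' giving six sections over a 1,200 m walk). A cycle belongs to
#' `floor(start_distance_m / bin_width_m)`, clamped to the last bin so a
#' cycle starting exactly at `total_m` still counts.
#'
#' @param start_distance_m Distance at cycle start (m); vectorized.
#' @param bin_width_m Bin width (m).
#' @param total_m Total walk length (m).
#' @return Integer 0-based bin indices.
#' @export
#' @examples
#' cycle_distance_bin(c(0, 1199.9), 200, 1200)  # 0 and 5
cycle_distance_bin <- function(start_distance_m, bin_width_m = 200,
                               total_m = 1200) {
  if (any(start_distance_m < 0)) stop("negative start distance")
  if (any(start_distance_m > total_m)) stop("start distance exceeds total_m")
  n_bins <- ceiling(total_m / bin_width_m)
  pmin(as.integer(floor(start_distance_m / bin_width_m)), n_bins - 1L)
}

#' Human-readable label for a distance bin
#'
#' @param bin 0-based bin index.
#' @param bin_width_m Bin width (m).
#' @return Character like `"200-400m"`.
#' @export
distance_bin_label <- function(bin, bin_width_m = 200) {
  sprintf("%d-%dm", bin * bin_width_m, (bin + 1) * bin_width_m)
}
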