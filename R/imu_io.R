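#' Flooring materials and age groups used throughout the package
#'
#' The four sidewalk pavement materials and five participant age groups the
#' study design compares. All validation of `material` / `age_group` labels
#' is against these closed sets.
#'
#' @return Character vector of labels.
#' @export
imu_materials <- function() MATERIALS

#' @rdname imu_materials
#' @export
imu_age_groups <- function() AGE_GROUPS

#' Construct and validate an IMU recording
#'
#' An `imu_recording` holds one walk of one participant on one flooring
#' material: a sample table with time `t` (s), tri-axial acceleration
#' `ax, ay, az` (m/s^2), tri-axial angular velocity `gx, gy, gz` (deg/s) and
#' cumulative walked distance `distance_m` (m), plus the nominal sampling
#' rate and the participant / material / age-group labels.
#'
#' @param samples data.frame with columns `t, ax, ay, az, gx, gy, gz` and
#'   optionally `distance_m`.
#' @param sample_rate_hz Nominal sampling rate (Hz).
#' @param participant_id Participant label.
#' @param material One of [imu_materials()].
#' @param age_group One of [imu_age_groups()].
#' @param speed_m_s Constant walking speed used to synthesize `distance_m`
#'   when the column is absent (default 1.3 m/s, inside the 1.2-1.5 m/s
#'   adult range reported for comfortable walking).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(samples, sample_rate_hz, participant_id,
                          material, age_group, speed_m_s = 1.3) {
  required <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!("distance_m" %in% names(samples)))
    samples$distance_m <- samples$t * speed_m_s
  samples <- samples[, c(required, "distance_m")]
  rec <- structure(
    list(samples = samples,
         sample_rate_hz = sample_rate_hz,
         participant_id = as.character(participant_id),
         material = material,
         age_group = age_group),
    class = "imu_recording")
  validate_imu_recording(rec)
}

#' Validate an `imu_recording` against its invariants
#'
#' Checks: at least 2 samples; `t` strictly increasing with inter-sample
#' spacing within 1\% of `1 / sample_rate_hz`; `distance_m` non-decreasing
#' and starting at >= 0; material and age-group labels from the closed sets.
#'
#' @param rec An `imu_recording`.
#' @return `rec`, invisibly usable, after validation (errors otherwise).
#' @export
validate_imu_recording <- function(rec) {
  s <- rec$samples
  if (nrow(s) < 2)
    stop("recording must have at least 2 samples")
  if (!all(is.finite(as.matrix(s))))
    stop("recording contains non-finite values")
  dt <- diff(s$t)
  if (any(dt <= 0))
    stop("time column must be strictly increasing (violation near row ",
         which(dt <= 0)[1] + 1L, ")")
  nominal <- 1 / rec$sample_rate_hz
  if (any(abs(dt - nominal) > 0.01 * nominal))
    stop("inter-sample spacing deviates more than 1% from 1/sample_rate_hz")
  if (any(diff(s$distance_m) < 0) || s$distance_m[1] < 0)
    stop("distance_m must be non-decreasing and start at >= 0")
  if (!(rec$material %in% MATERIALS))
    stop("unknown material '", rec$material, "'; expected one of: ",
         paste(MATERIALS, collapse = ", "))
  if (!(rec$age_group %in% AGE_GROUPS))
    stop("unknown age_group '", rec$age_group, "'; expected one of: ",
         paste(AGE_GROUPS, collapse = ", "))
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<imu_recording> %s | %s | %s\n  %d samples @ %g Hz, %.1f s, %.1f m walked\n",
    x$participant_id, x$material, x$age_group,
    nrow(s), x$sample_rate_hz, s$t[nrow(s)] - s$t[1], max(s$distance_m)))
  invisible(x)
}

#' Read an IMU recording from a self-describing CSV file
#'
#' The transport format is CSV with `#`-prefixed metadata lines of the form
#' `# key: value` for `participant_id`, `material`, `age_group` and
#' `sample_rate_hz`, followed by a header row naming the seven signal
#' columns (and optionally `distance_m`). When `distance_m` is absent it is
#' synthesized as `t * speed_m_s` (constant-speed assumption).
#'
#' @param path File to read.
#' @param speed_m_s Constant speed for distance synthesis (m/s).
#' @return An `imu_recording`.
#' @export
read_imu_recording <- function(path, speed_m_s = 1.3) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("participant_id", "material", "age_group", "sample_rate_hz"))
    if (is.null(meta[[key]]))
      stop("metadata line '# ", key, ": ...' missing in ", path)
  body_idx <- setdiff(seq_along(lines), meta_idx)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) < 2) stop("no data rows in ", path)
  header <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  nfield <- length(header)
  for (i in body_idx[-1]) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != nfield)
      stop("malformed row at line ", i, ": expected ", nfield,
           " fields, found ", length(f))
    if (anyNA(suppressWarnings(as.numeric(f))))
      stop("malformed row at line ", i, ": non-numeric field")
  }
  df <- read.csv(textConnection(lines[body_idx]), header = TRUE)
  imu_recording(df,
                sample_rate_hz = as.numeric(meta$sample_rate_hz),
                participant_id = meta$participant_id,
                material = meta$material,
                age_group = meta$age_group,
                speed_m_s = speed_m_s)
}

#' Write an IMU recording to the package CSV transport format
#'
#' @param rec An `imu_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_imu_recording <- function(rec, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c(
    paste0("# participant_id: ", rec$participant_id),
    paste0("# material: ", rec$material),
    paste0("# age_group: ", rec$age_group),
    paste0("# sample_rate_hz: ", format(rec$sample_rate_hz, digits = 15))
  ), con)
  df <- rec$samples
  num <- vapply(df, function(col) formatC(col, digits = 17, format = "g"),
                character(nrow(df)))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(matrix(num, nrow = nrow(df)), 1, paste, collapse = ","), con)
  invisible(path)
}

#' Write a cohort summary to a tidy long-format CSV
#'
#' One row per (material, age_group, distance_bin) cell with `n, mean, sd,
#' min, max`. Numeric values are written with full precision so a read-back
#' reproduces them bit-for-bit.
#'
#' @param summary A `cohort_summary` (see [aggregate_scores()]).
#' @param path Output file.
#' @param header_comment Optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path, header_comment = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  cells <- summary$cells
  if (!nrow(cells)) stop("summary is empty")
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  num_cols <- c("n", "mean", "sd", "min", "max")
  out <- cells
  for (cc in num_cols) out[[cc]] <- formatC(cells[[cc]], digits = 17, format = "g")
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

#' Read back a cohort summary written by [write_cohort_summary()]
#'
#' @param path File to read.
#' @return data.frame of summary cells.
#' @export
read_cohort_summary <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
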