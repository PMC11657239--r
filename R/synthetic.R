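#' Default flooring-material profiles for the gait simulator
#'
#' One row per material with the targets and shape parameters the
#' generator uses:
#' \itemize{
#'   \item `accel_svm_mean` / `accel_svm_sd` (m/s^2) and `gyro_svm_mean` /
#'     `gyro_svm_sd` (deg/s): target magnitude distributions of the
#'     per-sample SVM over a full walk. Defaults are the study's reported
#'     per-material values (wood 14.2 +/- 6.5, asphalt 15.7 +/- 7.1,
#'     concrete block 18.3 +/- 9.2, cement 19.1 +/- 9.5 for the
#'     accelerometer; 2.6/1.3, 2.5/1.2, 2.8/1.4, 2.9/1.5 for the gyro).
#'   \item `hardness`: ordinal surface hardness (cement > concrete block >
#'     asphalt > wood) driving waveform sharpness — harder surfaces give a
#'     spikier, higher-variance stride template.
#'   \item `sharpness`: second-harmonic weight of the stride template.
#'   \item `base_jitter`: cycle-to-cycle amplitude/timing jitter SD at the
#'     start of the walk — the parameter the DTW score tracks. Ordered
#'     cement > asphalt > concrete block > wood, matching the observed
#'     mean-DTW ordering across materials.
#'   \item `fatigue_drift`: fractional growth of the jitter SD over the
#'     full walk (e.g. 0.22 means 22\% more jitter at 1,200 m than at 0 m).
#'     Calibrated to the relative first-to-last 200 m bin DTW growth per
#'     material.
#' }
#'
#' @return data.frame, one row per material.
#' @export
default_material_profiles <- function() {
  data.frame(
    material       = c("wood", "asphalt", "concrete_block", "cement"),
    accel_svm_mean = c(14.2, 15.7, 18.3, 19.1),
    accel_svm_sd   = c(6.5, 7.1, 9.2, 9.5),
    gyro_svm_mean  = c(2.6, 2.5, 2.8, 2.9),
    gyro_svm_sd    = c(1.3, 1.2, 1.4, 1.5),
    hardness       = c(1L, 2L, 3L, 4L),
    sharpness      = c(0.05, 0.10, 0.14, 0.18),
    base_jitter    = c(0.04, 0.15, 0.10, 0.29),
    fatigue_drift  = c(2.35, 0.46, 0.79, 0.22),
    stringsAsFactors = FALSE)
}

#' Cohort design specification for the simulator
#'
#' Encodes the study design: `n_per_group` participants in each of the
#' five age groups (16 by default, an 80-participant cohort), each walking
#' `total_m` metres (1,200 m default) on each of the four materials,
#' sampled at `sample_rate_hz` (100 Hz default). Age-group walking speeds
#' default to 1.40/1.35/1.30/1.25 m/s for the four adult groups and
#' 1.00 m/s for 60+ (comfortable-pace ranges of 1.2-1.5 m/s for adults and
#' 0.8-1.2 m/s for over-60s); stride periods and the `age_gain` multiplier
#' on jitter grow with age.
#'
#' @param n_per_group Participants per age group.
#' @param total_m Walk length (m).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param seed Cohort RNG seed; per-recording sub-seeds are derived from
#'   it by counter, never from system entropy.
#' @param speed_m_s,stride_period_s,age_gain Named per-age-group vectors.
#' @param sensor_noise Within-cycle additive noise SD (normalized units).
#' @param fatigue_drift_scale Global multiplier on the per-material
#'   `fatigue_drift` (0 switches fatigue off).
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 16, total_m = 1200,
                        sample_rate_hz = 100, seed = 1,
                        speed_m_s = c("20-30" = 1.40, "30-40" = 1.35,
                                      "40-50" = 1.30, "50-60" = 1.25,
                                      "60+" = 1.00),
                        stride_period_s = c("20-30" = 1.00, "30-40" = 1.02,
                                            "40-50" = 1.05, "50-60" = 1.08,
                                            "60+" = 1.15),
                        age_gain = c("20-30" = 1.00, "30-40" = 1.05,
                                     "40-50" = 1.10, "50-60" = 1.15,
                                     "60+" = 1.20),
                        sensor_noise = 0.05,
                        fatigue_drift_scale = 1) {
  spec <- structure(list(n_per_group = as.integer(n_per_group),
                         total_m = total_m,
                         sample_rate_hz = sample_rate_hz,
                         seed = as.integer(seed),
                         speed_m_s = speed_m_s,
                         stride_period_s = stride_period_s,
                         age_gain = age_gain,
                         sensor_noise = sensor_noise,
                         fatigue_drift_scale = fatigue_drift_scale),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 1) stop("n_per_group must be >= 1")
  if (spec$total_m <= 0 || spec$sample_rate_hz <= 0)
    stop("total_m and sample_rate_hz must be positive")
  for (f in c("speed_m_s", "stride_period_s", "age_gain")) {
    v <- spec[[f]]
    if (!all(AGE_GROUPS %in% names(v)))
      stop(f, " must be named with all age groups")
    if (!all(is.finite(v)) || any(v <= 0)) stop(f, " must be finite and positive")
  }
  if (!is.finite(spec$sensor_noise) || spec$sensor_noise < 0 ||
      !is.finite(spec$fatigue_drift_scale) || spec$fatigue_drift_scale < 0)
    stop("rates must be finite and non-negative")
  spec
}

# standardize a waveform to a target mean/SD, flooring at 0 (SVM is a norm)
standardize_to <- function(u, target_mean, target_sd) {
  pmax(target_mean + target_sd * (u - mean(u)) / sd_pop(u), 0)
}

#' Simulate one IMU recording
#'
#' Generates a quasi-periodic walk: a two-harmonic stride template (second
#' harmonic weight = material `sharpness`) with per-cycle amplitude and
#' timing jitter whose SD grows linearly with walked distance at rate
#' `base_jitter * age_gain * (1 + fatigue_drift * d / total_m)`, plus
#' white sensor noise. The scalar SVM series is standardized to the
#' material's target mean/SD (accelerometer and gyroscope separately) and
#' decomposed onto three axes by a slowly wobbling direction vector, so
#' recomputing the SVM from the axes recovers the scalar exactly. The
#' distance channel assumes the age group's constant walking speed.
#'
#' @param profile One row of [default_material_profiles()].
#' @param age_group One of [imu_age_groups()].
#' @param spec A `cohort_spec`.
#' @param participant_seed Integer sub-seed for this recording.
#' @param participant_id Label.
#' @return An `imu_recording`.
#' @export
simulate_recording <- function(profile, age_group, spec,
                               participant_seed = spec$seed,
                               participant_id = "P001") {
  validate_cohort_spec(spec)
  if (profile$accel_svm_sd <= 0 || profile$gyro_svm_sd <= 0)
    stop("profile SDs must be positive")
  set.seed(participant_seed)
  # participant-level scatter of overall movement intensity (~2% CV), so
  # recordings on one material differ in their SVM level like real walkers
  scale_a <- 1 + rnorm(1, 0, 0.02)
  scale_g <- 1 + rnorm(1, 0, 0.02)
  fs <- spec$sample_rate_hz
  speed <- spec$speed_m_s[[age_group]]
  period <- spec$stride_period_s[[age_group]]
  gain <- spec$age_gain[[age_group]]
  duration <- spec$total_m / speed
  n <- floor(duration * fs)
  t <- (0:(n - 1)) / fs
  distance <- pmin(speed * t, spec$total_m)

  n_cyc <- ceiling(duration / period) + 1L
  cyc_d <- pmin((seq_len(n_cyc) - 1) * period * speed, spec$total_m)
  jsd <- profile$base_jitter * gain *
    (1 + spec$fatigue_drift_scale * profile$fatigue_drift * cyc_d / spec$total_m)
  amp_a <- 1 + rnorm(n_cyc, 0, jsd)
  amp_g <- 1 + rnorm(n_cyc, 0, jsd)
  ph <- rnorm(n_cyc, 0, 0.8 * jsd)

  idx <- pmin(floor(t / period) + 1L, n_cyc)
  k <- profile$sharpness
  phi <- 2 * pi * t / period + ph[idx]
  u_a <- amp_a[idx] * ((1 - k) * cos(phi) + k * cos(2 * phi)) +
    rnorm(n, 0, spec$sensor_noise)
  u_g <- amp_g[idx] * ((1 - k) * cos(phi + 0.6) + k * cos(2 * phi + 1.2)) +
    rnorm(n, 0, spec$sensor_noise)
  s_a <- standardize_to(u_a, scale_a * profile$accel_svm_mean,
                        scale_a * profile$accel_svm_sd)
  s_g <- standardize_to(u_g, scale_g * profile$gyro_svm_mean,
                        scale_g * profile$gyro_svm_sd)

  al_a <- 0.35 + rnorm(n, 0, 0.02); be_a <- 0.70 + rnorm(n, 0, 0.02)
  al_g <- 0.50 + rnorm(n, 0, 0.02); be_g <- 0.95 + rnorm(n, 0, 0.02)
  samples <- data.frame(
    t = t,
    ax = s_a * cos(al_a) * cos(be_a),
    ay = s_a * cos(al_a) * sin(be_a),
    az = s_a * sin(al_a),
    gx = s_g * cos(al_g) * cos(be_g),
    gy = s_g * cos(al_g) * sin(be_g),
    gz = s_g * sin(al_g),
    distance_m = distance)
  imu_recording(samples, fs, participant_id, profile$material, age_group)
}

# counter-derived sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %%
               2147483647)
}

#' Simulate a full study cohort
#'
#' One recording per participant x material (default 16 x 5 age groups x
#' 4 materials = 320 recordings), with a ground-truth manifest recording
#' every generator parameter per recording for parameter-recovery tests.
#' With `as = "manifest"` no recordings are materialized: rows are
#' realized on demand with [simulate_manifest_recording()], which keeps
#' full cohorts within modest memory.
#'
#' @param spec A `cohort_spec`.
#' @param profiles Material profile table.
#' @param as `"list"` (recordings + manifest) or `"manifest"`.
#' @return List with `manifest` (data.frame) and, for `as = "list"`,
#'   `recordings`.
#' @export
simulate_cohort <- function(spec, profiles = default_material_profiles(),
                            as = c("list", "manifest")) {
  as <- match.arg(as)
  validate_cohort_spec(spec)
  grid <- expand.grid(material = profiles$material,
                      p = seq_len(spec$n_per_group),
                      age_group = AGE_GROUPS,
                      stringsAsFactors = FALSE)
  counter <- seq_len(nrow(grid))
  pnum <- (match(grid$age_group, AGE_GROUPS) - 1L) * spec$n_per_group + grid$p
  pr <- profiles[match(grid$material, profiles$material), ]
  manifest <- data.frame(
    participant_id = sprintf("P%03d", pnum),
    age_group = grid$age_group,
    material = grid$material,
    seed = derive_seed(spec$seed, counter),
    speed_m_s = unname(spec$speed_m_s[grid$age_group]),
    stride_period_s = unname(spec$stride_period_s[grid$age_group]),
    age_gain = unname(spec$age_gain[grid$age_group]),
    base_jitter = pr$base_jitter,
    fatigue_drift = pr$fatigue_drift * spec$fatigue_drift_scale,
    sharpness = pr$sharpness,
    accel_svm_mean = pr$accel_svm_mean,
    accel_svm_sd = pr$accel_svm_sd,
    gyro_svm_mean = pr$gyro_svm_mean,
    gyro_svm_sd = pr$gyro_svm_sd,
    sensor_noise = spec$sensor_noise,
    stringsAsFactors = FALSE)
  dur <- spec$total_m / manifest$speed_m_s
  manifest$n_samples <- floor(dur * spec$sample_rate_hz)
  manifest$n_strides <- floor(dur / manifest$stride_period_s)
  out <- list(manifest = manifest, spec = spec)
  if (as == "list")
    out$recordings <- lapply(seq_len(nrow(manifest)), function(i)
      simulate_manifest_recording(manifest, i, spec, profiles))
  out
}

#' @rdname simulate_cohort
#' @param manifest Manifest data.frame from [simulate_cohort()].
#' @param i Row index to realize.
#' @export
simulate_manifest_recording <- function(manifest, i, spec,
                                        profiles = default_material_profiles()) {
  row <- manifest[i, ]
  profile <- profiles[profiles$material == row$material, ]
  simulate_recording(profile, row$age_group, spec,
                     participant_seed = row$seed,
                     participant_id = row$participant_id)
}

#' Write / read a cohort manifest (full-precision CSV round trip)
#'
#' @param manifest Manifest data.frame.
#' @param path CSV file.
#' @return `path` (write) or the manifest (read).
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  for (cc in names(out))
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]]))
      out[[cc]] <- formatC(out[[cc]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
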