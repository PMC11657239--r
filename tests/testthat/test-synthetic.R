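test_that("identical spec and seed reproduce a recording bit for bit", {
  spec <- tiny_spec(seed = 8, total_m = 60)
  r1 <- simulate_recording(material_profile("cement"), "60+", spec, 33)
  r2 <- simulate_recording(material_profile("cement"), "60+", spec, 33)
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_recording(material_profile("cement"), "60+", spec, 34)
  expect_false(identical(r3$samples, r1$samples))
})

test_that("achieved SVM distributions hit the per-material targets within 5%", {
  spec <- tiny_spec(seed = 2, total_m = 250)
  pr <- default_material_profiles()
  for (i in seq_len(nrow(pr))) {
    rec <- simulate_recording(pr[i, ], "30-40", spec, 100 + i)
    sa <- svm_from_recording(rec, "accel")$values
    sg <- svm_from_recording(rec, "gyro")$values
    expect_lt(abs(mean(sa) - pr$accel_svm_mean[i]) / pr$accel_svm_mean[i], 0.05)
    expect_lt(abs(sd(sa) - pr$accel_svm_sd[i]) / pr$accel_svm_sd[i], 0.05)
    expect_lt(abs(mean(sg) - pr$gyro_svm_mean[i]) / pr$gyro_svm_mean[i], 0.05)
    expect_true(all(sa >= 0) && all(sg >= 0))
  }
})

test_that("the distance channel matches the age group's constant speed", {
  spec <- tiny_spec(seed = 1, total_m = 100)
  rec <- simulate_recording(material_profile("wood"), "60+", spec, 5)
  s <- rec$samples
  expect_equal(s$distance_m,
               pmin(spec$speed_m_s[["60+"]] * s$t, spec$total_m))
  expect_equal(max(s$distance_m), 100, tolerance = 0.05)
})

test_that("cohort size is participants x materials, with full manifests", {
  co <- simulate_cohort(tiny_spec(seed = 3, total_m = 30))
  expect_length(co$recordings, 5 * 4)
  expect_equal(nrow(co$manifest), 20)
  expect_equal(sort(unique(co$manifest$material)), sort(imu_materials()))
  expect_equal(sort(unique(co$manifest$age_group)), sort(imu_age_groups()))
  # default design: 16 per group x 5 groups x 4 materials
  spec <- cohort_spec()
  expect_equal(nrow(simulate_cohort(spec, as = "manifest")$manifest), 320)
  expect_true(all(c("seed", "base_jitter", "fatigue_drift", "n_strides")
                  %in% names(co$manifest)))
  expect_true(all(co$manifest$seed > 0 & co$manifest$seed < 2^31))
})

test_that("cohorts are deterministic and manifest rows reproduce recordings", {
  spec <- tiny_spec(seed = 12, total_m = 30)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$recordings[[7]]$samples, c2$recordings[[7]]$samples)
  again <- simulate_manifest_recording(c1$manifest, 7, spec)
  expect_identical(again$samples, c1$recordings[[7]]$samples)
})

test_that("manifests round-trip through CSV unchanged", {
  co <- simulate_cohort(tiny_spec(seed = 9, total_m = 30), as = "manifest")
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(co$manifest, path)
  back <- read_manifest(path)
  expect_equal(back, co$manifest, tolerance = 0)
})

test_that("zero fatigue drift leaves per-bin scores flat; drift tilts them", {
  bin_change <- function(drift_scale) {
    spec <- cohort_spec(n_per_group = 1, total_m = 1200, sample_rate_hz = 25,
                        seed = 14, fatigue_drift_scale = drift_scale)
    rec <- simulate_recording(material_profile("wood"), "20-30", spec,
                              participant_seed = 77)
    tab <- process_recording(rec, cycle_step = 2)
    sc <- score_cohort(tab)
    bins <- tapply(sc$dtw, sc$distance_bin, mean)
    percent_change(bins[[1]], bins[[length(bins)]])
  }
  expect_lt(abs(bin_change(0)), 10)
  expect_gt(bin_change(1), 25)
})

test_that("invalid designs are rejected", {
  expect_error(cohort_spec(n_per_group = 0), "n_per_group")
  expect_error(cohort_spec(sensor_noise = -1), "non-negative")
  expect_error(cohort_spec(speed_m_s = c("20-30" = 1.3)), "age groups")
  bad <- material_profile("wood"); bad$accel_svm_sd <- 0
  expect_error(simulate_recording(bad, "20-30", tiny_spec(), 1), "positive")
})
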