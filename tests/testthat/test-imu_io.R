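make_samples <- function(n = 10, fs = 100) {
  t <- (0:(n - 1)) / fs
  data.frame(t = t, ax = 1 + sin(t), ay = 0.5 + cos(t), az = rep(9.8, n),
             gx = abs(sin(3 * t)), gy = abs(cos(3 * t)), gz = rep(0.2, n),
             distance_m = 1.3 * t)
}

test_that("a well-formed three-row file round-trips exactly", {
  rec <- imu_recording(make_samples(3), 100, "P001", "wood", "20-30")
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_recording(rec, path)
  back <- read_imu_recording(path)
  expect_equal(nrow(back$samples), 3)
  expect_equal(diff(back$samples$t), rep(0.01, 2))
  expect_equal(back$samples, rec$samples, tolerance = 0)
  expect_identical(back[c("participant_id", "material", "age_group")],
                   rec[c("participant_id", "material", "age_group")])
})

test_that("simulated recordings round-trip bit-for-bit", {
  spec <- tiny_spec(seed = 4, total_m = 40)
  for (mat in c("wood", "cement")) {
    rec <- simulate_recording(material_profile(mat), "40-50", spec, 17)
    path <- withr::local_tempfile(fileext = ".csv")
    write_imu_recording(rec, path)
    back <- read_imu_recording(path)
    expect_equal(back$samples, rec$samples, tolerance = 0)
    expect_identical(back$material, mat)
  }
})

test_that("missing distance is synthesized at constant speed", {
  s <- make_samples(1001, 100)
  s$distance_m <- NULL
  rec <- imu_recording(s, 100, "P002", "asphalt", "30-40", speed_m_s = 1.2)
  expect_equal(rec$samples$distance_m, 1.2 * s$t)
  expect_equal(max(rec$samples$distance_m), 12)
})

test_that("each recording invariant is enforced", {
  good <- make_samples(10)
  bad_t <- good; bad_t$t[5] <- bad_t$t[4]  # repeated timestamp
  expect_error(imu_recording(bad_t, 100, "P1", "wood", "20-30"),
               "strictly increasing")
  bad_gap <- good; bad_gap$t[6:10] <- bad_gap$t[6:10] + 0.005
  expect_error(imu_recording(bad_gap, 100, "P1", "wood", "20-30"), "spacing")
  bad_d <- good; bad_d$distance_m[4] <- 2; bad_d$distance_m[5] <- 1
  expect_error(imu_recording(bad_d, 100, "P1", "wood", "20-30"),
               "non-decreasing")
  expect_error(imu_recording(good, 100, "P1", "marble", "20-30"),
               "unknown material")
  expect_error(imu_recording(good, 100, "P1", "wood", "15-20"),
               "unknown age_group")
  expect_error(imu_recording(good[1, ], 100, "P1", "wood", "20-30"),
               "at least 2")
})

test_that("malformed files report the offending line", {
  rec <- imu_recording(make_samples(5), 100, "P003", "cement", "50-60")
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_recording(rec, path)
  lines <- readLines(path)
  lines[8] <- "0.02,1.0,0.5"  # too few fields (line 8 = 3rd data row)
  writeLines(lines, path)
  expect_error(read_imu_recording(path), "line 8")
  expect_error(read_imu_recording(tempfile()), "not found")
})

test_that("metadata lines are required", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# participant_id: P1", "t,ax", "0,1"), path)
  expect_error(read_imu_recording(path), "material")
})

test_that("cohort summaries round-trip and cover every occupied cell", {
  set.seed(6)
  scores <- expand.grid(participant_id = c("P1", "P2"),
                        material = c("wood", "cement"),
                        age_group = c("20-30", "60+"),
                        distance_bin = 0:5, stringsAsFactors = FALSE)
  scores$dtw <- abs(rnorm(nrow(scores), 10, 3))
  summ <- aggregate_scores(scores)
  expect_equal(nrow(summ$cells), 2 * 2 * 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_summary(summ, path)
  back <- read_cohort_summary(path)
  expect_equal(nrow(back), nrow(summ$cells))
  for (cc in c("n", "mean", "sd", "min", "max"))
    expect_identical(back[[cc]], as.vector(summ$cells[[cc]]))
  # one-cell summary: a single data row under the header
  one <- aggregate_scores(scores[1, , drop = FALSE])
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_summary(one, p2)
  expect_equal(nrow(read_cohort_summary(p2)), 1)
  expect_equal(read_cohort_summary(p2)$mean, scores$dtw[1])
})
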