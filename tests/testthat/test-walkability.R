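# noisy copies of a stride-like template
template_cycles <- function(n, seed, amp = rep(1, n), noise = 0.05) {
  set.seed(seed)
  phi <- seq(0, 2 * pi, length.out = 25)
  lapply(seq_len(n), function(i)
    amp[i] * (0.9 * cos(phi) + 0.1 * cos(2 * phi)) +
      rnorm(25, 0, noise))
}

test_that("the medoid of identical cycles is the first, at summed distance 0", {
  cyc <- rep(list(c(1, 2, 3, 2, 1)), 3)
  ref <- select_reference(cyc)
  expect_equal(ref$index, 1L)
  expect_equal(ref$summed_distance, 0)
  expect_identical(ref$selection_method, "dtw_medoid")
  expect_error(select_reference(cyc[1:2]), "at least 3")
})

test_that("the medoid avoids an outlier and matches brute-force pairwise sums", {
  cyc <- list(c(1, 2, 1), c(1, 2, 1), c(5, 9, 5))
  expect_true(select_reference(cyc)$index %in% c(1L, 2L))
  for (seed in 1:5) {
    amp <- rep(1, 20); amp[7] <- 2  # one amplitude-doubled outlier
    cyc <- template_cycles(20, seed, amp)
    ref <- select_reference(cyc)
    expect_false(ref$index == 7L)
    sums <- rowSums(outer(seq_along(cyc), seq_along(cyc),
                          Vectorize(function(i, j)
                            dtw_distance(cyc[[i]], cyc[[j]]))))
    expect_equal(ref$index, which.min(sums))
    expect_equal(ref$summed_distance, min(sums), tolerance = 1e-12)
  }
})

test_that("scoring returns zero for cycles equal to the reference", {
  cyc <- rep(list(c(0, 1, 2, 1, 0)), 4)
  ref <- select_reference(cyc)
  expect_equal(score_cycles(cyc, ref), rep(0, 4))
  expect_error(score_cycles(list(), ref), "empty")
})

test_that("an amplitude-doubled cycle scores its directly computed distance", {
  base <- template_cycles(1, 42)[[1]]
  ref <- structure(list(values = base), class = "reference_cycle")
  expect_equal(score_cycles(list(2 * base), ref),
               dtw_align(base, 2 * base)$distance, tolerance = 1e-12)
})

test_that("fatigue drift strictly raises mean scores on matched seeds", {
  score_one <- function(drift_scale) {
    spec <- tiny_spec(seed = 5, total_m = 300,
                      fatigue_drift_scale = drift_scale)
    rec <- simulate_recording(material_profile("wood"), "20-30", spec, 99)
    seg <- segment_cycles(normalized_svm(rec), recording = rec)
    ref <- select_reference(seg)
    mean(score_cycles(seg, ref))
  }
  expect_gt(score_one(1), score_one(0))
})

test_that("scoring is invariant to cycle order", {
  cyc <- template_cycles(12, 3)
  ref <- select_reference(cyc)
  sc <- score_cycles(cyc, ref)
  perm <- c(5, 1, 12, 3, 8, 2, 11, 7, 4, 10, 6, 9)
  expect_equal(score_cycles(cyc[perm], ref), sc[perm])
})

test_that("cell statistics are exact and permutation-invariant", {
  scores <- data.frame(participant_id = "P1", material = "wood",
                       age_group = "20-30", distance_bin = 0L,
                       dtw = c(2, 4, 6))
  s <- aggregate_scores(scores)
  expect_equal(s$cells$n, 3)
  expect_equal(s$cells$mean, 4)
  expect_equal(s$cells$sd, 2)       # sample SD
  expect_equal(s$cells$min, 2)
  expect_equal(s$cells$max, 6)
  expect_equal(aggregate_scores(scores, population_sd = TRUE)$cells$sd,
               sqrt(8 / 3))
  one <- aggregate_scores(data.frame(participant_id = "P1",
                                     material = "wood", age_group = "20-30",
                                     distance_bin = 2L, dtw = 7))
  expect_equal(one$cells[, c("n", "mean", "sd")],
               data.frame(n = 1L, mean = 7, sd = 0),
               ignore_attr = TRUE)
  set.seed(10)
  big <- data.frame(
    participant_id = sample(c("P1", "P2"), 40, TRUE),
    material = sample(c("wood", "cement"), 40, TRUE),
    age_group = "60+", distance_bin = sample(0:5, 40, TRUE),
    dtw = abs(rnorm(40)))
  a <- aggregate_scores(big)
  b <- aggregate_scores(big[sample(40), ])
  expect_equal(a$cells, b$cells)
  expect_equal(a$participant_means, b$participant_means)
  expect_true(all(a$cells$min <= a$cells$mean & a$cells$mean <= a$cells$max))
  expect_error(aggregate_scores(big[0, ]), "empty")
})

test_that("participant means average all of a participant's cycles per material", {
  scores <- data.frame(
    participant_id = c("P1", "P1", "P1", "P2"),
    material = c("wood", "wood", "cement", "wood"),
    age_group = "20-30",
    distance_bin = c(0L, 5L, 0L, 0L),
    dtw = c(1, 3, 10, 6))
  pm <- aggregate_scores(scores)$participant_means
  expect_equal(pm$mean_dtw[pm$participant_id == "P1" & pm$material == "wood"], 2)
  expect_equal(pm$mean_dtw[pm$participant_id == "P1" & pm$material == "cement"], 10)
  expect_equal(pm$mean_dtw[pm$participant_id == "P2" & pm$material == "wood"], 6)
})

test_that("identical cycles produce all-zero cells", {
  cyc <- rep(list(c(0, 2, 3, 2, 0)), 9)
  ref <- select_reference(cyc)
  scores <- data.frame(participant_id = "P1", material = "asphalt",
                       age_group = "40-50",
                       distance_bin = rep(0:2, each = 3),
                       dtw = score_cycles(cyc, ref))
  s <- aggregate_scores(scores)
  expect_equal(s$cells$mean, rep(0, 3))
  expect_equal(s$cells$sd, rep(0, 3))
})

test_that("percent change follows the one-decimal reporting convention", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(2, 3), 50)
  expect_equal(round(percent_change(4, 3), 1), -25)
  expect_equal(percent_below(4, 3), 25)
  expect_error(percent_change(0, 3), "positive")
  expect_error(percent_below(-1, 3), "positive")
})

test_that("stratified scoring uses each stratum's own reference", {
  cyc_a <- template_cycles(6, 1)
  cyc_b <- template_cycles(6, 2, amp = rep(3, 6))
  tab <- data.frame(participant_id = rep(c("P1", "P2"), each = 6),
                    material = rep(c("wood", "cement"), each = 6),
                    age_group = "20-30",
                    distance_bin = 0L)
  tab$values <- c(cyc_a, cyc_b)
  sc <- score_cohort(tab)
  refs <- attr(sc, "references")
  expect_setequal(names(refs), c("wood|20-30", "cement|20-30"))
  # strong amplitude difference: cross-stratum scoring would be far larger
  expect_lt(mean(sc$dtw), mean(score_cycles(cyc_b, refs[["wood|20-30"]])))
  g <- score_cohort(tab, global_reference = TRUE)
  expect_setequal(names(attr(g, "references")), "all")
})
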