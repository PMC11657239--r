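# Small simulator configurations used across tests. Sampling at 25 Hz and
# short walks keep unit tests quick; the design (materials, age groups,
# 200 m binning) is unchanged.
tiny_spec <- function(seed = 1, total_m = 120, sample_rate_hz = 25, ...) {
  cohort_spec(n_per_group = 1, total_m = total_m,
              sample_rate_hz = sample_rate_hz, seed = seed, ...)
}

material_profile <- function(name) {
  pr <- default_material_profiles()
  pr[pr$material == name, ]
}

# preprocess one recording the way the pipeline does, returning the
# normalized SVM series
normalized_svm <- function(rec, source = "accel") {
  normalize_svm(filter_svm(svm_from_recording(rec, source)))
}

# full single-cohort recovery run used by recovery tests and acceptance:
# per-material mean DTW and per-(material, bin) mean DTW
run_recovery_cohort <- function(seed, n_per_group = 16, sample_rate_hz = 25,
                                cycle_step = 6, fatigue_drift_scale = 1) {
  spec <- cohort_spec(n_per_group = n_per_group, total_m = 1200,
                      sample_rate_hz = sample_rate_hz, seed = seed,
                      fatigue_drift_scale = fatigue_drift_scale)
  co <- simulate_cohort(spec, as = "manifest")
  tabs <- vector("list", nrow(co$manifest))
  for (i in seq_len(nrow(co$manifest))) {
    rec <- simulate_manifest_recording(co$manifest, i, spec)
    tabs[[i]] <- process_recording(rec, cycle_step = cycle_step)
  }
  scores <- score_cohort(do.call(rbind, tabs))
  list(material_means = tapply(scores$dtw, scores$material, mean),
       bin_means = tapply(scores$dtw, list(scores$material,
                                           scores$distance_bin), mean),
       scores = scores)
}

# ordering of materials by a named vector of means, most unstable first
mean_ordering <- function(means) names(sort(means, decreasing = TRUE))
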