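#' Select the reference ("typical") gait cycle of a stratum
#'
#' The reference cycle of a (material, age-group) stratum is the DTW
#' medoid: the observed cycle minimizing the sum of DTW distances to all
#' other cycles considered. It is always an actual cycle, never an average
#' waveform. Ties break to the lowest index, making selection
#' deterministic. For large strata the medoid search runs over at most
#' `max_candidates` evenly spaced candidate cycles.
#'
#' @param cycles A `gait_cycles` object or a list of numeric cycle vectors
#'   (at least 3).
#' @param group_key Optional `c(material, age_group)` label pair.
#' @param cost Local cost passed to the DTW kernel.
#' @param max_candidates Cap on the number of cycles entering the pairwise
#'   medoid search.
#' @return A `reference_cycle`: list with `values`, `index` (position in
#'   the candidate list / input), `group_key`, `selection_method`.
#' @export
select_reference <- function(cycles, group_key = NULL,
                             cost = c("abs", "squared"),
                             max_candidates = 50) {
  cost <- match.arg(cost)
  vals <- if (inherits(cycles, "gait_cycles")) cycles$values else cycles
  if (length(vals) < 3) stop("need at least 3 cycles to select a reference")
  idx <- seq_along(vals)
  if (length(vals) > max_candidates)
    idx <- unique(as.integer(round(seq(1, length(vals),
                                       length.out = max_candidates))))
  cand <- vals[idx]
  D <- dtw_pairwise_cpp(cand, if (cost == "squared") 2L else 1L)
  sums <- rowSums(D)
  best <- which(sums == min(sums))[1]
  structure(list(values = cand[[best]], index = idx[best],
                 group_key = group_key,
                 selection_method = "dtw_medoid",
                 summed_distance = sums[best]),
            class = "reference_cycle")
}

#' Score gait cycles against a reference cycle
#'
#' One non-negative DTW distance per cycle; the reference cycle itself
#' scores 0.
#'
#' @param cycles A `gait_cycles` object or list of numeric cycle vectors.
#' @param ref A `reference_cycle` (or bare numeric vector).
#' @param cost Local cost.
#' @return Numeric vector of per-cycle DTW values.
#' @export
score_cycles <- function(cycles, ref, cost = c("abs", "squared")) {
  cost <- match.arg(cost)
  vals <- if (inherits(cycles, "gait_cycles")) cycles$values else cycles
  if (!length(vals)) stop("empty cycle list")
  rv <- if (inherits(ref, "reference_cycle")) ref$values else as.numeric(ref)
  dtw_distance_many_cpp(rv, vals, if (cost == "squared") 2L else 1L)
}

#' Aggregate per-cycle DTW scores into a cohort summary
#'
#' Cell statistics (n, mean, SD, min, max of the per-cycle DTW values) are
#' computed per (material, age_group, distance_bin); participant-level
#' means are computed per (participant, material) over all of that
#' participant's cycles on that material. Sample SD by default
#' (`population_sd = TRUE` switches the divisor to n).
#'
#' @param scores data.frame with columns `participant_id`, `material`,
#'   `age_group`, `distance_bin`, `dtw`.
#' @param population_sd Use the population (divisor-n) SD.
#' @return A `cohort_summary`: list with `cells` and `participant_means`
#'   data.frames.
#' @export
aggregate_scores <- function(scores, population_sd = FALSE) {
  needed <- c("participant_id", "material", "age_group", "distance_bin", "dtw")
  if (!nrow(scores)) stop("empty score table")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols))
    stop("score table missing column(s): ", paste(missing_cols, collapse = ", "))
  sdfun <- if (population_sd) sd_pop else function(x) if (length(x) > 1) sd(x) else 0
  key <- list(material = scores$material, age_group = scores$age_group,
              distance_bin = scores$distance_bin)
  cells <- do.call(rbind, lapply(split(seq_len(nrow(scores)), key, drop = TRUE),
    function(ii) {
      v <- scores$dtw[ii]
      data.frame(material = scores$material[ii[1]],
                 age_group = scores$age_group[ii[1]],
                 distance_bin = scores$distance_bin[ii[1]],
                 n = length(v), mean = mean(v), sd = sdfun(v),
                 min = min(v), max = max(v))
    }))
  cells <- cells[order(cells$material, cells$age_group, cells$distance_bin), ]
  rownames(cells) <- NULL
  pk <- list(participant_id = scores$participant_id, material = scores$material)
  pm <- do.call(rbind, lapply(split(seq_len(nrow(scores)), pk, drop = TRUE),
    function(ii) data.frame(participant_id = scores$participant_id[ii[1]],
                            material = scores$material[ii[1]],
                            n = length(ii), mean_dtw = mean(scores$dtw[ii]))))
  pm <- pm[order(pm$participant_id, pm$material), ]
  rownames(pm) <- NULL
  structure(list(cells = cells, participant_means = pm),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cells, %d participant x material means\n",
              nrow(x$cells), nrow(x$participant_means)))
  invisible(x)
}

#' Percent change between two values
#'
#' `percent_change(a, b)` is the increase from baseline `a` to `b`,
#' `100 * (b - a) / a`. `percent_below(ref, b)` expresses how far `b` sits
#' below the larger reference, `100 * (ref - b) / ref` ("X\% lower than").
#' Values are returned at full precision; the study convention is to print
#' one decimal.
#'
#' @param a Baseline (> 0).
#' @param b Comparison value.
#' @return Percent, full precision.
#' @export
#' @examples
#' round(percent_change(28.9, 35.2), 1)  # 21.8
percent_change <- function(a, b) {
  if (any(a <= 0)) stop("baseline must be positive")
  100 * (b - a) / a
}

#' @rdname percent_change
#' @param ref Reference value (> 0), the larger quantity.
#' @export
percent_below <- function(ref, b) {
  if (any(ref <= 0)) stop("reference must be positive")
  100 * (ref - b) / ref
}

#' Preprocess and segment one recording into labelled, binned cycles
#'
#' Runs the per-recording part of the pipeline: SVM, low-pass filter,
#' z-normalization, peak-to-peak segmentation, distance binning. Returns a
#' cycle table carrying the recording's labels, ready for reference
#' selection and scoring.
#'
#' @param rec An `imu_recording`.
#' @param source `"accel"` or `"gyro"` SVM.
#' @param cutoff_hz Filter cutoff (Hz).
#' @param bin_width_m,total_m Distance binning design.
#' @param cycle_step Keep every `cycle_step`-th cycle (systematic
#'   subsampling for large cohorts; 1 keeps all).
#' @param seg_opts List of overrides passed to [segment_cycles()].
#' @return data.frame with one row per kept cycle (`participant_id`,
#'   `material`, `age_group`, `distance_bin`, `duration_s`,
#'   `start_distance_m`) and the cycle SVM slices in the `values`
#'   list-column.
#' @export
process_recording <- function(rec, source = "accel", cutoff_hz = 6,
                              bin_width_m = 200, total_m = 1200,
                              cycle_step = 1, seg_opts = list()) {
  s <- svm_from_recording(rec, source)
  s <- filter_svm(s, cutoff_hz = cutoff_hz)
  s <- normalize_svm(s)
  cyc <- do.call(segment_cycles, c(list(s, recording = rec), seg_opts))
  keep <- seq(1, nrow(cyc$cycles), by = cycle_step)
  df <- cyc$cycles[keep, , drop = FALSE]
  out <- data.frame(participant_id = rec$participant_id,
                    material = rec$material,
                    age_group = rec$age_group,
                    distance_bin = cycle_distance_bin(df$start_distance_m,
                                                      bin_width_m, total_m),
                    start_distance_m = df$start_distance_m,
                    duration_s = df$duration_s)
  out$values <- cyc$values[keep]
  attr(out, "n_detected") <- cyc$n_detected
  attr(out, "n_dropped") <- cyc$n_dropped
  out
}

#' Score a cohort of processed cycle tables
#'
#' Pools cycles per (material, age_group) stratum, selects each stratum's
#' DTW-medoid reference, and scores every cycle against its own stratum's
#' reference (the study design; `global_reference = TRUE` scores all
#' cycles against one cohort-wide reference for sensitivity analysis).
#'
#' @param cycle_table data.frame as returned by (row-binding)
#'   [process_recording()].
#' @param cost Local cost.
#' @param max_ref_candidates Candidate cap for the medoid search.
#' @param global_reference Use a single cohort-wide reference.
#' @return The input table with a `dtw` column (and `values` dropped), plus
#'   the references in attribute `references`.
#' @export
score_cohort <- function(cycle_table, cost = c("abs", "squared"),
                         max_ref_candidates = 40, global_reference = FALSE) {
  cost <- match.arg(cost)
  if (!nrow(cycle_table)) stop("empty cycle table")
  grp <- if (global_reference) rep("all", nrow(cycle_table)) else
    paste(cycle_table$material, cycle_table$age_group, sep = "|")
  refs <- list()
  dtw <- numeric(nrow(cycle_table))
  for (g in unique(grp)) {
    ii <- which(grp == g)
    ref <- select_reference(cycle_table$values[ii],
                            group_key = strsplit(g, "|", fixed = TRUE)[[1]],
                            cost = cost, max_candidates = max_ref_candidates)
    refs[[g]] <- ref
    dtw[ii] <- score_cycles(cycle_table$values[ii], ref, cost = cost)
  }
  out <- cycle_table[, setdiff(names(cycle_table), "values"), drop = FALSE]
  out$dtw <- dtw
  attr(out, "references") <- refs
  out
}
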