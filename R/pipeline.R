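#' Default pipeline configuration
#'
#' A fully serializable nested list covering every stage: simulation
#' design, filter spec, segmentation parameters, DTW options, distance
#' binning, scoring and statistics options, plus the master seed. YAML
#' round-trips through [write_pipeline_config()] / [read_pipeline_config()];
#' unknown keys are rejected on read.
#'
#' @return Named nested list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "gaitdtw-output",
    simulate = list(n_per_group = 16L, total_m = 1200, sample_rate_hz = 100,
                    fatigue_drift_scale = 1),
    filter = list(type = "butterworth", cutoff_hz = 6, order = 4),
    segmentation = list(min_peak_sep_s = 0.4, prominence_factor = 0.5,
                        min_duration_s = 0.4, max_duration_s = 2.5),
    dtw = list(cost = "abs", max_ref_candidates = 40,
               global_reference = FALSE),
    binning = list(bin_width_m = 200, total_m = 1200),
    scoring = list(cycle_step = 1L, source = "accel"),
    stats = list(population_sd = FALSE)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' @rdname default_pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user)
}

#' @rdname default_pipeline_config
#' @param config Configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# FNV-1a hash of the serialized config, for provenance headers; the output
# location does not affect the analysis and is excluded
config_hash <- function(config) {
  config$output_dir <- NULL
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

stage_wrap <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop("stage <", stage, "> failed for ", id, ": ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full walkability pipeline
#'
#' simulate (or load) -> SVM preprocessing -> gait-cycle segmentation ->
#' DTW scoring against per-stratum reference cycles -> aggregation and
#' statistics. Writes five CSV artifacts to `config$output_dir` (cohort
#' summary, participant means, ANOVA table, percent-change table,
#' per-age-group distribution summaries) plus a JSON echo of the config.
#' Every output carries a `# config_hash=... seed=...` header line, and
#' identical config + seed reproduces byte-identical files.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param recordings Optional list of `imu_recording`s (or a directory of
#'   transport CSVs) to analyse instead of simulating.
#' @param quiet Suppress per-stage log messages.
#' @return Invisible list: `scores`, `summary`, `anova_accel`,
#'   `anova_gyro`, `percent_change`, `distributions`, `features`, `paths`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         recordings = NULL, quiet = FALSE) {
  config <- merge_config(default_pipeline_config(), config)
  log_msg <- function(...) if (!quiet) message("[gaitdtw] ", sprintf(...))
  sim <- config$simulate
  if (is.null(recordings)) {
    spec <- cohort_spec(n_per_group = sim$n_per_group, total_m = sim$total_m,
                        sample_rate_hz = sim$sample_rate_hz,
                        seed = config$seed,
                        fatigue_drift_scale = sim$fatigue_drift_scale)
    cohort <- simulate_cohort(spec, as = "manifest")
    n_rec <- nrow(cohort$manifest)
    get_rec <- function(i) simulate_manifest_recording(cohort$manifest, i, spec)
    rec_id <- function(i) paste0(cohort$manifest$participant_id[i], "/",
                                 cohort$manifest$material[i])
  } else {
    if (is.character(recordings)) {
      files <- list.files(recordings, pattern = "\\.csv$", full.names = TRUE)
      recordings <- lapply(files, read_imu_recording)
    }
    n_rec <- length(recordings)
    get_rec <- function(i) recordings[[i]]
    rec_id <- function(i) paste0(recordings[[i]]$participant_id, "/",
                                 recordings[[i]]$material)
  }
  log_msg("recordings in: %d", n_rec)

  cycle_tables <- vector("list", n_rec)
  feats <- vector("list", n_rec)
  n_detected <- 0L; n_dropped <- 0L
  for (i in seq_len(n_rec)) {
    rec <- stage_wrap("simulate/read", paste0("recording ", i), get_rec(i))
    tab <- stage_wrap("preprocess/segment", rec_id(i),
      process_recording(rec, source = config$scoring$source,
                        cutoff_hz = config$filter$cutoff_hz,
                        bin_width_m = config$binning$bin_width_m,
                        total_m = config$binning$total_m,
                        cycle_step = config$scoring$cycle_step,
                        seg_opts = config$segmentation))
    n_detected <- n_detected + attr(tab, "n_detected")
    n_dropped <- n_dropped + attr(tab, "n_dropped")
    cycle_tables[[i]] <- tab
    sa <- svm_from_recording(rec, "accel")$values
    sg <- svm_from_recording(rec, "gyro")$values
    feats[[i]] <- data.frame(participant_id = rec$participant_id,
                             material = rec$material,
                             age_group = rec$age_group,
                             accel_svm_mean = mean(sa), accel_svm_sd = sd(sa),
                             gyro_svm_mean = mean(sg), gyro_svm_sd = sd(sg))
  }
  cycles <- do.call(rbind, cycle_tables)
  features <- do.call(rbind, feats)
  log_msg("cycles detected: %d, dropped: %d, scored: %d",
          n_detected, n_dropped, nrow(cycles))

  scores <- stage_wrap("score", "cohort",
    score_cohort(cycles, cost = config$dtw$cost,
                 max_ref_candidates = config$dtw$max_ref_candidates,
                 global_reference = config$dtw$global_reference))
  summary <- aggregate_scores(scores,
                              population_sd = config$stats$population_sd)
  log_msg("cells reported: %d", nrow(summary$cells))

  anova_accel <- anova_oneway(split(features$accel_svm_mean, features$material))
  anova_gyro <- anova_oneway(split(features$gyro_svm_mean, features$material))

  # per-material fatigue trend: first vs last distance-bin mean
  pc <- do.call(rbind, lapply(split(summary$cells, summary$cells$material),
    function(cc) {
      bins <- aggregate(cc$mean, list(bin = cc$distance_bin), mean)
      first <- bins$x[which.min(bins$bin)]
      last <- bins$x[which.max(bins$bin)]
      data.frame(material = cc$material[1],
                 first_bin_mean = first, last_bin_mean = last,
                 percent_change = percent_change(first, last))
    }))
  rownames(pc) <- NULL

  dists <- lapply(split(scores$dtw, scores$age_group), summarize_distribution)

  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("config_hash=%s seed=%s", config_hash(config),
                 format(config$seed))
  paths <- list(
    cohort_summary = file.path(out_dir, "cohort_summary.csv"),
    participant_means = file.path(out_dir, "participant_means.csv"),
    anova = file.path(out_dir, "anova.csv"),
    percent_change = file.path(out_dir, "percent_change.csv"),
    distribution_summary = file.path(out_dir, "distribution_summary.csv"),
    config = file.path(out_dir, "config.json"))
  write_cohort_summary(summary, paths$cohort_summary, header_comment = hdr)

  write_csv_hdr <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    out <- df
    for (cc in names(out))
      if (is.numeric(out[[cc]]) && !is.integer(out[[cc]]))
        out[[cc]] <- formatC(out[[cc]], digits = 17, format = "g")
    writeLines(paste(names(out), collapse = ","), con)
    writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  }
  write_csv_hdr(summary$participant_means, paths$participant_means)
  an_row <- function(tab, label) data.frame(
    classification = label,
    component = c("between", "within", "total"),
    sum_of_squares = c(tab$ss_between, tab$ss_within, tab$ss_total),
    df = c(tab$df_between, tab$df_within, tab$df_total),
    mean_square = c(tab$ms_between, tab$ms_within, NA),
    f_ratio = c(tab$f_ratio, NA, NA),
    p_value = c(tab$p_value, NA, NA))
  write_csv_hdr(rbind(an_row(anova_accel, "accel_svm"),
                      an_row(anova_gyro, "gyro_svm")), paths$anova)
  write_csv_hdr(pc, paths$percent_change)
  dd <- do.call(rbind, lapply(names(dists), function(g) {
    d <- dists[[g]]
    data.frame(age_group = g, n = d$n, median = d$median, q1 = d$q1,
               q3 = d$q3, iqr = d$iqr, whisker_lo = d$whisker_lo,
               whisker_hi = d$whisker_hi, n_outliers = length(d$outliers))
  }))
  write_csv_hdr(dd, paths$distribution_summary)
  jsonlite::write_json(c(list(config_hash = config_hash(config)), config),
                       paths$config, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  log_msg("artifacts written to %s", out_dir)
  invisible(list(scores = scores, summary = summary,
                 anova_accel = anova_accel, anova_gyro = anova_gyro,
                 percent_change = pc, distributions = dists,
                 features = features, paths = paths))
}
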