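# Brute-force DTW oracle: exhaustive depth-first enumeration of every
# admissible warping path (monotone, continuous, boundary-respecting),
# taking the minimum total local cost. Independent of the package's
# dynamic-programming kernel: no memoization, no cost matrix.
oracle_dtw <- function(a, b, cost = "abs") {
  lc <- if (cost == "squared") function(x, y) (x - y)^2 else
    function(x, y) abs(x - y)
  n <- length(a)
  m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + lc(a[i], b[j])
    if (i == n && j == m) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1L, j, acc)
    if (j < m) walk(i, j + 1L, acc)
    if (i < n && j < m) walk(i + 1L, j + 1L, acc)
  }
  walk(1L, 1L, 0)
  best
}

# textbook one-way ANOVA decomposition, written out directly (oracle for
# anova_oneway, which delegates to stats::aov)
oracle_anova_ss <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  list(ss_between = ss_b, ss_within = ss_w,
       df_between = length(groups) - 1L,
       df_within = length(all_v) - length(groups))
}
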