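#' One-way ANOVA across groups
#'
#' Between/within variance decomposition for k independent groups (the
#' across-materials comparison of per-recording SVM statistics). The model
#' fit is delegated to [stats::aov()]; the result is returned as an
#' `anova_table` with the full decomposition (sums of squares, degrees of
#' freedom, mean squares, F ratio, upper-tail p).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return An `anova_table`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))$f_ratio  # 13.5
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(seq_along(groups),
                                      vapply(groups, length, 1L))))
  tab <- anova(aov(value ~ group, data = df))
  anova_from_ss(tab["group", "Sum Sq"], tab["group", "Df"],
                tab["Residuals", "Sum Sq"], tab["Residuals", "Df"])
}

#' ANOVA table from printed sums of squares
#'
#' Reconstructs mean squares, the F ratio and the p-value from the four
#' quantities a published one-way ANOVA table prints, enabling direct
#' checks of reported tables. Mean squares are always recomputed as SS/df.
#'
#' @param ss_between,ss_within Sums of squares (positive).
#' @param df_between,df_within Degrees of freedom (positive).
#' @return An `anova_table`: list with `ss_between`, `ss_within`,
#'   `ss_total`, `df_between`, `df_within`, `df_total`, `ms_between`,
#'   `ms_within`, `f_ratio`, `p_value`.
#' @export
#' @examples
#' round(anova_from_ss(8524.6, 3, 5043.2, 76)$f_ratio, 1)  # 42.8
anova_from_ss <- function(ss_between, df_between, ss_within, df_within) {
  if (df_between <= 0 || df_within <= 0) stop("degrees of freedom must be positive")
  if (ss_between < 0 || ss_within < 0) stop("sums of squares must be non-negative")
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  f <- ms_b / ms_w
  structure(list(ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_between + ss_within,
                 df_between = df_between, df_within = df_within,
                 df_total = df_between + df_within,
                 ms_between = ms_b, ms_within = ms_w,
                 f_ratio = f,
                 p_value = pf(f, df_between, df_within, lower.tail = FALSE)),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf(
    "<anova_table>\n  between: SS %.4g, df %d, MS %.4g\n  within:  SS %.4g, df %d, MS %.4g\n  F = %.4g, p = %.3g\n",
    x$ss_between, x$df_between, x$ms_between,
    x$ss_within, x$df_within, x$ms_within, x$f_ratio, x$p_value))
  invisible(x)
}

#' Boxplot and histogram summary of a value distribution
#'
#' Tukey boxplot convention: quartiles by linear interpolation (type-7
#' quantiles), whiskers at the most extreme data points within 1.5 IQR of
#' the quartiles, everything beyond flagged as outliers. Histogram counts
#' always sum to n.
#'
#' @param values Numeric vector (n >= 1).
#' @param breaks Histogram break specification (passed to
#'   [graphics::hist()]).
#' @return A `distribution_summary`: list with `n`, `median`, `q1`, `q3`,
#'   `iqr`, `whisker_lo`, `whisker_hi`, `outliers`, `bin_edges`, `counts`.
#' @export
summarize_distribution <- function(values, breaks = "Sturges") {
  if (!length(values)) stop("empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(list(n = length(values),
                 median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 whisker_lo = min(values[inside]),
                 whisker_hi = max(values[inside]),
                 outliers = sort(values[!inside]),
                 bin_edges = h$breaks, counts = h$counts),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "<distribution_summary> n %d, median %.4g [Q1 %.4g, Q3 %.4g], whiskers [%.4g, %.4g], %d outliers\n",
    x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi, length(x$outliers)))
  invisible(x)
}

#' 2-D feature clustering of recordings (exploratory)
#'
#' Simple seeded k-means on per-recording feature pairs (typically mean
#' accelerometer SVM vs mean gyroscope SVM), one cluster per material, as
#' a quick visual classification of flooring properties. Exploratory; not
#' part of the quantitative pipeline.
#'
#' @param features data.frame/matrix with two numeric feature columns.
#' @param k Number of clusters (default: number of materials).
#' @param seed RNG seed for reproducible restarts.
#' @param nstart Random restarts.
#' @return A [stats::kmeans()] fit.
#' @export
material_feature_clusters <- function(features, k = length(MATERIALS),
                                      seed = 1, nstart = 10) {
  m <- as.matrix(features)
  if (ncol(m) != 2) stop("expected exactly two feature columns")
  set.seed(seed)
  stats::kmeans(m, centers = k, nstart = nstart)
}
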