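#' Dynamic Time Warping alignment of two scalar series
#'
#' Computes the accumulated-cost matrix under the symmetric step pattern
#' \{(1,0), (0,1), (1,1)\}, the minimal total local cost over all monotone,
#' continuous, boundary-respecting warping paths, and one optimal path.
#' Local cost is the absolute difference (default) or squared difference of
#' the aligned samples. Backtracking breaks ties deterministically:
#' diagonal, then vertical (advance in `a`), then horizontal.
#'
#' The distance is the raw sum of local costs along the optimal path; set
#' `normalize_path = TRUE` to divide by the path length instead.
#'
#' @param a,b Numeric series (non-empty).
#' @param cost `"abs"` or `"squared"` local cost.
#' @param band Optional Sakoe-Chiba band radius: cells with `|i - j| > band`
#'   are excluded. Must be at least `abs(length(a) - length(b))`.
#'   `NULL` (default) disables the constraint.
#' @param normalize_path Divide the distance by the number of path steps.
#' @return A `dtw_result`: list with `distance`, `path` (two-column matrix
#'   of 1-based index pairs from `(1, 1)` to `(n, m)`), `cost_matrix`
#'   (accumulated costs, rows indexing `a`), and the options used.
#' @export
#' @examples
#' dtw_align(c(1, 2, 3), c(1, 2, 2, 3))$distance  # 0
dtw_align <- function(a, b, cost = c("abs", "squared"), band = NULL,
                      normalize_path = FALSE) {
  cost <- match.arg(cost)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty series")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite input")
  band_i <- -1L
  if (!is.null(band)) {
    if (band < abs(length(a) - length(b)))
      stop("band_radius smaller than the length difference: no feasible path")
    band_i <- as.integer(band)
  }
  ct <- if (cost == "squared") 2L else 1L
  D <- dtw_cost_matrix_cpp(a, b, ct, band_i)
  n <- length(a); m <- length(b)
  # backtrack; tie preference: diagonal, vertical (i-1), horizontal (j-1)
  path <- matrix(NA_integer_, n + m, 2)
  i <- n; j <- m; k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    cand_i <- c(i - 1, i - 1, i)
    cand_j <- c(j - 1, j, j - 1)
    keep <- cand_i >= 1 & cand_j >= 1
    ci <- cand_i[keep]; cj <- cand_j[keep]
    vals <- D[cbind(ci, cj)]
    pick <- which(vals == min(vals))[1]
    i <- ci[pick]; j <- cj[pick]
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("a", "b")
  dist <- D[n, m]
  if (normalize_path) dist <- dist / nrow(path)
  structure(list(distance = dist, path = path, cost_matrix = D,
                 cost = cost, band = band, normalized = normalize_path),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g (%s cost), path length %d, matrix %dx%d\n",
              x$distance, x$cost, nrow(x$path),
              nrow(x$cost_matrix), ncol(x$cost_matrix)))
  invisible(x)
}

#' DTW distance only (fast path)
#'
#' Same recursion as [dtw_align()] without materializing the matrix or the
#' path; used for medoid search and cohort scoring.
#'
#' @inheritParams dtw_align
#' @return Non-negative scalar distance.
#' @export
dtw_distance <- function(a, b, cost = c("abs", "squared"), band = NULL) {
  cost <- match.arg(cost)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty series")
  band_i <- -1L
  if (!is.null(band)) {
    if (band < abs(length(a) - length(b)))
      stop("band_radius smaller than the length difference: no feasible path")
    band_i <- as.integer(band)
  }
  dtw_distance_cpp(a, b, if (cost == "squared") 2L else 1L, band_i)
}

#' Straight (Euclidean-style) index-to-index alignment cost
#'
#' The pre-warping comparison: local costs summed along the diagonal
#' pairing `a[i] ~ b[i]`. Series of unequal length are truncated to the
#' shorter. For equal lengths the diagonal is itself an admissible warping
#' path, so this is always >= the DTW distance under the same local cost.
#'
#' @inheritParams dtw_align
#' @return Non-negative scalar.
#' @export
euclidean_align <- function(a, b, cost = c("abs", "squared")) {
  cost <- match.arg(cost)
  if (!length(a) && !length(b)) stop("empty series")
  n <- min(length(a), length(b))
  if (n == 0) stop("empty series")
  d <- as.numeric(a[seq_len(n)]) - as.numeric(b[seq_len(n)])
  if (cost == "squared") sum(d^2) else sum(abs(d))
}

#' Dump an accumulated-cost matrix to CSV (debug aid)
#'
#' @param result A `dtw_result`.
#' @param path Output CSV; rows index series `a`.
#' @return `path`, invisibly.
#' @export
write_cost_matrix <- function(result, path) {
  write.csv(result$cost_matrix, path, row.names = FALSE)
  invisible(path)
}
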