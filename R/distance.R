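#' Min-max normalize a feature matrix into the 0-1 range
#'
#' Each column is mapped by `(x - min) / (max - min)` using its observed
#' minimum and maximum; a constant column maps to all zeros, and a 0/1 binary
#' column is unchanged by construction. The observed per-column ranges are
#' retained as attributes so a run can be reproduced on new data.
#'
#' @param m numeric matrix or data.frame, patients in rows, no missing values.
#' @return a numeric matrix with attribute `normalized = TRUE` and a `ranges`
#'   attribute holding the per-column min/max used.
#' @export
minmax_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 patients to normalize")
  bad <- colnames(m)[colSums(is.na(m)) > 0]
  if (length(bad)) stop("missing values in column(s): ", paste(bad, collapse = ", "))
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  span <- hi - lo
  out <- sweep(m, 2, lo, "-")
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")  # constant column -> 0
  attr(out, "normalized") <- TRUE
  attr(out, "ranges") <- rbind(min = lo, max = hi)
  out
}

#' Marczewski-Steinhaus distance between two nonnegative scalars
#'
#' `D(a, b) = |a - b| / max(a, b)`, with `D(0, 0) = 0` (identical objects).
#' Bounded by 1 and invariant to a common positive rescaling of both inputs.
#'
#' @param a,b nonnegative numbers (vectorized).
#' @return distance(s) in `[0, 1]`.
#' @export
ms_distance_scalar <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("inputs must be nonnegative")
  mx <- pmax(a, b)
  ifelse(mx == 0, 0, abs(a - b) / mx)
}

#' Marczewski-Steinhaus distance between two feature vectors
#'
#' Two multivariate aggregations of the scalar metric are offered.
#' `"soergel"` (the default) is the standard vector extension of the
#' set-theoretic form: `sum |u_i - v_i| / sum max(u_i, v_i)`; it is a true
#' metric bounded by 1. `"mean_per_variable"` averages the scalar distance
#' over coordinates.
#'
#' @param u,v nonnegative numeric vectors of equal length (features are
#'   expected to be normalized into `[0, 1]` first).
#' @param mode `"soergel"` or `"mean_per_variable"`.
#' @return a distance in `[0, 1]`; 0 when both vectors are all-zero.
#' @export
ms_distance_vector <- function(u, v, mode = c("soergel", "mean_per_variable")) {
  mode <- match.arg(mode)
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (any(u < 0) || any(v < 0)) stop("inputs must be nonnegative")
  if (mode == "soergel") {
    den <- sum(pmax(u, v))
    if (den == 0) 0 else sum(abs(u - v)) / den
  } else {
    mean(ms_distance_scalar(u, v))
  }
}

#' Pairwise Marczewski-Steinhaus distance matrix
#'
#' @param m a normalized feature matrix from [minmax_normalize()].
#' @param mode aggregation mode, see [ms_distance_vector()].
#' @param labels optional row labels (patient ids); defaults to rownames.
#' @return a symmetric `n x n` matrix of class `ms_dist` with zero diagonal
#'   and entries in `[0, 1]`.
#' @export
pairwise_distances <- function(m, mode = c("soergel", "mean_per_variable"),
                               labels = NULL) {
  mode <- match.arg(mode)
  if (!isTRUE(attr(m, "normalized")))
    stop("input must be normalized (see minmax_normalize)")
  m <- unclass(m)
  n <- nrow(m)
  p <- ncol(m)
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (mode == "soergel") {
    num <- matrix(0, n, n)
    den <- matrix(0, n, n)
    for (j in seq_len(p)) {
      x <- m[, j]
      num <- num + abs(outer(x, x, "-"))
      den <- den + outer(x, x, pmax)
    }
    d <- ifelse(den == 0, 0, num / den)
  } else {
    d <- matrix(0, n, n)
    for (j in seq_len(p)) {
      x <- m[, j]
      mx <- outer(x, x, pmax)
      sc <- abs(outer(x, x, "-"))
      d <- d + ifelse(mx == 0, 0, sc / mx)
    }
    d <- d / p
  }
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  class(d) <- c("ms_dist", "matrix")
  d
}
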