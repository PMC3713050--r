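#' Complete-linkage agglomerative clustering
#'
#' Builds the merge tree from a pairwise distance matrix: at each step the
#' pair of clusters at minimal distance is merged, where the distance between
#' two clusters is the largest dissimilarity over cross-cluster pairs
#' (complete linkage, which makes merge heights nondecreasing). Ties on the
#' minimal distance are broken by the lexicographically smallest pair of
#' cluster representatives (a cluster's representative is its smallest member
#' index), so the merge sequence is deterministic.
#'
#' @param d a symmetric distance matrix (class `ms_dist`, `dist`, or plain
#'   matrix) over `n >= 2` objects.
#' @return an object of class `merge_tree`: list with `merge` (an
#'   `(n-1) x 2` matrix in [stats::hclust()] convention — negative entries
#'   are leaves, positive entries earlier merges), `height`, and `labels`.
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  n <- nrow(d)
  if (is.null(n) || n < 2) stop("need at least 2 objects")
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-12))
    stop("distance matrix must be square and symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  work <- d
  diag(work) <- Inf
  active <- rep(TRUE, n)
  node <- -seq_len(n)        # hclust code of the cluster rooted at each row
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    h <- min(sub)
    # candidate pairs at the minimum; rows/cols are ordered by representative
    # (original smallest member index), so the first row-major hit with
    # i < j is the lexicographic tie-break
    cand <- which(sub <= h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- idx[cand[1, 1]]
    j <- idx[cand[1, 2]]
    merge[step, ] <- .order_pair(node[i], node[j])
    height[step] <- h
    # Lance-Williams update for complete linkage: max of the two rows
    newrow <- pmax(work[i, ], work[j, ])
    work[i, ] <- newrow
    work[, i] <- newrow
    work[i, i] <- Inf
    active[j] <- FALSE
    node[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = "complete"),
            class = "merge_tree")
}

# hclust convention: singletons (negative codes) before merged clusters, and
# within a kind the smaller magnitude first
.order_pair <- function(a, b) {
  if ((a < 0 && b < 0 && abs(a) > abs(b)) || (a > 0 && b > 0 && a > b) ||
      (a > 0 && b < 0))
    c(b, a) else c(a, b)
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("complete-linkage merge tree:", length(x$labels), "leaves,",
      nrow(x$merge), "merges; height range [",
      format(min(x$height), digits = 3), ",",
      format(max(x$height), digits = 3), "]\n")
  invisible(x)
}

#' Convert a merge tree to hclust
#'
#' @param x a `merge_tree`.
#' @param ... unused.
#' @return a [stats::hclust()] object.
#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = .leaf_order(x), labels = x$labels,
                 method = x$method, dist.method = "marczewski-steinhaus"),
            class = "hclust")
}

.leaf_order <- function(tree) {
  collect <- function(code) {
    if (code < 0) return(-code)
    c(collect(tree$merge[code, 1]), collect(tree$merge[code, 2]))
  }
  collect(nrow(tree$merge))
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting clusters
#' `1..k` in decreasing size; ties in size are broken by the smallest member
#' index, so labels are deterministic.
#'
#' @param tree a `merge_tree` from [complete_linkage()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer vector of cluster labels named by the leaf labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  comp <- seq_len(n)                  # component id per leaf
  if (n - k >= 1) {
    members <- as.list(seq_len(n))    # leaves of each merge node
    for (step in seq_len(n - k)) {
      pick <- function(code) if (code < 0) -code else members[[n + code]]
      mem <- c(pick(tree$merge[step, 1]), pick(tree$merge[step, 2]))
      members[[n + step]] <- mem
      comp[mem] <- min(comp[mem])
    }
    # later merges still need member lists even though they are not applied
  }
  sizes <- table(comp)
  reps <- as.integer(names(sizes))
  ord <- order(-as.integer(sizes), reps)
  relabel <- integer(n)
  relabel[reps[ord]] <- seq_along(ord)
  stats::setNames(relabel[comp], tree$labels)
}

#' Export a merge tree as a Newick string
#'
#' Branch lengths are height differences between a node and its parent merge
#' (leaves start at height 0), so root-to-leaf path lengths equal the root
#' merge height.
#'
#' @param tree a `merge_tree`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  min_leaf <- function(code) {
    if (code < 0) -code
    else min(min_leaf(tree$merge[code, 1]), min_leaf(tree$merge[code, 2]))
  }
  # children ordered by smallest contained leaf, so output is deterministic
  kids <- function(code) {
    ab <- tree$merge[code, ]
    if (min_leaf(ab[1]) <= min_leaf(ab[2])) ab else rev(ab)
  }
  build <- function(code, parent_h) {
    if (code < 0) {
      paste0(tree$labels[-code], ":", fmt(parent_h))
    } else {
      h <- tree$height[code]
      ab <- kids(code)
      paste0("(", build(ab[1], h), ",", build(ab[2], h), "):",
             fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  ab <- kids(root)
  paste0("(", build(ab[1], h), ",", build(ab[2], h), ");")
}
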