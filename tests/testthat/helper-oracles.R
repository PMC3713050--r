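# Independent reference implementations used as oracles. They recompute the
# same quantities by the most literal route available (exhaustive search,
# direct per-step recomputation, plain density formulas) and never share code
# with the package internals they check.

# Complete linkage by literal recomputation: at every step rebuild all
# cluster-pair distances as the max over cross pairs of the ORIGINAL matrix.
# Tie-break: lexicographically smallest (min member of a, min member of b).
# Returns merge heights and the partition after each merge.
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      h <- max(d[clusters[[a]], clusters[[b]]])
      key <- c(min(clusters[[a]]), min(clusters[[b]]))
      key <- sort(key)
      if (is.null(best) || h < best$h - 1e-15 ||
          (abs(h - best$h) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(a = a, b = b, h = h, key = key)
      }
    }
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- clusters[-c(best$a, best$b)]
    clusters <- c(clusters, list(merged))
    heights[step] <- best$h
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[step]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# all permutations of 1..k (k small)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) for (pos in 0:(k - 1)) {
    out[[length(out) + 1]] <- append(p, k, after = pos)
  }
  out
}

# exhaustive assignment: best matched-diagonal sum over all permutations
exhaustive_match_sum <- function(confusion) {
  k <- max(dim(confusion))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(confusion)), seq_len(ncol(confusion))] <- confusion
  max(vapply(all_perms(k),
             function(p) sum(sq[cbind(seq_len(k), p)]), numeric(1)))
}

# plain (non-log-space) multivariate normal density
direct_dmvnorm <- function(x, mean, cov) {
  p <- length(mean)
  apply(x, 1, function(r) {
    z <- r - mean
    exp(-0.5 * drop(t(z) %*% solve(cov, z))) /
      sqrt((2 * pi)^p * det(cov))
  })
}

# a small random cohort-like feature matrix in [0, 1]
random_unit_matrix <- function(n, p) {
  matrix(runif(n * p), n, p)
}
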