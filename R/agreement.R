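#' Confusion matrix between two partitions
#'
#' @param labels_a,labels_b cluster labels of the same patients in the same
#'   order (any atomic type; levels are sorted).
#' @return integer count matrix, rows = `labels_a` levels, cols = `labels_b`
#'   levels.
#' @export
confusion_matrix <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  as.matrix(table(a = labels_a, b = labels_b))
}

# Hungarian algorithm (Jonker/e-maxx shortest augmenting path variant) for a
# square cost matrix; returns for each row the assigned column. O(n^3).
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j+1]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    way <- integer(n)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Optimal label matching between two clusterings
#'
#' Cluster numbers are arbitrary, so before agreement can be measured the
#' columns of the confusion matrix must be aligned to its rows. This solves
#' the assignment problem maximizing the matched diagonal sum (Hungarian
#' algorithm); a rectangular confusion matrix is zero-padded to square.
#'
#' @param confusion a count matrix from [confusion_matrix()].
#' @return integer vector `m` of length `nrow`: row label `i` is matched to
#'   column `m[i]` (indices into the padded square matrix).
#' @export
match_labels <- function(confusion) {
  k <- max(dim(confusion))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(confusion)), seq_len(ncol(confusion))] <- confusion
  .hungarian(max(sq) - sq)   # maximize diagonal = minimize complement
}

#' Direct agreement percentage after label matching
#'
#' @param confusion count matrix.
#' @param matching column permutation from [match_labels()].
#' @return percent of patients on the matched diagonal, in `[0, 100]`.
#' @export
direct_agreement <- function(confusion, matching) {
  k <- max(dim(confusion))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(confusion)), seq_len(ncol(confusion))] <- confusion
  100 * sum(sq[cbind(seq_len(k), matching)]) / sum(confusion)
}

#' Cohen's kappa for a matched confusion matrix
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with `po` the
#' matched-diagonal proportion and `pe` the product-of-margins expectation.
#' The standard error is the large-sample formula under the null hypothesis
#' of chance agreement (appropriate for testing kappa = 0), giving
#' `z = kappa / se` and a two-sided normal p-value.
#'
#' @param confusion a square count matrix whose diagonal is the matched
#'   agreement (apply [match_labels()] first if numberings are arbitrary).
#' @return list with `kappa`, `se`, `z`, `p`, `po`, `pe`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square (after matching/padding)")
  n <- sum(confusion)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / n
  pr <- rowSums(confusion) / n
  pc <- colSums(confusion) / n
  pe <- sum(pr * pc)
  if (pe >= 1) {
    if (po == 1) return(list(kappa = 1, se = NA_real_, z = NA_real_,
                             p = NA_real_, po = po, pe = pe))
    stop("degenerate margins: expected agreement is 1 but observed is not")
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(pe + pe^2 - sum(pr * pc * (pr + pc))) / ((1 - pe) * sqrt(n))
  z <- kappa / se
  list(kappa = kappa, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       po = po, pe = pe)
}

#' Full agreement report between two partitions
#'
#' @param labels_a,labels_b cluster labels over the same patients.
#' @return list of class `agreement_report`: `confusion`, `matching`,
#'   `direct_agreement` (percent), `kappa`, `kappa_se`, `z`, `p`.
#' @export
agreement_report <- function(labels_a, labels_b) {
  cm <- confusion_matrix(labels_a, labels_b)
  m <- match_labels(cm)
  k <- max(dim(cm))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(cm)), seq_len(ncol(cm))] <- cm
  matched <- sq[, m, drop = FALSE]
  kp <- cohens_kappa(matched)
  structure(list(confusion = cm, matching = m,
                 direct_agreement = direct_agreement(cm, m),
                 kappa = kp$kappa, kappa_se = kp$se, z = kp$z, p = kp$p),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("direct agreement ", format(x$direct_agreement, digits = 3),
      "%, kappa = ", format(x$kappa, digits = 3),
      " (z = ", format(x$z, digits = 3),
      ", p = ", format(x$p, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' ~0 for independent ones. Used to score cluster recovery against known
#' ground-truth types.
#'
#' @param labels_a,labels_b cluster labels over the same patients.
#' @return a number `<= 1`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  cm <- confusion_matrix(labels_a, labels_b)
  n <- sum(cm)
  ch2 <- function(x) x * (x - 1) / 2
  sum_cells <- sum(ch2(cm))
  sum_rows <- sum(ch2(rowSums(cm)))
  sum_cols <- sum(ch2(colSums(cm)))
  expected <- sum_rows * sum_cols / ch2(n)
  mx <- (sum_rows + sum_cols) / 2
  if (mx == expected) return(1)
  (sum_cells - expected) / (mx - expected)
}
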