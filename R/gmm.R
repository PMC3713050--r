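#' Configuration for the Gaussian-mixture EM fitter
#'
#' @param G number of mixture components (default 4, the number of patient
#'   types assumed throughout the comparison).
#' @param covariance_model `"full"` (unconstrained symmetric covariance per
#'   component) or `"diagonal"`.
#' @param tol absolute log-likelihood change declaring convergence.
#' @param max_iter iteration cap per restart.
#' @param restarts number of random initializations; the fit with the best
#'   final log-likelihood is kept.
#' @param seed integer seed making initialization reproducible.
#' @param ridge nonnegative diagonal regularizer added to every covariance;
#'   `NULL` uses `1e-6 * trace(global covariance) / p`.
#' @return a list of class `gmm_config`.
#' @export
gmm_config <- function(G = 4L, covariance_model = c("full", "diagonal"),
                       tol = 1e-8, max_iter = 2000L, restarts = 8L,
                       seed = 1L, ridge = NULL) {
  covariance_model <- match.arg(covariance_model)
  stopifnot(G >= 1, tol > 0, restarts >= 1, max_iter >= 1,
            is.null(ridge) || ridge >= 0)
  structure(list(G = as.integer(G), covariance_model = covariance_model,
                 tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 ridge = ridge),
            class = "gmm_config")
}

# log N(x; mean, cov) for all rows of x, via Cholesky (log-space throughout)
.log_dmvnorm <- function(x, mean, cov) {
  p <- ncol(x)
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) stop("singular covariance (after ridge)")
  z <- backsolve(R, t(x) - mean, transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

#' E step: responsibilities and observed-data log-likelihood
#'
#' Component membership probabilities are computed in log-space:
#' `r(i, g)` is proportional to `weight_g * N(x_i; mean_g, cov_g)` with each
#' row normalized, and the log-likelihood is the sum over patients of the
#' log mixture density.
#'
#' @param x numeric data matrix (patients x features).
#' @param model list with `weights`, `means` (G x p), `covariances`
#'   (list of G p x p matrices).
#' @return list with `responsibilities` (n x G, rows on the simplex) and
#'   `loglik`.
#' @export
gmm_e_step <- function(x, model) {
  x <- as.matrix(x)
  G <- length(model$weights)
  logp <- vapply(seq_len(G), function(g) {
    tryCatch(
      log(model$weights[g]) + .log_dmvnorm(x, model$means[g, ], model$covariances[[g]]),
      error = function(e) stop("component ", g, ": ", conditionMessage(e)))
  }, numeric(nrow(x)))
  logp <- matrix(logp, nrow = nrow(x))
  m <- apply(logp, 1, max)
  lse <- m + log(rowSums(exp(logp - m)))
  list(responsibilities = exp(logp - lse), loglik = sum(lse))
}

#' M step: maximum-likelihood parameters given responsibilities
#'
#' Weights are the responsibility column means, means the
#' responsibility-weighted data means, and covariances the
#' responsibility-weighted scatter (n-denominator) plus `ridge` times the
#' identity. A component whose total responsibility collapses to ~0 is
#' re-seeded from the data point farthest from the current means.
#'
#' @param x data matrix.
#' @param resp n x G responsibility matrix, rows on the simplex.
#' @param covariance_model `"full"` or `"diagonal"`.
#' @param ridge diagonal regularizer.
#' @return model list (`weights`, `means`, `covariances`).
#' @export
gmm_m_step <- function(x, resp, covariance_model = "full", ridge = 0) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x); G <- ncol(resp)
  nk <- colSums(resp)
  empty <- which(nk < n * 1e-10)
  means <- matrix(0, G, p)
  covs <- vector("list", G)
  for (g in setdiff(seq_len(G), empty)) {
    w <- resp[, g] / nk[g]
    mu <- colSums(x * w)
    xc <- sweep(x, 2, mu)
    S <- crossprod(xc * sqrt(w), xc * sqrt(w))
    if (covariance_model == "diagonal") S <- diag(diag(S), p)
    means[g, ] <- mu
    covs[[g]] <- S + diag(ridge, p)
  }
  if (length(empty)) {
    # farthest-point re-seed for collapsed components
    live <- means[setdiff(seq_len(G), empty), , drop = FALSE]
    gcov <- stats::cov(x) * (n - 1) / n + diag(ridge, p)
    for (g in empty) {
      dmin <- apply(x, 1, function(r) min(colSums((t(live) - r)^2)))
      far <- which.max(dmin)
      means[g, ] <- x[far, ]
      covs[[g]] <- if (covariance_model == "diagonal")
        diag(diag(gcov), p) else gcov
      nk[g] <- 1
      live <- rbind(live, x[far, ])
      message("re-seeded empty component ", g, " from data point ", far)
    }
  }
  list(weights = nk / sum(nk), means = means, covariances = covs)
}

# farthest-point ("k-means++"-style) seeding: random first center, then each
# next center is the point maximizing its distance to the chosen set
.init_model <- function(x, G, covariance_model, ridge) {
  n <- nrow(x); p <- ncol(x)
  centers <- sample.int(n, 1)
  if (G > 1) for (g in 2:G) {
    dmin <- apply(x, 1, function(r) min(colSums((t(x[centers, , drop = FALSE]) - r)^2)))
    dmin[centers] <- -Inf
    centers <- c(centers, which.max(dmin))
  }
  gcov <- stats::cov(x) * (n - 1) / n + diag(ridge, p)
  if (covariance_model == "diagonal") gcov <- diag(diag(gcov), p)
  list(weights = rep(1 / G, G), means = x[centers, , drop = FALSE],
       covariances = rep(list(gcov), G))
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Alternates [gmm_e_step()] and [gmm_m_step()] until the absolute
#' log-likelihood change drops below `tol` or `max_iter` is reached; the best
#' of `restarts` farthest-point initializations (by final log-likelihood) is
#' returned. The mixture runs on the feature scales it is given — no internal
#' normalization.
#'
#' @param x numeric data matrix or data.frame (patients x features).
#' @param config a [gmm_config()].
#' @return an object of class `gmm_model`: `weights`, `means`,
#'   `covariances`, `responsibilities`, `loglik_trace`, `loglik`, `labels`
#'   (MAP component per patient), `converged`, `config`.
#' @export
gmm_fit <- function(x, config = gmm_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  ridge <- config$ridge
  if (is.null(ridge)) {
    gv <- stats::cov(x) * (n - 1) / n
    ridge <- 1e-6 * sum(diag(gv)) / p
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  best <- NULL
  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + r - 1L)
    model <- .init_model(x, config$G, config$covariance_model, ridge)
    trace <- numeric(0)
    converged <- FALSE
    es <- gmm_e_step(x, model)
    for (it in seq_len(config$max_iter)) {
      model <- gmm_m_step(x, es$responsibilities, config$covariance_model, ridge)
      es_new <- gmm_e_step(x, model)
      trace <- c(trace, es_new$loglik)
      if (it > 1 && abs(es_new$loglik - es$loglik) < config$tol) {
        es <- es_new
        converged <- TRUE
        break
      }
      es <- es_new
    }
    if (is.null(best) || es$loglik > best$es$loglik) {
      best <- list(model = model, es = es, trace = trace, converged = converged)
    }
  }
  if (!best$converged)
    warning("EM did not converge within max_iter = ", config$max_iter)
  structure(list(weights = best$model$weights, means = best$model$means,
                 covariances = best$model$covariances,
                 responsibilities = best$es$responsibilities,
                 loglik_trace = best$trace, loglik = best$es$loglik,
                 labels = max.col(best$es$responsibilities),
                 converged = best$converged, config = config),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("Gaussian mixture (", length(x$weights), " components, ",
      x$config$covariance_model, " covariance): loglik ",
      format(x$loglik, digits = 8),
      if (x$converged) ", converged\n" else ", NOT converged\n", sep = "")
  invisible(x)
}

#' MAP-classify data under a fitted mixture
#'
#' @param object a `gmm_model`.
#' @param newdata data matrix on the scale the model was fitted on.
#' @param ... unused.
#' @return integer component labels.
#' @export
predict.gmm_model <- function(object, newdata, ...) {
  es <- gmm_e_step(as.matrix(newdata), object)
  max.col(es$responsibilities)
}
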