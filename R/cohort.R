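#' Specify one latent patient type
#'
#' A type is the generative unit of the synthetic cohort: a fixed diabetes
#' status plus truncated-normal age and NIHSS distributions, and per-day
#' Barthel Index (BI) and modified Rankin Scale (mRS) outcome distributions
#' coupled through a latent severity factor.
#'
#' @param label integer type label (ground truth carried through the cohort).
#' @param n number of patients of this type.
#' @param age_mean,age_sd age distribution in years.
#' @param nihss_mean,nihss_sd NIHSS distribution (integer scale 0-42).
#' @param dm diabetes status, 0 or 1, identical for every patient of the type.
#' @param bi_mean,bi_sd named numeric vectors over follow-up days
#'   (`"30","90","180","360"`) for the Barthel Index (0-100).
#' @param mrs_mean,mrs_sd same shape, for the modified Rankin Scale (0-6).
#' @param rho latent-severity coupling in `[0, 1)`. BI loads negatively and
#'   mRS positively on the shared severity factor, which induces the
#'   within-type BI-mRS anticorrelation seen in real follow-up tables.
#' @return an object of class `type_spec`.
#' @export
type_spec <- function(label, n, age_mean, age_sd, nihss_mean, nihss_sd, dm,
                      bi_mean, bi_sd, mrs_mean, mrs_sd, rho = 0.7) {
  if (n < 1) stop("type ", label, ": n must be >= 1")
  sds <- c(age_sd, nihss_sd, bi_sd, mrs_sd)
  if (any(sds < 0)) stop("type ", label, ": standard deviations must be >= 0")
  if (rho < 0 || rho >= 1) stop("type ", label, ": rho must lie in [0, 1)")
  if (!dm %in% c(0, 1)) stop("type ", label, ": dm must be 0 or 1")
  days <- c("30", "90", "180", "360")
  stopifnot(all(days %in% names(bi_mean)), all(days %in% names(bi_sd)),
            all(days %in% names(mrs_mean)), all(days %in% names(mrs_sd)))
  structure(list(label = as.integer(label), n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 nihss_mean = nihss_mean, nihss_sd = nihss_sd,
                 dm = as.integer(dm),
                 bi_mean = bi_mean[days], bi_sd = bi_sd[days],
                 mrs_mean = mrs_mean[days], mrs_sd = mrs_sd[days],
                 rho = rho),
            class = "type_spec")
}

#' Specify a whole synthetic cohort
#'
#' @param types list of [type_spec()] objects.
#' @param seed integer seed governing all randomness of [generate_cohort()].
#' @param age_bounds,nihss_bounds,bi_bounds,mrs_bounds closed truncation
#'   intervals keeping sampled values clinically valid.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(types, seed = 1L,
                        age_bounds = c(18, 100), nihss_bounds = c(0, 42),
                        bi_bounds = c(0, 100), mrs_bounds = c(0, 6)) {
  stopifnot(length(types) >= 1, all(vapply(types, inherits, TRUE, "type_spec")))
  labs <- vapply(types, `[[`, 1L, "label")
  if (anyDuplicated(labs)) stop("type labels must be unique")
  structure(list(types = types, seed = as.integer(seed),
                 age_bounds = age_bounds, nihss_bounds = nihss_bounds,
                 bi_bounds = bi_bounds, mrs_bounds = mrs_bounds),
            class = "cohort_spec")
}

# Per-type generative parameters of the two packaged presets. "ms" carries the
# published per-type age/NIHSS/DM summaries and follow-up outcome grids of the
# taxonomic (M-S) classification arm; "em" those of the Gaussian-mixture arm.
# Sizes sum to 602 in both. Type 1 (n = 188) is the only DM-positive type.
.preset_tables <- function(name) {
  days <- c("30", "90", "180", "360")
  g <- function(x) stats::setNames(x, days)
  if (name == "ms") {
    list(
      base = data.frame(label = 1:4, n = c(188L, 217L, 85L, 112L),
                        age_mean = c(68.7, 77.9, 55.5, 57.0),
                        age_sd = c(10.7, 7.7, 5.7, 8.8),
                        nihss_mean = c(7.8, 7.6, 2.2, 12.3),
                        nihss_sd = c(6.6, 7.0, 1.6, 6.4),
                        dm = c(1L, 0L, 0L, 0L)),
      bi_mean = list(g(c(61.1, 61.3, 60.6, 55.5)), g(c(63.4, 65.6, 63.7, 58.2)),
                     g(c(94.0, 96.1, 96.2, 95.2)), g(c(56.0, 62.3, 63.8, 59.7))),
      bi_sd = list(g(c(39.8, 40.4, 41.0, 43.6)), g(c(39.1, 40.8, 42.2, 43.6)),
                   g(c(12.8, 9.5, 11.4, 13.5)), g(c(39.0, 39.6, 40.5, 43.1))),
      mrs_mean = list(g(c(3.0, 3.0, 3.0, 3.3)), g(c(2.8, 2.6, 2.7, 3.0)),
                      g(c(0.9, 0.7, 0.6, 0.7)), g(c(3.2, 2.9, 2.8, 3.0))),
      mrs_sd = list(g(c(2.2, 2.2, 2.3, 2.4)), g(c(2.2, 2.4, 2.4, 2.4)),
                    g(c(1.4, 1.2, 1.2, 1.3)), g(c(2.1, 2.2, 2.4, 2.5))))
  } else if (name == "em") {
    list(
      base = data.frame(label = 1:4, n = c(188L, 159L, 136L, 119L),
                        age_mean = c(68.7, 76.9, 57.0, 67.6),
                        age_sd = c(10.7, 6.7, 5.3, 16.6),
                        nihss_mean = c(7.8, 4.6, 3.5, 16.9),
                        nihss_sd = c(6.6, 2.9, 2.4, 6.0),
                        dm = c(1L, 0L, 0L, 0L)),
      bi_mean = list(g(c(61.1, 61.3, 60.6, 55.5)), g(c(75.0, 77.3, 75.3, 70.0)),
                     g(c(89.4, 90.6, 90.4, 89.4)), g(c(33.6, 39.2, 40.5, 35.5))),
      bi_sd = list(g(c(39.8, 40.4, 41.0, 43.6)), g(c(32.4, 32.8, 35.5, 37.9)),
                   g(c(19.3, 20.1, 22.3, 25.5)), g(c(37.1, 42.3, 43.3, 43.0))),
      mrs_mean = list(g(c(3.0, 3.0, 3.0, 3.3)), g(c(2.2, 2.0, 2.1, 2.4)),
                      g(c(1.3, 1.1, 1.1, 1.1)), g(c(4.4, 4.1, 4.1, 4.3))),
      mrs_sd = list(g(c(2.2, 2.2, 2.3, 2.4)), g(c(2.0, 2.1, 2.2, 2.2)),
                    g(c(1.7, 1.6, 1.7, 1.7)), g(c(1.7, 2.1, 2.3, 2.3))))
  } else {
    stop("unknown preset '", name, "' (available: 'ms', 'em')")
  }
}

#' Packaged cohort presets
#'
#' `cohort_preset("ms")` carries the per-type baseline summaries and follow-up
#' outcome grids of the published taxonomic classification (sizes
#' 188/217/85/112 of n = 602); `cohort_preset("em")` those of the
#' Gaussian-mixture classification (sizes 188/159/136/119).
#'
#' @param name `"ms"` or `"em"`.
#' @param seed integer seed stored in the spec.
#' @param n_scale integer factor multiplying every type size (for
#'   large-sample checks of the generator itself).
#' @param rho latent-severity coupling passed to every type.
#' @return a [cohort_spec()].
#' @export
cohort_preset <- function(name = c("ms", "em"), seed = 1L, n_scale = 1L, rho = 0.7) {
  name <- match.arg(name)
  tab <- .preset_tables(name)
  types <- lapply(seq_len(nrow(tab$base)), function(i) {
    b <- tab$base[i, ]
    type_spec(label = b$label, n = b$n * n_scale,
              age_mean = b$age_mean, age_sd = b$age_sd,
              nihss_mean = b$nihss_mean, nihss_sd = b$nihss_sd, dm = b$dm,
              bi_mean = tab$bi_mean[[i]], bi_sd = tab$bi_sd[[i]],
              mrs_mean = tab$mrs_mean[[i]], mrs_sd = tab$mrs_sd[[i]],
              rho = rho)
  })
  cohort_spec(types, seed = seed)
}

# Truncated-normal sampling by rejection; falls back to the clamped bound when
# the acceptance region has negligible mass (degenerate sd = 0 passes through).
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(n)
  todo <- seq_len(n)
  for (tries in 1:1000) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  out[todo] <- min(max(mean, lower), upper)
  out
}

#' Generate a synthetic cohort
#'
#' Draws, for each type, age and NIHSS from truncated normals (NIHSS rounded
#' to the integer scale), sets diabetes status deterministically, and couples
#' the follow-up outcomes through a per-patient latent severity factor
#' `u ~ N(0,1)`: at each day, BI loads with `-rho` and mRS with `+rho` on `u`
#' (independent residual noise), so more severe patients have lower Barthel
#' and higher Rankin scores. mRS is rounded to its integer grade.
#'
#' @param spec a [cohort_spec()]; its `seed` makes the draw reproducible
#'   (identical spec + seed gives an identical cohort).
#' @param missing_rate optional per-day probability that a follow-up
#'   observation is missing (dropout emulation); default 0, i.e. complete
#'   follow-up.
#' @return a `data.frame` with one row per patient and columns
#'   `patient_id, age, nihss, dm, bi_30..bi_360, mrs_30..mrs_360, true_type`.
#' @export
generate_cohort <- function(spec, missing_rate = 0) {
  stopifnot(inherits(spec, "cohort_spec"), missing_rate >= 0, missing_rate < 1)
  days <- c("30", "90", "180", "360")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  parts <- lapply(spec$types, function(ts) {
    n <- ts$n
    age <- .rtruncnorm(n, ts$age_mean, ts$age_sd,
                       spec$age_bounds[1], spec$age_bounds[2])
    nihss <- round(.rtruncnorm(n, ts$nihss_mean, ts$nihss_sd,
                               spec$nihss_bounds[1], spec$nihss_bounds[2]))
    u <- stats::rnorm(n)  # latent severity shared by all follow-up days
    res <- sqrt(1 - ts$rho^2)
    out <- data.frame(age = age, nihss = as.integer(nihss),
                      dm = rep(ts$dm, n))
    for (d in days) {
      bi <- ts$bi_mean[[d]] + ts$bi_sd[[d]] * (-ts$rho * u + res * stats::rnorm(n))
      out[[paste0("bi_", d)]] <- pmin(pmax(bi, spec$bi_bounds[1]), spec$bi_bounds[2])
      mrs <- ts$mrs_mean[[d]] + ts$mrs_sd[[d]] * (ts$rho * u + res * stats::rnorm(n))
      out[[paste0("mrs_", d)]] <-
        as.integer(round(pmin(pmax(mrs, spec$mrs_bounds[1]), spec$mrs_bounds[2])))
    }
    if (missing_rate > 0) {
      for (col in c(paste0("bi_", days), paste0("mrs_", days)))
        out[[col]][stats::runif(n) < missing_rate] <- NA
    }
    out$true_type <- rep(ts$label, n)
    out
  })
  cohort <- do.call(rbind, parts)
  cohort <- cbind(patient_id = sprintf("P%04d", seq_len(nrow(cohort))), cohort)
  rownames(cohort) <- NULL
  cohort
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a cohort CSV
#'
#' The on-disk schema is fixed: header
#' `patient_id,age,nihss,dm,bi_30,bi_90,bi_180,bi_360,mrs_30,mrs_90,mrs_180,mrs_360,true_type`
#' with missing values as empty fields. `true_type` is optional on read.
#'
#' @param cohort a cohort `data.frame` as returned by [generate_cohort()].
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("patient_id", "age", "nihss", "dm",
            paste0("bi_", c(30, 90, 180, 360)),
            paste0("mrs_", c(30, 90, 180, 360)), "true_type")
  have <- intersect(cols, names(cohort))
  utils::write.csv(cohort[have], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "nihss", "dm")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort file lacks column(s): ", paste(miss, collapse = ", "))
  cohort
}
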