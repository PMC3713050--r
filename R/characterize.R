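#' Per-group n, mean and SD of one variable
#'
#' @param values numeric vector.
#' @param labels group labels aligned with `values`.
#' @return data.frame with columns `label`, `n`, `mean`, `sd` (sample SD,
#'   `n - 1` denominator; `NA` for singleton groups).
#' @export
group_summary <- function(values, labels) {
  if (length(values) != length(labels)) stop("values and labels must align")
  if (anyNA(values)) stop("missing values in the summarized variable")
  lev <- sort(unique(labels))
  out <- data.frame(
    label = lev,
    n = as.integer(tapply(values, labels, length)[as.character(lev)]),
    mean = as.numeric(tapply(values, labels, mean)[as.character(lev)]),
    sd = as.numeric(tapply(values, labels, stats::sd)[as.character(lev)]))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA on raw data
#'
#' Classical fixed-effects between/within decomposition, fitted through a
#' linear model on the group factor.
#'
#' @param values numeric response.
#' @param labels group labels (>= 2 groups, each with >= 2 observations).
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway_raw <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs n >= 2")
  at <- stats::anova(stats::lm(values ~ labels))
  structure(list(F = at[["F value"]][1],
                 df_between = at[["Df"]][1], df_within = at[["Df"]][2],
                 p = at[["Pr(>F)"]][1]),
            class = "anova_result")
}

#' One-way ANOVA from published group summaries
#'
#' Recomputes the F test from per-group n/mean/SD alone, as printed in a
#' summary table: `SSB = sum n_i (mean_i - grand mean)^2`,
#' `SSW = sum (n_i - 1) sd_i^2`, `F = (SSB / (k-1)) / (SSW / (n-k))`.
#' Algebraically identical to [anova_oneway_raw()] on the underlying data.
#'
#' @param ns,means,sds per-group sample sizes, means, and sample SDs.
#' @return an `anova_result`; `F` is `Inf` when groups differ but have zero
#'   within-group variance.
#' @export
anova_from_summaries <- function(ns, means, sds) {
  k <- length(ns)
  stopifnot(length(means) == k, length(sds) == k, k >= 2,
            all(ns >= 2), all(sds >= 0))
  n <- sum(ns)
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) {
    F <- if (ssb > 0) Inf else 0
  } else {
    F <- (ssb / (k - 1)) / (ssw / (n - k))
  }
  structure(list(F = F, df_between = k - 1L, df_within = as.integer(n - k),
                 p = stats::pf(F, k - 1, n - k, lower.tail = FALSE)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$F, digits = 4), ", p = ", format(x$p, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Rough categorical typing of clusters
#'
#' Places each cluster's mean age and NIHSS into three ordered categories
#' against two ascending cutpoints (closed-left intervals: a mean exactly on
#' a cutpoint takes the lower category), and labels diabetes by the cluster's
#' modal status. Default cutpoints — age 60/75 years, NIHSS 5/10 — reproduce
#' the published rough typings from the printed cluster means; the published
#' analysis never states its thresholds, so they are configurable.
#'
#' @param age_means,nihss_means per-cluster means.
#' @param dm_modal per-cluster modal diabetes status (0/1).
#' @param age_cutpoints,nihss_cutpoints two ascending thresholds each.
#' @return data.frame with columns `age`, `nihss`, `dm` of categories
#'   (`younger/medium/older`, `lower/medium/higher`, `negative/positive`).
#' @export
rough_categorize <- function(age_means, nihss_means, dm_modal,
                             age_cutpoints = c(60, 75),
                             nihss_cutpoints = c(5, 10)) {
  check <- function(cp, what) {
    if (length(cp) != 2 || diff(cp) <= 0)
      stop(what, " cutpoints must be two ascending thresholds")
  }
  check(age_cutpoints, "age"); check(nihss_cutpoints, "NIHSS")
  cut3 <- function(x, cp, levels)
    levels[1 + (x > cp[1]) + (x > cp[2])]
  data.frame(
    age = cut3(age_means, age_cutpoints, c("younger", "medium", "older")),
    nihss = cut3(nihss_means, nihss_cutpoints, c("lower", "medium", "higher")),
    dm = ifelse(dm_modal >= 0.5, "positive", "negative"))
}

#' Number of hypothetical categorical types
#'
#' Product of level counts over the rough variables, e.g. three age bands x
#' three NIHSS bands x two diabetes statuses = 18 combinations.
#'
#' @param levels_per_variable integer vector of level counts (all >= 1).
#' @return integer product.
#' @export
count_combinations <- function(levels_per_variable) {
  stopifnot(all(levels_per_variable >= 1))
  prod(levels_per_variable)
}

#' Per-type follow-up outcome table
#'
#' Mean (SD) of Barthel Index and modified Rankin Scale per cluster and
#' follow-up day, shaped like a published outcome grid. Missing follow-up
#' values are excluded cell-wise and the per-cell n reported.
#'
#' @param cohort cohort data.frame with `bi_*`/`mrs_*` columns.
#' @param labels cluster labels aligned with cohort rows.
#' @return data.frame with columns `type`, `scale` (`bi`/`mrs`), `day`,
#'   `n`, `mean`, `sd`; cells with no observations carry `NA` mean.
#' @export
followup_summary <- function(cohort, labels) {
  stopifnot(nrow(cohort) == length(labels))
  days <- c(30, 90, 180, 360)
  rows <- list()
  for (ty in sort(unique(labels))) {
    sel <- labels == ty
    for (scale in c("bi", "mrs")) for (d in days) {
      col <- paste0(scale, "_", d)
      if (!col %in% names(cohort)) stop("cohort lacks follow-up column ", col)
      v <- cohort[[col]][sel]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        type = ty, scale = scale, day = d, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Disability level per type from a follow-up grid
#'
#' A type has `"lower"` disability (favorable outcome) when its mean Barthel
#' Index across the four follow-up days is at least `bi_threshold`,
#' otherwise `"higher"`. The default threshold 85 separates a
#' near-independent type (mean BI in the mid-90s) from types in the 30-75
#' range.
#'
#' @param followup a grid from [followup_summary()] (or any data.frame with
#'   `type`, `scale`, `mean`).
#' @param bi_threshold Barthel Index threshold, 0-100.
#' @return named character vector, `"lower"`/`"higher"` per type.
#' @export
disability_level <- function(followup, bi_threshold = 85) {
  bi <- followup[followup$scale == "bi", ]
  if (anyNA(bi$mean)) stop("follow-up grid has empty Barthel cells")
  avg <- tapply(bi$mean, bi$type, mean)
  stats::setNames(as.vector(ifelse(avg >= bi_threshold, "lower", "higher")),
                  names(avg))
}

#' Share of patients with the best prognosis
#'
#' Percent of the cohort belonging to types with `"lower"` disability,
#' reported to one decimal (e.g. 85 of 602 patients = 14.1).
#'
#' @param type_sizes named vector of type sizes.
#' @param disability_levels named `"lower"`/`"higher"` vector over the same
#'   types (see [disability_level()]).
#' @return percent, rounded to one decimal.
#' @export
best_prognosis_share <- function(type_sizes, disability_levels) {
  stopifnot(length(type_sizes) == length(disability_levels))
  if (!is.null(names(type_sizes)) && !is.null(names(disability_levels)))
    disability_levels <- disability_levels[names(type_sizes)]
  good <- disability_levels == "lower"
  if (!any(good)) {
    warning("no type reaches the lower-disability level")
    return(0)
  }
  round(100 * sum(type_sizes[good]) / sum(type_sizes), 1)
}

#' Rounded between-type gaps
#'
#' Difference of two group means with each mean first rounded the way such
#' gaps are quoted in clinical prose: age to the nearest year, NIHSS to one
#' decimal.
#'
#' @param mean_a,mean_b the two group means (`a - b` is returned).
#' @param rounding `"integer"` or `"one_decimal"`.
#' @return the rounded-mean difference.
#' @export
gap_arithmetic <- function(mean_a, mean_b, rounding = c("integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  digits <- if (rounding == "integer") 0 else 1
  round(mean_a, digits) - round(mean_b, digits)
}
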