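#' Taxonomic (M-S) clustering pipeline
#'
#' Normalizes the baseline features (age, NIHSS, diabetes status) into 0-1,
#' computes the pairwise Marczewski-Steinhaus distance matrix, builds the
#' complete-linkage dendrogram and cuts it into `k` types.
#'
#' @param cohort cohort data.frame (needs `patient_id`, `age`, `nihss`, `dm`).
#' @param k number of types to cut (default 4).
#' @param mode distance aggregation, see [ms_distance_vector()].
#' @return list of class `ms_fit`: `labels` (named integer vector),
#'   `tree` (`merge_tree`), `distances` (`ms_dist`), `features`
#'   (the normalized matrix).
#' @export
ms_pipeline <- function(cohort, k = 4, mode = c("soergel", "mean_per_variable")) {
  mode <- match.arg(mode)
  feats <- as.matrix(cohort[, c("age", "nihss", "dm")])
  rownames(feats) <- cohort$patient_id
  norm <- minmax_normalize(feats)
  d <- pairwise_distances(norm, mode = mode)
  tree <- complete_linkage(d)
  structure(list(labels = cut_tree(tree, k), tree = tree,
                 distances = d, features = norm, mode = mode, k = k),
            class = "ms_fit")
}

#' Gaussian-mixture (E-M) clustering pipeline
#'
#' Fits a G-component Gaussian mixture to the raw-scale baseline features and
#' MAP-classifies every patient; components are renumbered 1..G by decreasing
#' size (ties by smallest member index) so labels are comparable across runs.
#' The mixture runs on raw feature scales by default; set
#' `normalize = TRUE` to reuse the 0-1 normalization of the taxonomic arm.
#'
#' @param cohort cohort data.frame.
#' @param config a [gmm_config()].
#' @param normalize run on min-max-normalized features instead of raw scales.
#' @return list of class `em_fit`: `labels` (named, renumbered), `model`
#'   (`gmm_model`).
#' @export
em_pipeline <- function(cohort, config = gmm_config(), normalize = FALSE) {
  feats <- as.matrix(cohort[, c("age", "nihss", "dm")])
  rownames(feats) <- cohort$patient_id
  if (normalize) feats <- minmax_normalize(feats)
  model <- gmm_fit(feats, config)
  structure(list(labels = stats::setNames(.renumber_by_size(model$labels),
                                          cohort$patient_id),
                 model = model),
            class = "em_fit")
}

# renumber labels 1..k by decreasing cluster size, ties by smallest member
.renumber_by_size <- function(labels) {
  sizes <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  lev <- names(sizes)[order(-as.integer(sizes), first)]
  match(as.character(labels), lev)
}

#' Run the full replication pipeline
#'
#' Simulate (or load) a cohort, run the taxonomic and Gaussian-mixture
#' classifications, compare them, and characterize the resulting types.
#' All artifacts are written under `out_dir`:
#' `cohort.csv`, `distances.tsv`, `dendrogram.nwk`, `ms_labels.csv`,
#' `em_labels.csv`, `agreement.json`, `baseline_summary.tsv`,
#' `followup_ms.tsv`, `rough_types.tsv`, `anova.json`, and `run.log`.
#'
#' @param preset cohort preset name (`"ms"` or `"em"`), ignored when
#'   `cohort` is given.
#' @param cohort optional cohort data.frame or path to a cohort CSV.
#' @param k number of types (both arms).
#' @param mode M-S distance aggregation.
#' @param seed master seed; the cohort draw and the EM initialization use
#'   fixed offsets of it, so stages are independently reproducible.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing and just returns the results.
#' @param gmm a [gmm_config()]; its seed is overridden by `seed + 1000`.
#' @return invisible list with `cohort`, `ms`, `em`, `agreement`,
#'   `baseline`, `followup`, `rough`, `anova`.
#' @export
run_all <- function(preset = "ms", cohort = NULL, k = 4, mode = "soergel",
                    seed = 1L, out_dir = NULL, gmm = gmm_config()) {
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...))
  if (is.null(cohort)) {
    spec <- cohort_preset(preset, seed = seed)
    cohort <- generate_cohort(spec)
    say("simulated preset '", preset, "' cohort, n = ", nrow(cohort),
        ", seed = ", seed)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
    say("loaded cohort from file, n = ", nrow(cohort))
  }
  gmm$seed <- as.integer(seed + 1000L)
  ms <- ms_pipeline(cohort, k = k, mode = mode)
  say("M-S arm: ", k, " types of sizes ",
      paste(as.integer(table(ms$labels)), collapse = "/"))
  em <- em_pipeline(cohort, config = gmm)
  say("E-M arm: ", length(em$model$weights), " components, loglik ",
      format(em$model$loglik, digits = 8))
  agr <- agreement_report(ms$labels, em$labels)
  say("agreement: ", format(agr$direct_agreement, digits = 3),
      "%, kappa = ", format(agr$kappa, digits = 3))

  baseline <- rbind(
    cbind(variable = "age", group_summary(cohort$age, ms$labels)),
    cbind(variable = "nihss", group_summary(cohort$nihss, ms$labels)))
  anova <- list(
    age = anova_oneway_raw(cohort$age, ms$labels),
    nihss = anova_oneway_raw(cohort$nihss, ms$labels))
  age_s <- baseline[baseline$variable == "age", ]
  nihss_s <- baseline[baseline$variable == "nihss", ]
  dm_modal <- as.numeric(tapply(cohort$dm, ms$labels, function(x) mean(x) >= 0.5))
  rough <- cbind(type = age_s$label,
                 rough_categorize(age_s$mean, nihss_s$mean, dm_modal))
  followup <- followup_summary(cohort, ms$labels)
  dis <- disability_level(followup)
  share <- best_prognosis_share(table(ms$labels), dis)
  say("best-prognosis share: ", share, "%")

  res <- list(cohort = cohort, ms = ms, em = em, agreement = agr,
              baseline = baseline, followup = followup, rough = rough,
              anova = anova, disability = dis, best_prognosis_share = share,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    write_cohort(cohort, fp("cohort.csv"))
    utils::write.table(round(unclass(ms$distances), 6), fp("distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    writeLines(to_newick(ms$tree), fp("dendrogram.nwk"))
    utils::write.csv(data.frame(patient_id = names(ms$labels),
                                ms_type = as.integer(ms$labels)),
                     fp("ms_labels.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(patient_id = names(em$labels),
                                em_type = as.integer(em$labels)),
                     fp("em_labels.csv"), row.names = FALSE, quote = FALSE)
    .write_json(list(confusion = unname(as.matrix(agr$confusion)),
                     matching = agr$matching,
                     direct_agreement = agr$direct_agreement,
                     kappa = agr$kappa, kappa_se = agr$kappa_se,
                     z = agr$z, p = agr$p), fp("agreement.json"))
    utils::write.table(baseline, fp("baseline_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(followup, fp("followup_ms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rough, fp("rough_types.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_json(list(age = unclass(anova$age), nihss = unclass(anova$nihss),
                     disability = as.list(dis),
                     best_prognosis_share = share), fp("anova.json"))
    say("artifacts written to ", out_dir)
    writeLines(log, fp("run.log"))
  }
  invisible(res)
}

# minimal JSON writer for report lists (numbers, strings, vectors, matrices,
# nested lists); avoids a hard dependency for the package core
.write_json <- function(x, path) {
  writeLines(.to_json(x), path)
}
.to_json <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    paste0("{", paste0("\"", names(x), "\": ",
                       vapply(x, .to_json, ""), collapse = ", "), "}")
  } else if (is.matrix(x)) {
    paste0("[", paste(apply(x, 1, function(r) .to_json(unname(r))),
                      collapse = ", "), "]")
  } else if (length(x) > 1 || is.list(x)) {
    paste0("[", paste(vapply(unname(as.list(x)), .to_json, ""), collapse = ", "), "]")
  } else if (is.character(x)) {
    paste0("\"", x, "\"")
  } else if (is.na(x)) {
    "null"
  } else if (is.infinite(x)) {
    paste0("\"", x, "\"")
  } else {
    format(unclass(x), digits = 15)
  }
}
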