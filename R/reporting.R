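#' The published variable-set grid
#'
#' The 19 harmonic power variable combinations evaluated in the published
#' LTOCV accuracy table, in printed row order.
#'
#' @return Named list of character vectors.
#' @export
published_variable_sets <- function() {
  v <- harmonic_variables()
  sets <- list(
    v[c(1, 2)], v[c(1, 3)], v[c(1, 4)], v[c(2, 3)], v[c(2, 4)], v[c(3, 4)],
    v[c(1, 2, 3)], v[c(1, 2, 4)], v[c(1, 3, 4)], v[c(2, 3, 4)],
    v[c(1, 2, 8)], v[c(1, 2, 12)], v[c(1, 4, 8)],
    v[1:4], v[c(1, 2, 4, 8)], v[c(1, 4, 8, 12)],
    v[c(1:4, 8)], v[c(1:4, 12)], v[1:8])
  names(sets) <- vapply(sets, paste, character(1), collapse = "+")
  sets
}

.label_algorithms <- c(knn = "knn", logistic_regression = "logistic_regression",
                       random_forest = "random_forest",
                       gradient_boosted_trees = "gradient_boosted_trees",
                       svm = "svm", naive_bayes = "naive_bayes")

#' Reproduce the published result tables and figure data
#'
#' Re-runs the full evaluation protocol on the embedded cohort and writes
#' paper-shaped artifacts to `out_dir`:
#'
#' * `table3.csv` — exhaustive LTOCV accuracy (percent) for every variable
#'   set x algorithm combination, with exceeds-baseline flags;
#' * `table4.csv` — LTOCV accuracy using fold-embedded 2D PCA variables,
#'   gated to combinations whose plain run exceeded baseline (empty cells
#'   are `NA`);
#' * `table5.csv` — KNN LOOCV accuracy, plain and PCA columns, restricted
#'   to variable sets whose plain LOOCV run exceeded baseline;
#' * `fig3_confusion_plain.json`, `fig3_confusion_pca.json` — pooled
#'   confusion matrices of the two headline KNN models on
#'   (`P_FF`, `P_2H`, `P_3H`);
#' * `fig4_pca.csv` — 2D PCA coordinates of all 11 recordings, fitted on
#'   all rows of (`P_FF`, `P_2H`, `P_3H`);
#' * `fig2_profiles.csv` — long-format harmonic power data for bar plots;
#' * `manifest.json` — configuration, seed, checksums of every emitted
#'   file.
#'
#' The full six-algorithm grid takes a few minutes (the stochastic
#' algorithms are repeated 25 times each); restrict `algorithms` for a
#' quick KNN-only reproduction of the headline numbers.
#'
#' @param out_dir Output directory (created if missing).
#' @param algorithms Algorithms to include (default: the full suite).
#' @param seed Base seed for stochastic algorithms.
#' @param repeats Repeats for stochastic algorithms (default 25).
#' @return Invisibly, a list with the three tables and output paths.
#' @export
reproduce_tables <- function(out_dir, algorithms = names(.label_algorithms),
                             seed = 20250502, repeats = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_embedded_cohort()
  profiles <- cohort$profiles
  vsets <- published_variable_sets()
  baseline_pct <- as_percent(zeror_baseline(profiles$outcome, "ltocv"))

  acc_tab <- function(scheme, pca, gate = NULL) {
    out <- data.frame(variables = names(vsets), stringsAsFactors = FALSE)
    for (alg in algorithms) {
      col <- rep(NA_real_, length(vsets))
      for (i in seq_along(vsets)) {
        if (!is.null(gate) && !gate[[alg]][i]) next
        r <- run_cv(profiles, vsets[[i]], alg, scheme = scheme, pca = pca,
                    seed = seed, repeats = repeats)
        col[i] <- r$accuracy_pct
      }
      out[[alg]] <- col
    }
    out
  }

  table3 <- acc_tab("ltocv", "none")
  gate3 <- lapply(algorithms, function(alg) table3[[alg]] > baseline_pct)
  names(gate3) <- algorithms
  table4 <- acc_tab("ltocv", "2d", gate = gate3)

  knn_loocv <- acc_tab("loocv", "none")
  loocv_gate <- knn_loocv[["knn"]] > baseline_pct
  table5 <- data.frame(variables = names(vsets)[loocv_gate],
                       plain = knn_loocv[["knn"]][loocv_gate],
                       stringsAsFactors = FALSE)
  table5$pca <- vapply(vsets[loocv_gate], function(vs)
    run_cv(profiles, vs, "knn", scheme = "loocv", pca = "2d")$accuracy_pct,
    numeric(1))
  table3$baseline <- baseline_pct
  table4$baseline <- baseline_pct

  headline_vars <- c("P_FF", "P_2H", "P_3H")
  fig3_plain <- run_cv(profiles, headline_vars, "knn")
  fig3_pca <- run_cv(profiles, headline_vars, "knn", pca = "2d")
  pm <- fit_pca(profiles[, headline_vars], 2)
  coords <- predict(pm, profiles[, headline_vars])
  fig4 <- data.frame(patient_id = profiles$patient_id,
                     pc1 = coords[, 1], pc2 = coords[, 2],
                     outcome = profiles$outcome, stringsAsFactors = FALSE)

  paths <- c(table3 = "table3.csv", table4 = "table4.csv",
             table5 = "table5.csv", fig2 = "fig2_profiles.csv",
             fig3_plain = "fig3_confusion_plain.json",
             fig3_pca = "fig3_confusion_pca.json", fig4 = "fig4_pca.csv")
  paths <- vapply(paths, function(p) file.path(out_dir, p), character(1))
  utils::write.csv(table3, paths[["table3"]], row.names = FALSE)
  utils::write.csv(table4, paths[["table4"]], row.names = FALSE)
  utils::write.csv(table5, paths[["table5"]], row.names = FALSE)
  report_profile_chart(profiles, paths[["fig2"]])
  for (nm in c("fig3_plain", "fig3_pca")) {
    r <- get(nm)
    jsonlite::write_json(list(variables = r$variables, pca = r$pca,
                              confusion = as.list(r$confusion),
                              metrics = r$metrics,
                              accuracy_pct = r$accuracy_pct),
                         paths[[nm]], auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(fig4, paths[["fig4"]], row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pumpharmonics")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed, algorithms = algorithms,
    knn_config = list(ltocv_plain = knn_reproduction_defaults("ltocv", "none"),
                      pca = knn_reproduction_defaults("ltocv", "2d"),
                      loocv_plain = knn_reproduction_defaults("loocv", "none")),
    baseline_pct = baseline_pct,
    files = lapply(paths, function(p) list(path = basename(p),
                                           md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table3 = table3, table4 = table4, table5 = table5,
                 fig4 = fig4, paths = paths))
}

#' Long-format harmonic power data for bar plotting
#'
#' Melts a feature table into (patient_id, harmonic, harmonic_index, dB,
#' outcome) rows — one row per recording per harmonic — the layout used to
#' draw per-recording harmonic power bar charts.
#'
#' @param profiles Feature table.
#' @param path Optional CSV output path.
#' @return The long data frame (invisibly if `path` is given).
#' @export
report_profile_chart <- function(profiles, path = NULL) {
  validate_profiles(profiles)
  vars <- harmonic_variables()
  long <- do.call(rbind, lapply(seq_along(vars), function(i) {
    data.frame(patient_id = profiles$patient_id, harmonic = vars[i],
               harmonic_index = i, power_db = profiles[[vars[i]]],
               outcome = profiles$outcome, stringsAsFactors = FALSE)
  }))
  long <- long[order(match(long$patient_id, profiles$patient_id),
                     long$harmonic_index), ]
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.csv(long, path, row.names = FALSE)
    return(invisible(long))
  }
  long
}
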