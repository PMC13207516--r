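# Pipeline orchestration and file I/O: cohort simulation to disk, feature
# extraction over batches of field series, and the end-to-end assessment
# (consensus -> reliability -> nested CV -> comparison -> attribution).

#' Write / read a feature or rating table as CSV
#'
#' Plain CSV with a header row and a `sample_id` column; empty cells are
#' missing ratings.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE,
                             stringsAsFactors = FALSE))
}

#' Simulate a cohort and write it to a run directory
#'
#' Writes `features.csv`, `ratings.csv`, `truth.csv` and a `manifest.json`
#' (seed plus a hash of the full spec) sufficient to reproduce the cohort
#' exactly. Refuses to overwrite an existing cohort unless `force = TRUE`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @return The [generate_cohort()] list, invisibly.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir, force = FALSE) {
  paths <- file.path(dir, c("features.csv", "ratings.csv", "truth.csv",
                            "manifest.json"))
  if (!force && any(file.exists(paths)))
    abort("outputs already exist; use force = TRUE to overwrite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  write_table_csv(cohort$features, paths[1])
  write_table_csv(cohort$ratings, paths[2])
  write_table_csv(cohort$truth, paths[3])
  jsonlite::write_json(
    list(seed = spec$seed, n_samples = spec$n_samples,
         n_raters = spec$n_raters, spec_hash = rlang::hash(spec)),
    paths[4], auto_unbox = TRUE
  )
  invisible(cohort)
}

#' Extract feature rows from a batch of field series
#'
#' Applies [compute_features()] to each element of a list of
#' `list(wall =, flow =)` pairs; a failing sample is logged and skipped
#' (its row is omitted), and the call errors only if every sample fails.
#'
#' @param series Named list; each element has `wall` and `flow` components.
#' @param fluid A [fluid_properties()].
#' @param reference_diameter Reference diameter (mm).
#' @return Tibble: `sample_id` plus the 19 features, input order preserved.
#' @export
features_from_series <- function(series, fluid = fluid_properties(),
                                 reference_diameter = 3.0) {
  ids <- names(series) %||% sprintf("S%04d", seq_along(series))
  rows <- purrr::imap(series, function(s, nm) {
    tryCatch(
      dplyr::bind_cols(tibble::tibble(sample_id = nm),
                       compute_features(s$wall, s$flow, fluid,
                                        reference_diameter)),
      error = function(e) {
        warn(sprintf("sample %s failed: %s", nm, conditionMessage(e)))
        NULL
      })
  })
  ok <- purrr::compact(rows)
  if (!length(ok)) abort("feature extraction failed for every sample")
  dplyr::bind_rows(ok)
}

#' Read / write a run configuration as YAML
#'
#' A run configuration bundles the cohort spec arguments, the
#' evolution-strategy settings, the families to run, fold counts and the
#' master seed.
#'
#' @param path YAML file path.
#' @param config Named list (writer).
#' @return Named list (reader); `path` invisibly (writer).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("run config must set a seed")
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' End-to-end assessment of a cohort
#'
#' Runs the full analysis: consensus scores from the rating table,
#' inter-rater reliability (with a warning if ICC3k falls below the 0.8
#' benchmark; the run continues), nested cross-validation over the requested
#' families, fold summaries with bootstrap CIs, the model-comparison report,
#' and a Shapley importance ranking for the best family (lowest mean RMSE)
#' refit on the full dataset.
#'
#' @param features Feature tibble (`sample_id` + 19 features).
#' @param ratings Rating tibble (`sample_id` + rater columns).
#' @param families Families to compare.
#' @param evo_cfg An [evo_config()].
#' @param outer_k,inner_k Fold counts.
#' @param seed Master seed.
#' @param n_boot Bootstrap replicates for the summaries.
#' @param shap_samples How many samples to explain for the importance
#'   ranking (subsampled; default 60).
#' @param n_permutations Permutation walks per explained sample.
#' @param spaces Optional per-family `search_space` overrides.
#' @param dir Optional output directory; when given, writes
#'   `comparison.csv`, `importance.csv`, `reliability.json`,
#'   `predictions.csv` and `manifest.json`.
#' @return A `flowgrade_assessment` list: `reliability`, `cv`, `summary`,
#'   `comparison`, `best_family`, `final_model`, `attributions`,
#'   `importance`, `predictions`.
#' @export
run_assessment <- function(features, ratings,
                           families = regressor_families(),
                           evo_cfg = evo_config(), outer_k = 10,
                           inner_k = 5, seed = 1L, n_boot = 2000,
                           shap_samples = 60, n_permutations = 100,
                           spaces = NULL, dir = NULL) {
  cons <- consensus_scores(ratings)
  rel <- icc3k(ratings)
  if (!isTRUE(rel$benchmark_pass))
    warn(sprintf("ICC3k = %.3f is below the 0.8 reliability benchmark",
                 rel$icc3k))
  data <- dplyr::inner_join(features, cons, by = "sample_id")
  if (nrow(data) != nrow(features))
    warn("some samples lack ratings and were dropped")
  cv <- nested_cv(data, outcome = "consensus", families = families,
                  evo_cfg = evo_cfg, outer_k = outer_k, inner_k = inner_k,
                  seed = seed, spaces = spaces)
  summ <- summarize_cv(cv, n_boot = n_boot, seed = seed)
  comp <- comparison_report(summ)
  rmse_mean <- summ[summ$metric == "rmse", ]
  best_family <- rmse_mean$family[which.min(rmse_mean$mean)]

  # full-data refit of the winner (modal fold hyperparameters by inner MSE)
  bf <- cv$folds[cv$folds$family == best_family, ]
  best_params <- bf$hyperparameters[[which.min(bf$inner_mse)]]
  X <- data[setdiff(names(data), c("consensus", "sample_id"))]
  final <- fit_regressor(best_family, best_params, X, data$consensus,
                         seed = derive_seed(seed, "final"))
  expl_idx <- if (nrow(data) > shap_samples)
    withr::with_seed(derive_seed(seed, "shap"),
                     sort(sample.int(nrow(data), shap_samples)))
  else seq_len(nrow(data))
  attr_tab <- attribution_table(final, data[expl_idx, ], background = data,
                                method = "sampled",
                                n_permutations = n_permutations,
                                seed = derive_seed(seed, "shapattr"))
  imp <- importance_report(attr_tab)
  preds <- tibble::tibble(sample_id = data$sample_id,
                          consensus = data$consensus,
                          predicted = predict(final, X))

  out <- structure(
    list(reliability = rel, cv = cv, summary = summ, comparison = comp,
         best_family = best_family, final_model = final,
         attributions = attr_tab, importance = imp, predictions = preds,
         seed = seed),
    class = "flowgrade_assessment")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(comp, file.path(dir, "comparison.csv"))
    write_table_csv(imp, file.path(dir, "importance.csv"))
    write_table_csv(preds, file.path(dir, "predictions.csv"))
    jsonlite::write_json(glance(rel), file.path(dir, "reliability.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(
      list(seed = seed, families = families, outer_k = outer_k,
           inner_k = inner_k, best_family = best_family,
           package_version = as.character(utils::packageVersion("flowgrade"))),
      file.path(dir, "manifest.json"), auto_unbox = TRUE)
  }
  out
}

#' @export
print.flowgrade_assessment <- function(x, ...) {
  cat("<flowgrade_assessment>\n")
  print(x$reliability)
  cat("best family by mean RMSE:", x$best_family, "\n")
  rm <- x$summary[x$summary$metric == "rmse" &
                    x$summary$family == x$best_family, ]
  cat(sprintf("  RMSE %.3f (SE %.3f) (CI %.3f-%.3f)\n", rm$mean, rm$se,
              rm$ci_low, rm$ci_high))
  cat("top features by mean |SHAP|:\n")
  print(utils::head(x$importance, 6))
  invisible(x)
}
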