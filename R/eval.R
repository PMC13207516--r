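# Nested cross-validation, the five performance metrics, bootstrap CIs and
# the model-comparison report.

#' Regression performance metrics
#'
#' RMSE, MAE, MAPE, R^2 and `P(E < 0.5)` (fraction of predictions whose
#' absolute error is strictly below half a score point).
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return One-row tibble `rmse`, `mae`, `mape`, `r2`, `p_under_half`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 3))
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  e <- y_true - y_pred
  r2 <- if (var(y_true) == 0) {
    warn("zero-variance y_true: R^2 undefined")
    NA_real_
  } else 1 - sum(e^2) / sum((y_true - mean(y_true))^2)
  tibble::tibble(
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    mape = mean(abs(e) / abs(y_true)),
    r2 = r2,
    p_under_half = mean(abs(e) < 0.5)
  )
}

# stratified k-fold assignment: bin the outcome into quantile bins (4 by
# default) and deal each bin's samples round-robin into folds
make_folds <- function(y, k, seed, n_bins = 4) {
  n <- length(y)
  if (n < k) abort("not enough samples for the requested fold count")
  br <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    offset <- 0L
    for (b in sort(unique(bins))) {
      idx <- sample(which(bins == b))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# inner-CV mean MSE of one hyperparameter configuration
inner_cv_mse <- function(family, genome, X, y, inner_fold, seed) {
  errs <- purrr::map_dbl(sort(unique(inner_fold)), function(f) {
    tr <- inner_fold != f
    m <- fit_regressor(family, genome, X[tr, , drop = FALSE], y[tr],
                       seed = seed)
    mean((y[!tr] - predict(m, X[!tr, , drop = FALSE]))^2)
  })
  mean(errs)
}

#' Nested cross-validation with evolutionary hyperparameter tuning
#'
#' Outer K folds (stratified by outcome quantile bins) give unbiased
#' generalization estimates; within each outer-training portion, an inner
#' K'-fold loop supplies the fitness (mean MSE) for the mu+lambda
#' evolution-strategy search over each family's hyperparameter space. The
#' tuned winner is refit on the full outer-training portion and evaluated on
#' the held-out fold. Hyperparameter selection therefore never touches
#' outer-test data. Any column named `sample_id` is carried as an identifier
#' and excluded from the features.
#'
#' @param data Tibble containing the outcome column, optionally `sample_id`,
#'   and the feature columns (everything else).
#' @param outcome Name of the outcome column (default `"consensus"`).
#' @param families Character vector of families to run.
#' @param evo_cfg An [evo_config()] controlling the search.
#' @param outer_k,inner_k Outer / inner fold counts (defaults 10 / 5).
#' @param seed Integer seed controlling folds, search and model fits.
#' @param spaces Optional named list of `search_space` overrides per family.
#' @return A `flowgrade_cv` object: `folds` (per fold x family: chosen
#'   hyperparameters and metrics), `oof` (pooled out-of-fold predictions),
#'   `failed` (fold x family failures, if any).
#' @export
nested_cv <- function(data, outcome = "consensus",
                      families = regressor_families(),
                      evo_cfg = evo_config(), outer_k = 10, inner_k = 5,
                      seed = 1L, spaces = NULL) {
  stopifnot(outcome %in% names(data))
  ids <- if ("sample_id" %in% names(data)) data$sample_id
         else sprintf("S%04d", seq_len(nrow(data)))
  y <- data[[outcome]]
  X <- data[setdiff(names(data), c(outcome, "sample_id"))]
  if (anyNA(X) || anyNA(y)) abort("missing values are not allowed")
  if (nrow(X) < outer_k) abort("n must be >= outer_k")
  stopifnot(inherits(evo_cfg, "evo_config"))
  outer_fold <- make_folds(y, outer_k, derive_seed(seed, "outer"))

  fold_rows <- list(); oof_rows <- list(); failed <- list()
  for (fam in families) {
    space <- (spaces[[fam]] %||% default_space(fam))
    for (f in seq_len(outer_k)) {
      tr <- outer_fold != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      inner_fold <- make_folds(ytr, inner_k,
                               derive_seed(seed, "inner", fam, f))
      fit_seed <- derive_seed(seed, "fit", fam, f)
      fitness <- function(genome)
        inner_cv_mse(fam, genome, Xtr, ytr, inner_fold, fit_seed)
      res <- tryCatch({
        cfg <- evo_cfg
        cfg$seed <- derive_seed(seed, "evo", fam, f)
        es <- evolve(space, fitness, cfg)
        final <- fit_regressor(fam, es$best$genome, Xtr, ytr,
                               seed = fit_seed)
        pred <- predict(final, X[!tr, , drop = FALSE])
        list(es = es, pred = pred)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("fold %d / %s failed: %s", f, fam,
                     conditionMessage(res)))
        failed[[length(failed) + 1L]] <-
          tibble::tibble(fold = f, family = fam,
                         message = conditionMessage(res))
        next
      }
      met <- regression_metrics(y[!tr], res$pred)
      fold_rows[[length(fold_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(family = fam, fold = f,
                       hyperparameters = list(res$es$best$genome),
                       inner_mse = res$es$best$fitness,
                       generations = max(res$es$history$generation)),
        met
      )
      oof_rows[[length(oof_rows) + 1L]] <- tibble::tibble(
        family = fam, fold = f, sample_id = ids[!tr],
        y_true = y[!tr], y_pred = res$pred
      )
    }
  }
  if (!length(fold_rows)) abort("every fold-family run failed")
  structure(list(folds = dplyr::bind_rows(fold_rows),
                 oof = dplyr::bind_rows(oof_rows),
                 failed = dplyr::bind_rows(failed),
                 outcome = outcome, outer_k = outer_k, inner_k = inner_k,
                 families = families, seed = seed),
            class = "flowgrade_cv")
}

#' @export
print.flowgrade_cv <- function(x, ...) {
  cat("<flowgrade_cv> ", x$outer_k, "-fold outer / ", x$inner_k,
      "-fold inner, families: ", paste(x$families, collapse = ", "), "\n",
      sep = "")
  if (nrow(x$failed)) cat("  failed fold-family runs:", nrow(x$failed), "\n")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.flowgrade_cv <- function(x, ...) {
  x$folds |>
    dplyr::select(!"hyperparameters") |>
    tidyr::pivot_longer(c("rmse", "mae", "mape", "r2", "p_under_half"),
                        names_to = "metric", values_to = "value")
}

#' @export
glance.flowgrade_cv <- function(x, ...) {
  x$folds |>
    dplyr::summarise(dplyr::across(c("rmse", "mae", "mape", "r2",
                                    "p_under_half"), mean),
                     .by = "family")
}

#' Fold-mean, standard error and bootstrap CI per metric and family
#'
#' Means and standard errors are taken over the fold-level metric values;
#' the 95% interval is a percentile bootstrap over the pooled out-of-fold
#' predictions (per family), recomputing the metric on each resample.
#' Pooled-prediction resampling is used because 10 fold-level values give
#' unstable percentile intervals.
#'
#' @param cv A `flowgrade_cv`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param conf_level Interval coverage (default 0.95).
#' @return A `flowgrade_cv_summary` tibble: family, metric, mean, se,
#'   ci_low, ci_high.
#' @export
summarize_cv <- function(cv, n_boot = 2000, seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(cv, "flowgrade_cv"))
  metrics <- c("rmse", "mae", "mape", "r2", "p_under_half")
  alpha <- 1 - conf_level
  out <- purrr::map(unique(cv$folds$family), function(fam) {
    fold_m <- cv$folds[cv$folds$family == fam, metrics]
    oof <- cv$oof[cv$oof$family == fam, ]
    n <- nrow(oof)
    boot <- withr::with_seed(derive_seed(seed, "boot", fam), {
      purrr::map(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        regression_metrics(oof$y_true[i], oof$y_pred[i])
      })
    }) |> dplyr::bind_rows()
    purrr::map(metrics, function(mt) {
      v <- fold_m[[mt]]
      ci <- quantile(boot[[mt]], c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
      tibble::tibble(family = fam, metric = mt, mean = mean(v),
                     se = sd(v) / sqrt(length(v)),
                     ci_low = ci[[1]], ci_high = ci[[2]])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(out) <- c("flowgrade_cv_summary", class(out))
  out
}

#' Model-comparison report table
#'
#' One row per family, one column per metric formatted
#' `mean (SE) (ci_low-ci_high)`; the best family per metric (lowest for
#' error metrics, highest for R^2 and P(E < 0.5)) is flagged in
#' `best_<metric>` columns.
#'
#' @param summary A `flowgrade_cv_summary` from [summarize_cv()].
#' @return A tibble report.
#' @export
comparison_report <- function(summary) {
  fmt <- function(m, s, lo, hi)
    sprintf("%.3f (%.3f) (%.3f-%.3f)", m, s, lo, hi)
  higher_better <- c("r2", "p_under_half")
  wide <- summary |>
    dplyr::mutate(cell = fmt(mean, .data$se, .data$ci_low, .data$ci_high))
  best <- wide |>
    dplyr::mutate(is_best = if (unique(.data$metric) %in% higher_better)
      .data$mean == max(.data$mean) else .data$mean == min(.data$mean),
      .by = "metric")
  tab <- best |>
    dplyr::select("family", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
  flags <- best |>
    dplyr::select("family", "metric", "is_best") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "is_best",
                       names_prefix = "best_")
  dplyr::left_join(tab, flags, by = "family")
}

#' @export
autoplot.flowgrade_cv_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$family, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fold mean (bootstrap 95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
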