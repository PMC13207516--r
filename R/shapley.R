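# Shapley feature attributions with an interventional (marginal) value
# function: v(S) = mean over background rows of predictions on hybrids that
# take the features in S from the explained sample and the rest from the
# background row. Exact enumeration is the oracle for small p; a permutation
# sampler covers the full 19-feature space.

shap_check_inputs <- function(model, background, x) {
  fn <- model$feature_names
  stopifnot(all(fn %in% names(background)), nrow(x) == 1,
            all(fn %in% names(x)))
  fn
}

#' Exact Shapley attributions by subset enumeration
#'
#' Exhaustively enumerates all `2^p` feature coalitions (p <= 12) and
#' applies the Shapley kernel weights, so the attribution satisfies the
#' efficiency, symmetry and dummy axioms to numerical precision:
#' `baseline + sum(attribution) = prediction`. For an additive linear model
#' the attribution of feature i reduces to
#' `coefficient_i * (x_i - mean(background_i))`.
#'
#' @param model A `flowgrade_model`.
#' @param background Data frame of background rows defining the marginal
#'   expectation.
#' @param x One-row data frame: the sample to explain.
#' @return Named attribution vector with attribute `"baseline"` (mean
#'   background prediction).
#' @export
exact_shapley <- function(model, background, x) {
  fn <- shap_check_inputs(model, background, x)
  p <- length(fn)
  if (p > 12)
    abort("exact enumeration limited to 12 features; use sampled_shapley()")
  B <- as.matrix(background[fn])
  xv <- as.numeric(x[1, fn])
  nb <- nrow(B)
  n_masks <- bitwShiftL(1L, p)
  # v(S) for every coalition mask
  v <- numeric(n_masks)
  for (m in 0:(n_masks - 1L)) {
    H <- B
    for (j in seq_len(p))
      if (bitwAnd(m, bitwShiftL(1L, j - 1L)) != 0L) H[, j] <- xv[j]
    Hd <- as.data.frame(H)
    names(Hd) <- fn
    v[m + 1L] <- mean(predict(model, Hd))
  }
  sizes <- vapply(0:(n_masks - 1L), function(m) sum(bitwAnd(
    m, bitwShiftL(1L, 0:(p - 1L))) != 0L), 0L)
  wt <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) /
    factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_masks - 1L), bit) == 0L)  # 1-based masks+1
    s <- sizes[without]
    phi[j] <- sum(wt[s + 1L] * (v[without + bit] - v[without]))
  }
  names(phi) <- fn
  attr(phi, "baseline") <- v[1L]
  phi
}

#' Sampled Shapley attributions by permutation walks
#'
#' Unbiased permutation-sampling estimator of the interventional Shapley
#' value: per permutation a background row is drawn, and features are
#' switched from background to the explained sample in permutation order;
#' the successive prediction increments are the marginal contributions.
#' Reports a Monte-Carlo standard error per feature. Efficiency holds
#' exactly against the baseline formed by the sampled background rows.
#'
#' @param model A `flowgrade_model`.
#' @param background Background data frame.
#' @param x One-row data frame to explain.
#' @param n_permutations Number of permutation walks (>= 50).
#' @param seed Integer seed.
#' @return Named attribution vector with attributes `"baseline"` and `"se"`
#'   (named per-feature Monte-Carlo standard errors).
#' @export
sampled_shapley <- function(model, background, x, n_permutations = 200,
                            seed = 1L) {
  fn <- shap_check_inputs(model, background, x)
  p <- length(fn)
  if (n_permutations < 50) abort("`n_permutations` must be >= 50")
  B <- as.matrix(background[fn])
  xv <- as.numeric(x[1, fn])
  nb <- nrow(B)
  contrib <- matrix(0, n_permutations, p, dimnames = list(NULL, fn))
  base_preds <- numeric(n_permutations)
  withr::with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(p)
      b <- B[sample.int(nb, 1L), ]
      # walk: p + 1 hybrid rows from all-background to all-x
      H <- matrix(b, p + 1L, p, byrow = TRUE)
      row_cur <- b
      for (k in seq_len(p)) {
        row_cur[perm[k]] <- xv[perm[k]]
        H[k + 1L, ] <- row_cur
      }
      Hd <- as.data.frame(H)
      names(Hd) <- fn
      preds <- predict(model, Hd)
      contrib[r, perm] <- diff(preds)
      base_preds[r] <- preds[1L]
    }
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, sd) / sqrt(n_permutations)
  attr(phi, "baseline") <- mean(base_preds)
  attr(phi, "se") <- se
  phi
}

#' Attribution table for many samples
#'
#' Applies [exact_shapley()] (p <= 12) or [sampled_shapley()] to each row of
#' `data` against a common background (subsampled to at most
#' `max_background` rows for cost).
#'
#' @param model A `flowgrade_model`.
#' @param data Data frame of samples to explain (may carry `sample_id`).
#' @param background Background data (defaults to `data`).
#' @param method `"auto"`, `"exact"` or `"sampled"`.
#' @param n_permutations Permutations per sample for the sampler.
#' @param max_background Background subsample cap (default 100).
#' @param seed Integer seed.
#' @return A `flowgrade_attribution` tibble: `sample_id`, `baseline`,
#'   `prediction`, then one signed attribution column per feature.
#' @export
attribution_table <- function(model, data, background = data,
                              method = c("auto", "exact", "sampled"),
                              n_permutations = 200, max_background = 100,
                              seed = 1L) {
  method <- match.arg(method)
  fn <- model$feature_names
  p <- length(fn)
  if (method == "auto") method <- if (p <= 12) "exact" else "sampled"
  bg <- background[fn]
  if (nrow(bg) > max_background) {
    keep <- withr::with_seed(derive_seed(seed, "bg"),
                             sample.int(nrow(bg), max_background))
    bg <- bg[keep, , drop = FALSE]
  }
  ids <- if ("sample_id" %in% names(data)) data$sample_id
         else sprintf("S%04d", seq_len(nrow(data)))
  preds <- predict(model, data[fn])
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    xi <- data[i, fn]
    phi <- if (method == "exact") exact_shapley(model, bg, xi)
    else sampled_shapley(model, bg, xi, n_permutations,
                         seed = derive_seed(seed, "perm", i))
    dplyr::bind_cols(
      tibble::tibble(sample_id = ids[i],
                     baseline = attr(phi, "baseline"),
                     prediction = preds[i]),
      tibble::as_tibble(as.list(phi))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flowgrade_attribution", class(out))
  attr(out, "feature_names") <- fn
  attr(out, "method") <- method
  out
}

#' Ranked mean-absolute-attribution importance
#'
#' Mean absolute Shapley attribution per feature over all explained samples,
#' sorted descending, with the top `top_n` features flagged.
#'
#' @param attributions A `flowgrade_attribution` table.
#' @param top_n How many leading features to flag (default 6).
#' @return Tibble `feature`, `mean_abs_attribution`, `rank`, `top`.
#' @export
importance_report <- function(attributions, top_n = 6) {
  fn <- attr(attributions, "feature_names")
  stopifnot(!is.null(fn))
  attributions |>
    tidyr::pivot_longer(dplyr::all_of(fn), names_to = "feature",
                        values_to = "attribution") |>
    dplyr::summarise(mean_abs_attribution = mean(abs(.data$attribution)),
                     .by = "feature") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_attribution)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  top = .data$rank <= top_n)
}

#' @export
autoplot.flowgrade_attribution <- function(object, ...) {
  fn <- attr(object, "feature_names")
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(fn), names_to = "feature",
                        values_to = "attribution")
  ord <- long |>
    dplyr::summarise(m = mean(abs(.data$attribution)), .by = "feature") |>
    dplyr::arrange(.data$m)
  long$feature <- factor(long$feature, levels = ord$feature)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribution,
                                     y = .data$feature)) +
    ggplot2::geom_jitter(height = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Shapley attribution (score points)", y = NULL) +
    ggplot2::theme_minimal()
}
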