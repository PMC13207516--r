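# Consensus scoring and annotation-quality statistics.

rating_matrix <- function(ratings) {
  rater_cols <- setdiff(names(ratings), "sample_id")
  m <- as.matrix(ratings[rater_cols])
  rownames(m) <- ratings$sample_id
  m
}

#' Sample-wise consensus scores
#'
#' Arithmetic mean of the non-missing ratings of each sample; the single
#' outcome variable for the regression models. Missing entries are ignored,
#' never imputed. Errors if any sample has fewer than two ratings.
#'
#' @param ratings Rating tibble: `sample_id` plus one column per rater
#'   (NA = missing).
#' @return Tibble `sample_id`, `consensus`.
#' @export
#' @examples
#' r <- tibble::tibble(sample_id = "a", rater_1 = 4, rater_2 = 6)
#' consensus_scores(r)$consensus  # 5
consensus_scores <- function(ratings) {
  m <- rating_matrix(ratings)
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok < 2))
    abort(sprintf("%d sample(s) have fewer than 2 ratings", sum(n_ok < 2)))
  tibble::tibble(sample_id = ratings$sample_id,
                 consensus = unname(rowMeans(m, na.rm = TRUE)))
}

#' Intraclass correlation ICC(3,k) with 95% confidence interval
#'
#' Two-way mixed-effects, consistency definition, average of k raters:
#' `ICC3k = (MS_samples - MS_error) / MS_samples` from the two-way ANOVA of
#' the complete-case sample x rater matrix. The 95% CI uses the standard
#' F-distribution interval. Consistency ICC ignores constant per-rater
#' shifts. The report carries a pass flag against the ICC3k >= 0.8
#' reliability benchmark.
#'
#' @param ratings Rating tibble as in [consensus_scores()]; samples with any
#'   missing rating are dropped for the ANOVA (complete-case).
#' @param conf_level Confidence level (default 0.95).
#' @return A `flowgrade_reliability` object: `icc3k`, `ci95`,
#'   `n_samples_used`, `k_raters`, `benchmark_pass` (ICC >= 0.8).
#' @export
icc3k <- function(ratings, conf_level = 0.95) {
  m <- rating_matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    abort("need at least 2 complete-case samples and 2 raters")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps) {
    warn("zero between-sample variance: ICC3k undefined")
    est <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    est <- (msr - mse) / msr
    alpha <- 1 - conf_level
    if (mse <= 0) {
      ci <- c(1, 1)
    } else {
      f <- msr / mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      fl <- f / qf(1 - alpha / 2, df1, df2)
      fu <- f * qf(1 - alpha / 2, df2, df1)
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  }
  structure(list(icc3k = est, ci95 = ci, n_samples_used = n, k_raters = k,
                 conf_level = conf_level,
                 benchmark_pass = isTRUE(est >= 0.8)),
            class = "flowgrade_reliability")
}

#' @export
print.flowgrade_reliability <- function(x, ...) {
  cat(sprintf("ICC3k = %.3f (CI%d%%: %.3f-%.3f), n = %d, k = %d [%s]\n",
              x$icc3k, round(100 * x$conf_level), x$ci95[1], x$ci95[2],
              x$n_samples_used, x$k_raters,
              if (x$benchmark_pass) "meets 0.8 benchmark"
              else "below 0.8 benchmark"))
  invisible(x)
}

#' @export
tidy.flowgrade_reliability <- function(x, ...) {
  tibble::tibble(term = "icc3k", estimate = x$icc3k,
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @export
glance.flowgrade_reliability <- function(x, ...) {
  tibble::tibble(icc3k = x$icc3k, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], n_samples_used = x$n_samples_used,
                 k_raters = x$k_raters, benchmark_pass = x$benchmark_pass)
}

#' Spearman rank correlation validity check
#'
#' Rank correlation with average-rank (midrank) tie handling and a two-sided
#' p value from the t approximation
#' `t = rs sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 4).
#' @return Tibble `rs`, `p_value`, `n`.
#' @export
spearman_validity <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) abort("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: rank correlation undefined")
    return(tibble::tibble(rs = NA_real_, p_value = NA_real_, n = n))
  }
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  tibble::tibble(rs = rs, p_value = p, n = n)
}
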