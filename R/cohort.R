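# Synthetic cohort generator: correlated lognormal hemodynamic features, a
# latent quality score monotonically decreasing in the adverse indicators,
# and noisy, biased raters on a continuous 1-10 scale.

# default lognormal medians (physiologically plausible magnitudes for a 3 mm
# end-to-side anastomosis) and log-sds; one-factor loadings define the
# feature correlation (a common "hemodynamic severity" factor)
cohort_defaults <- function() {
  medians <- c(
    "WSS_trans" = 0.4, "WSSG" = 0.8, "dp_in2-out" = 50,
    "Vorticity_max" = 1500, "TAWSS" = 1.2, "Strain_max" = 2000,
    "RRT" = 0.9, "v_max" = 0.6, "Helicity_max" = 0.3, "v_average" = 0.15,
    "E_loss" = 1.5e-3, "dp_in1-out" = 80, "p_max" = 450, "OSI" = 0.03,
    "E_eff" = 0.75, "v_out" = 0.2, "Reynolds_max" = 550, "Q_in1" = 350,
    "Q_in2" = 120
  )
  # the dominant adverse indicators are strongly right-skewed (an order of
  # magnitude and more between clean and badly distorted anastomoses), which
  # is what makes the latent quality genuinely nonlinear in the raw features
  sdlog <- c(
    "WSS_trans" = 0.9, "WSSG" = 0.9, "dp_in2-out" = 0.8,
    "Vorticity_max" = 0.5, "TAWSS" = 0.4, "Strain_max" = 0.5,
    "RRT" = 0.5, "v_max" = 0.35, "Helicity_max" = 0.6, "v_average" = 0.3,
    "E_loss" = 0.6, "dp_in1-out" = 0.5, "p_max" = 0.4, "OSI" = 0.7,
    "E_eff" = 0.08, "v_out" = 0.3, "Reynolds_max" = 0.35, "Q_in1" = 0.3,
    "Q_in2" = 0.4
  )
  loadings <- c(
    "WSS_trans" = 0.75, "WSSG" = 0.70, "dp_in2-out" = 0.60,
    "Vorticity_max" = 0.65, "TAWSS" = 0.55, "Strain_max" = 0.55,
    "RRT" = 0.50, "v_max" = 0.55, "Helicity_max" = 0.50, "v_average" = 0.45,
    "E_loss" = 0.65, "dp_in1-out" = 0.55, "p_max" = 0.50, "OSI" = 0.45,
    "E_eff" = -0.40, "v_out" = -0.35, "Reynolds_max" = 0.50,
    "Q_in1" = 0.30, "Q_in2" = 0.30
  )
  # signed generative weights of the latent quality; the three dominant
  # adverse indicators carry the largest negative weights
  weights <- c(
    "WSS_trans" = -1.0, "WSSG" = -0.9, "dp_in2-out" = -0.7,
    "Vorticity_max" = -0.45, "TAWSS" = 0, "Strain_max" = 0,
    "RRT" = -0.2, "v_max" = 0, "Helicity_max" = -0.2, "v_average" = 0,
    "E_loss" = -0.3, "dp_in1-out" = -0.15, "p_max" = -0.25, "OSI" = -0.15,
    "E_eff" = 0.3, "v_out" = 0.2, "Reynolds_max" = 0, "Q_in1" = 0,
    "Q_in2" = 0
  )
  list(medians = medians, sdlog = sdlog, loadings = loadings,
       weights = weights)
}

#' Specification of a synthetic assessment cohort
#'
#' Declares the generative model for a synthetic cohort: a Gaussian copula
#' with one-factor correlation over the 19 log-features, lognormal marginals,
#' a latent quality score obtained from a weighted combination of
#' standardized log-features through a logistic (saturating) link onto
#' `score_range`, and independent noisy, biased raters. The default rater
#' noise is calibrated in closed form so the expected consistency ICC of
#' `n_raters` averaged raters equals `target_icc3k`.
#'
#' @param n_samples Cohort size (default 419).
#' @param n_raters Number of raters (default 3).
#' @param score_range Numeric `[low, high]` score scale (default `c(1, 10)`).
#' @param quality_weights Named signed weights over (a subset of) the 19
#'   features; `WSS_trans`, `WSSG` and `dp_in2-out` must be strictly
#'   negative (quality decreases as they grow).
#' @param quality_intercept,quality_sd Location and spread of the latent
#'   linear predictor before the logistic link (defaults 0.79 / 0.703, chosen
#'   so the expected score range at n = 419 is roughly 3 to 9.5).
#' @param rater_bias_sd SD of per-rater additive bias (score points).
#' @param rater_noise_sd SD of per-rating noise; `NULL` derives it from
#'   `target_icc3k`.
#' @param target_icc3k Desired consistency ICC of averaged raters used to
#'   derive `rater_noise_sd` (default 0.846).
#' @param feature_correlation Optional 19 x 19 positive-semidefinite
#'   correlation matrix overriding the one-factor default.
#' @param seed Integer seed controlling all sampling.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 419, n_raters = 3,
                        score_range = c(1, 10),
                        quality_weights = NULL,
                        quality_intercept = 0.79, quality_sd = 0.703,
                        rater_bias_sd = 0.3, rater_noise_sd = NULL,
                        target_icc3k = 0.846,
                        feature_correlation = NULL, seed = 1L) {
  d <- cohort_defaults()
  if (is.null(quality_weights)) quality_weights <- d$weights
  w <- rep(0, length(FEATURE_NAMES))
  names(w) <- FEATURE_NAMES
  w[names(quality_weights)] <- quality_weights
  for (f in c("WSS_trans", "WSSG", "dp_in2-out"))
    if (!(w[[f]] < 0))
      abort(sprintf("quality weight for %s must be strictly negative", f))
  if (is.null(feature_correlation)) {
    l <- d$loadings
    feature_correlation <- tcrossprod(l) + diag(1 - l^2)
    dimnames(feature_correlation) <- list(FEATURE_NAMES, FEATURE_NAMES)
  } else {
    if (!isTRUE(all.equal(unname(diag(feature_correlation)),
                          rep(1, length(FEATURE_NAMES)))))
      abort("feature_correlation must have unit diagonal")
    ev <- eigen(feature_correlation, symmetric = TRUE, only.values = TRUE)
    if (min(ev$values) < -1e-8)
      abort("feature_correlation must be positive semidefinite")
  }
  if (score_range[1] >= score_range[2])
    abort("score_range low must be < high")
  spec <- structure(list(
    n_samples = as.integer(n_samples), n_raters = as.integer(n_raters),
    score_range = score_range, meanlog = log(d$medians), sdlog = d$sdlog,
    feature_correlation = feature_correlation, quality_weights = w,
    quality_intercept = quality_intercept, quality_sd = quality_sd,
    rater_bias_sd = rater_bias_sd, target_icc3k = target_icc3k,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  spec$rater_noise_sd <- rater_noise_sd %||% derive_rater_noise_sd(spec)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n = ", x$n_samples, ", raters = ", x$n_raters,
      ", scale [", x$score_range[1], ", ", x$score_range[2],
      "], rater noise sd = ", round(x$rater_noise_sd, 3), "\n", sep = "")
  invisible(x)
}

# calibrated per-feature coefficients on log(feature): scale the raw signed
# weights so the latent predictor eta is N(quality_intercept, quality_sd^2)
# exactly under the copula, and fold the log-median centering into the
# intercept
calibrated_quality <- function(spec) {
  w <- spec$quality_weights
  R <- spec$feature_correlation
  denom <- sqrt(drop(t(w) %*% R %*% w))
  if (denom == 0) {
    coefs <- w * 0
  } else {
    coefs <- spec$quality_sd * w / (spec$sdlog * denom)
  }
  intercept <- spec$quality_intercept - sum(coefs * spec$meanlog)
  list(coefficients = coefs, intercept = intercept)
}

# moments of the score distribution under the generative model, by numeric
# integration over eta ~ N(mu, sd): used for the closed-form rater-noise
# calibration
latent_score_moments <- function(spec) {
  lo <- spec$score_range[1]; hi <- spec$score_range[2]
  mu <- spec$quality_intercept; s <- spec$quality_sd
  f1 <- function(e) (lo + (hi - lo) * plogis(e)) * stats::dnorm(e, mu, s)
  f2 <- function(e) (lo + (hi - lo) * plogis(e))^2 * stats::dnorm(e, mu, s)
  m1 <- stats::integrate(f1, mu - 10 * s, mu + 10 * s)$value
  m2 <- stats::integrate(f2, mu - 10 * s, mu + 10 * s)$value
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# noise sd giving E[ICC3k] = target under the consistency two-way model:
# icc = var_s / (var_s + var_e / k)  =>  sd_e = sd_s sqrt(k (1/icc - 1))
derive_rater_noise_sd <- function(spec) {
  sd_s <- latent_score_moments(spec)[["sd"]]
  k <- spec$n_raters
  sd_s * sqrt(k * (1 / spec$target_icc3k - 1))
}

#' Sample a synthetic feature cohort
#'
#' Draws `n_samples` correlated feature vectors from the Gaussian copula +
#' lognormal marginal model of the spec. All features are strictly positive;
#' identical spec and seed give an identical table.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble: `sample_id` plus the 19 feature columns.
#' @export
#' @examples
#' head(sample_feature_cohort(cohort_spec(n_samples = 5)))
sample_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  p <- length(FEATURE_NAMES)
  Z <- withr::with_seed(derive_seed(spec$seed, "features"), {
    matrix(rnorm(n * p), n, p) %*% chol(spec$feature_correlation)
  })
  X <- exp(sweep(sweep(Z, 2, spec$sdlog, `*`), 2, spec$meanlog, `+`))
  colnames(X) <- FEATURE_NAMES
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%04d", seq_len(n))),
    tibble::as_tibble(X)
  )
}

#' Latent quality score of feature vectors
#'
#' Deterministic monotone map from features to a quality score: an affine
#' combination of log-features passed through a logistic link onto
#' `score_range`. Strictly decreasing in every feature with a negative
#' coefficient. With all-zero coefficients and zero intercept every sample
#' sits at the midpoint of the scale.
#'
#' @param features Tibble/data frame containing the feature columns named in
#'   `coefficients`.
#' @param coefficients Named numeric vector of per-feature coefficients on
#'   `log(feature)`.
#' @param intercept Scalar offset of the linear predictor.
#' @param score_range `[low, high]` of the score scale.
#' @return Numeric score per row.
#' @export
latent_quality <- function(features, coefficients, intercept = 0,
                           score_range = c(1, 10)) {
  miss <- setdiff(names(coefficients), names(features))
  if (length(miss))
    abort(paste("features missing for coefficients:",
                paste(miss, collapse = ", ")))
  X <- log(as.matrix(features[names(coefficients)]))
  eta <- intercept + drop(X %*% coefficients)
  score_range[1] + diff(score_range) * plogis(eta)
}

#' True cohort quality under a spec
#'
#' Applies the spec's calibrated generative quality function to a feature
#' table.
#'
#' @param features Feature tibble from [sample_feature_cohort()].
#' @param spec The [cohort_spec()] that generated it.
#' @return Tibble `sample_id`, `quality`.
#' @export
cohort_quality <- function(features, spec) {
  cq <- calibrated_quality(spec)
  tibble::tibble(
    sample_id = features$sample_id,
    quality = latent_quality(features, cq$coefficients, cq$intercept,
                             spec$score_range)
  )
}

#' Simulate a multi-rater score table
#'
#' Each rating is `clip(score_i + b_j + e_ij)` with per-rater bias
#' `b_j ~ N(0, bias_sd^2)`, per-rating noise `e_ij ~ N(0, noise_sd^2)` and
#' clipping at the score-scale bounds. Every sample must retain at least two
#' non-missing ratings.
#'
#' @param true_scores Numeric vector of true scores, or a tibble with
#'   `sample_id` and `quality` columns.
#' @param n_raters Number of raters (>= 2).
#' @param rater_bias_sd,rater_noise_sd Bias / noise SDs in score points.
#' @param missing_pattern Optional logical matrix (samples x raters), `TRUE`
#'   for missing.
#' @param score_range Clipping bounds.
#' @param seed Integer seed.
#' @return Tibble: `sample_id` plus one `rater_*` column per rater.
#' @export
simulate_ratings <- function(true_scores, n_raters = 3, rater_bias_sd = 0.3,
                             rater_noise_sd = 1, missing_pattern = NULL,
                             score_range = c(1, 10), seed = 1L) {
  if (n_raters < 2) abort("`n_raters` must be >= 2")
  if (is.data.frame(true_scores)) {
    ids <- true_scores$sample_id
    s <- true_scores$quality
  } else {
    s <- as.numeric(true_scores)
    ids <- sprintf("S%04d", seq_along(s))
  }
  n <- length(s)
  if (!is.null(missing_pattern)) {
    stopifnot(is.logical(missing_pattern),
              all(dim(missing_pattern) == c(n, n_raters)))
    if (any(rowSums(!missing_pattern) < 2))
      abort("missing pattern leaves a sample with fewer than 2 ratings")
  }
  R <- withr::with_seed(derive_seed(seed, "ratings"), {
    b <- rnorm(n_raters, 0, rater_bias_sd)
    e <- matrix(rnorm(n * n_raters, 0, rater_noise_sd), n, n_raters)
    sweep(e, 2, b, `+`) + s
  })
  R <- pmin(pmax(R, score_range[1]), score_range[2])
  if (!is.null(missing_pattern)) R[missing_pattern] <- NA_real_
  colnames(R) <- sprintf("rater_%d", seq_len(n_raters))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(R))
}

#' Generate a complete synthetic cohort
#'
#' Features, true latent quality, and a noisy rating table in one call.
#'
#' @param spec A [cohort_spec()].
#' @return List with `features`, `truth` (sample_id, quality) and `ratings`
#'   tibbles, plus the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  features <- sample_feature_cohort(spec)
  truth <- cohort_quality(features, spec)
  ratings <- simulate_ratings(truth, spec$n_raters, spec$rater_bias_sd,
                              spec$rater_noise_sd,
                              score_range = spec$score_range,
                              seed = derive_seed(spec$seed, "raters"))
  list(features = features, truth = truth, ratings = ratings, spec = spec)
}
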