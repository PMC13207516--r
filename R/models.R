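# The six-family regressor pool behind a uniform fit/predict contract.
# No regression-ML package exists in the target library, so the engines are
# implemented here: closed-form ridge, NIPALS partial least squares, kernel
# support vector regression via a smoothed epsilon-insensitive objective,
# and compiled CART ensembles (random forest, extremely randomized trees,
# gradient boosting).

REGRESSOR_FAMILIES <- c("ridge", "pls", "svr", "random_forest",
                        "extra_trees", "gradient_boosting")

#' Names of the regressor families
#' @return Character vector of the six family names.
#' @export
regressor_families <- function() REGRESSOR_FAMILIES

#' Hyperparameter domain constructors
#'
#' Building blocks of a [search_space()]: a continuous interval (optionally
#' log-scaled), an integer range, or a categorical set.
#'
#' @param name Hyperparameter name.
#' @param lo,hi Domain bounds (`lo < hi`; log-scaled domains must be
#'   strictly positive).
#' @param log Sample and mutate on the log scale.
#' @param values Categorical values (length >= 2).
#' @return A parameter-domain list consumed by [search_space()].
#' @export
param_cont <- function(name, lo, hi, log = FALSE) {
  stopifnot(lo < hi, !log || lo > 0)
  list(name = name, type = "cont", lo = lo, hi = hi, log = log)
}

#' @rdname param_cont
#' @export
param_int <- function(name, lo, hi) {
  stopifnot(lo < hi)
  list(name = name, type = "int", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname param_cont
#' @export
param_cat <- function(name, values) {
  stopifnot(length(values) >= 2)
  list(name = name, type = "cat", values = values)
}

#' Assemble a hyperparameter search space
#'
#' @param params List of domains from [param_cont()], [param_int()],
#'   [param_cat()].
#' @return A `search_space` object.
#' @export
#' @examples
#' search_space(list(param_cont("alpha", 1e-3, 1e3, log = TRUE)))
search_space <- function(params) {
  names(params) <- vapply(params, `[[`, "", "name")
  structure(params, class = "search_space")
}

new_search_space <- search_space

#' Default hyperparameter search space of a family
#'
#' Conventional wide boxes per family: ridge penalty log-uniform over
#' `[1e-3, 1e3]`; PLS components `[1, 19]`; SVR kernel in
#' `{linear, polynomial, rbf}` with log-scaled `C`, `epsilon`, `gamma` and
#' polynomial degree `{2, 3, 4}`; tree ensembles with tree count, depth,
#' minimum leaf size and feature fraction; gradient boosting additionally
#' with log-scaled learning rate, row/column subsampling and an L2 leaf
#' penalty.
#'
#' @param family One of [regressor_families()].
#' @return A `search_space` object (named list of parameter domains).
#' @export
default_space <- function(family) {
  switch(
    match.arg(family, REGRESSOR_FAMILIES),
    ridge = new_search_space(list(
      param_cont("alpha", 1e-3, 1e3, log = TRUE)
    )),
    pls = new_search_space(list(
      param_int("ncomp", 1, 19)
    )),
    svr = new_search_space(list(
      param_cat("kernel", c("linear", "polynomial", "rbf")),
      param_cont("C", 1e-2, 1e3, log = TRUE),
      param_cont("epsilon", 1e-3, 1, log = TRUE),
      param_cont("gamma", 1e-4, 1e1, log = TRUE),
      param_cat("degree", c(2L, 3L, 4L))
    )),
    random_forest = new_search_space(list(
      param_int("n_trees", 50, 500),
      param_int("max_depth", 2, 20),
      param_int("min_leaf", 1, 20),
      param_cont("feature_fraction", 0.2, 1.0)
    )),
    extra_trees = new_search_space(list(
      param_int("n_trees", 50, 500),
      param_int("max_depth", 2, 20),
      param_int("min_leaf", 1, 20),
      param_cont("feature_fraction", 0.2, 1.0)
    )),
    gradient_boosting = new_search_space(list(
      param_int("n_trees", 50, 500),
      param_cont("learning_rate", 0.01, 0.3, log = TRUE),
      param_int("max_depth", 2, 10),
      param_cont("subsample", 0.5, 1.0),
      param_cont("colsample", 0.5, 1.0),
      param_cont("lambda", 1e-3, 10, log = TRUE)
    ))
  )
}

needs_scaling <- function(family) family %in% c("ridge", "pls", "svr")

default_params <- function(family) {
  switch(
    family,
    ridge = list(alpha = 1),
    pls = list(ncomp = 5L),
    svr = list(kernel = "rbf", C = 10, epsilon = 0.1, gamma = 1 / 19,
               degree = 3L),
    random_forest = list(n_trees = 200L, max_depth = 12L, min_leaf = 2L,
                         feature_fraction = 0.5),
    extra_trees = list(n_trees = 200L, max_depth = 12L, min_leaf = 2L,
                       feature_fraction = 0.5),
    gradient_boosting = list(n_trees = 200L, learning_rate = 0.05,
                             max_depth = 3L, min_leaf = 2L, subsample = 0.8,
                             colsample = 0.8, lambda = 1)
  )
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv, X = sweep(sweep(X, 2, mu), 2, sdv, `/`))
}
scale_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mu), 2, scaler$sd, `/`)
}

fit_ridge <- function(X, y, alpha) {
  p <- ncol(X)
  G <- crossprod(X) + diag(alpha, p)
  ym <- mean(y)
  beta <- solve(G, crossprod(X, y - ym))
  list(beta = beta, intercept = ym)
}

fit_pls <- function(X, y, ncomp) {
  # NIPALS partial least squares regression on centered data
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1)
  ym <- mean(y)
  E <- X; f <- y - ym
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1; break }
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    W[, a] <- w; P[, a] <- p_; qv[a] <- q_; Tm[, a] <- t_
  }
  if (ncomp < 1) return(list(beta = matrix(0, p, 1), intercept = ym))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  beta <- W %*% solve(crossprod(P, W), qv)
  list(beta = beta, intercept = ym)
}

svr_kernel <- function(kernel, gamma, degree) {
  switch(kernel,
         linear = function(A, B) tcrossprod(A, B),
         polynomial = function(A, B) (gamma * tcrossprod(A, B) + 1)^degree,
         rbf = function(A, B) {
           d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) -
             2 * tcrossprod(A, B)
           exp(-gamma * pmax(d2, 0))
         })
}

fit_svr <- function(X, y, kernel, C, epsilon, gamma, degree) {
  # kernel SVR by minimizing 0.5 b'Kb + C sum sqhinge_eps(Kb + b0 - y)
  # (squared epsilon-insensitive loss: smooth, deterministic L-BFGS)
  kf <- svr_kernel(kernel, gamma, as.integer(degree))
  K <- kf(X, X)
  n <- nrow(X)
  obj <- function(par) {
    b <- par[1:n]; b0 <- par[n + 1]
    Kb <- drop(K %*% b)
    r <- Kb + b0 - y
    ex <- pmax(abs(r) - epsilon, 0)
    0.5 * sum(b * Kb) + C * sum(ex^2)
  }
  grd <- function(par) {
    b <- par[1:n]; b0 <- par[n + 1]
    Kb <- drop(K %*% b)
    r <- Kb + b0 - y
    lp <- 2 * pmax(abs(r) - epsilon, 0) * sign(r)
    c(Kb + C * drop(K %*% lp), C * sum(lp))
  }
  fit <- optim(rep(0, n + 1), obj, grd, method = "L-BFGS-B",
               control = list(maxit = 300))
  list(beta = fit$par[1:n], intercept = fit$par[n + 1], kernel_fn = kf,
       X_train = X)
}

#' Fit a regression model from the pool
#'
#' Uniform fit contract over the six families. Scale-sensitive families
#' (ridge, PLS, SVR) are fit on z-scored features; the scaler is learned on
#' the training data only and bundled into the model, so callers never
#' pre-scale. Tree ensembles are seeded and refit identically for the same
#' seed.
#'
#' @param family One of [regressor_families()].
#' @param params Named list of hyperparameters (defaults filled in for any
#'   omitted).
#' @param X Data frame / tibble of numeric features.
#' @param y Numeric outcome, same length as `nrow(X)`.
#' @param seed Integer seed for the stochastic families.
#' @return A `flowgrade_model` with a [predict()] method that aligns columns
#'   by name.
#' @export
fit_regressor <- function(family, params = list(), X, y, seed = 1L) {
  family <- match.arg(family, REGRESSOR_FAMILIES)
  if (anyNA(X) || anyNA(y)) abort("missing values are not allowed")
  if (length(y) != nrow(X)) abort("y length must match nrow(X)")
  if (nrow(X) < 2) abort("need at least 2 training samples")
  if (sd(y) == 0) abort("degenerate constant outcome")
  p <- utils::modifyList(default_params(family), params)
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  feature_names <- colnames(Xm)
  scaler <- NULL
  if (needs_scaling(family)) {
    sc <- scale_train(Xm)
    scaler <- sc[c("mu", "sd")]
    Xm <- sc$X
  }
  fit <- switch(
    family,
    ridge = fit_ridge(Xm, y, p$alpha),
    pls = fit_pls(Xm, y, as.integer(p$ncomp)),
    svr = fit_svr(Xm, y, p$kernel, p$C, p$epsilon, p$gamma, p$degree),
    random_forest = fg_forest_fit(Xm, y, as.integer(p$n_trees),
                                  as.integer(p$max_depth),
                                  as.integer(p$min_leaf),
                                  p$feature_fraction, TRUE, FALSE,
                                  as.integer(seed)),
    extra_trees = fg_forest_fit(Xm, y, as.integer(p$n_trees),
                                as.integer(p$max_depth),
                                as.integer(p$min_leaf),
                                p$feature_fraction, FALSE, TRUE,
                                as.integer(seed)),
    gradient_boosting = fg_gbt_fit(Xm, y, as.integer(p$n_trees),
                                   p$learning_rate, as.integer(p$max_depth),
                                   as.integer(p$min_leaf), p$subsample,
                                   p$colsample, p$lambda, as.integer(seed))
  )
  structure(list(family = family, hyperparameters = p, fit = fit,
                 scaler = scaler, feature_names = feature_names,
                 seed = as.integer(seed)),
            class = "flowgrade_model")
}

#' @export
print.flowgrade_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v)
                format(v, digits = 3), ""),
              sep = "=", collapse = ", ")
  cat("<flowgrade_model> ", x$family, " (", hp, "), ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict scores from a fitted model
#'
#' Columns of `newdata` are aligned to the training feature names; a
#' mismatch errors listing the difference. Any bundled scaler is applied
#' internally.
#'
#' @param object A `flowgrade_model`.
#' @param newdata Data frame with (at least) the training feature columns.
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.flowgrade_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  extra <- setdiff(setdiff(names(newdata), "sample_id"),
                   object$feature_names)
  if (length(miss))
    abort(paste0("newdata is missing feature(s): ",
                 paste(miss, collapse = ", "),
                 if (length(extra)) paste0("; unexpected: ",
                                           paste(extra, collapse = ", "))))
  Xm <- as.matrix(newdata[object$feature_names])
  storage.mode(Xm) <- "double"
  if (!is.null(object$scaler)) Xm <- scale_apply(object$scaler, Xm)
  out <- switch(
    object$family,
    ridge = drop(Xm %*% object$fit$beta) + object$fit$intercept,
    pls = drop(Xm %*% object$fit$beta) + object$fit$intercept,
    svr = drop(object$fit$kernel_fn(Xm, object$fit$X_train) %*%
                 object$fit$beta) + object$fit$intercept,
    random_forest = fg_forest_predict(object$fit, Xm),
    extra_trees = fg_forest_predict(object$fit, Xm),
    gradient_boosting = fg_gbt_predict(object$fit, Xm)
  )
  as.numeric(out)
}
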