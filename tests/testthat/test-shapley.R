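# Shapley axioms under the interventional value function. For a linear
# model f(x) = b0 + sum b_i x_i the exact attribution is
# b_i (x_i - mean(background_i)).

fit_linear_oracle <- function(p = 5, n = 60, seed = 1) {
  withr::with_seed(seed, {
    X <- tibble::as_tibble(matrix(rnorm(n * p), n, p,
                                  dimnames = list(NULL, paste0("f",
                                                               seq_len(p)))))
    beta <- rnorm(p)
    beta[p] <- 0  # one dummy feature the model ignores
    y <- drop(as.matrix(X) %*% beta) + 3
  })
  m <- fit_regressor("ridge", list(alpha = 1e-10), X, y)
  list(model = m, X = X, beta = beta)
}

test_that("exact Shapley matches the linear closed form, dummy and
          efficiency axioms", {
  o <- fit_linear_oracle(p = 6, seed = 2)
  mu_bg <- colMeans(as.matrix(o$X))
  slope <- drop(o$model$fit$beta) / o$model$scaler$sd
  for (i in c(1, 7, 20)) {
    phi <- exact_shapley(o$model, o$X, o$X[i, ])
    expected <- slope * (as.numeric(o$X[i, ]) - mu_bg)
    expect_lt(max(abs(phi - expected)), 1e-9)
    expect_lt(abs(phi[["f6"]]), 1e-9)  # dummy feature
    expect_lt(abs(attr(phi, "baseline") + sum(phi) -
                    predict(o$model, o$X[i, ])), 1e-9)
  }
  d13 <- fix_xy(n = 30, p = 13, seed = 1)
  m13 <- fit_regressor("ridge", list(), d13$X, d13$y)
  expect_error(exact_shapley(m13, d13$X, d13$X[1, ]), "12 features")
})

test_that("two functionally identical features share attribution", {
  withr::with_seed(4, {
    X <- tibble::tibble(f1 = rnorm(80), f2 = rnorm(80))
    X$f3 <- X$f1  # clone of f1
    y <- X$f1 + X$f3 + 0.5 * X$f2
  })
  m <- fit_regressor("ridge", list(alpha = 1e-8), X, y)
  phi <- exact_shapley(m, X, X[5, ])
  # collinear clone: equal shares up to the tiny-ridge conditioning error
  expect_lt(abs(phi[["f1"]] - phi[["f3"]]), 1e-6)
})

test_that("sampled Shapley agrees with the exact oracle within 3 SEs", {
  o <- fit_linear_oracle(p = 8, seed = 3)
  phi_ex <- exact_shapley(o$model, o$X, o$X[4, ])
  phi_s <- sampled_shapley(o$model, o$X, o$X[4, ], n_permutations = 400,
                           seed = 7)
  se <- attr(phi_s, "se")
  expect_true(all(abs(phi_s - phi_ex) <= 3 * se + 1e-9))
  # efficiency against the sampled baseline
  expect_lt(abs(attr(phi_s, "baseline") + sum(phi_s) -
                  predict(o$model, o$X[4, ])), 1e-9)
  # seeded reproducibility
  phi_s2 <- sampled_shapley(o$model, o$X, o$X[4, ], n_permutations = 400,
                            seed = 7)
  expect_identical(phi_s, phi_s2)
})

test_that("Monte-Carlo error shrinks roughly as 1/sqrt(permutations)", {
  o <- fit_linear_oracle(p = 6, seed = 5)
  se200 <- mean(attr(sampled_shapley(o$model, o$X, o$X[2, ], 200,
                                     seed = 1), "se"))
  se800 <- mean(attr(sampled_shapley(o$model, o$X, o$X[2, ], 800,
                                     seed = 1), "se"))
  expect_gt(se200 / se800, 1.5)
  expect_lt(se200 / se800, 2.7)
})

test_that("importance ranking orders features by mean |attribution|", {
  withr::with_seed(6, {
    X <- tibble::as_tibble(matrix(rnorm(120 * 4), 120, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))))
    y <- 3 * X$f2 + 0.5 * X$f4 + rnorm(120, 0, 0.05)
  })
  m <- fit_regressor("gradient_boosting",
                     list(n_trees = 150, max_depth = 3), X, y, seed = 2)
  at <- attribution_table(m, X[1:40, ], background = X, method = "exact")
  imp <- importance_report(at, top_n = 2)
  expect_equal(imp$feature[1], "f2")
  expect_true(imp$top[1] && imp$top[2])
  expect_false(any(imp$top[3:4]))
  expect_true(all(imp$mean_abs_attribution >= 0))
  expect_equal(imp$mean_abs_attribution, sort(imp$mean_abs_attribution,
                                              decreasing = TRUE))
})

test_that("signed attributions track the sign of the generative effect", {
  withr::with_seed(8, {
    X <- tibble::as_tibble(matrix(rlnorm(150 * 3), 150, 3,
                                  dimnames = list(NULL, paste0("f", 1:3))))
    y <- 8 - 1.5 * log(X$f1) + 0.2 * log(X$f3) + rnorm(150, 0, 0.1)
  })
  m <- fit_regressor("gradient_boosting",
                     list(n_trees = 150, max_depth = 3), X, y, seed = 3)
  at <- attribution_table(m, X[1:60, ], background = X, method = "exact")
  # negative-weight feature: value and signed attribution anticorrelate
  expect_lt(cor(X$f1[1:60], at$f1), -0.5)
})
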