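test_that("metrics match hand-computed values", {
  perfect <- regression_metrics(c(2, 4, 6), c(2, 4, 6))
  expect_equal(unlist(perfect), c(rmse = 0, mae = 0, mape = 0, r2 = 1,
                                  p_under_half = 1))
  # strict inequality in P(E < 0.5): errors 0.1, 0.6, 0.4, 0.5 -> 2 of 4
  y <- c(4, 5, 6, 7)
  m <- regression_metrics(y, y - c(0.1, 0.6, 0.4, 0.5))
  expect_equal(m$p_under_half, 0.5)
  # constant predictor at the mean: R^2 = 0
  yt <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(yt, rep(mean(yt), 4))$r2, 0)
  expect_warning(regression_metrics(c(2, 2), c(1, 3)), "zero-variance")
})

test_that("rmse >= mae and the fold r2 identity hold on random data", {
  withr::with_seed(10, {
    for (i in 1:20) {
      yt <- rnorm(30, 6, 1.5)
      yp <- yt + rnorm(30, 0, 0.7)
      m <- regression_metrics(yt, yp)
      expect_gte(m$rmse, m$mae)
      expect_equal(m$r2, 1 - mean((yt - yp)^2) / mean((yt - mean(yt))^2),
                   tolerance = 1e-12)
    }
  })
})

test_that("stratified folds partition the data and balance the outcome", {
  y <- withr::with_seed(3, rnorm(105, 6, 1.5))
  f <- flowgrade:::make_folds(y, 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  expect_true(all(table(f) >= 10))
  fold_means <- tapply(y, f, mean)
  expect_lt(max(abs(fold_means - mean(y))), 1)
})

test_that("nested CV assigns each sample to exactly one outer test fold", {
  d <- fix_xy(n = 60, p = 4, seed = 5)
  data <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("x%02d", 1:60),
                                          consensus = d$y), d$X)
  cv <- nested_cv(data, families = "ridge",
                  evo_cfg = fix_evo_cfg(seed = 2), outer_k = 5, inner_k = 3,
                  seed = 9)
  expect_setequal(cv$oof$sample_id, data$sample_id)
  expect_equal(nrow(cv$oof), 60)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sort(unique(cv$folds$fold)), 1:5)
  # chosen hyperparameters lie inside the search space
  for (hp in cv$folds$hyperparameters)
    expect_true(hp$alpha >= 1e-3 && hp$alpha <= 1e3)
})

test_that("tuning beats the median random configuration from the space", {
  d <- fix_xy(n = 120, p = 5, seed = 21, nonlinear = TRUE)
  space <- fix_gb_space()
  inner <- flowgrade:::make_folds(d$y, 4, seed = 3)
  fitness <- function(g)
    flowgrade:::inner_cv_mse("gradient_boosting", g, d$X, d$y, inner, 7L)
  res <- evolve(space, fitness, evo_config(mu = 8, lambda = 8,
                                           max_generations = 6, seed = 31))
  rand_f <- withr::with_seed(32,
    sapply(1:11, function(i) fitness(random_genome(space))))
  expect_lt(res$best$fitness, median(rand_f))
})

test_that("fold summaries degenerate correctly and bootstrap is seeded", {
  d <- fix_xy(n = 50, p = 3, seed = 6)
  data <- dplyr::bind_cols(tibble::tibble(consensus = d$y), d$X)
  cv <- nested_cv(data, families = "ridge", evo_cfg = fix_evo_cfg(seed = 1),
                  outer_k = 5, inner_k = 3, seed = 4)
  s1 <- summarize_cv(cv, n_boot = 200, seed = 11)
  s2 <- summarize_cv(cv, n_boot = 200, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1$ci_low <= s1$ci_high))
  # identical fold metrics give SE 0 and a degenerate CI
  cv2 <- cv
  cv2$folds[c("rmse", "mae", "mape", "r2", "p_under_half")] <-
    lapply(c(0.5, 0.4, 0.1, 0.8, 0.7), rep, 5)
  cv2$oof$y_pred <- cv2$oof$y_true  # degenerate pooled predictions
  s3 <- summarize_cv(cv2, n_boot = 50, seed = 1)
  expect_equal(unique(s3$se), 0)
  rmse_row <- s3[s3$metric == "rmse", ]
  expect_equal(rmse_row$ci_low, rmse_row$ci_high)
})

test_that("comparison report formats cells and flags the best family", {
  summ <- tibble::tibble(
    family = rep(c("a", "b"), each = 5),
    metric = rep(c("rmse", "mae", "mape", "r2", "p_under_half"), 2),
    mean = c(0.8, 0.6, 0.12, 0.60, 0.70, 0.7, 0.5, 0.11, 0.70, 0.80),
    se = rep(0.02, 10), ci_low = rep(0.1, 10), ci_high = rep(0.9, 10)
  )
  class(summ) <- c("flowgrade_cv_summary", class(summ))
  rep_ <- comparison_report(summ)
  expect_true(all(rep_$best_rmse == c(FALSE, TRUE)))
  expect_true(all(rep_$best_r2 == c(FALSE, TRUE)))   # higher is better
  expect_match(rep_$rmse[1], "^0.800 \\(0.020\\) \\(0.100-0.900\\)$")
  # formatting round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(rep_, path)
  back <- read_table_csv(path)
  expect_equal(back$rmse, rep_$rmse)
  nums <- as.numeric(sub(" .*", "", back$rmse))
  expect_equal(nums, c(0.8, 0.7))
})
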