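test_that("probability schedules start, end, and move monotonically", {
  cfg <- evo_config()
  p0 <- schedule_probabilities(0, cfg)
  expect_equal(p0[["p_cx"]], 0.2)
  expect_equal(p0[["p_mut"]], 0.8)
  pinf <- schedule_probabilities(20 * cfg$tau, cfg)
  expect_lt(abs(pinf[["p_cx"]] - 0.8), 1e-6)
  expect_lt(abs(pinf[["p_mut"]] - 0.2), 1e-6)
  ps <- t(sapply(0:30, function(g) schedule_probabilities(g, cfg)))
  expect_true(all(diff(ps[, "p_cx"]) > 0))
  expect_true(all(diff(ps[, "p_mut"]) < 0))
})

test_that("evo config enforces its invariants", {
  expect_error(evo_config(mu = 30, lambda = 20), "mu must equal lambda")
  expect_error(evo_config(p_cx_start = 0.9, p_cx_end = 0.2), "crossover")
  expect_error(evo_config(p_mut_start = 0.1, p_mut_end = 0.9), "mutation")
  expect_error(evo_config(stagnation_patience = 0), "patience")
})

test_that("crossover clones or exchanges genes, never invents values", {
  a <- list(x = 1, y = "u", z = 10L)
  b <- list(x = 2, y = "v", z = 20L)
  withr::with_seed(1, {
    expect_identical(crossover(a, b, 0), list(a, b))  # no crossover
    expect_identical(crossover(a, a, 1), list(a, a))  # identical parents
    for (i in 1:50) {
      kids <- crossover(a, b, 1)
      for (k in kids) for (nm in names(a))
        expect_true(identical(k[[nm]], a[[nm]]) ||
                      identical(k[[nm]], b[[nm]]))
    }
  })
})

test_that("mutation respects bounds, types and the zero-probability
          identity", {
  space <- new_search_space_for_tests()
  g <- list(cont = 5, logc = 1, int = 10L, cat = "a")
  withr::with_seed(2, {
    expect_identical(mutate(g, space, 0), g)
    for (i in 1:2000) {
      gm <- mutate(g, space, 1)
      expect_true(gm$cont >= 0 && gm$cont <= 10)
      expect_true(gm$logc >= 1e-3 && gm$logc <= 1e3)   # never <= 0
      expect_true(gm$int >= 1L && gm$int <= 50L && is.integer(gm$int))
      expect_true(gm$cat %in% c("a", "b", "c"))
      g <- gm  # random walk stays in bounds
    }
  })
})

test_that("mu+lambda selection is elitist truncation with stable ties", {
  mk <- function(f, id) list(genome = list(), fitness = f, id = id)
  parents <- lapply(1:30, function(i) mk(10 + i, i))
  offspring <- lapply(1:30, function(i) mk(5 + i, 30 + i))
  surv <- select_mu_plus_lambda(parents, offspring, 30)
  expect_length(surv, 30)
  expect_equal(surv[[1]]$fitness, 6)  # best survives
  worst_kept <- max(sapply(surv, `[[`, "fitness"))
  all_f <- c(sapply(parents, `[[`, "fitness"),
             sapply(offspring, `[[`, "fitness"))
  discarded <- sort(all_f, decreasing = TRUE)[1:30]
  expect_lte(worst_kept, min(discarded))
  # ties: earlier creation order wins
  tied <- select_mu_plus_lambda(list(mk(1, 5), mk(1, 2)), list(mk(1, 9)), 2)
  expect_equal(sapply(tied, `[[`, "id"), c(2, 5))
  expect_error(select_mu_plus_lambda(list(mk(NA, 1)), list(mk(1, 2)), 1),
               "evaluated")
})

test_that("the strategy optimizes a 1-D convex fitness across seeds", {
  space <- search_space(list(param_cont("x", 0, 10)))
  ok <- sapply(1:10, function(sd_) {
    res <- evolve(space, function(g) (g$x - 3)^2,
                  evo_config(seed = sd_))
    abs(res$best$genome$x - 3) < 0.1
  })
  expect_gte(sum(ok), 9)
})

test_that("fixed seed reproduces the full history bit for bit", {
  space <- search_space(list(param_cont("x", 0, 10)))
  r1 <- evolve(space, function(g) (g$x - 7)^2, evo_config(seed = 123,
                                                          max_generations = 8))
  r2 <- evolve(space, function(g) (g$x - 7)^2, evo_config(seed = 123,
                                                          max_generations = 8))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
})

test_that("best-so-far fitness never increases and evaluations stay within
          budget", {
  space <- search_space(list(param_cont("x", 0, 10)))
  evals <- 0L
  cfg <- evo_config(seed = 4)
  res <- evolve(space, function(g) { evals <<- evals + 1L; (g$x - 5)^2 },
                cfg)
  expect_true(all(diff(res$history$best_fitness) <= 0))
  expect_lte(evals, cfg$mu + cfg$lambda * cfg$max_generations)
})

test_that("non-finite fitness is demoted to worst, not fatal", {
  space <- search_space(list(param_cont("x", 0, 10)))
  res <- evolve(space, function(g) if (g$x < 5) NaN else (g$x - 7)^2,
                evo_config(seed = 6, max_generations = 10))
  expect_gt(res$n_nonfinite, 0)
  expect_true(is.finite(res$best$fitness))
  expect_gte(res$best$genome$x, 5)
})

test_that("evolution history serializes to JSON lines", {
  space <- search_space(list(param_cont("x", 0, 10)))
  res <- evolve(space, function(g) g$x, evo_config(seed = 1,
                                                   max_generations = 3))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_evo_history(res$history, path)
  lines <- readLines(path)
  expect_length(lines, nrow(res$history))
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$generation, 1)
  expect_equal(rec$pool_size, 60)
})
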