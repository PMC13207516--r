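# mu+lambda evolution strategy for hyperparameter search, with adaptive
# (saturating-exponential) crossover/mutation probability schedules and
# stagnation-based early stopping. Fitness is minimized (mean squared
# error in the tuning application).

#' Configuration of the mu+lambda evolution strategy
#'
#' `mu` parents produce `lambda` offspring per generation; the next `mu`
#' parents are the best of the combined pool (elitist truncation), so after
#' the first generation the working pool holds `mu + lambda` individuals
#' (60 at the defaults). Crossover probability rises and mutation
#' probability decays along saturating exponentials with timescale `tau`.
#' The run stops at `max_generations` or once the best fitness has stagnated
#' (no improvement beyond `1e-9`) for `stagnation_patience` successive
#' generations.
#'
#' @param mu Number of parents (default 30). Must equal `lambda`.
#' @param lambda Number of offspring per generation (default 30).
#' @param max_generations Generation cap (default 30).
#' @param stagnation_patience Successive stagnating generations triggering
#'   early stop (default 10).
#' @param p_cx_start,p_cx_end Crossover probability schedule endpoints
#'   (increasing; defaults 0.2 to 0.8).
#' @param p_mut_start,p_mut_end Mutation probability schedule endpoints
#'   (decaying; defaults 0.8 to 0.2).
#' @param tau Schedule timescale in generations (default 10).
#' @param seed Integer seed.
#' @return An `evo_config` list.
#' @export
evo_config <- function(mu = 30, lambda = 30, max_generations = 30,
                       stagnation_patience = 10,
                       p_cx_start = 0.2, p_cx_end = 0.8,
                       p_mut_start = 0.8, p_mut_end = 0.2,
                       tau = 10, seed = 1L) {
  if (mu != lambda) abort("mu must equal lambda (mu+lambda-ES as configured)")
  ps <- c(p_cx_start, p_cx_end, p_mut_start, p_mut_end)
  if (any(ps < 0 | ps > 1)) abort("probabilities must lie in [0, 1]")
  if (p_cx_start > p_cx_end) abort("crossover probability must not decay")
  if (p_mut_start < p_mut_end) abort("mutation probability must not grow")
  if (stagnation_patience < 1) abort("stagnation_patience must be >= 1")
  structure(list(mu = as.integer(mu), lambda = as.integer(lambda),
                 max_generations = as.integer(max_generations),
                 stagnation_patience = as.integer(stagnation_patience),
                 p_cx_start = p_cx_start, p_cx_end = p_cx_end,
                 p_mut_start = p_mut_start, p_mut_end = p_mut_end,
                 tau = tau, seed = as.integer(seed)),
            class = "evo_config")
}

#' Adaptive crossover/mutation probabilities at a generation
#'
#' `p_cx(g) = p_cx_end - (p_cx_end - p_cx_start) exp(-g / tau)` and the
#' mirrored decaying form for mutation: crossover rises and mutation decays
#' exponentially toward their end values.
#'
#' @param generation Generation index (>= 0).
#' @param cfg An [evo_config()].
#' @return Named numeric vector `c(p_cx, p_mut)`.
#' @export
schedule_probabilities <- function(generation, cfg) {
  stopifnot(generation >= 0)
  e <- exp(-generation / cfg$tau)
  c(p_cx = cfg$p_cx_end - (cfg$p_cx_end - cfg$p_cx_start) * e,
    p_mut = cfg$p_mut_end + (cfg$p_mut_start - cfg$p_mut_end) * e)
}

#' Draw a uniform-random genome from a search space
#' @param space A `search_space`.
#' @return Named list, one value per hyperparameter.
#' @export
random_genome <- function(space) {
  purrr::map(unclass(space), function(d) {
    switch(d$type,
           cont = if (d$log) exp(runif(1, log(d$lo), log(d$hi)))
                  else runif(1, d$lo, d$hi),
           int = sample(seq(d$lo, d$hi), 1),
           cat = d$values[[sample.int(length(d$values), 1)]])
  })
}

#' Uniform crossover of two genomes
#'
#' With probability `p_cx` the pair undergoes uniform per-gene exchange;
#' otherwise both offspring are exact clones. Every offspring gene comes
#' from one of the two parents, so bounds are preserved trivially.
#'
#' @param a,b Genomes (named lists over the same space).
#' @param p_cx Crossover probability.
#' @return List of two offspring genomes.
#' @export
crossover <- function(a, b, p_cx) {
  stopifnot(identical(names(a), names(b)))
  if (runif(1) >= p_cx) return(list(a, b))
  swap <- runif(length(a)) < 0.5
  o1 <- a; o2 <- b
  o1[swap] <- b[swap]
  o2[swap] <- a[swap]
  list(o1, o2)
}

#' Mutate a genome
#'
#' Each gene is independently perturbed with probability `p_mut`: continuous
#' genes take a Gaussian step with sd 10% of the domain width (in log space
#' for log-scaled domains), clipped to bounds; integer genes a rounded
#' Gaussian step; categorical genes a uniform resample. Log-scaled genes can
#' never leave the positive domain.
#'
#' @param genome Named list over `space`.
#' @param space The `search_space`.
#' @param p_mut Per-gene mutation probability.
#' @return Mutated genome.
#' @export
mutate <- function(genome, space, p_mut) {
  for (nm in names(genome)) {
    if (runif(1) >= p_mut) next
    d <- space[[nm]]
    genome[[nm]] <- switch(
      d$type,
      cont = if (d$log) {
        lo <- log(d$lo); hi <- log(d$hi)
        exp(min(max(log(genome[[nm]]) + rnorm(1, 0, 0.1 * (hi - lo)), lo),
                hi))
      } else {
        min(max(genome[[nm]] + rnorm(1, 0, 0.1 * (d$hi - d$lo)), d$lo),
            d$hi)
      },
      int = {
        step <- round(rnorm(1, 0, max(1, 0.1 * (d$hi - d$lo))))
        as.integer(min(max(genome[[nm]] + step, d$lo), d$hi))
      },
      cat = d$values[[sample.int(length(d$values), 1)]]
    )
  }
  genome
}

#' Elitist mu+lambda survivor selection
#'
#' Truncation selection of the `mu` best individuals (lowest fitness) from
#' the union of parents and offspring; ties broken by earlier creation
#' order. The best individual always survives.
#'
#' @param parents,offspring Lists of individuals (each a list with `genome`,
#'   `fitness`, `id`).
#' @param mu Number of survivors.
#' @return List of `mu` individuals.
#' @export
select_mu_plus_lambda <- function(parents, offspring, mu) {
  pool <- c(parents, offspring)
  fit <- vapply(pool, `[[`, 0.0, "fitness")
  if (anyNA(fit)) abort("all individuals must be evaluated before selection")
  ids <- vapply(pool, `[[`, 0.0, "id")
  pool[order(fit, ids)][seq_len(mu)]
}

#' Run the mu+lambda evolution strategy
#'
#' Initializes `mu` uniform-random genomes, then per generation applies the
#' probability schedule, produces `lambda` offspring by uniform crossover of
#' randomly paired parents followed by mutation, evaluates them, and selects
#' survivors elitistically. Non-finite fitness values are replaced by `Inf`
#' (worst) and counted. Stops on the generation cap or on
#' `stagnation_patience` successive generations without improvement of the
#' best fitness beyond `1e-9`.
#'
#' @param space A `search_space`.
#' @param fitness_fn Function `genome -> scalar fitness` (minimized).
#' @param cfg An [evo_config()].
#' @return List: `best` (list with `genome`, `fitness`), `history` (tibble
#'   with one row per generation, generation 0 = initialization: best and
#'   population fitness statistics, applied probabilities, pool size),
#'   `stop_reason` (`"stagnation"` or `"max_generations"`), and
#'   `n_nonfinite` (count of non-finite fitness evaluations).
#' @export
evolve <- function(space, fitness_fn, cfg = evo_config()) {
  withr::with_seed(cfg$seed, evolve_impl(space, fitness_fn, cfg))
}

evolve_impl <- function(space, fitness_fn, cfg) {
  n_nonfinite <- 0L
  id_counter <- 0L
  evaluate <- function(ind) {
    f <- tryCatch(fitness_fn(ind$genome), error = function(e) NA_real_)
    if (!is.finite(f)) {
      n_nonfinite <<- n_nonfinite + 1L
      f <- Inf
    }
    ind$fitness <- f
    ind
  }
  new_ind <- function(genome) {
    id_counter <<- id_counter + 1L
    list(genome = genome, fitness = NA_real_, id = id_counter)
  }

  parents <- purrr::map(seq_len(cfg$mu), function(i)
    evaluate(new_ind(random_genome(space))))
  pf <- vapply(parents, `[[`, 0.0, "fitness")
  best <- parents[[which.min(pf)]]
  hist_rows <- list(tibble::tibble(
    generation = 0L, best_fitness = best$fitness,
    mean_fitness = mean(pf[is.finite(pf)]),
    sd_fitness = sd(pf[is.finite(pf)]),
    p_cx = NA_real_, p_mut = NA_real_, pool_size = length(parents)
  ))

  stall <- 0L
  stop_reason <- "max_generations"
  for (g in seq_len(cfg$max_generations)) {
    pr <- schedule_probabilities(g, cfg)
    pairing <- sample.int(cfg$mu)
    offspring <- list()
    i <- 1L
    while (length(offspring) < cfg$lambda) {
      a <- parents[[pairing[(i - 1L) %% cfg$mu + 1L]]]$genome
      b <- parents[[pairing[i %% cfg$mu + 1L]]]$genome
      kids <- crossover(a, b, pr[["p_cx"]])
      for (k in kids) {
        if (length(offspring) >= cfg$lambda) break
        offspring[[length(offspring) + 1L]] <-
          new_ind(mutate(k, space, pr[["p_mut"]]))
      }
      i <- i + 2L
    }
    offspring <- purrr::map(offspring, evaluate)
    pool_size <- length(parents) + length(offspring)
    parents <- select_mu_plus_lambda(parents, offspring, cfg$mu)
    pf <- vapply(parents, `[[`, 0.0, "fitness")
    gen_best <- parents[[1L]]
    improved <- gen_best$fitness < best$fitness - 1e-9
    if (improved) {
      best <- gen_best
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    hist_rows[[length(hist_rows) + 1L]] <- tibble::tibble(
      generation = g, best_fitness = best$fitness,
      mean_fitness = mean(pf[is.finite(pf)]),
      sd_fitness = sd(pf[is.finite(pf)]),
      p_cx = pr[["p_cx"]], p_mut = pr[["p_mut"]], pool_size = pool_size
    )
    if (stall >= cfg$stagnation_patience) {
      stop_reason <- "stagnation"
      break
    }
  }
  list(best = best[c("genome", "fitness")],
       history = dplyr::bind_rows(hist_rows),
       stop_reason = stop_reason, n_nonfinite = n_nonfinite)
}

#' Write an evolution history as JSON lines
#' @param history History tibble from [evolve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_evo_history <- function(history, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(history)))
    writeLines(jsonlite::toJSON(as.list(history[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}
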