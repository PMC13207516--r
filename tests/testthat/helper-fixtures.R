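# Shared fixtures, built in code. Kept small: the heavy configurations live
# only in the tests that need them.

fix_mesh <- function(radius = 1.5, length = 20, n_axial = 10, n_circ = 16) {
  make_tube_mesh(radius, length, n_axial, n_circ)
}

fix_fluid <- function() fluid_properties(density = 1060, viscosity = 0.0035)

# small steady Poiseuille bundle reused across hemo tests
fix_poiseuille <- function(Q = 500, n_r = 16, n_theta = 16, n_z = 6) {
  poiseuille_fields(fix_mesh(), Q, fix_fluid(), n_steps = 1,
                    n_r = n_r, n_theta = n_theta, n_z = n_z)
}

# random small regression problem with named features
fix_xy <- function(n = 80, p = 5, seed = 1, nonlinear = FALSE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    beta <- seq_len(p) - p / 2
    y <- drop(X %*% beta)
    if (nonlinear) y <- y + 2 * sin(X[, 1]) * X[, 2]
    y <- y + rnorm(n, 0, 0.1)
    list(X = tibble::as_tibble(X), y = y)
  })
}

# tiny evolution config for fast search tests
fix_evo_cfg <- function(max_generations = 5, ...) {
  evo_config(mu = 6, lambda = 6, max_generations = max_generations, ...)
}

# mixed-type search space exercising all three domain kinds
new_search_space_for_tests <- function() {
  search_space(list(
    param_cont("cont", 0, 10),
    param_cont("logc", 1e-3, 1e3, log = TRUE),
    param_int("int", 1, 50),
    param_cat("cat", c("a", "b", "c"))
  ))
}

# scaled-down gradient-boosting search box used by runtime-bounded CV tests
fix_gb_space <- function() {
  s <- default_space("gradient_boosting")
  s$n_trees$lo <- 30L
  s$n_trees$hi <- 120L
  s$max_depth$hi <- 6L
  s
}
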