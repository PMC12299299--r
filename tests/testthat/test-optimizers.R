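sphere <- function(v) sum(v^2)

test_that("config validation", {
  expect_error(optimizer_config(pop = 1), "population")
  expect_error(optimizer_config(iters = 0), "iters")
  expect_error(optimizer_config(bounds = c(3, -3)), "bounds")
})

test_that("the WOA decay coefficient is exactly linear from 2 to 0", {
  t_max <- 50
  a <- uriquant:::woa_a(0:t_max, t_max)
  expect_identical(a[1], 2)
  expect_identical(a[t_max + 1], 0)
  expect_equal(diff(a), rep(-2 / t_max, t_max))
})

test_that("WOA update algebra: encircling with A = 0 lands on the best", {
  # X <- X* - A |C X* - X| with A = 0 collapses to X* regardless of C
  best <- c(1, -2); X <- c(5, 5); A <- 0; C <- 1
  expect_identical(best - A * abs(C * best - X), best)
  # spiral at D' = 0 stays at X* for any l
  l <- 0.37
  expect_identical(0 * exp(l) * cos(2 * pi * l) + best, best)
})

test_that("WOA solves the 5-D sphere across seeds", {
  for (s in 1:3) {
    run <- woa_optimize(sphere, 5,
                        optimizer_config(pop = 30, iters = 200, seed = s))
    expect_lt(run$best_fitness, 1e-2)
    expect_false(is.unsorted(-run$history))      # monotone non-increasing
    expect_true(all(run$best >= -3 & run$best <= 3))
    expect_equal(length(run$history), 200)
  }
})

test_that("optimizer runs are reproducible by seed", {
  cfg <- optimizer_config(pop = 12, iters = 30, seed = 5)
  expect_identical(woa_optimize(sphere, 4, cfg)$history,
                   woa_optimize(sphere, 4, cfg)$history)
  expect_identical(pso_optimize(sphere, 4, cfg)$history,
                   pso_optimize(sphere, 4, cfg)$history)
  expect_identical(ga_optimize(sphere, 4, cfg)$history,
                   ga_optimize(sphere, 4, cfg)$history)
})

test_that("PSO solves the sphere and freezes when all coefficients are zero", {
  run <- pso_optimize(sphere, 5, optimizer_config(pop = 30, iters = 200,
                                                  seed = 1))
  expect_lt(run$best_fitness, 1e-2)
  expect_false(is.unsorted(-run$history))
  frozen <- pso_optimize(sphere, 3,
                         optimizer_config(pop = 8, iters = 20, seed = 2),
                         inertia = 0, cognitive = 0, social = 0)
  expect_true(all(frozen$history == frozen$history[1]))
})

test_that("GA solves the sphere; zero-rate GA with elitism is constant", {
  run <- ga_optimize(sphere, 5, optimizer_config(pop = 30, iters = 200,
                                                 seed = 1))
  expect_lt(run$best_fitness, 1e-1)
  expect_false(is.unsorted(-run$history))
  still <- ga_optimize(sphere, 3,
                       optimizer_config(pop = 10, iters = 25, seed = 3),
                       crossover_rate = 0, mutation_rate = 0)
  expect_true(all(diff(still$history) <= 0))
  expect_true(all(still$history >= still$best_fitness))
})

test_that("all three respect the box bounds on a minimum outside the box", {
  # minimum at (10, 10) lies outside [-3, 3]^2: solutions must stay clipped
  shifted <- function(v) sum((v - 10)^2)
  for (fn in list(woa_optimize, pso_optimize, ga_optimize)) {
    run <- fn(shifted, 2, optimizer_config(pop = 15, iters = 60, seed = 4))
    expect_true(all(run$best >= -3 & run$best <= 3))
  }
})

test_that("WOA converges to a 1-D convex quadratic minimum", {
  quad <- function(v) (v - 1.25)^2 + 0.5
  run <- woa_optimize(quad, 1, optimizer_config(pop = 20, iters = 400,
                                                seed = 11))
  expect_lt(abs(run$best - 1.25), 1e-3)
})

test_that("non-finite fitness aborts with the offending vector", {
  bad <- function(v) if (v[1] > 0) NaN else sum(v^2)
  expect_error(woa_optimize(bad, 2, optimizer_config(pop = 10, iters = 10,
                                                     seed = 1)),
               "non-finite fitness")
})

test_that("runs serialize to JSON with their history", {
  run <- woa_optimize(sphere, 3, optimizer_config(pop = 10, iters = 15,
                                                  seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_optimizer_run(run, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$history, run$history)
  expect_equal(obj$best_fitness, run$best_fitness)
})
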