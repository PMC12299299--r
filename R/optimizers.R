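# Population metaheuristics over flat real vectors: the whale optimization
# algorithm (WOA) plus particle swarm (PSO) and real-coded genetic algorithm
# (GA) baselines. All three minimize a user-supplied fitness function inside a
# box, are fully seeded, clip to the bounds after every move, and report the
# best-so-far fitness history.
#
# WOA mimics humpback bubble-net feeding. Each whale i holds a position X_i;
# with X* the best position so far, one iteration updates every whale by one
# of three moves, chosen by random draws p (uniform [0,1]) and the coefficient
# A = 2 a r - a (r uniform [0,1], a decaying linearly from 2 to 0):
#   encircling (p < 0.5, |A| < 1):  D = |C X* - X|,      X <- X* - A D
#   searching  (p < 0.5, |A| >= 1): D = |C X_rand - X|,  X <- X_rand - A D
#   spiral     (p >= 0.5):          D' = |X* - X|,       X <- D' e^(b l) cos(2 pi l) + X*
# with C = 2 r, l uniform [-1,1], b the spiral-shape constant, and X_rand a
# randomly chosen whale. r, A, C, p, l are scalar per whale per iteration.

#' Optimizer configuration
#'
#' Shared configuration for [woa_optimize()], [pso_optimize()] and
#' [ga_optimize()].
#'
#' @param pop population size (>= 2); default 30.
#' @param iters maximum iterations / generations T_max (>= 1); default 50.
#' @param bounds length-2 vector `c(lower, upper)` applied to every
#'   dimension, or a 2 x dim matrix; default c(-3, 3).
#' @param b WOA spiral-shape constant; default 1.
#' @param seed integer RNG seed.
#' @return a list of class `optimizer_config`.
#' @export
optimizer_config <- function(pop = 30, iters = 50, bounds = c(-3, 3),
                             b = 1, seed = 1) {
  pop <- as.integer(pop); iters <- as.integer(iters)
  if (pop < 2L) stop("population must be >= 2", call. = FALSE)
  if (iters < 1L) stop("iters must be >= 1", call. = FALSE)
  if (is.null(dim(bounds))) {
    if (length(bounds) != 2L || bounds[1] >= bounds[2])
      stop("bounds must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  structure(list(pop = pop, iters = iters, bounds = bounds, b = b,
                 seed = seed),
            class = "optimizer_config")
}

# Linearly decaying WOA coefficient: 2 at t = 0, 0 at t = T_max.
woa_a <- function(t, t_max) 2 * (1 - t / t_max)

.expand_bounds <- function(bounds, dim) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, 2, dim)
  if (ncol(bounds) != dim) stop("bounds/dim mismatch", call. = FALSE)
  bounds
}

.clip_box <- function(X, lo, hi) {
  pmin(pmax(X, matrix(lo, nrow(X), ncol(X), byrow = TRUE)),
       matrix(hi, nrow(X), ncol(X), byrow = TRUE))
}

.eval_pop <- function(fitness, X) {
  f <- apply(X, 1, fitness)
  bad <- which(!is.finite(f))
  if (length(bad) > 0)
    stop("non-finite fitness at vector [",
         paste(signif(X[bad[1], ], 4), collapse = ", "), "]", call. = FALSE)
  f
}

.finish_run <- function(algorithm, best_x, best_f, history, n_eval, config) {
  structure(list(algorithm = algorithm, best = best_x, best_fitness = best_f,
                 history = history, n_eval = n_eval, seed = config$seed,
                 config = config),
            class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf("%s run: best fitness %.6g after %d iterations (%d evaluations)\n",
              toupper(x$algorithm), x$best_fitness, length(x$history),
              x$n_eval))
  invisible(x)
}

#' Whale Optimization Algorithm
#'
#' Minimizes `fitness` over a `dim`-dimensional box. Per iteration and whale,
#' a scalar r in \[0,1\] yields A = 2 a r - a and C = 2 r (with a decaying
#' linearly from 2 to 0); a scalar p in \[0,1\] selects between encircling the
#' best position (p < 0.5, |A| < 1), searching around a random whale
#' (p < 0.5, |A| >= 1), and the logarithmic spiral move toward the best
#' (p >= 0.5) with l uniform in \[-1,1\]. Positions are clipped to the bounds
#' and the best position is updated after each full sweep.
#'
#' @param fitness function mapping a numeric vector of length `dim` to a
#'   finite scalar to be minimized.
#' @param dim problem dimension (>= 1).
#' @param config an [optimizer_config()].
#' @return an `optimizer_run`: list with `best` (vector), `best_fitness`,
#'   `history` (best-so-far fitness after each iteration, monotone
#'   non-increasing), `n_eval` and the seed/config.
#' @export
woa_optimize <- function(fitness, dim, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"), dim >= 1)
  bd <- .expand_bounds(config$bounds, dim)
  lo <- bd[1, ]; hi <- bd[2, ]
  with_seed(config$seed, {
    n <- config$pop
    X <- matrix(stats::runif(n * dim, rep(lo, each = n), rep(hi, each = n)),
                n, dim)
    f <- .eval_pop(fitness, X)
    n_eval <- n
    best_i <- which.min(f)
    best_x <- X[best_i, ]; best_f <- f[best_i]
    history <- numeric(config$iters)
    for (t in seq_len(config$iters) - 1L) {
      a <- woa_a(t, config$iters)
      for (i in seq_len(n)) {
        r <- stats::runif(1)
        A <- 2 * a * r - a
        C <- 2 * r
        p <- stats::runif(1)
        if (p < 0.5) {
          if (abs(A) < 1) {                  # encircling the prey
            D <- abs(C * best_x - X[i, ])
            X[i, ] <- best_x - A * D
          } else {                           # searching for prey
            j <- sample.int(n, 1)
            D <- abs(C * X[j, ] - X[i, ])
            X[i, ] <- X[j, ] - A * D
          }
        } else {                             # bubble-net spiral
          l <- stats::runif(1, -1, 1)
          Dp <- abs(best_x - X[i, ])
          X[i, ] <- Dp * exp(config$b * l) * cos(2 * pi * l) + best_x
        }
      }
      X <- .clip_box(X, lo, hi)
      f <- .eval_pop(fitness, X)
      n_eval <- n_eval + n
      it_best <- which.min(f)
      if (f[it_best] < best_f) {
        best_f <- f[it_best]; best_x <- X[it_best, ]
      }
      history[t + 1L] <- best_f
    }
    .finish_run("woa", best_x, best_f, history, n_eval, config)
  })
}

#' Particle swarm optimization (baseline)
#'
#' Standard global-best PSO with constriction-style constants: inertia 0.72,
#' cognitive and social coefficients 1.49. Velocities start at zero;
#' positions are clipped to the bounds.
#'
#' @inheritParams woa_optimize
#' @param inertia,cognitive,social PSO coefficients.
#' @return an `optimizer_run`.
#' @export
pso_optimize <- function(fitness, dim, config = optimizer_config(),
                         inertia = 0.72, cognitive = 1.49, social = 1.49) {
  stopifnot(inherits(config, "optimizer_config"), dim >= 1)
  bd <- .expand_bounds(config$bounds, dim)
  lo <- bd[1, ]; hi <- bd[2, ]
  with_seed(config$seed, {
    n <- config$pop
    X <- matrix(stats::runif(n * dim, rep(lo, each = n), rep(hi, each = n)),
                n, dim)
    V <- matrix(0, n, dim)
    f <- .eval_pop(fitness, X)
    n_eval <- n
    P <- X; pf <- f                       # personal bests
    g <- which.min(pf)
    best_x <- P[g, ]; best_f <- pf[g]
    history <- numeric(config$iters)
    for (t in seq_len(config$iters)) {
      r1 <- matrix(stats::runif(n * dim), n, dim)
      r2 <- matrix(stats::runif(n * dim), n, dim)
      V <- inertia * V + cognitive * r1 * (P - X) +
        social * r2 * matrix(best_x, n, dim, byrow = TRUE) - social * r2 * X
      X <- .clip_box(X + V, lo, hi)
      f <- .eval_pop(fitness, X)
      n_eval <- n_eval + n
      improved <- f < pf
      P[improved, ] <- X[improved, ]; pf[improved] <- f[improved]
      g <- which.min(pf)
      if (pf[g] < best_f) { best_f <- pf[g]; best_x <- P[g, ] }
      history[t] <- best_f
    }
    .finish_run("pso", best_x, best_f, history, n_eval, config)
  })
}

#' Real-coded genetic algorithm (baseline)
#'
#' Tournament selection (k = 3), blend (BLX-alpha) crossover with
#' alpha = 0.5 at rate 0.9, per-gene Gaussian mutation with sigma = 5% of the
#' box range at rate 0.1, and one-elite survival.
#'
#' @inheritParams woa_optimize
#' @param crossover_rate,mutation_rate,alpha,tournament_k GA operators.
#' @return an `optimizer_run`.
#' @export
ga_optimize <- function(fitness, dim, config = optimizer_config(),
                        crossover_rate = 0.9, mutation_rate = 0.1,
                        alpha = 0.5, tournament_k = 3) {
  stopifnot(inherits(config, "optimizer_config"), dim >= 1)
  bd <- .expand_bounds(config$bounds, dim)
  lo <- bd[1, ]; hi <- bd[2, ]
  sig <- 0.05 * (hi - lo)
  with_seed(config$seed, {
    n <- config$pop
    X <- matrix(stats::runif(n * dim, rep(lo, each = n), rep(hi, each = n)),
                n, dim)
    f <- .eval_pop(fitness, X)
    n_eval <- n
    g <- which.min(f)
    best_x <- X[g, ]; best_f <- f[g]
    history <- numeric(config$iters)
    tournament <- function() {
      cand <- sample.int(n, tournament_k)
      cand[which.min(f[cand])]
    }
    for (t in seq_len(config$iters)) {
      child <- matrix(0, n, dim)
      child[1, ] <- best_x                       # elitism
      i <- 2L
      while (i <= n) {
        p1 <- X[tournament(), ]; p2 <- X[tournament(), ]
        if (stats::runif(1) < crossover_rate) {
          cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
          d <- cmax - cmin
          c1 <- stats::runif(dim, cmin - alpha * d, cmax + alpha * d)
          c2 <- stats::runif(dim, cmin - alpha * d, cmax + alpha * d)
        } else { c1 <- p1; c2 <- p2 }
        child[i, ] <- c1
        if (i + 1L <= n) child[i + 1L, ] <- c2
        i <- i + 2L
      }
      mut <- matrix(stats::runif(n * dim) < mutation_rate, n, dim)
      mut[1, ] <- FALSE                          # never mutate the elite
      noise <- matrix(stats::rnorm(n * dim, sd = rep(sig, each = n)), n, dim)
      child <- child + mut * noise
      X <- .clip_box(child, lo, hi)
      f <- .eval_pop(fitness, X)
      n_eval <- n_eval + n
      g <- which.min(f)
      if (f[g] < best_f) { best_f <- f[g]; best_x <- X[g, ] }
      history[t] <- best_f
    }
    .finish_run("ga", best_x, best_f, history, n_eval, config)
  })
}

#' Read an optimizer configuration from YAML
#'
#' Any subset of the [optimizer_config()] arguments may appear as top-level
#' keys; the rest keep their defaults.
#'
#' @param path YAML file path.
#' @return an `optimizer_config`.
#' @export
read_optimizer_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(optimizer_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(vals$bounds)) vals$bounds <- as.numeric(vals$bounds)
  do.call(optimizer_config, vals)
}

#' Export an optimizer run as JSON
#'
#' Writes the algorithm name, seed, best vector, best fitness and the
#' best-so-far history (suitable for plotting fitness iteration curves).
#'
#' @param run an `optimizer_run`; @param path file path.
#' @export
write_optimizer_run <- function(run, path) {
  stopifnot(inherits(run, "optimizer_run"))
  jsonlite::write_json(list(algorithm = run$algorithm, seed = run$seed,
                            best = run$best, best_fitness = run$best_fitness,
                            history = run$history, n_eval = run$n_eval),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
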