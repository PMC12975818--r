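#' Covariance-matrix-adaptation evolution strategy (minimization)
#'
#' Standard (mu/mu_w, lambda)-CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation. Box constraints are handled
#' by evaluating each candidate at its projection onto the box (the search
#' distribution itself is unconstrained). Derivative-free, suited to the
#' noisy, non-differentiable fitness of the neural agent.
#'
#' @param par numeric start vector (distribution mean).
#' @param fn objective to minimize; called with one numeric vector (already
#'   projected into the box).
#' @param lower,upper box bounds, recycled to `length(par)`.
#' @param sigma initial global step size, as a fraction of the box width
#'   per coordinate is often sensible; this is an absolute scalar applied
#'   to coordinates scaled by `scale` (default: 0.3 of the box width).
#' @param lambda population size (default `4 + floor(3 * log(n))`).
#' @param maxgen maximum number of generations.
#' @param tol stop early when the best objective improves by less than
#'   `tol` over 30 consecutive generations (0 disables).
#' @return list with `par` (best-ever projected solution), `value`
#'   (its objective), `trace` (per-generation data.frame: `generation`,
#'   `best`, `mean`, `p16`, `p84` of the population objective) and
#'   `converged` (logical: stopped before `maxgen`).
#' @export
cma_es <- function(par, fn, lower, upper, sigma = NULL, lambda = NULL,
                   maxgen = 100, tol = 0) {
  n <- length(par)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  scale <- upper - lower
  if (is.null(sigma)) sigma <- 0.3
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  # work in box-scaled coordinates so one sigma fits all parameters
  xmean <- (par - lower) / scale
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n)
  eigen_stale <- 0

  best_val <- Inf; best_x <- par
  trace <- vector("list", maxgen)
  stall <- 0; prev_best <- Inf

  for (g in seq_len(maxgen)) {
    arz <- matrix(stats::rnorm(n * lambda), nrow = n)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    fitness <- numeric(lambda)
    for (i in seq_len(lambda)) {
      x_nat <- pmin(pmax(lower + scale * arx[, i], lower), upper)
      fitness[i] <- fn(x_nat)
    }
    ord <- order(fitness)
    sel <- ord[seq_len(mu)]

    if (fitness[ord[1]] < best_val) {
      best_val <- fitness[ord[1]]
      best_x <- pmin(pmax(lower + scale * arx[, ord[1]], lower), upper)
    }

    zmean <- drop(arz[, sel, drop = FALSE] %*% w)
    ymean <- drop(ary[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(B %*% zmean)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean

    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / (c1 + cmu) / n / 10))) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eig$values, .Machine$double.eps))
      B <- eig$vectors
    }

    trace[[g]] <- data.frame(
      generation = g, best = fitness[ord[1]], mean = mean(fitness),
      p16 = unname(stats::quantile(fitness, 0.16)),
      p84 = unname(stats::quantile(fitness, 0.84)))

    if (tol > 0) {
      if (prev_best - best_val < tol) stall <- stall + 1 else stall <- 0
      prev_best <- best_val
      if (stall >= 30) {
        return(list(par = best_x, value = best_val,
                    trace = do.call(rbind, trace[seq_len(g)]),
                    converged = TRUE))
      }
    }
  }
  list(par = best_x, value = best_val, trace = do.call(rbind, trace),
       converged = FALSE)
}

#' Evolution configuration for the agent genome
#'
#' @param population_size individuals per generation (>= 2; the benchmark
#'   scale is 256).
#' @param generations generation count (benchmark scale 80).
#' @param fitness_envs character vector of environment variants entering
#'   the fitness (default the abrupt, gradual and oscillatory drifts).
#' @param k_values arm counts evaluated per environment (benchmark scale
#'   `c(40, 200)`).
#' @param iterations_per_env repetitions per environment x K cell.
#' @param rounds_per_trial,n_trials episode shape inside the fitness.
#' @param seed master seed; fitness episodes use seeds derived from it and
#'   shared across individuals (common random numbers), so fitness is
#'   deterministic given the genome.
#' @param sigma0 initial CMA-ES step size (box-scaled coordinates).
#' @return a list of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 16, generations = 20,
                             fitness_envs = c("mab-p", "mab-d", "mab-sin"),
                             k_values = c(40, 200), iterations_per_env = 2,
                             rounds_per_trial = 2000, n_trials = 2,
                             seed = 1, sigma0 = 0.15) {
  if (population_size < 2 || generations < 1) {
    stop("need `population_size` >= 2 and `generations` >= 1", call. = FALSE)
  }
  structure(list(population_size = population_size, generations = generations,
                 fitness_envs = fitness_envs, k_values = k_values,
                 iterations_per_env = iterations_per_env,
                 rounds_per_trial = rounds_per_trial, n_trials = n_trials,
                 seed = seed, sigma0 = sigma0),
            class = "evolution_config")
}

#' Fitness of a genome: average collected reward
#'
#' Runs one episode per (environment variant x arm count x iteration) cell
#' and returns the grand mean of the per-round rewards. Episode seeds are
#' derived from the configuration seed only, so all genomes are evaluated
#' on identical reward-probability trajectories (common random numbers) and
#' the fitness is deterministic in the genome. Genomes outside the bounds
#' of [genome_bounds()] are evaluated at their projection onto the box.
#'
#' @param genome an [nsa_genome()] or a 22-vector.
#' @param config an [evolution_config()].
#' @return scalar mean reward in \[0, 1\].
#' @export
nsa_fitness <- function(genome, config) {
  if (!inherits(genome, "nsa_genome")) {
    b <- genome_bounds()
    genome <- genome_from_vector(pmin(pmax(as.numeric(genome), b$lower),
                                      b$upper))
  }
  total <- 0; cells <- 0
  for (ei in seq_along(config$fitness_envs)) {
    for (ki in seq_along(config$k_values)) {
      for (it in seq_len(config$iterations_per_env)) {
        seed <- derive_seed(config$seed, "evolution",
                            ei * 10000L + ki * 100L + it)
        set.seed(seed)
        env <- bandit_env(config$fitness_envs[ei], K = config$k_values[ki],
                          rounds_per_trial = config$rounds_per_trial,
                          n_trials = config$n_trials)
        log <- nsa_episode(genome, env)
        total <- total + mean(log$R)
        cells <- cells + 1
      }
    }
  }
  total / cells
}

#' Evolve the agent genome by CMA-ES
#'
#' Maximizes [nsa_fitness()] over the 22-parameter box of
#' [genome_bounds()]. The returned report carries per-generation best,
#' mean and 16-84 percentile band of the population fitness
#' (maximization scale).
#'
#' @param config an [evolution_config()].
#' @param x0 starting genome (an [nsa_genome()] or 22-vector); defaults to
#'   the box midpoint.
#' @return list with `genome` (best-ever [nsa_genome()]), `fitness` (its
#'   mean reward) and `report` (per-generation data.frame with columns
#'   `generation`, `best`, `mean`, `p16`, `p84`).
#' @export
evolve_genome <- function(config, x0 = NULL) {
  b <- genome_bounds()
  if (is.null(x0)) {
    x0 <- (b$lower + b$upper) / 2
  } else if (inherits(x0, "nsa_genome")) {
    x0 <- genome_to_vector(x0)
  }
  set.seed(derive_seed(config$seed, "evolution", 0L))
  res <- cma_es(as.numeric(x0), function(x) -nsa_fitness(x, config),
                lower = b$lower, upper = b$upper,
                sigma = config$sigma0, lambda = config$population_size,
                maxgen = config$generations)
  report <- res$trace
  # back to maximization scale; percentile band must stay ordered
  report <- data.frame(generation = report$generation,
                       best = -report$best, mean = -report$mean,
                       p16 = -report$p84, p84 = -report$p16)
  list(genome = genome_from_vector(res$par), fitness = -res$value,
       report = report)
}
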