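.seed_streams <- c(environment = 0L, nsa = 1L, ts = 2L, ucb1 = 3L,
                   egreedy = 4L, random = 5L, oracle = 6L, evolution = 7L,
                   analysis = 8L)

#' Derive a child seed from a master seed
#'
#' Deterministic, collision-free derivation of per-stream, per-index seeds
#' from one master seed: a fixed linear map modulo the Mersenne prime
#' 2^31 - 1. Distinct (stream, index) pairs map to distinct seeds for all
#' indices below 100003, so every simulation and every algorithm gets its
#' own reproducible stream while the environment stream is shared across
#' algorithms within a simulation index.
#'
#' @param master_seed integer master seed.
#' @param stream stream name (one of `"environment"`, `"nsa"`, `"ts"`,
#'   `"ucb1"`, `"egreedy"`, `"random"`, `"oracle"`, `"evolution"`,
#'   `"analysis"`) or a small non-negative integer.
#' @param index non-negative integer (e.g. simulation index).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, stream, index) {
  m <- 2147483647
  sid <- if (is.character(stream)) {
    if (!stream %in% names(.seed_streams)) {
      stop("unknown seed stream: ", stream, call. = FALSE)
    }
    .seed_streams[[stream]]
  } else {
    as.integer(stream)
  }
  s <- ((master_seed %% m) * 48271 + sid * 100003 + index) %% m
  as.integer(if (s == 0) m - 1 else s)
}

#' Experiment configuration
#'
#' Bundles the benchmark protocol: one environment variant, a set of
#' algorithms, the episode shape (trials x rounds) and the number of
#' independent simulations. Per-simulation and per-algorithm seeds are
#' derived deterministically from `seed`; within a simulation index all
#' algorithms face the identical reward-probability trajectory and reward
#' draws (paired environments), unless `paired = FALSE`, in which case each
#' algorithm gets independently drawn environments.
#'
#' @param variant environment variant, see [bandit_env()].
#' @param K number of arms.
#' @param algorithms character vector among `"nsa"`, `"ts"`, `"ucb1"`,
#'   `"egreedy"`, `"random"`, `"oracle"`.
#' @param n_trials,rounds_per_trial episode shape (benchmark: 2 x 2000).
#' @param n_simulations independent repetitions (benchmark: 64).
#' @param seed master seed.
#' @param genome an [nsa_genome()] for the `"nsa"` algorithm (default
#'   [default_genome()]).
#' @param paired share environment draws across algorithms within a
#'   simulation index (default TRUE).
#' @param keep_choices retain the per-round chosen arms for entropy
#'   analysis (default FALSE).
#' @param tau_p,delta,freq_range variant parameters, see [bandit_env()].
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(variant, K, algorithms = c("ts", "ucb1",
                                                         "egreedy", "random"),
                              n_trials = 2, rounds_per_trial = 2000,
                              n_simulations = 64, seed = 1, genome = NULL,
                              paired = TRUE, keep_choices = FALSE,
                              tau_p = 200, delta = 0.05,
                              freq_range = c(1 / 4000, 1 / 500)) {
  if (n_simulations < 1) stop("`n_simulations` must be >= 1", call. = FALSE)
  unknown <- setdiff(algorithms, names(.seed_streams))
  if (length(unknown)) {
    stop("unknown algorithm(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(variant = variant, K = as.integer(K),
                 algorithms = algorithms, n_trials = n_trials,
                 rounds_per_trial = rounds_per_trial,
                 n_simulations = n_simulations, seed = seed, genome = genome,
                 paired = paired, keep_choices = keep_choices,
                 tau_p = tau_p, delta = delta, freq_range = freq_range),
            class = "experiment_config")
}

# One episode of `algorithm` against a pre-materialized trajectory P with
# shared reward uniforms u. Selection randomness comes from the caller's
# RNG state; rewards are paired across algorithms through u.
run_episode <- function(algorithm, P, u, genome = NULL, dt = 1) {
  n <- nrow(P); K <- ncol(P)
  agent <- bandit_agent(algorithm, K, genome = genome, dt = dt)
  k <- integer(n); R <- integer(n); agreed <- rep(NA, n)
  for (r in seq_len(n)) {
    sel <- agent_select(agent, p_true = P[r, ])
    k[r] <- sel
    a <- attr(sel, "agreed")
    if (!is.null(a)) agreed[r] <- a
    R[r] <- as.integer(u[r] < P[r, k[r]])
    agent <- agent_observe(agent, k[r], R[r])
  }
  p_star <- do.call(pmax, as.data.frame(P))
  data.frame(t = seq_len(n), k = k, R = R, p_star = p_star,
             p_chosen = P[cbind(seq_len(n), k)], agreed = agreed)
}

#' Run the benchmark protocol
#'
#' For every algorithm and simulation index: a fresh agent and a fresh
#' environment from deterministically derived seeds, one full episode, and
#' the per-simulation pseudo-regret. Results are aggregated into mean
#' regrets and, when at least two algorithms ran, a Welch/Bonferroni
#' comparison table against the neural agent (or the first algorithm).
#' Re-running with an identical configuration is bit-identical.
#'
#' @param config an [experiment_config()].
#' @return object of class `bandit_experiment`: list with `config`,
#'   `regret` (matrix simulations x algorithms), `summary` (data.frame of
#'   mean/sd regret per algorithm), `comparison` (or NULL), and `choices`
#'   (per-algorithm list of simulations x rounds matrices when
#'   `keep_choices`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n_sims <- config$n_simulations
  n_rounds <- config$n_trials * config$rounds_per_trial
  algos <- config$algorithms
  reg <- matrix(NA_real_, nrow = n_sims, ncol = length(algos),
                dimnames = list(NULL, algos))
  choices <- if (config$keep_choices) {
    stats::setNames(lapply(algos, function(a)
      matrix(NA_integer_, n_sims, n_rounds)), algos)
  }
  genome <- config$genome
  if ("nsa" %in% algos && is.null(genome)) genome <- default_genome()

  make_env <- function(seed) {
    bandit_env(config$variant, K = config$K,
               rounds_per_trial = config$rounds_per_trial,
               n_trials = config$n_trials, tau_p = config$tau_p,
               delta = config$delta, freq_range = config$freq_range,
               seed = seed)
  }

  for (sim in seq_len(n_sims)) {
    P <- NULL; u <- NULL
    if (config$paired) {
      set.seed(derive_seed(config$seed, "environment", sim))
      P <- env_trajectory(make_env(seed = NULL))
      u <- stats::runif(n_rounds)
    }
    for (a in algos) {
      if (!config$paired) {
        # independent environment per algorithm: fold the algorithm stream
        # into the environment seed
        set.seed(derive_seed(config$seed, "environment",
                             sim * 10L + .seed_streams[[a]]))
        P <- env_trajectory(make_env(seed = NULL))
        u <- stats::runif(n_rounds)
      }
      set.seed(derive_seed(config$seed, a, sim))
      log <- run_episode(a, P, u, genome = genome)
      reg[sim, a] <- regret(log)
      if (config$keep_choices) choices[[a]][sim, ] <- log$k
    }
  }

  summary <- data.frame(algorithm = algos,
                        mean_regret = colMeans(reg),
                        sd_regret = apply(reg, 2, stats::sd),
                        row.names = NULL)
  comparison <- if (length(algos) >= 2) {
    compare_algorithms(lapply(stats::setNames(algos, algos),
                              function(a) reg[, a]))
  }
  structure(list(config = config, regret = reg, summary = summary,
                 comparison = comparison, choices = choices),
            class = "bandit_experiment")
}

#' @export
print.bandit_experiment <- function(x, ...) {
  cat(sprintf("<bandit_experiment> %s, K = %d, %d sims x (%d x %d rounds)\n",
              x$config$variant, x$config$K, x$config$n_simulations,
              x$config$n_trials, x$config$rounds_per_trial))
  print(x$summary)
  invisible(x)
}

#' Write experiment results to a directory
#'
#' Emits `summary.csv`, `regret.csv` (per-simulation regrets),
#' `comparison.csv` (when present) and `config.json` (provenance echo,
#' schema version 1).
#'
#' @param x a `bandit_experiment` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "bandit_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  reg <- data.frame(simulation = seq_len(nrow(x$regret)), x$regret)
  utils::write.csv(reg, file.path(dir, "regret.csv"), row.names = FALSE)
  if (!is.null(x$comparison)) {
    utils::write.csv(x$comparison, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
  }
  cfg <- x$config
  cfg$genome <- if (!is.null(cfg$genome)) as.list(genome_to_vector(cfg$genome))
  cfg$schema_version <- 1L
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
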