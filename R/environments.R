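#' Draw a piecewise-stationary arm probability vector
#'
#' Each arm's Bernoulli success probability is sampled i.i.d. from
#' Normal(0.5, 0.2) and clipped into \[0, 1\]. Arms are independent
#' Bernoulli sources; the vector is deliberately not normalized to sum
#' to one.
#'
#' @param K number of arms (>= 1).
#' @return numeric vector of length `K` with entries in \[0, 1\].
#' @export
draw_piecewise_distribution <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) {
    stop("`K` must be a single integer >= 1", call. = FALSE)
  }
  pmin(pmax(stats::rnorm(K, mean = 0.5, sd = 0.2), 0), 1)
}

#' Evaluate sinusoidal arm probabilities at a round
#'
#' Arm k follows `sin(2 * pi * f_k * t + lambda_k)` with amplitude 1,
#' clipped into \[0, 1\] so that it remains a valid Bernoulli probability
#' (negative half-waves are silenced at 0). Arms flagged constant in the
#' spec return their frozen value (the partial-sinusoidal variant).
#'
#' @param t round index (>= 0).
#' @param spec a list with `frequencies`, `phases` (length K), and
#'   optionally `constant_mask` (logical, length K) and `constant_values`.
#' @return numeric vector of length K in \[0, 1\].
#' @export
sinusoidal_probabilities <- function(t, spec) {
  p <- pmin(pmax(sin(2 * pi * spec$frequencies * t + spec$phases), 0), 1)
  if (!is.null(spec$constant_mask) && any(spec$constant_mask)) {
    p[spec$constant_mask] <- spec$constant_values[spec$constant_mask]
  }
  p
}

#' One drift step toward the current target distribution
#'
#' Explicit Euler step of `tau_p * dp/dt = q - p` with unit round step:
#' `p <- p + (q - p) / tau_p`, clipped to \[0, 1\]. When every arm is
#' within `delta` of the target (sup-norm), a fresh target is drawn from
#' the piecewise-stationary distribution.
#'
#' @param state list with `current`, `target` (numeric, length K),
#'   `tau_p` (> 0, rounds) and `delta` (> 0).
#' @return the updated state list.
#' @export
step_drift <- function(state) {
  if (!is.numeric(state$tau_p) || state$tau_p <= 0) {
    stop("`tau_p` must be > 0", call. = FALSE)
  }
  p <- state$current + (state$target - state$current) / state$tau_p
  state$current <- pmin(pmax(p, 0), 1)
  if (max(abs(state$target - state$current)) < state$delta) {
    state$target <- draw_piecewise_distribution(length(state$current))
  }
  state
}

#' Sample a Bernoulli reward from a chosen arm
#'
#' @param p arm probability vector.
#' @param k chosen arm index (1-based).
#' @return 0 or 1, with `P(1) = p[k]`.
#' @export
sample_reward <- function(p, k) {
  if (k < 1 || k > length(p)) stop("arm index out of range", call. = FALSE)
  as.integer(stats::runif(1) < p[k])
}

#' Construct a non-stationary bandit environment
#'
#' Four concept-drift variants of the K-armed Bernoulli bandit:
#' \describe{
#'   \item{`mab-p`}{piecewise stationary: probabilities drawn from clipped
#'     Normal(0.5, 0.2), redrawn at every trial boundary (every
#'     `rounds_per_trial` rounds).}
#'   \item{`mab-d`}{gradual drift: probabilities relax toward a target by
#'     `tau_p * dp/dt = q - p` (one Euler step per round); the target is
#'     redrawn when all arms are within `delta` of it. There are no proper
#'     trials, but per-trial blocks are kept for uniform reporting.}
#'   \item{`mab-sin`}{each arm follows a clipped unit-amplitude sinusoid
#'     with per-arm frequency and phase.}
#'   \item{`mab-sinp`}{as `mab-sin`, but `floor(K / 2)` randomly chosen
#'     arms are frozen at constant values drawn from clipped
#'     Normal(0.5, 0.2). The vector is not normalized.}
#' }
#'
#' The constructor consumes the current RNG stream (set a seed beforehand,
#' or pass `seed`). Identical seeds give bit-identical trajectories.
#'
#' @param variant one of `"mab-p"`, `"mab-d"`, `"mab-sin"`, `"mab-sinp"`.
#' @param K number of arms (>= 1).
#' @param rounds_per_trial rounds per trial block (default 2000).
#' @param n_trials number of trial blocks (default 2).
#' @param tau_p drift time constant in rounds (`mab-d`; default 200).
#' @param delta target-switch threshold, sup-norm distance (`mab-d`;
#'   default 0.05).
#' @param freq_range sinusoid frequency range in cycles/round, sampled
#'   uniformly per arm (default `c(1/4000, 1/500)`).
#' @param seed optional integer; if given, seeds the RNG before drawing the
#'   environment's initial state.
#' @return an object of class `bandit_env` whose `$p` holds the arm
#'   probabilities in force for the next round.
#' @seealso [advance()], [env_trajectory()]
#' @export
bandit_env <- function(variant = c("mab-p", "mab-d", "mab-sin", "mab-sinp"),
                       K, rounds_per_trial = 2000, n_trials = 2,
                       tau_p = 200, delta = 0.05,
                       freq_range = c(1 / 4000, 1 / 500), seed = NULL) {
  variant <- match.arg(variant)
  if (K < 1 || rounds_per_trial < 1 || n_trials < 1) {
    stop("`K`, `rounds_per_trial` and `n_trials` must all be >= 1",
         call. = FALSE)
  }
  if (tau_p <= 0 || delta <= 0) {
    stop("`tau_p` and `delta` must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  env <- list(variant = variant, K = as.integer(K),
              rounds_per_trial = as.integer(rounds_per_trial),
              n_trials = as.integer(n_trials),
              tau_p = tau_p, delta = delta, t = 0L)
  if (variant %in% c("mab-p", "mab-d")) {
    env$p <- draw_piecewise_distribution(K)
    if (variant == "mab-d") env$target <- draw_piecewise_distribution(K)
  } else {
    spec <- list(frequencies = stats::runif(K, freq_range[1], freq_range[2]),
                 phases = stats::runif(K, 0, 2 * pi))
    if (variant == "mab-sinp") {
      frozen <- sample.int(K, floor(K / 2))
      spec$constant_mask <- seq_len(K) %in% frozen
      spec$constant_values <- ifelse(
        spec$constant_mask,
        pmin(pmax(stats::rnorm(K, 0.5, 0.2), 0), 1), NA_real_)
    }
    env$spec <- spec
    env$p <- sinusoidal_probabilities(0, spec)
  }
  structure(env, class = "bandit_env")
}

#' @export
print.bandit_env <- function(x, ...) {
  cat(sprintf("<bandit_env> %s, K = %d, %d trial(s) x %d rounds, round %d\n",
              x$variant, x$K, x$n_trials, x$rounds_per_trial, x$t))
  invisible(x)
}

#' Advance an environment by one round
#'
#' Increments the round counter and updates the arm probabilities according
#' to the variant: piecewise-stationary environments redraw only at trial
#' boundaries, drifting environments take one Euler step toward their
#' target, sinusoidal environments are re-evaluated at the new round index.
#' Consumes the RNG stream only where a redraw occurs.
#'
#' @param env a [bandit_env()] object.
#' @return the updated environment.
#' @export
advance <- function(env) {
  stopifnot(inherits(env, "bandit_env"))
  env$t <- env$t + 1L
  switch(env$variant,
    "mab-p" = {
      if (env$t %% env$rounds_per_trial == 0L) {
        env$p <- draw_piecewise_distribution(env$K)
      }
    },
    "mab-d" = {
      st <- step_drift(list(current = env$p, target = env$target,
                            tau_p = env$tau_p, delta = env$delta))
      env$p <- st$current
      env$target <- st$target
    },
    {
      env$p <- sinusoidal_probabilities(env$t, env$spec)
    })
  env
}

#' Materialize the full probability trajectory of an environment
#'
#' Repeatedly applies [advance()] over the configured horizon
#' (`n_trials * rounds_per_trial` rounds) and collects the probability
#' vector in force at each round. Row r is the distribution rewards were
#' drawn from during round r.
#'
#' @param env a freshly constructed [bandit_env()] (round counter 0).
#' @return numeric matrix with `n_trials * rounds_per_trial` rows and `K`
#'   columns.
#' @export
env_trajectory <- function(env) {
  stopifnot(inherits(env, "bandit_env"))
  n <- env$n_trials * env$rounds_per_trial
  P <- matrix(NA_real_, nrow = n, ncol = env$K)
  for (r in seq_len(n)) {
    P[r, ] <- env$p
    env <- advance(env)
  }
  P
}

#' Export a probability trajectory as CSV
#'
#' Writes columns `round, arm_1 ... arm_K` for drift visualisation.
#'
#' @param P trajectory matrix from [env_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(P, path) {
  df <- data.frame(round = seq_len(nrow(P)), P)
  names(df) <- c("round", paste0("arm_", seq_len(ncol(P))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
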