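#' Fresh network state for K options
#'
#' Two rate populations of K units each: U holds the option traces and
#' receives the external input, V encodes option values. The V-to-U
#' connectivity is a fixed identity diagonal; the U-to-V diagonal weights
#' `W_uv` are the only plastic parameters and start at zero, so a fresh
#' network carries no bias toward any arm.
#'
#' @param K number of options.
#' @return an object of class `network_state` with fields `u`, `v`
#'   (activities, zeros) and `W_uv` (plastic weights, zeros).
#' @export
network_state <- function(K) {
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  structure(list(u = numeric(K), v = numeric(K), W_uv = numeric(K),
                 K = as.integer(K)),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> K = %d, max u = %.4g, max v = %.4g, max W = %.4g\n",
              x$K, max(x$u), max(x$v), max(x$W_uv)))
  invisible(x)
}

#' One synchronous Euler step of the coupled rate dynamics
#'
#' Advances both populations by `dt` ms from their pre-step values:
#' \deqn{u \leftarrow u + (dt/\tau_u)(-u + \phi_v(v) + I_{ext})}
#' \deqn{v \leftarrow v + (dt/\tau_v)(-v + \Phi_v(W_{uv}) \odot \phi_u(u))}
#' where the option-value filter \eqn{\Phi_v} is applied elementwise to the
#' diagonal weights and the external input enters only when `i_ext_on`.
#'
#' @param state a [network_state()].
#' @param i_ext_on logical: deliver the constant external input to U?
#' @param genome an [nsa_genome()].
#' @param dt integration step in ms (default 1).
#' @return the updated state.
#' @export
euler_step <- function(state, i_ext_on, genome, dt = 1) {
  gate <- gaussian_sigmoid(state$W_uv, genome$phi_v)
  u <- state$u
  v <- state$v
  state$u <- u + dt / genome$tau_u *
    (-u + neural_response(v, genome$resp_v) + if (i_ext_on) genome$i_ext else 0)
  state$v <- v + dt / genome$tau_v *
    (-v + gate * neural_response(u, genome$resp_u))
  if (!all(is.finite(state$u)) || !all(is.finite(state$v))) {
    stop("non-finite network state during integration", call. = FALSE)
  }
  state
}

#' Integrate one full selection round (two phases)
#'
#' Resets both populations to zero, integrates `dur_pre` ms with the
#' external input on, then `dur_post` ms with the input off (dynamics then
#' driven purely by the inter-population coupling). Durations are rounded
#' to integer multiples of `dt`. Uses a compiled inner loop equivalent to
#' iterating [euler_step()].
#'
#' @param state a [network_state()]; its weights are used, its activities
#'   are reset.
#' @inheritParams euler_step
#' @return the state after both phases.
#' @export
integrate_round <- function(state, genome, dt = 1) {
  gate <- gaussian_sigmoid(state$W_uv, genome$phi_v)
  res <- integrate_phases_cpp(
    numeric(state$K), numeric(state$K), gate,
    as.integer(round(genome$dur_pre / dt)),
    as.integer(round(genome$dur_post / dt)),
    dt, genome$tau_u, genome$tau_v, genome$i_ext,
    genome$resp_u$gain, genome$resp_u$offset, genome$resp_u$threshold,
    genome$resp_v$gain, genome$resp_v$offset, genome$resp_v$threshold)
  state$u <- res$u
  state$v <- res$v
  if (!all(is.finite(state$u)) || !all(is.finite(state$v))) {
    stop("non-finite network state during integration", call. = FALSE)
  }
  state
}

#' Agreement-based option selection
#'
#' Each population nominates its most active unit (first index on exact
#' ties). If the nominations coincide the common arm is chosen (the
#' populations agree: exploitation); otherwise a uniformly random arm is
#' chosen (disagreement: exploration).
#'
#' @param state a [network_state()] after [integrate_round()].
#' @return list with `k` (chosen arm), `agreed` (logical), `k_u`, `k_v`
#'   (per-population argmax indices, 1-based).
#' @export
select_option <- function(state) {
  if (state$K < 1 || !length(state$u)) stop("empty network state", call. = FALSE)
  k_u <- which.max(state$u)
  k_v <- which.max(state$v)
  if (k_u == k_v) {
    list(k = k_v, agreed = TRUE, k_u = k_u, k_v = k_v)
  } else {
    list(k = sample.int(state$K, 1L), agreed = FALSE, k_u = k_u, k_v = k_v)
  }
}

#' Reward-gated weight update of the chosen arm
#'
#' Applies the plasticity rule
#' \deqn{\Delta W_k = \tilde\eta_k (R \cdot w^+ - W_k)}
#' to the chosen arm only, where the learning rate
#' \eqn{\tilde\eta_k = \mathrm{clip}(\Phi_\eta(W_k), 0, 1)} depends on the
#' synapse's own current weight. With the learning rate in \[0, 1\] and
#' rewards in \{0, 1\}, weights started at zero remain in \[0, w_plus\].
#'
#' @param W_uv numeric weight vector.
#' @param k chosen arm (1-based).
#' @param R reward, 0 or 1.
#' @param genome an [nsa_genome()].
#' @return the updated weight vector.
#' @export
update_weights <- function(W_uv, k, R, genome) {
  eta <- min(max(gaussian_sigmoid(W_uv[k], genome$phi_eta), 0), 1)
  W_uv[k] <- W_uv[k] + eta * (R * genome$w_plus - W_uv[k])
  W_uv
}

#' Play one full round against an environment
#'
#' Runs the two-phase integration, selects an arm by population agreement,
#' samples a Bernoulli reward from the environment's current distribution,
#' updates the chosen arm's weight, and advances the environment.
#'
#' @param state a [network_state()] carrying the learned weights.
#' @param genome an [nsa_genome()].
#' @param env a [bandit_env()].
#' @param dt Euler step in ms.
#' @return list with `record` (one-row data.frame: `t`, `k`, `R`, `p_star`,
#'   `p_chosen`, `agreed`, `k_u`, `k_v`), `state`, and `env`.
#' @export
run_round <- function(state, genome, env, dt = 1) {
  p <- env$p
  state <- integrate_round(state, genome, dt = dt)
  sel <- select_option(state)
  R <- sample_reward(p, sel$k)
  state$W_uv <- update_weights(state$W_uv, sel$k, R, genome)
  record <- data.frame(t = env$t + 1L, k = sel$k, R = R,
                       p_star = max(p), p_chosen = p[sel$k],
                       agreed = sel$agreed, k_u = sel$k_u, k_v = sel$k_v)
  list(record = record, state = state, env = advance(env))
}

#' Run a full episode of the agent on an environment
#'
#' Plays `n_trials * rounds_per_trial` rounds from a fresh network (weights
#' zero). Weights persist across trial boundaries within the episode: the
#' agent must recalibrate to each new distribution, which is the point of
#' the non-stationary benchmark.
#'
#' @param genome an [nsa_genome()].
#' @param env a freshly constructed [bandit_env()].
#' @param dt Euler step in ms.
#' @return data.frame episode log, one row per round, with the columns of
#'   [run_round()]'s record.
#' @export
nsa_episode <- function(genome, env, dt = 1) {
  n <- env$n_trials * env$rounds_per_trial
  state <- network_state(env$K)
  k <- integer(n); R <- integer(n); p_star <- numeric(n)
  p_chosen <- numeric(n); agreed <- logical(n)
  k_u <- integer(n); k_v <- integer(n)
  for (r in seq_len(n)) {
    p <- env$p
    state <- integrate_round(state, genome, dt = dt)
    sel <- select_option(state)
    R[r] <- sample_reward(p, sel$k)
    state$W_uv <- update_weights(state$W_uv, sel$k, R[r], genome)
    k[r] <- sel$k; p_star[r] <- max(p); p_chosen[r] <- p[sel$k]
    agreed[r] <- sel$agreed; k_u[r] <- sel$k_u; k_v[r] <- sel$k_v
    env <- advance(env)
  }
  data.frame(t = seq_len(n), k = k, R = R, p_star = p_star,
             p_chosen = p_chosen, agreed = agreed, k_u = k_u, k_v = k_v)
}
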