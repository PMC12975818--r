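#' Per-arm reward statistics
#'
#' Counts backing the baseline algorithms: per-arm successes, failures and
#' pulls, plus the total number of rounds elapsed. Statistics are never
#' reset within a simulation: the baselines run continuously through
#' distribution changes, which is the object of the non-stationary
#' benchmark.
#'
#' @param K number of arms.
#' @return an object of class `arm_statistics`.
#' @export
arm_statistics <- function(K) {
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  structure(list(successes = numeric(K), failures = numeric(K),
                 pulls = numeric(K), t = 0, K = as.integer(K)),
            class = "arm_statistics")
}

#' Record one observed reward
#'
#' @param stats an [arm_statistics()] object.
#' @param k pulled arm (1-based).
#' @param R reward, 0 or 1.
#' @return the updated statistics.
#' @export
update_stats <- function(stats, k, R) {
  stats$pulls[k] <- stats$pulls[k] + 1
  stats$t <- stats$t + 1
  if (R == 1) stats$successes[k] <- stats$successes[k] + 1
  else stats$failures[k] <- stats$failures[k] + 1
  stats
}

#' Thompson sampling selection
#'
#' Samples one value per arm from the Beta(1 + successes, 1 + failures)
#' posterior (uniform Beta(1, 1) prior) and returns the arm with the
#' largest sample (first index on exact ties).
#'
#' @param stats an [arm_statistics()] object.
#' @return chosen arm index (1-based).
#' @export
thompson_select <- function(stats) {
  theta <- stats::rbeta(stats$K, 1 + stats$successes, 1 + stats$failures)
  which.max(theta)
}

#' UCB1 selection
#'
#' Any arm never pulled is selected first (lowest index); otherwise returns
#' the arm maximizing `mean_k + sqrt(2 * log(t) / pulls_k)` (first index on
#' ties). No tunable hyperparameters.
#'
#' @param stats an [arm_statistics()] object.
#' @return chosen arm index (1-based).
#' @export
ucb1_select <- function(stats) {
  unpulled <- which(stats$pulls == 0)
  if (length(unpulled)) return(unpulled[1L])
  idx <- stats$successes / stats$pulls + sqrt(2 * log(stats$t) / stats$pulls)
  which.max(idx)
}

#' Arm-count rule for the epsilon-greedy exploration rate
#'
#' `epsilon = 0.4 * log2(0.6 * K)`, clipped into \[0, 1\] (the raw formula
#' exceeds 1 for K >= 6, and a probability is required).
#'
#' @param K number of arms.
#' @return exploration probability in \[0, 1\].
#' @export
epsilon_rule <- function(K) {
  min(max(0.4 * log2(0.6 * K), 0), 1)
}

#' Epsilon-greedy selection
#'
#' With probability `epsilon` a uniformly random arm, otherwise the arm
#' with the highest running empirical mean reward (arms never pulled count
#' as mean 0; first index on ties).
#'
#' @param stats an [arm_statistics()] object.
#' @param epsilon exploration probability; defaults to [epsilon_rule()] of
#'   the arm count.
#' @return chosen arm index (1-based).
#' @export
epsilon_greedy_select <- function(stats, epsilon = epsilon_rule(stats$K)) {
  if (stats::runif(1) < epsilon) return(sample.int(stats$K, 1L))
  means <- ifelse(stats$pulls > 0, stats$successes / stats$pulls, 0)
  which.max(means)
}

#' Uniformly random selection
#'
#' @param K number of arms.
#' @return chosen arm index (1-based).
#' @export
random_select <- function(K) {
  sample.int(K, 1L)
}

#' Construct a bandit agent
#'
#' Common interface treating the neural agreement agent and the baselines
#' identically: construct with the arm count, [agent_select()] an arm each
#' round, [agent_observe()] the reward.
#'
#' @param algorithm one of `"nsa"`, `"ts"`, `"ucb1"`, `"egreedy"`,
#'   `"random"`, `"oracle"` (the oracle is a diagnostic agent that must be
#'   handed the true probabilities at selection time).
#' @param K number of arms.
#' @param genome an [nsa_genome()] for the `"nsa"` algorithm (defaults to
#'   [default_genome()]).
#' @param dt Euler step in ms for the `"nsa"` algorithm.
#' @return an object of classes `agent_<algorithm>` and `bandit_agent`.
#' @export
bandit_agent <- function(algorithm = c("nsa", "ts", "ucb1", "egreedy",
                                       "random", "oracle"),
                         K, genome = NULL, dt = 1) {
  algorithm <- match.arg(algorithm)
  agent <- list(algorithm = algorithm, K = as.integer(K))
  if (algorithm == "nsa") {
    agent$genome <- if (is.null(genome)) default_genome() else genome
    agent$state <- network_state(K)
    agent$dt <- dt
  } else if (algorithm %in% c("ts", "ucb1", "egreedy")) {
    agent$stats <- arm_statistics(K)
    if (algorithm == "egreedy") agent$epsilon <- epsilon_rule(K)
  }
  structure(agent, class = c(paste0("agent_", algorithm), "bandit_agent"))
}

#' Select an arm
#'
#' @param agent a [bandit_agent()].
#' @param p_true true arm probabilities; consulted only by the oracle agent.
#' @return chosen arm index (1-based). For the neural agent the last
#'   selection's agreement flag is stored in the agent and reported by the
#'   experiment runner.
#' @export
agent_select <- function(agent, p_true = NULL) UseMethod("agent_select")

#' @export
agent_select.agent_ts <- function(agent, p_true = NULL) thompson_select(agent$stats)

#' @export
agent_select.agent_ucb1 <- function(agent, p_true = NULL) ucb1_select(agent$stats)

#' @export
agent_select.agent_egreedy <- function(agent, p_true = NULL) {
  epsilon_greedy_select(agent$stats, agent$epsilon)
}

#' @export
agent_select.agent_random <- function(agent, p_true = NULL) random_select(agent$K)

#' @export
agent_select.agent_oracle <- function(agent, p_true = NULL) {
  if (is.null(p_true)) stop("the oracle agent needs the true probabilities",
                            call. = FALSE)
  which.max(p_true)
}

#' @export
agent_select.agent_nsa <- function(agent, p_true = NULL) {
  st <- integrate_round(agent$state, agent$genome, dt = agent$dt)
  sel <- select_option(st)
  attr(sel$k, "agreed") <- sel$agreed
  sel$k
}

#' Observe a reward
#'
#' @param agent a [bandit_agent()].
#' @param k pulled arm (1-based).
#' @param R reward, 0 or 1.
#' @return the updated agent.
#' @export
agent_observe <- function(agent, k, R) UseMethod("agent_observe")

#' @export
agent_observe.bandit_agent <- function(agent, k, R) {
  if (!is.null(agent$stats)) agent$stats <- update_stats(agent$stats, k, R)
  agent
}

#' @export
agent_observe.agent_nsa <- function(agent, k, R) {
  agent$state$W_uv <- update_weights(agent$state$W_uv, k, R, agent$genome)
  agent
}
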