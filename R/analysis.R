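#' Mean per-round pseudo-regret
#'
#' Average over rounds of the gap between the optimal arm's success
#' probability and the chosen arm's success probability,
#' \deqn{\rho = \frac{1}{T} \sum_{t=1}^{T} (p^*_t - p_{chosen,t}).}
#' This is pseudo-regret on probabilities, not on realized rewards, so the
#' oracle policy scores exactly 0 and values lie in \[0, 1\] for Bernoulli
#' arms.
#'
#' @param log episode log: a data.frame with columns `p_star` and
#'   `p_chosen` (as produced by [nsa_episode()] or the experiment runner).
#' @return scalar regret.
#' @export
regret <- function(log) {
  if (!NROW(log)) stop("empty episode log", call. = FALSE)
  mean(log$p_star - log$p_chosen)
}

#' Sliding-window entropy of arm selections
#'
#' For each round from `window` onward, the Shannon entropy (nats, with
#' `0 * log(0) = 0`) of the empirical distribution of the arms chosen in
#' the trailing `window` rounds. Ranges from 0 (a single arm chosen
#' throughout the window: confident exploitation) to `log(window)` resp.
#' `log(K)` (all-distinct / uniform choices: full exploration). An optional
#' moving average smooths the trace for plotting.
#'
#' @param choices integer vector of chosen arms (1-based).
#' @param K number of arms.
#' @param window sliding-window length in rounds (default 20).
#' @param smoothing moving-average span in rounds applied to the entropy
#'   trace (0 = none; the benchmark figures use 30).
#' @return data.frame with columns `round` (window end) and `entropy`, plus
#'   `smoothed` when `smoothing > 0`.
#' @export
selection_entropy <- function(choices, K, window = 20, smoothing = 0) {
  n <- length(choices)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (n < window) stop("need at least `window` choices", call. = FALSE)
  counts <- tabulate(choices[seq_len(window)], nbins = K)
  ent <- numeric(n - window + 1L)
  entropy_of <- function(cnt) {
    p <- cnt[cnt > 0] / window
    -sum(p * log(p))
  }
  ent[1L] <- entropy_of(counts)
  if (n > window) {
    for (r in seq.int(window + 1L, n)) {
      counts[choices[r - window]] <- counts[choices[r - window]] - 1L
      counts[choices[r]] <- counts[choices[r]] + 1L
      ent[r - window + 1L] <- entropy_of(counts)
    }
  }
  out <- data.frame(round = seq.int(window, n), entropy = ent)
  if (smoothing > 0) {
    sm <- stats::filter(ent, rep(1 / smoothing, smoothing), sides = 1)
    out$smoothed <- as.numeric(sm)
  }
  out
}

#' Shannon entropy of a reward-probability profile
#'
#' Arm probabilities are independent Bernoulli parameters and need not sum
#' to one, so the vector is first normalized to a distribution; the entropy
#' `-sum(p * log(p))` is then computed in nats with `0 * log(0) = 0`.
#'
#' @param p non-negative numeric vector of arm probabilities.
#' @return scalar entropy in nats, in \[0, log(length(p))\].
#' @export
distribution_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s == 0) stop("all-zero probability vector", call. = FALSE)
  q <- p[p > 0] / s
  -sum(q * log(q))
}

#' Build reward profiles of increasing entropy at fixed mean
#'
#' Interpolates between a strongly peaked arm-probability profile (one
#' dominant arm) and a homogeneous one with the same mean, by convex mixing
#' `p_lambda = (1 - lambda) * p_peaked + lambda * p_uniform` over a lambda
#' grid. Entropy increases strictly along the ladder while the mean
#' probability is conserved, isolating reward-profile uncertainty from
#' overall reward density.
#'
#' @param K number of arms.
#' @param n_levels number of profiles (>= 2).
#' @param mean_p common mean probability of every profile (default 0.5).
#' @param peak_p probability of the dominant arm in the most peaked profile
#'   (default 0.95).
#' @param peak_arm index of the dominant arm; by default drawn uniformly.
#' @return list of length `n_levels`; each element has `p` (probabilities),
#'   `entropy` (nats) and `delta_h` (entropy difference to the uniform
#'   reference of equal mean, which is `log(K)` after normalization).
#' @export
make_entropy_ladder <- function(K, n_levels, mean_p = 0.5, peak_p = 0.95,
                                peak_arm = sample.int(K, 1L)) {
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  rest <- (K * mean_p - peak_p) / (K - 1)
  if (rest < 0 || rest > 1 || peak_p < 0 || peak_p > 1) {
    stop("infeasible mean/peak combination", call. = FALSE)
  }
  p_peaked <- rep(rest, K)
  p_peaked[peak_arm] <- peak_p
  p_uniform <- rep(mean_p, K)
  lambdas <- seq(0, 1, length.out = n_levels)
  h_ref <- log(K)
  lapply(lambdas, function(l) {
    p <- (1 - l) * p_peaked + l * p_uniform
    h <- distribution_entropy(p)
    list(p = p, entropy = h, delta_h = h - h_ref)
  })
}

#' Pairwise Welch comparison of algorithm regrets
#'
#' Welch's independent two-sample t-test of every algorithm against a
#' reference (by default the neural agreement agent), with Bonferroni
#' correction over the comparisons and conventional star annotations
#' (`*`, `**`, `***` at adjusted p < 0.05, 0.01, 0.001). Degenerate
#' zero-variance pairs are handled as exact ties (p = 1 when the means
#' coincide, p = 0 otherwise).
#'
#' @param results named list of numeric vectors of per-simulation regrets.
#' @param reference name of the reference algorithm (default `"nsa"` if
#'   present, else the first element).
#' @return data.frame with one row per non-reference algorithm: mean
#'   regret, Welch `t` and `df`, raw and Bonferroni-adjusted p-values, and
#'   `stars`.
#' @export
compare_algorithms <- function(results,
                               reference = if ("nsa" %in% names(results))
                                 "nsa" else names(results)[1]) {
  if (!reference %in% names(results)) {
    stop("reference algorithm not in `results`", call. = FALSE)
  }
  others <- setdiff(names(results), reference)
  if (!length(others)) stop("need at least two algorithms", call. = FALSE)
  ref <- results[[reference]]
  rows <- lapply(others, function(name) {
    x <- results[[name]]
    if (stats::var(x) == 0 && stats::var(ref) == 0) {
      p <- if (isTRUE(all.equal(mean(x), mean(ref)))) 1 else 0
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = p)
    } else {
      tt <- stats::t.test(x, ref, var.equal = FALSE)
    }
    data.frame(algorithm = name, mean_regret = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$stars <- ifelse(out$p_adjusted < 0.001, "***",
               ifelse(out$p_adjusted < 0.01, "**",
               ifelse(out$p_adjusted < 0.05, "*", "")))
  out$reference <- reference
  out$reference_mean <- mean(ref)
  out
}
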