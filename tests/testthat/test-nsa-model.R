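test_that("uncoupled dynamics follow the scalar linear-decay closed form", {
  g <- inert_genome(tau_u = 25, i_ext = 1.5)
  st <- network_state(3)
  err <- 0
  for (n in 1:400) {
    st <- euler_step(st, i_ext_on = TRUE, genome = g, dt = 1)
    err <- max(err, abs(st$u - g$i_ext * (1 - (1 - 1 / g$tau_u)^n)))
  }
  expect_lt(err, 1e-12)
  expect_equal(st$v, rep(0, 3))
  # leak-only decay with input off
  u_on <- st$u
  st <- euler_step(st, i_ext_on = FALSE, genome = g, dt = 1)
  expect_equal(st$u, u_on * (1 - 1 / g$tau_u), tolerance = 1e-12)
})

test_that("a self-consistent state is a fixed point of the Euler map", {
  set.seed(31)
  g <- random_genome()
  st <- network_state(4)
  st$W_uv <- runif(4, 0, g$w_plus)
  gate <- gaussian_sigmoid(st$W_uv, g$phi_v)
  # solve the coupled fixed point by damped iteration
  u <- rep(g$i_ext, 4); v <- gate * neural_response(u, g$resp_u)
  for (i in 1:5000) {
    u <- neural_response(v, g$resp_v) + g$i_ext
    v <- gate * neural_response(u, g$resp_u)
  }
  st$u <- u; st$v <- v
  st2 <- euler_step(st, i_ext_on = TRUE, genome = g, dt = 1)
  expect_equal(st2$u, st$u, tolerance = 1e-8)
  expect_equal(st2$v, st$v, tolerance = 1e-8)
})

test_that("compiled two-phase integration equals iterated R Euler steps", {
  set.seed(17)
  for (rep in 1:5) {
    g <- random_genome()
    K <- sample(2:8, 1)
    st <- network_state(K)
    st$W_uv <- runif(K, 0, g$w_plus)
    ref <- st
    for (i in seq_len(round(g$dur_pre))) {
      ref <- euler_step(ref, i_ext_on = TRUE, genome = g, dt = 1)
    }
    for (i in seq_len(round(g$dur_post))) {
      ref <- euler_step(ref, i_ext_on = FALSE, genome = g, dt = 1)
    }
    out <- integrate_round(st, g, dt = 1)
    expect_equal(out$u, ref$u, tolerance = 1e-12)
    expect_equal(out$v, ref$v, tolerance = 1e-12)
  }
})

test_that("activities stay in their invariant boxes for random genomes", {
  set.seed(23)
  for (rep in 1:5) {
    g <- random_genome()
    st <- network_state(5)
    st$W_uv <- runif(5, 0, g$w_plus)
    ok <- TRUE
    for (i in 1:200) {
      st <- euler_step(st, i_ext_on = i <= 100, genome = g, dt = 1)
      ok <- ok && all(st$u >= 0 & st$u <= g$i_ext + 1) &&
        all(st$v >= 0 & st$v <= 1)
    }
    expect_true(ok)
  }
})

test_that("selection agrees on matching argmax and explores otherwise", {
  st <- network_state(2)
  st$u <- c(0.1, 0.9); st$v <- c(0.2, 0.7)
  sel <- select_option(st)
  expect_true(sel$agreed)
  expect_equal(sel$k, 2L)
  expect_equal(sel$k_u, 2L)
  # exact ties resolve to the first index in both populations
  st$u <- c(0.5, 0.5); st$v <- c(0.3, 0.3)
  sel <- select_option(st)
  expect_true(sel$agreed)
  expect_equal(sel$k, 1L)
  # disagreement: uniform random choice
  st$u <- c(0.9, 0.1); st$v <- c(0.1, 0.9)
  set.seed(4)
  ks <- replicate(1e4, select_option(st)$k)
  expect_false(any(replicate(50, select_option(st)$agreed)))
  expect_equal(mean(ks == 1), 0.5, tolerance = 0.02)
})

test_that("plasticity updates only the chosen arm and respects fixed points", {
  g <- constant_eta_genome(eta = 0.1, w_plus = 1)
  # saturation: W = w_plus under reward is a fixed point
  W <- c(1, 0.3, 0)
  expect_equal(update_weights(W, 1, 1, g), W)
  # from zero, one rewarded update moves to eta * w_plus
  expect_equal(update_weights(c(0, 0, 0), 2, 1, g), c(0, 0.1, 0))
  # locality: other entries untouched
  W2 <- update_weights(W, 2, 0, g)
  expect_equal(W2[c(1, 3)], W[c(1, 3)])
  expect_equal(W2[2], 0.3 - 0.1 * 0.3)
})

test_that("constant-rate rewarded updates follow the geometric recursion", {
  g <- constant_eta_genome(eta = 0.1, w_plus = 1)
  W <- 0
  err <- 0
  for (n in 1:50) {
    W <- update_weights(W, 1, 1, g)
    err <- max(err, abs(W - (1 - 0.9^n)))
  }
  expect_lt(err, 1e-12)
})

test_that("weights stay in [0, w_plus] for random genomes and reward streams", {
  set.seed(12)
  for (rep in 1:5) {
    g <- random_genome()
    W <- numeric(4)
    ok <- TRUE
    for (i in 1:500) {
      W <- update_weights(W, sample.int(4, 1), rbinom(1, 1, 0.5), g)
      ok <- ok && all(W >= 0 & W <= g$w_plus)
    }
    expect_true(ok)
  }
})

test_that("a fresh network favors no arm and a trained one is followed", {
  g <- default_genome()
  st <- integrate_round(network_state(6), g)
  expect_true(all(st$u == st$u[1])) # uniform input, zero weights: no bias
  expect_true(all(st$v == st$v[1]))
  # strongly weight-selective state: the trained arm wins in both layers
  gs <- selective_genome()
  st2 <- network_state(2)
  st2$W_uv <- c(0.95, 0)
  st2 <- integrate_round(st2, gs)
  sel <- select_option(st2)
  expect_true(sel$agreed)
  expect_equal(sel$k, 1L)
})

test_that("episodes are deterministic given genome and seeds", {
  g <- default_genome()
  run <- function() {
    env <- bandit_env("mab-p", K = 4, rounds_per_trial = 30, n_trials = 2,
                      seed = 99)
    set.seed(100)
    nsa_episode(g, env)
  }
  expect_identical(run(), run())
})

test_that("a single round plays, learns and advances the environment", {
  g <- default_genome()
  env <- bandit_env("mab-p", K = 3, rounds_per_trial = 10, n_trials = 1,
                    seed = 14)
  st <- network_state(3)
  set.seed(15)
  out <- run_round(st, g, env)
  expect_equal(out$env$t, 1L)
  expect_equal(out$record$t, 1L)
  expect_true(out$record$k %in% 1:3)
  expect_equal(out$record$p_star, max(env$p))
  expect_equal(out$record$p_chosen, env$p[out$record$k])
  # only the chosen arm's weight can have moved
  expect_true(all(out$state$W_uv[-out$record$k] == 0))
  if (out$record$R == 1) expect_gt(out$state$W_uv[out$record$k], 0)
})

test_that("round records are internally consistent", {
  g <- default_genome()
  env <- bandit_env("mab-sin", K = 5, rounds_per_trial = 25, n_trials = 2,
                    seed = 8)
  set.seed(9)
  log <- nsa_episode(g, env)
  expect_equal(nrow(log), 50L)
  expect_true(all(log$p_chosen <= log$p_star + 1e-12))
  expect_true(all(log$R %in% c(0L, 1L)))
  expect_true(all(log$agreed == (log$k_u == log$k_v)))
  expect_true(all(log$k[log$agreed] == log$k_v[log$agreed]))
})
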