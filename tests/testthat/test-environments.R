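test_that("piecewise draws are clipped Normal(0.5, 0.2) with the right moments", {
  set.seed(1)
  p <- draw_piecewise_distribution(2e5)
  expect_true(all(p >= 0 & p <= 1))
  # clipping mass at 2.5 sd is negligible: moments survive to ~3 MC SEs
  expect_equal(mean(p), 0.5, tolerance = 0.005)
  expect_equal(sd(p), 0.2, tolerance = 0.01)
  expect_error(draw_piecewise_distribution(0), "K")
})

test_that("drift steps follow the closed-form geometric relaxation", {
  # K = 1, p0 = 0, target 1, tau_p = 10: p_n = 1 - (1 - 1/10)^n
  st <- list(current = 0, target = 1, tau_p = 10, delta = 1e-12)
  for (n in 1:30) {
    st <- step_drift(st)
    expect_equal(st$current, 1 - (1 - 1 / 10)^n, tolerance = 1e-12)
  }
  # tau_p -> infinity: no movement
  st <- list(current = 0.3, target = 0.9, tau_p = 1e15, delta = 1e-12)
  expect_equal(step_drift(st)$current, 0.3, tolerance = 1e-12)
  expect_error(step_drift(list(current = 0, target = 1, tau_p = 0,
                               delta = 0.1)), "tau_p")
})

test_that("reaching the target redraws it", {
  set.seed(5)
  st <- list(current = rep(0.5, 4), target = rep(0.5, 4), tau_p = 10,
             delta = 0.01)
  st2 <- step_drift(st) # zero distance is below any positive delta
  expect_false(identical(st2$target, st$target))
  expect_equal(st2$current, st$current)
})

test_that("sinusoidal probabilities clip the unit sine and honor masks", {
  spec <- list(frequencies = c(0.01, 0.01), phases = c(pi / 2, -pi / 2))
  expect_equal(sinusoidal_probabilities(0, spec), c(1, 0))
  # mean of the clipped sine over one full period is 1/pi
  spec1 <- list(frequencies = 1 / 1000, phases = 0)
  m <- mean(vapply(0:999, sinusoidal_probabilities, numeric(1), spec = spec1))
  expect_equal(m, 1 / pi, tolerance = 1e-3)
  # frozen arms return their constant
  spec$constant_mask <- c(TRUE, FALSE)
  spec$constant_values <- c(0.42, NA)
  expect_equal(sinusoidal_probabilities(0, spec), c(0.42, 0))
  # periodicity at integer multiples of 1/f
  expect_equal(sinusoidal_probabilities(123, spec1),
               sinusoidal_probabilities(123 + 1000, spec1))
})

test_that("bernoulli rewards match the arm probability", {
  expect_equal(sample_reward(c(1, 0), 1), 1L)
  expect_equal(sample_reward(c(1, 0), 2), 0L)
  expect_error(sample_reward(c(0.5), 2), "range")
  set.seed(2)
  draws <- replicate(1e4, sample_reward(c(0.1, 0.3), 2))
  se <- sqrt(0.3 * 0.7 / 1e4)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
})

test_that("piecewise environments redraw exactly at trial boundaries", {
  env <- bandit_env("mab-p", K = 5, rounds_per_trial = 50, n_trials = 3,
                    seed = 11)
  p0 <- env$p
  for (i in 1:49) {
    env <- advance(env)
    expect_identical(env$p, p0) # stationary within the trial
  }
  env <- advance(env) # round 50: boundary
  expect_false(identical(env$p, p0))
})

test_that("drifting environments close the gap monotonically between redraws", {
  env <- bandit_env("mab-d", K = 8, rounds_per_trial = 100, n_trials = 1,
                    tau_p = 50, delta = 0.05, seed = 3)
  d_prev <- max(abs(env$target - env$p))
  for (i in 1:100) {
    target_before <- env$target
    env <- advance(env)
    if (identical(target_before, env$target)) {
      d <- max(abs(env$target - env$p))
      expect_lte(d, d_prev + 1e-12)
      d_prev <- d
    } else {
      d_prev <- max(abs(env$target - env$p))
    }
  }
})

test_that("partial sinusoidal variant freezes exactly half the arms", {
  for (K in c(4, 9)) {
    env <- bandit_env("mab-sinp", K = K, seed = 21)
    expect_equal(sum(env$spec$constant_mask), floor(K / 2))
    frozen <- which(env$spec$constant_mask)
    P <- env_trajectory(bandit_env("mab-sinp", K = K, rounds_per_trial = 200,
                                   n_trials = 1, seed = 21))
    expect_true(all(apply(P[, frozen, drop = FALSE], 2,
                          function(x) length(unique(x)) == 1L)))
  }
})

test_that("all variants emit probabilities in [0, 1] for random configs", {
  set.seed(9)
  for (variant in c("mab-p", "mab-d", "mab-sin", "mab-sinp")) {
    for (rep in 1:3) {
      K <- sample(1:20, 1)
      env <- bandit_env(variant, K = K, rounds_per_trial = sample(10:80, 1),
                        n_trials = 2)
      P <- env_trajectory(env)
      expect_true(all(P >= 0 & P <= 1), label = variant)
    }
  }
})

test_that("equal seeds give bit-identical trajectories, unequal seeds differ", {
  for (variant in c("mab-p", "mab-d", "mab-sin")) {
    P1 <- env_trajectory(bandit_env(variant, K = 6, rounds_per_trial = 40,
                                    n_trials = 2, seed = 123))
    P2 <- env_trajectory(bandit_env(variant, K = 6, rounds_per_trial = 40,
                                    n_trials = 2, seed = 123))
    P3 <- env_trajectory(bandit_env(variant, K = 6, rounds_per_trial = 40,
                                    n_trials = 2, seed = 124))
    expect_identical(P1, P2)
    expect_false(identical(P1, P3))
  }
})

test_that("sinusoidal arms with equal parameters are exchangeable", {
  spec <- list(frequencies = rep(1 / 200, 5), phases = rep(0, 5))
  for (t in c(0, 37, 150)) {
    p <- sinusoidal_probabilities(t, spec)
    expect_true(all(p == p[1]))
  }
})

test_that("invalid environment configurations are rejected", {
  expect_error(bandit_env("mab-p", K = 0), ">= 1")
  expect_error(bandit_env("mab-d", K = 3, tau_p = -5), "tau_p")
  expect_error(bandit_env("nope", K = 3))
})
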