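test_that("degenerate initial states produce constant trajectories", {
  p0 <- model_params(20, s = 0.1, mu = 0)
  # fixation is absorbing: zero jumps
  tr <- simulate_trajectory(p0, i0 = 20, t_max = 50, seed = 1)
  expect_length(tr$times, 0)
  expect_true(tr$absorbed)
  expect_identical(tr$final_state, 20L)
  # extinction is absorbing only without mutation
  tr0 <- simulate_trajectory(p0, i0 = 0, t_max = 50, seed = 1)
  expect_length(tr0$times, 0)
  expect_identical(tr0$final_state, 0L)
  # with mutation the clone is re-seeded from state 0
  pmu <- model_params(20, s = 0.1, mu = 0.05)
  trmu <- simulate_trajectory(pmu, i0 = 0, t_max = 200, seed = 2)
  expect_gt(length(trmu$times), 0)
  expect_gt(max(trmu$states), 0)
})

test_that("trajectories are valid sample paths and seed-reproducible", {
  p <- model_params(30, s = 0.1, mu = 0.001)
  tr <- simulate_trajectory(p, i0 = 3, t_max = 100, seed = 42)
  expect_true(all(diff(tr$times) > 0))
  steps <- diff(c(tr$i0, tr$states))
  expect_true(all(abs(steps) == 1))
  expect_true(all(tr$states >= 0 & tr$states <= 30))
  # absorbed-at-N paths stop jumping
  if (tr$absorbed && tr$final_state == 30)
    expect_identical(tr$states[length(tr$states)], 30L)
  tr2 <- simulate_trajectory(p, i0 = 3, t_max = 100, seed = 42)
  expect_identical(tr$times, tr2$times)
  expect_identical(tr$states, tr2$states)
  # and the caller's RNG stream is untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(simulate_trajectory(p, 3, 10, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("event cap signals runaway simulations", {
  p <- model_params(1000, s = 0.01, mu = 0)
  expect_error(simulate_trajectory(p, 500, t_max = 1000, max_events = 10),
               "event-count cap")
})

test_that("sampling a trajectory is right-continuous piecewise-constant", {
  # hand-built 3-jump path: i0=2, jumps at t=1 (->3), 2.5 (->2), 4 (->3)
  tr <- make_trajectory(times = c(1, 2.5, 4), states = c(3L, 2L, 3L),
                        i0 = 2L, N = 10, t_end = 5)
  expect_identical(sample_at_times(tr, 0), 2L)       # before first jump
  expect_identical(sample_at_times(tr, 0.99), 2L)
  expect_identical(sample_at_times(tr, 1), 3L)       # right-continuity
  expect_identical(sample_at_times(tr, c(1.7, 2.5, 3.2, 4.5)),
                   c(3L, 2L, 2L, 3L))
  expect_error(sample_at_times(tr, 5.1), "beyond simulated horizon")
  # absorbed trajectories may be queried arbitrarily far ahead
  trN <- make_trajectory(times = c(1, 2), states = c(9L, 10L), i0 = 8L,
                         N = 10, t_end = 2, absorbed = TRUE)
  expect_identical(sample_at_times(trN, 1e6), 10L)
})

test_that("ensemble summary reduces to a single trajectory at n_reps = 1", {
  p <- model_params(50, s = 0.05, mu = 0.001)
  grid <- seq(0, 40, 5)
  es <- ensemble_summary(p, i0 = 10, t_grid = grid, n_reps = 1, seed = 11)
  seed1 <- getFromNamespace("spawn_seeds", "moranselect")(11, 1)
  tr <- simulate_trajectory(p, 10, t_max = 40 + 1e-9, seed = seed1)
  expect_equal(es$mean_freq, sample_at_times(tr, grid) / 50)
  expect_equal(es$sd_freq, rep(0, length(grid)))
})

test_that("ensemble frequencies are bounded and reproducible", {
  p <- model_params(200, s = 0.05, mu = 1e-4)
  grid <- seq(0, 60, 10)
  es1 <- ensemble_summary(p, 40, grid, n_reps = 30, seed = 5)
  es2 <- ensemble_summary(p, 40, grid, n_reps = 30, seed = 5)
  expect_equal(es1$mean_freq, es2$mean_freq)
  expect_true(all(es1$mean_freq >= 0 & es1$mean_freq <= 1))
  expect_true(all(es1$sd_freq >= 0))
  expect_equal(es1$mean_freq[1], 0.2)  # exact at t = 0
  expect_equal(es1$sd_freq[1], 0)
})

test_that("Monte-Carlo fixation fraction agrees with the closed form", {
  # moderate-scale check (99.9% interval); the acceptance suite runs the
  # full-size 99% version
  p <- model_params(15, s = 0.15, mu = 0)
  n <- 1000
  seeds <- getFromNamespace("spawn_seeds", "moranselect")(303, n)
  fixed <- vapply(seeds, function(sd) {
    simulate_trajectory(p, 1, t_max = Inf, seed = sd)$final_state == 15L
  }, logical(1))
  x <- sum(fixed)
  ci <- c(qbeta(5e-4, x, n - x + 1), qbeta(1 - 5e-4, x + 1, n - x))
  phi <- fixation_probability(1, 15, 0.15)
  expect_gte(phi, ci[1])
  expect_lte(phi, ci[2])
})
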