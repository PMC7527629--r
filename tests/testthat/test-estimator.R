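test_that("alpha transform and odds follow their definitions", {
  expect_equal(alpha_of(0.5, 0), 1)
  expect_equal(alpha_of(0.24, 0), 1 / 0.315789473684211, tolerance = 1e-12)
  expect_equal(round(1 / alpha_of(0.24, 0), 2), 0.32)  # tabulated odds convention
  expect_equal(alpha_of(0.2, 0.1), 0.8 / 0.3)
  # strictly decreasing in y and in u
  expect_true(all(diff(alpha_of(seq(0.1, 0.9, 0.1), 0.05)) < 0))
  expect_lt(alpha_of(0.3, 0.2), alpha_of(0.3, 0.1))
  expect_error(alpha_of(1, 0), "\\(0, 1\\)")
  # at u = 0, alpha is the reciprocal odds
  y <- c(0.1, 0.43, 0.83)
  expect_equal(alpha_of(y, 0) * y / (1 - y), rep(1, 3))
})

test_that("two-point estimate reproduces hand-checked values", {
  # published AML-phase transition: y 0.56 -> 0.83 over 3 years
  obs <- two_point_observation(0.56, 0.83, 3, lambda = 24,
                               phase = "AML", mutation = "Q726X")
  e <- estimate_s_given_u(obs, u = 0)
  expect_equal(round(e$s_hat, 3), 0.019)
  expect_equal(e$dt_generations, 72)
  expect_equal(round(e$odds0, 2), 1.27)
  expect_equal(round(e$odds1, 2), 4.88)
  expect_equal(e$mu_implied, 0)
  # u = 0 estimate equals the log odds-ratio per generation
  expect_equal(e$s_hat, log((0.83 / 0.17) / (0.56 / 0.44)) / 72,
               tolerance = 1e-14)
  # no change, no selection
  flat <- two_point_observation(0.4, 0.4, 2)
  expect_equal(estimate_s_given_u(flat)$s_hat, 0)
})

test_that("estimate sign tracks the direction of frequency change", {
  up <- estimate_s_given_u(two_point_observation(0.1, 0.4, 1))
  down <- estimate_s_given_u(two_point_observation(0.4, 0.1, 1))
  expect_gt(up$s_hat, 0)
  expect_lt(down$s_hat, 0)
  # shrinking-clone published case: y 0.13 -> 0.07 over 0.45 years
  shrink <- estimate_s_given_u(two_point_observation(0.13, 0.07, 0.45))
  expect_lt(shrink$s_hat, 0)
  expect_equal(round(shrink$s_hat, 3), -0.063)
})

test_that("estimates scale exactly as 1/lambda and are N-free", {
  obs <- two_point_observation(0.43, 0.65, 0.75, lambda = 24)
  base <- estimate_s_given_u(obs)$s_hat
  expect_equal(round(base, 3), 0.050)
  sens <- sensitivity_to_lambda(obs, c(12, 24, 48, 96))
  expect_equal(sens$s_hat, base * 24 / sens$lambda, tolerance = 1e-12)
  expect_equal(sens$s_hat[sens$lambda == 48], base / 2)
  # the product s_hat * lambda is lambda-invariant
  expect_equal(unique(round(sens$s_hat * sens$lambda, 12)),
               round(base * 24, 12))
  expect_error(sensitivity_to_lambda(obs, c(24, 0)), "> 0")
})

test_that("trade-off curve is continuous, monotone, and anchored at u = 0", {
  obs <- two_point_observation(0.2, 0.6, 4)
  single <- tradeoff_curve(obs, 0)
  expect_equal(nrow(single), 1L)
  expect_equal(single$s_hat, estimate_s_given_u(obs, 0)$s_hat)
  u_grid <- seq(0, 1, 0.01)
  tc <- tradeoff_curve(obs, u_grid)
  expect_true(all(diff(tc$s_hat) < 0))           # nonincreasing for growth
  expect_true(all(tc$s_hat <= tc$s_hat[1]))
  expect_true(all(abs(diff(tc$s_hat)) < 0.05 * tc$s_hat[1]))  # no jumps
  # small u barely moves the estimate
  expect_lt(abs(tradeoff_curve(obs, 1e-4)$s_hat - tc$s_hat[1]),
            1e-3 * tc$s_hat[1])
  expect_equal(tc$mu_implied, tc$u * tc$s_hat)
})

test_that("observation container validates its domain", {
  expect_error(two_point_observation(0, 0.5, 1), "strictly in \\(0, 1\\)")
  expect_error(two_point_observation(0.5, 1, 1), "strictly in \\(0, 1\\)")
  expect_error(two_point_observation(0.2, 0.5, 0), "dt_years")
  expect_error(two_point_observation(0.2, 0.5, 1, lambda = -2), "lambda")
  expect_error(two_point_observation(0.2, 0.5, 1, phase = "CML"), "phase")
})

test_that("estimate_table appends estimates row-wise", {
  df <- data.frame(case_id = c("a", "b"), y0 = c(0.1, 0.3),
                   y1 = c(0.3, 0.35), dt_years = c(4.5, 0.33))
  out <- estimate_table(df)
  expect_equal(nrow(out), 2)
  expect_true(all(c("odds0", "odds1", "dt_generations", "s_hat",
                    "mu_implied") %in% names(out)))
  expect_equal(out$s_hat[1],
               estimate_s_given_u(two_point_observation(0.1, 0.3, 4.5))$s_hat)
  # lambda override rescales
  out12 <- estimate_table(df, lambda = 12)
  expect_equal(out12$s_hat, out$s_hat * 2)
  expect_error(estimate_table(df[, c("y0", "y1")]), "missing required column")
})
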