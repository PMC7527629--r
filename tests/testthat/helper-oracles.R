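# Independent oracles used by the tests. These deliberately avoid the
# code paths they check.

# Fixation probability by first-step analysis: solve the linear system
# h(i) = p_up h(i+1) + p_down h(i-1) + (1 - p_up - p_down) h(i),
# h(0) = 0, h(N) = 1, for the mutation-free discrete chain.
fixation_prob_linear_system <- function(N, s) {
  if (N < 2) stop("need N >= 2")
  n <- N - 1
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    w <- (1 - s) * (N - i) + i
    p_up <- (N - i) / N * i / w
    p_down <- i / N * (1 - s) * (N - i) / w
    A[i, i] <- p_up + p_down
    if (i > 1) A[i, i - 1] <- -p_down
    if (i < n) A[i, i + 1] <- -p_up
    if (i == n) b[i] <- p_up  # h(N) = 1
  }
  c(0, solve(A, b), 1)
}

# Numerical integration of the mean-field ODE, as an oracle for the
# closed-form curve (requires deSolve).
mean_frequency_numeric <- function(t, y0, s, mu = 0, t0 = 0) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  rhs <- function(t, y, parms) list((1 - y) * y * parms$s + parms$mu * (1 - y))
  times <- sort(unique(c(t0, t)))
  sol <- deSolve::ode(y = c(y = y0), times = times, func = rhs,
                      parms = list(s = s, mu = mu),
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  sol[match(t, sol[, "time"]), "y"]
}

# exact 99% (Clopper-Pearson) binomial interval for a Monte-Carlo count
binom_ci99 <- function(x, n) {
  lower <- if (x == 0) 0 else qbeta(0.005, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(0.995, x + 1, n - x)
  c(lower, upper)
}

# hand-built sparse trajectory for interpolation tests
make_trajectory <- function(times, states, i0, N, t_end = max(times),
                            absorbed = FALSE) {
  structure(list(times = times, states = states, i0 = i0,
                 t_end = t_end, absorbed = absorbed,
                 final_state = if (length(states)) states[length(states)] else i0,
                 params = model_params(N, s = 0.1), seed = NULL),
            class = "moran_trajectory")
}
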