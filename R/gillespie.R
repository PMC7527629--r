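# Exact stochastic simulation of the time-continuous Moran chain.
# The event loop lives in src/gillespie.cpp; these wrappers own seeding,
# validation and the sparse trajectory container.

default_event_cap <- function(N, t_max) {
  # generous guard against runaway parameter mistakes; total event rate is
  # O(N) per generation, so 10*N*t_max is far above any sane realization
  10 * N * min(t_max, 1e4) + 1e6
}

#' Simulate one trajectory of the Moran chain (Gillespie algorithm)
#'
#' Exact simulation of the time-continuous Moran process with selection
#' and recurrent mutation: from state `i` the holding time is exponential
#' with rate `q_up + q_down` (see [continuous_rates()]) and the jump goes
#' up with probability `q_up / (q_up + q_down)`. Simulation stops at
#' `t_max` or at absorption (state `N`; also state 0 when `mu = 0`).
#' Trajectories are stored sparsely as jump times plus post-jump states.
#'
#' @param params A [model_params()] object.
#' @param i0 Initial mutant count in `[0, N]`.
#' @param t_max Time horizon in generations (`Inf` allowed when the chain
#'   is certain to absorb, e.g. `mu = 0`).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param max_events Event-count cap; exceeding it raises an error.
#' @return A `moran_trajectory`: list with `times` (strictly increasing
#'   jump times), `states` (mutant counts after each jump), `i0`,
#'   `t_end`, `absorbed`, `final_state`, `params`, `seed`.
#' @examples
#' tr <- simulate_trajectory(model_params(50, s = 0.1), i0 = 5,
#'                           t_max = 100, seed = 1)
#' head(as.data.frame(tr))
#' @export
simulate_trajectory <- function(params, i0, t_max, seed = NULL,
                                max_events = NULL) {
  stopifnot(inherits(params, "moran_params"))
  check_state(i0, params$N)
  if (!is.numeric(t_max) || length(t_max) != 1L || is.na(t_max) || t_max <= 0)
    stop_invalid("t_max must be > 0")
  if (is.null(max_events)) max_events <- default_event_cap(params$N, t_max)
  raw <- with_seed(seed, cpp_simulate_trajectory(
    params$N, params$s, params$mu, as.integer(i0), t_max, max_events))
  structure(
    list(times = raw$times, states = raw$states, i0 = as.integer(i0),
         t_end = raw$t_end, absorbed = raw$absorbed,
         final_state = raw$final_state, params = params, seed = seed),
    class = "moran_trajectory")
}

#' @export
print.moran_trajectory <- function(x, ...) {
  cat(sprintf(
    "Moran trajectory: %d jumps over %.3g generations (N = %d, s = %g, mu = %g)\n",
    length(x$times), x$t_end, x$params$N, x$params$s, x$params$mu))
  cat(sprintf("  i0 = %d -> final state %d%s\n", x$i0, x$final_state,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' @export
as.data.frame.moran_trajectory <- function(x, ...) {
  data.frame(time = c(0, x$times),
             count = c(x$i0, x$states),
             frequency = c(x$i0, x$states) / x$params$N)
}

#' Sample a trajectory at arbitrary times
#'
#' Piecewise-constant, right-continuous interpolation of a sparse
#' trajectory: the value at `t` is the state after the last jump at or
#' before `t` (the initial count before the first jump). Times beyond the
#' simulated horizon are allowed only if the trajectory was absorbed
#' (the absorbing state holds forever).
#'
#' @param traj A `moran_trajectory`.
#' @param t_grid Numeric vector of query times, each `>= 0`.
#' @return Integer mutant counts at each query time.
#' @export
sample_at_times <- function(traj, t_grid) {
  stopifnot(inherits(traj, "moran_trajectory"))
  if (any(t_grid < 0)) stop_invalid("query times must be >= 0")
  if (!traj$absorbed && any(t_grid > traj$t_end))
    stop_invalid("query time beyond simulated horizon t_max = ", traj$t_end)
  all_states <- c(traj$i0, traj$states)
  all_states[findInterval(t_grid, traj$times) + 1L]
}

#' Ensemble mean and standard deviation of mutant frequency
#'
#' Runs `n_reps` independent trajectories and summarises the mutant
#' frequency `X(t)/N` on a time grid: per-point mean and standard
#' deviation across replicates. Per-replicate seeds are derived
#' deterministically from `seed`, so the ensemble is reproducible.
#' Replicates are simulated directly onto the grid (no jump storage), so
#' memory is independent of `N`.
#'
#' @param params A [model_params()] object.
#' @param i0 Initial mutant count.
#' @param t_grid Increasing sampling times (generations).
#' @param n_reps Number of replicate trajectories, `>= 1`.
#' @param seed Master seed (optional).
#' @param max_events Per-replicate event cap.
#' @return A `moran_ensemble`: list with `t_grid`, `mean_freq`, `sd_freq`,
#'   `n_reps`, `params`, `i0`, `seed`.
#' @examples
#' es <- ensemble_summary(model_params(200, s = 0.05), i0 = 40,
#'                        t_grid = seq(0, 50, 10), n_reps = 20, seed = 7)
#' as.data.frame(es)
#' @export
ensemble_summary <- function(params, i0, t_grid, n_reps, seed = NULL,
                             max_events = NULL) {
  stopifnot(inherits(params, "moran_params"))
  check_state(i0, params$N)
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  if (is.unsorted(t_grid, strictly = FALSE) || any(t_grid < 0))
    stop_invalid("t_grid must be nondecreasing and nonnegative")
  if (is.null(max_events))
    max_events <- default_event_cap(params$N, max(t_grid))
  seeds <- spawn_seeds(seed, n_reps)
  freq <- matrix(NA_real_, nrow = n_reps, ncol = length(t_grid))
  for (r in seq_len(n_reps)) {
    freq[r, ] <- with_seed(seeds[r], cpp_simulate_on_grid(
      params$N, params$s, params$mu, as.integer(i0),
      as.numeric(t_grid), max_events)) / params$N
  }
  structure(
    list(t_grid = as.numeric(t_grid),
         mean_freq = colMeans(freq),
         sd_freq = if (n_reps > 1) apply(freq, 2, sd) else rep(0, length(t_grid)),
         n_reps = n_reps, params = params, i0 = as.integer(i0), seed = seed),
    class = "moran_ensemble")
}

#' @export
print.moran_ensemble <- function(x, ...) {
  cat(sprintf(
    "Moran ensemble: %d replicates on %d grid points (N = %d, s = %g, mu = %g)\n",
    x$n_reps, length(x$t_grid), x$params$N, x$params$s, x$params$mu))
  invisible(x)
}

#' @export
as.data.frame.moran_ensemble <- function(x, ...) {
  data.frame(time = x$t_grid, mean_freq = x$mean_freq, sd_freq = x$sd_freq)
}

# initial count from a target frequency: nearest integer on the N-grid
i0_from_frequency <- function(y0, N) {
  i0 <- as.integer(round(y0 * N))
  min(max(i0, 0L), as.integer(N))
}
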