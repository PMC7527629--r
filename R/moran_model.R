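#' Moran model parameters
#'
#' Bundles the three parameters of the Moran process with directional
#' selection and recurrent mutation: the constant population size `N`
#' (cells), the selection coefficient `s` (dimensionless; the wildtype
#' reproduces with weight `1 - s`), and the recurrent mutation rate `mu`
#' (per wildtype cell per generation). Time is measured in generations —
#' one expected division per cell; conversion to calendar years happens
#' only in the estimator via the divisions-per-year rate `lambda`.
#'
#' @param N Integer population size, `>= 2`.
#' @param s Selection coefficient, `0 <= s < 1`.
#' @param mu Mutation rate per wildtype cell per generation, `>= 0`.
#' @return An object of class `moran_params`.
#' @examples
#' model_params(N = 10000, s = 0.01, mu = 1e-6)
#' @export
model_params <- function(N, s = 0, mu = 0) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop_invalid("N must be a single integer >= 2")
  if (length(s) != 1L || !is.finite(s) || s < 0 || s >= 1)
    stop_invalid("s must lie in [0, 1)")
  if (length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop_invalid("mu must be >= 0")
  structure(list(N = as.integer(N), s = s, mu = mu), class = "moran_params")
}

#' @export
print.moran_params <- function(x, ...) {
  cat(sprintf("Moran model: N = %d cells, s = %g, mu = %g per cell per generation\n",
              x$N, x$s, x$mu))
  invisible(x)
}

check_state <- function(i, N) {
  if (any(i < 0 | i > N | i != round(i)))
    stop_invalid("mutant count i must be an integer in [0, N]")
}

#' Discrete-time Moran transition probabilities
#'
#' One step of the discrete-time Moran chain with directional selection:
#' a uniformly chosen cell dies and is replaced by the offspring of a cell
#' chosen with weight `1 - s` for wildtype and 1 for mutant. Only the
#' events "wildtype dies, mutant reproduces" and "mutant dies, wildtype
#' reproduces" change the mutant count `i`, giving
#' \deqn{p_{i,i+1} = \frac{N-i}{N}\,\frac{i}{(1-s)(N-i)+i}, \qquad
#'       p_{i,i-1} = \frac{i}{N}\,\frac{(1-s)(N-i)}{(1-s)(N-i)+i};}
#' the remainder is the self-transition. States 0 and `N` are absorbing
#' (no recurrent mutation in the discrete chain).
#'
#' @param i Mutant count, integer in `[0, N]`.
#' @param N Population size.
#' @param s Selection coefficient in `[0, 1)`.
#' @return Named numeric vector `c(p_up, p_down)`.
#' @examples
#' discrete_transition_probs(i = 2, N = 4, s = 0.5)  # c(1/3, 1/6)
#' @export
discrete_transition_probs <- function(i, N, s) {
  if (s < 0 || s >= 1) stop_invalid("s must lie in [0, 1)")
  check_state(i, N)
  w <- (1 - s) * (N - i) + i
  if (w == 0) return(c(p_up = 0, p_down = 0))  # i = 0, s -> degenerate guard
  c(p_up = (N - i) / N * i / w,
    p_down = i / N * (1 - s) * (N - i) / w)
}

#' Continuous-time Moran transition rates with recurrent mutation
#'
#' Transition intensities of the time-continuous chain: in addition to the
#' selection-biased birth-death events, each of the `N - i` wildtype cells
#' independently mutates at rate `mu`, so state 0 is no longer absorbing
#' when `mu > 0` — transiently extinct clones are re-seeded by recurrent
#' mutation. State `N` (fixation) is always absorbing.
#' \deqn{q_{i,i+1} = \frac{(N-i)i}{N} + \mu(N-i), \qquad
#'       q_{i,i-1} = \frac{i(1-s)(N-i)}{N}.}
#'
#' @param i Mutant count, integer in `[0, N]`.
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(q_up, q_down)` (per generation).
#' @examples
#' continuous_rates(10, model_params(100, s = 0.01, mu = 0.001))
#' @export
continuous_rates <- function(i, params) {
  stopifnot(inherits(params, "moran_params"))
  check_state(i, params$N)
  N <- params$N
  c(q_up = (N - i) * i / N + params$mu * (N - i),
    q_down = i * (1 - params$s) * (N - i) / N)
}

#' Fixation probability of the mutation-free Moran chain
#'
#' Probability that the chain started from `i` mutants is absorbed at `N`
#' (clone fixation) rather than 0 (clone extinction), for the chain
#' without recurrent mutation:
#' \deqn{P[T_N < T_0] = \frac{1-(1-s)^i}{1-(1-s)^N}}
#' with the neutral limit `i/N` at `s = 0` (the formula is continuous in
#' `s`, so the neutral case is returned exactly rather than as 0/0).
#' Computed via `expm1()` on the log scale, stable for large `N`.
#'
#' @param i Initial mutant count(s), integer(s) in `[0, N]`; vectorized.
#' @param N Population size.
#' @param s Selection coefficient in `[0, 1)`.
#' @return Fixation probability/ies in `[0, 1]`.
#' @examples
#' fixation_probability(1, N = 5, s = 0.5)   # 0.516129...
#' fixation_probability(0:10, N = 10, s = 0) # i/N
#' @export
fixation_probability <- function(i, N, s) {
  if (s < 0 || s >= 1) stop_invalid("s must lie in [0, 1)")
  check_state(i, N)
  if (s == 0) return(i / N)
  expm1(i * log1p(-s)) / expm1(N * log1p(-s))
}

#' Asymptotic expected fixation time
#'
#' The large-`N` asymptotic of the expected time to fixation from a single
#' mutant under selection, `(2/s) log(N)` generations. This is a rough
#' reference quantity only — it is known to be inaccurate at moderate `N`
#' — and is never used inside estimation.
#'
#' @param N Population size (`>= 1`).
#' @param s Selection coefficient, `> 0`.
#' @return Expected fixation time in generations.
#' @examples
#' expected_fixation_time_asymptotic(10000, 0.01)  # 1842.068
#' @export
expected_fixation_time_asymptotic <- function(N, s) {
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop_invalid("s must be > 0 for the fixation-time asymptotic")
  if (any(N < 1)) stop_invalid("N must be >= 1")
  2 / s * log(N)
}
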