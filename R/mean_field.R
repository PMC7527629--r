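# Deterministic (mean-field) approximation of the expected mutant
# frequency y(t) = E[X(t)]/N, obtained by replacing X(t) with its
# expectation in the one-step conditional mean of the chain.

#' Mean-field growth rate of the mutant frequency
#'
#' Right-hand side of the mean-field ODE for the mutant frequency,
#' \deqn{\dot y = (1-y)\,y\,s + \mu (1-y),}
#' i.e. logistic growth driven by selection plus an influx from recurrent
#' mutation of the remaining wildtype fraction. Zero at `y = 1` (fixation
#' is a fixed point); equals `mu` at `y = 0`.
#'
#' @param y Mutant frequency in `[0, 1]` (vectorized).
#' @param s Selection coefficient.
#' @param mu Mutation rate per generation.
#' @return dy/dt in per-generation units.
#' @export
mean_frequency_rhs <- function(y, s, mu = 0) {
  if (any(y < 0 | y > 1)) stop_invalid("y must lie in [0, 1]")
  (1 - y) * y * s + mu * (1 - y)
}

#' Closed-form mean-field mutant frequency curve
#'
#' Explicit solution of the mean-field ODE with initial condition
#' `y(t0) = y0`. For `s > 0`, with `u = mu/s` and
#' `alpha0 = (1 - y0)/(y0 + u)`,
#' \deqn{y(t) = \frac{1 - u\,\alpha_0 e^{-(\mu+s)(t-t_0)}}
#'                   {1 + \alpha_0 e^{-(\mu+s)(t-t_0)}},}
#' which reduces to the plain logistic `1/(1 + \alpha_0 e^{-s(t-t_0)})`
#' when `mu = 0`. For `s = 0` the `u = mu/s` parameterisation is
#' undefined; the exact pure-mutation solution
#' `y(t) = 1 - (1 - y0) e^{-mu (t - t0)}` is used instead, keeping the
#' curve defined over the whole parameter space. The population size `N`
#' does not appear: the curve depends only on `(y0, s, mu)`.
#'
#' @param t Time(s) in generations, `>= t0` (vectorized).
#' @param y0 Initial frequency in `(0, 1)`.
#' @param s Selection coefficient, `>= 0`.
#' @param mu Mutation rate per generation, `>= 0`.
#' @param t0 Start time (generations), default 0.
#' @return Frequency value(s) in `(0, 1]`, nondecreasing in `t`.
#' @examples
#' mean_frequency(0:300, y0 = 0.2, s = 0.01)
#' @export
mean_frequency <- function(t, y0, s, mu = 0, t0 = 0) {
  if (length(y0) != 1L || y0 <= 0 || y0 >= 1)
    stop_invalid("y0 must lie in (0, 1)")
  if (s < 0) stop_invalid("s must be >= 0")
  if (mu < 0) stop_invalid("mu must be >= 0")
  if (any(t < t0)) stop_invalid("t must be >= t0")
  if (s == 0) return(1 - (1 - y0) * exp(-mu * (t - t0)))
  u <- mu / s
  alpha0 <- (1 - y0) / (y0 + u)
  E <- exp(-(mu + s) * (t - t0))
  (1 - u * alpha0 * E) / (1 + alpha0 * E)
}
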