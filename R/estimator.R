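# Two-time-point selection-coefficient estimation.
#
# Inverting the closed-form mean-field curve between two observed
# frequencies (y0 at t0, y1 at t1) constrains (s, mu) only to a curve
# indexed by u = mu/s; for each assumed u the estimate is
#
#   s_hat = ln(alpha0/alpha1) / ((1 + u) * dt_generations),
#   alpha_i = (1 - y_i) / (y_i + u).
#
# Note on sign: writing the inversion as mu + s = ln(alpha1/alpha0)/dt,
# with alpha decreasing in y, would make growing clones come out negative;
# the orientation used here (alpha0 over alpha1) is the one consistent
# with alpha1 = alpha0 * exp(-(mu+s) dt) and gives s_hat > 0 iff y1 > y0.
# At u = 0 it is simply the per-generation change in log-odds:
# s_hat = ln[(y1/(1-y1)) / (y0/(1-y0))] / (lambda * dt_years).

#' Two-time-point clone-frequency observation
#'
#' One observation unit for the estimator: the mutant-clone frequency
#' (e.g. a variant allele frequency) measured at two times, the elapsed
#' calendar time, and the assumed number of stem-cell divisions per year
#' `lambda` converting years to model generations (default 24, i.e. a
#' 15-day interdivision time).
#'
#' @param y0,y1 Frequencies at the first and second sampling, in `(0, 1)`.
#' @param dt_years Elapsed time `t1 - t0` in years, `> 0`.
#' @param lambda Divisions per year, `> 0` (default 24).
#' @param case_id,phase,mutation,source Optional labels (`phase` one of
#'   `"MDS"`, `"AML"`, `"unclassified"`).
#' @return A `two_point_obs` object.
#' @examples
#' two_point_observation(0.56, 0.83, dt_years = 3)
#' @export
two_point_observation <- function(y0, y1, dt_years, lambda = 24,
                                  case_id = NA_character_,
                                  phase = NA_character_,
                                  mutation = NA_character_,
                                  source = NA_character_) {
  for (y in list(y0 = y0, y1 = y1)) {
    if (length(y) != 1L || !is.finite(y) || y <= 0 || y >= 1)
      stop_invalid("frequencies must lie strictly in (0, 1); got ", y)
  }
  if (!is.finite(dt_years) || dt_years <= 0)
    stop_invalid("dt_years must be > 0")
  if (!is.finite(lambda) || lambda <= 0)
    stop_invalid("lambda must be > 0")
  if (!is.na(phase) && !phase %in% c("MDS", "AML", "unclassified"))
    stop_invalid("phase must be MDS, AML or unclassified")
  structure(list(y0 = y0, y1 = y1, dt_years = dt_years, lambda = lambda,
                 case_id = case_id, phase = phase, mutation = mutation,
                 source = source),
            class = "two_point_obs")
}

#' @export
print.two_point_obs <- function(x, ...) {
  cat(sprintf("Two-point observation%s: y0 = %g -> y1 = %g over %g years (lambda = %g/yr)\n",
              if (is.na(x$case_id)) "" else paste0(" [", x$case_id, "]"),
              x$y0, x$y1, x$dt_years, x$lambda))
  invisible(x)
}

#' Alpha transform of a frequency
#'
#' The quantity `alpha = (1 - y)/(y + u)` appearing in the closed-form
#' curve and the estimator; strictly decreasing in both `y` and `u`. At
#' `u = 0` it is the reciprocal of the odds `y/(1 - y)` (published tables
#' of these data tabulate the odds convention).
#'
#' @param y Frequency in `(0, 1)` (vectorized).
#' @param u Mutation-to-selection ratio `mu/s`, `>= 0`.
#' @return Positive value(s) of the transform.
#' @export
alpha_of <- function(y, u = 0) {
  if (any(y <= 0 | y >= 1)) stop_invalid("y must lie in (0, 1)")
  if (u < 0) stop_invalid("u must be >= 0")
  (1 - y) / (y + u)
}

#' Estimate the selection coefficient from two frequencies
#'
#' Inverts the closed-form mean-field curve between two observed clone
#' frequencies under an assumed mutation-to-selection ratio `u = mu/s`:
#' `s_hat = ln(alpha0/alpha1) / ((1 + u) * lambda * dt_years)`. At
#' `u = 0` this is the change in log-odds per generation. The estimate is
#' positive exactly when the clone grew, is independent of the population
#' size `N`, and scales as `1/lambda` at fixed `u`. The implied mutation
#' rate `u * s_hat` is returned alongside.
#'
#' @param obs A [two_point_observation()] (or a bare list with fields
#'   `y0`, `y1`, `dt_years`, `lambda`).
#' @param u Assumed ratio `mu/s`, `>= 0` (default 0: mutation-free).
#' @return A `selection_estimate`: list with `s_hat`, `u`, `mu_implied`,
#'   `alpha0`, `alpha1`, `odds0`, `odds1`, `dt_generations`, `obs`.
#' @examples
#' obs <- two_point_observation(0.56, 0.83, dt_years = 3)
#' estimate_s_given_u(obs)  # s_hat = 0.0187 (rounds to 0.019)
#' @export
estimate_s_given_u <- function(obs, u = 0) {
  if (!inherits(obs, "two_point_obs"))
    obs <- two_point_observation(obs$y0, obs$y1, obs$dt_years,
                                 if (is.null(obs$lambda)) 24 else obs$lambda)
  if (length(u) != 1L || !is.finite(u) || u < 0)
    stop_invalid("u must be a single value >= 0")
  dt_gen <- obs$lambda * obs$dt_years
  a0 <- alpha_of(obs$y0, u)
  a1 <- alpha_of(obs$y1, u)
  s_hat <- log(a0 / a1) / ((1 + u) * dt_gen)
  structure(list(s_hat = s_hat, u = u, mu_implied = u * s_hat,
                 alpha0 = a0, alpha1 = a1,
                 odds0 = obs$y0 / (1 - obs$y0),
                 odds1 = obs$y1 / (1 - obs$y1),
                 dt_generations = dt_gen, obs = obs),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("Selection estimate: s_hat = %.4g per generation (u = %g, implied mu = %.3g)\n",
              x$s_hat, x$u, x$mu_implied))
  cat(sprintf("  odds %0.3g -> %0.3g over %g generations\n",
              x$odds0, x$odds1, x$dt_generations))
  invisible(x)
}

#' Mutation-selection trade-off curve
#'
#' One two-point observation constrains `(s, mu)` only to a curve: for
#' each assumed `u = mu/s` in `u_grid` the estimate is recomputed, tracing
#' the set of `(mu, s)` pairs compatible with the observed frequency
#' change. For a growing clone `s_hat(u)` is continuous and nonincreasing
#' in `u`, so any positive mutation rate can only lower the selection
#' estimate relative to the mutation-free value.
#'
#' @param obs A [two_point_observation()].
#' @param u_grid Nonnegative ratios to sweep.
#' @return A data.frame with columns `u`, `mu_implied`, `s_hat`,
#'   `alpha0`, `alpha1`.
#' @export
tradeoff_curve <- function(obs, u_grid) {
  if (any(u_grid < 0)) stop_invalid("all u must be >= 0")
  rows <- lapply(u_grid, function(u) {
    e <- estimate_s_given_u(obs, u)
    data.frame(u = u, mu_implied = e$mu_implied, s_hat = e$s_hat,
               alpha0 = e$alpha0, alpha1 = e$alpha1)
  })
  do.call(rbind, rows)
}

#' Sensitivity of the estimate to the divisions-per-year assumption
#'
#' The estimate depends on the assumed HSC interdivision time only
#' through the conversion of calendar time to generations, so at fixed
#' `u` it scales exactly as `1/lambda`: doubling the assumed divisions
#' per year halves `s_hat`.
#'
#' @param obs A [two_point_observation()].
#' @param lambda_values Positive divisions-per-year values to sweep.
#' @param u Assumed `mu/s` ratio (default 0).
#' @return A data.frame with columns `lambda`, `dt_generations`, `s_hat`,
#'   `mu_implied`.
#' @export
sensitivity_to_lambda <- function(obs, lambda_values, u = 0) {
  if (any(lambda_values <= 0)) stop_invalid("all lambda must be > 0")
  rows <- lapply(lambda_values, function(lam) {
    o <- obs; o$lambda <- lam
    e <- estimate_s_given_u(o, u)
    data.frame(lambda = lam, dt_generations = e$dt_generations,
               s_hat = e$s_hat, mu_implied = e$mu_implied)
  })
  do.call(rbind, rows)
}

#' Estimate selection coefficients for a table of observations
#'
#' Row-wise application of [estimate_s_given_u()] to a data.frame with
#' columns `y0`, `y1`, `dt_years` and optionally `lambda` (default 24).
#' Appends `odds0`, `odds1`, `dt_generations`, `s_hat`, `mu_implied`.
#'
#' @param df Input data.frame.
#' @param u Assumed `mu/s` ratio.
#' @param lambda Optional override applied to every row.
#' @return `df` with the five estimate columns appended.
#' @export
estimate_table <- function(df, u = 0, lambda = NULL) {
  need <- c("y0", "y1", "dt_years")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_invalid("input is missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  lam <- if (!is.null(lambda)) rep(lambda, nrow(df))
         else if ("lambda" %in% names(df)) df$lambda
         else rep(24, nrow(df))
  out <- df
  out$odds0 <- out$odds1 <- out$dt_generations <- out$s_hat <-
    out$mu_implied <- NA_real_
  for (k in seq_len(nrow(df))) {
    obs <- two_point_observation(df$y0[k], df$y1[k], df$dt_years[k], lam[k])
    e <- estimate_s_given_u(obs, u)
    out$odds0[k] <- e$odds0
    out$odds1[k] <- e$odds1
    out$dt_generations[k] <- e$dt_generations
    out$s_hat[k] <- e$s_hat
    out$mu_implied[k] <- e$mu_implied
  }
  out
}
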