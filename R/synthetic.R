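# Synthetic two-time-point observations with known ground truth, for
# end-to-end validation of the estimator against the stochastic model it
# assumes. A scenario fixes the true (N, s, mu), the target initial
# frequency, the sampling interval, and an optional binomial read-depth
# noise model standing in for sequencing-limited frequency calls (the
# clinical sources publish no measurement model; binomial sampling is
# this package's stand-in, and depth defaults to infinite = noise-free).

#' Define a synthetic two-time-point scenario
#'
#' @param params True [model_params()] (ground-truth `N`, `s`, `mu`).
#' @param y0_target Target initial frequency in `(0, 1)`; the initial
#'   mutant count is `round(y0_target * N)`.
#' @param dt_years Sampling interval in years, `> 0`.
#' @param lambda Divisions per year (default 24).
#' @param read_depth Sequencing depth for binomial frequency noise;
#'   `Inf` (default) for exact, noise-free frequencies.
#' @param n_reps Number of replicate observations the scenario supports.
#' @param seed Master seed; per-replicate seeds are derived from it, so
#'   replicate `k` is reproducible in isolation.
#' @return A `synthetic_scenario` object.
#' @examples
#' scn <- synthetic_scenario(model_params(1000, s = 0.05), y0_target = 0.2,
#'                           dt_years = 1, n_reps = 10, seed = 42)
#' generate_observation(scn, 1)
#' @export
synthetic_scenario <- function(params, y0_target = 0.2, dt_years, lambda = 24,
                               read_depth = Inf, n_reps = 1, seed = 1) {
  stopifnot(inherits(params, "moran_params"))
  if (y0_target <= 0 || y0_target >= 1)
    stop_invalid("y0_target must lie in (0, 1)")
  if (dt_years <= 0) stop_invalid("dt_years must be > 0")
  if (lambda <= 0) stop_invalid("lambda must be > 0")
  if (!(is.infinite(read_depth) || (read_depth >= 1 && read_depth == round(read_depth))))
    stop_invalid("read_depth must be a positive integer or Inf")
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  structure(list(params = params, y0_target = y0_target,
                 dt_years = dt_years, lambda = lambda,
                 read_depth = read_depth, n_reps = as.integer(n_reps),
                 seed = seed,
                 rep_seeds = spawn_seeds(seed, n_reps)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: N = %d, s = %g, mu = %g; y0 ~ %g, %g years (%g gen), depth %s, %d reps\n",
    x$params$N, x$params$s, x$params$mu, x$y0_target, x$dt_years,
    x$lambda * x$dt_years,
    if (is.infinite(x$read_depth)) "Inf" else format(x$read_depth), x$n_reps))
  invisible(x)
}

# binomial read-depth noise with rejection of boundary draws (the
# estimator's domain is open (0,1); clamping would bias recovery tests)
observe_frequency <- function(y_true, depth) {
  if (is.infinite(depth)) {
    list(y = y_true, redraws = 0L, boundary_truth = (y_true <= 0 || y_true >= 1))
  } else {
    redraws <- 0L
    repeat {
      y <- rbinom(1L, depth, y_true) / depth
      if (y > 0 && y < 1) break
      redraws <- redraws + 1L
      if (redraws > 1000L)
        stop("read-depth noise: frequency ", y_true,
             " cannot produce an interior observation at depth ", depth)
    }
    list(y = y, redraws = redraws, boundary_truth = FALSE)
  }
}

#' Generate one synthetic two-time-point observation
#'
#' Simulates one Moran trajectory under the scenario's true parameters
#' over `lambda * dt_years` generations and reads the frequency at both
#' ends, through binomial read-depth noise if the scenario's depth is
#' finite. Boundary observations (0 or 1) are rejected and redrawn, with
#' the redraw count recorded in the `"redraws"` attribute. A trajectory
#' whose true terminal frequency is 0 or 1 under infinite depth cannot
#' yield a usable observation and raises an error.
#'
#' @param scn A [synthetic_scenario()].
#' @param rep_index Which replicate (`1..n_reps`); fixes the seed.
#' @return A [two_point_observation()] with attributes `y1_true` (exact
#'   terminal frequency) and `redraws`.
#' @export
generate_observation <- function(scn, rep_index = 1) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  if (rep_index < 1 || rep_index > scn$n_reps)
    stop_invalid("rep_index must lie in 1..n_reps")
  p <- scn$params
  i0 <- i0_from_frequency(scn$y0_target, p$N)
  dt_gen <- scn$lambda * scn$dt_years
  with_seed(scn$rep_seeds[rep_index], {
    i1 <- cpp_simulate_on_grid(p$N, p$s, p$mu, i0, dt_gen,
                               default_event_cap(p$N, dt_gen))
    y1_true <- i1 / p$N
    if (is.infinite(scn$read_depth) && (y1_true <= 0 || y1_true >= 1))
      stop("trajectory reached the boundary (terminal frequency ", y1_true,
           "); unusable for the open-domain estimator")
    o0 <- observe_frequency(i0 / p$N, scn$read_depth)
    o1 <- observe_frequency(y1_true, scn$read_depth)
    obs <- two_point_observation(o0$y, o1$y, scn$dt_years, scn$lambda,
                                 case_id = sprintf("synthetic_rep%03d", rep_index),
                                 source = "synthetic")
    attr(obs, "y1_true") <- y1_true
    attr(obs, "redraws") <- o0$redraws + o1$redraws
    obs
  })
}

#' Parameter-recovery experiment for the selection estimator
#'
#' For each true selection coefficient in `s_values`, generates
#' `n_reps` synthetic observations under the scenario template and
#' estimates `s` from each at `u = 0`, summarising bias, RMSE and the
#' spread of the estimates. Replicates where the trajectory hit a
#' boundary (unusable under infinite depth) are dropped and counted.
#'
#' @param s_values True selection coefficients to sweep.
#' @param scn_template A [synthetic_scenario()] whose `s` is replaced by
#'   each value in turn (its `N`, `mu`, `y0_target`, interval, depth,
#'   `n_reps` and seed are reused).
#' @return A data.frame with one row per `s`: `s_true`, `n_used`,
#'   `n_dropped`, `mean_s_hat`, `median_s_hat`, `bias`, `rmse`, `sd_s_hat`,
#'   `q025`, `q975`.
#' @examples
#' scn <- synthetic_scenario(model_params(1000, s = 0.05), y0_target = 0.2,
#'                           dt_years = 1.2, n_reps = 20, seed = 99)
#' recovery_experiment(c(0.03, 0.05), scn)
#' @export
recovery_experiment <- function(s_values, scn_template) {
  stopifnot(inherits(scn_template, "synthetic_scenario"))
  rows <- lapply(s_values, function(s_true) {
    p <- scn_template$params
    scn <- synthetic_scenario(model_params(p$N, s_true, p$mu),
                              y0_target = scn_template$y0_target,
                              dt_years = scn_template$dt_years,
                              lambda = scn_template$lambda,
                              read_depth = scn_template$read_depth,
                              n_reps = scn_template$n_reps,
                              seed = scn_template$seed)
    # warn when the mean-field endpoint is near the boundary: estimates
    # there are dominated by boundary rejection, not by s
    y1_mf <- mean_frequency(scn$lambda * scn$dt_years, scn$y0_target,
                            max(s_true, 1e-12), p$mu)
    if (y1_mf > 0.99)
      warning("expected terminal frequency ", signif(y1_mf, 3),
              " is close to 1; recovery summary may be boundary-limited")
    s_hats <- rep(NA_real_, scn$n_reps)
    for (k in seq_len(scn$n_reps)) {
      obs <- tryCatch(generate_observation(scn, k), error = function(e) NULL)
      if (!is.null(obs)) s_hats[k] <- estimate_s_given_u(obs, u = 0)$s_hat
    }
    used <- s_hats[is.finite(s_hats)]
    data.frame(s_true = s_true, n_used = length(used),
               n_dropped = scn$n_reps - length(used),
               mean_s_hat = mean(used), median_s_hat = median(used),
               bias = mean(used) - s_true,
               rmse = sqrt(mean((used - s_true)^2)),
               sd_s_hat = sd(used),
               q025 = quantile(used, 0.025, names = FALSE),
               q975 = quantile(used, 0.975, names = FALSE))
  })
  do.call(rbind, rows)
}
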