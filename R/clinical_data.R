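# The packaged clinical dataset: serial CSF3R-truncation variant allele
# frequencies from bone-marrow sequencing of severe congenital neutropenia
# patients progressing to MDS/AML, curated from three source publications
# (Klimiankou et al. 2019; Beekman et al. 2012; Skokowa et al. 2014).
# Only cases with an unambiguous monotone frequency trend are included.
# The printed_* columns carry the published odds and selection-coefficient
# values exactly as printed, for comparison against recomputation.

#' Load the packaged CSF3R clone-frequency dataset
#'
#' Fourteen two-time-point observations of mutant-CSF3R clone frequency
#' in SCN patients, one row per patient/phase: observed frequencies `y0`,
#' `y1`, elapsed years `dt_years`, the assumed divisions-per-year rate
#' `lambda = 24`, disease phase (`MDS`, `AML`, or `unclassified` for the
#' cases published only as "CN-MDS/AML"), the CSF3R variant, and the
#' published odds (`printed_odds0`, `printed_odds1`) and selection
#' coefficient (`printed_s_hat`) for each row.
#'
#' @return A 14-row data.frame.
#' @examples
#' tab <- load_table1()
#' subset(tab, phase == "MDS")
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "csf3r_clone_frequencies.csv",
                      package = "moranselect", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 14L, all(df$lambda == 24))
  df
}

#' Reproduce the published per-patient selection estimates
#'
#' Re-runs the two-time-point estimator on every row of the packaged
#' dataset and compares, at printed precision (odds to 2 decimals, s_hat
#' to 3 decimals), against the published values. Rows whose published
#' numbers are not recovered from the rounded printed inputs are flagged,
#' not altered: the printed frequencies are rounded readings of source
#' figures, so recomputation from them cannot always match the authors'
#' unrounded spreadsheet.
#'
#' @param u Assumed mutation-to-selection ratio (default 0, as published).
#' @param lambda Optional divisions-per-year override.
#' @return A data.frame with one row per record: the inputs, computed
#'   `odds0`/`odds1`/`s_hat` (full precision and rounded), the printed
#'   values, and logical `match_odds0`, `match_odds1`, `match_s_hat`,
#'   `match_all` flags.
#' @examples
#' rep <- reproduce_table1()
#' rep$identifier[rep$match_s_hat]   # rows whose published s-hat reproduces
#' @export
reproduce_table1 <- function(u = 0, lambda = NULL) {
  tab <- load_table1()
  est <- estimate_table(tab[, c("y0", "y1", "dt_years", "lambda")],
                        u = u, lambda = lambda)
  out <- data.frame(
    identifier = tab$identifier, case_label = tab$case_label,
    phase = tab$phase, mutation = tab$mutation,
    y0 = tab$y0, y1 = tab$y1, dt_years = tab$dt_years,
    lambda = est$dt_generations / tab$dt_years,
    odds0 = est$odds0, odds1 = est$odds1, s_hat = est$s_hat,
    odds0_rounded = round(est$odds0, 2),
    odds1_rounded = round(est$odds1, 2),
    s_hat_rounded = round(est$s_hat, 3),
    printed_odds0 = tab$printed_odds0,
    printed_odds1 = tab$printed_odds1,
    printed_s_hat = tab$printed_s_hat,
    stringsAsFactors = FALSE)
  out$match_odds0 <- out$odds0_rounded == out$printed_odds0
  out$match_odds1 <- out$odds1_rounded == out$printed_odds1
  out$match_s_hat <- out$s_hat_rounded == out$printed_s_hat
  out$match_all <- out$match_odds0 & out$match_odds1 & out$match_s_hat
  out
}

#' Association between estimated selection and observation interval
#'
#' Summarises per-case selection estimates against the elapsed time
#' between the two sequencing instances: Pearson and Spearman
#' correlations (reported both including and excluding negative
#' estimates, since a single shrinking clone is an influential point),
#' per-phase mean estimates, and the labelled scatter data. A negative
#' association is the expected signature of ascertainment: faster
#' progression (larger s) triggers the second sequencing sooner.
#'
#' @param estimates Optional data.frame with columns `identifier`,
#'   `s_hat`, `dt_years` and optionally `phase`; by default the packaged
#'   dataset's published estimates are used.
#' @return A list with `pearson`, `spearman`, `pearson_positive_only`,
#'   `spearman_positive_only`, `phase_means` (named vector), and
#'   `scatter` (data.frame `identifier`, `s_hat`, `dt_years`, `phase`).
#' @examples
#' fig3_summary()$pearson   # negative
#' @export
fig3_summary <- function(estimates = NULL) {
  if (is.null(estimates)) {
    tab <- load_table1()
    estimates <- data.frame(identifier = tab$identifier,
                            s_hat = tab$printed_s_hat,
                            dt_years = tab$dt_years,
                            phase = tab$phase,
                            stringsAsFactors = FALSE)
  }
  if (!all(c("s_hat", "dt_years") %in% names(estimates)))
    stop_invalid("estimates must have columns s_hat and dt_years")
  ok <- is.finite(estimates$s_hat) & is.finite(estimates$dt_years)
  estimates <- estimates[ok, , drop = FALSE]
  if (nrow(estimates) < 3L)
    stop_invalid("need at least 3 records with valid estimates")
  if (sd(estimates$s_hat) == 0 || sd(estimates$dt_years) == 0)
    stop_invalid("correlation undefined: zero variance in s_hat or dt_years")
  pos <- estimates[estimates$s_hat > 0, , drop = FALSE]
  cor_or_na <- function(d, method) {
    if (nrow(d) < 3L || sd(d$s_hat) == 0 || sd(d$dt_years) == 0) return(NA_real_)
    cor(d$s_hat, d$dt_years, method = method)
  }
  phase <- if ("phase" %in% names(estimates)) estimates$phase
           else rep("unclassified", nrow(estimates))
  list(
    pearson = cor(estimates$s_hat, estimates$dt_years),
    spearman = cor(estimates$s_hat, estimates$dt_years, method = "spearman"),
    pearson_positive_only = cor_or_na(pos, "pearson"),
    spearman_positive_only = cor_or_na(pos, "spearman"),
    phase_means = tapply(estimates$s_hat, phase, mean),
    scatter = data.frame(
      identifier = if ("identifier" %in% names(estimates))
        estimates$identifier else seq_len(nrow(estimates)),
      s_hat = estimates$s_hat, dt_years = estimates$dt_years,
      phase = phase, stringsAsFactors = FALSE))
}
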