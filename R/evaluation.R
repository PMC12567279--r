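# PK summary metrics and model-qualification statistics.

#' Pharmacokinetic metrics over the final dosing interval
#'
#' Computes Cmax, Tmax (relative to the start of the interval), AUC
#' (trapezoidal on the profile grid), trough (Cmin,ss, end of interval),
#' average (Cavg,ss = AUC/tau), and Cmax,ss on the last complete dosing
#' interval of the profile.
#'
#' @param profile a `conc_profile` (or data.frame with `time` and a
#'   concentration column)
#' @param interval dosing interval, h; defaults to the profile's metadata
#' @param column concentration column to summarize
#' @return list with `c_max`, `t_max`, `auc`, `c_min_ss`, `c_avg_ss`,
#'   `c_max_ss` (concentrations ng/mL, AUC ng*h/mL)
#' @export
compute_pk_metrics <- function(profile, interval = attr(profile, "interval"),
                               column = "maternal_plasma") {
  if (is.null(interval)) stop_domain("no dosing interval available")
  t_end <- max(profile$time)
  if (t_end < interval)
    stop_domain("profile shorter than one dosing interval")
  sel <- profile$time >= t_end - interval
  tt <- profile$time[sel]
  cc <- profile[[column]][sel]
  i_max <- which.max(cc)
  auc <- trapz(tt, cc)
  list(c_max = cc[i_max],
       t_max = tt[i_max] - (t_end - interval),
       auc = auc,
       c_min_ss = cc[length(cc)],
       c_avg_ss = auc / interval,
       c_max_ss = cc[i_max])
}

#' Prediction ratio (predicted / observed)
#'
#' @param predicted predicted metric value
#' @param observed observed metric value (> 0)
#' @return the quotient, with attribute `acceptable` (TRUE iff in
#'   `[0.7, 1.3]`)
#' @export
prediction_ratio <- function(predicted, observed) {
  if (any(observed <= 0)) stop_domain("observed value must be positive")
  r <- predicted / observed
  structure(r, acceptable = r >= 0.7 & r <= 1.3)
}

#' Absolute average fold error
#'
#' `AAFE = 10 ^ mean(|log10(predicted / observed)|)`; 1 is a perfect
#' prediction, values below 2 are conventionally acceptable.
#'
#' @param predicted,observed positive numeric vectors of equal length
#' @return the AAFE (>= 1)
#' @export
aafe <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1)
  if (any(predicted <= 0) || any(observed <= 0))
    stop_domain("AAFE requires positive values")
  10^mean(abs(log10(predicted / observed)))
}

#' Fraction of observed points inside a population prediction band
#'
#' The 5th and 95th percentile profiles are interpolated linearly at the
#' observation times; a point is covered when it lies within (inclusive) the
#' band.
#'
#' @param observed data.frame with columns `time_h` and `conc`
#' @param band a [run_population()] summary (uses `$time`, `$p5`, `$p95`)
#' @return covered fraction in `[0, 1]`
#' @export
coverage_check <- function(observed, band) {
  if (nrow(observed) == 0) stop_domain("empty observed dataset")
  if (any(observed$time_h < min(band$time)) ||
      any(observed$time_h > max(band$time)))
    stop_domain("observation times outside the band time range")
  lo <- stats::approx(band$time, band$p5, xout = observed$time_h)$y
  hi <- stats::approx(band$time, band$p95, xout = observed$time_h)$y
  mean(observed$conc >= lo & observed$conc <= hi)
}

#' Verification report for predicted-vs-observed comparisons
#'
#' Bundles prediction ratios, AAFE, and band coverage with the conventional
#' pass flags (ratios within 0.7-1.3, AAFE < 2).
#'
#' @param prediction_ratios named vector of per-metric prediction ratios
#' @param aafe_value pooled AAFE across concentration pairs
#' @param n_pairs number of predicted-observed pairs behind `aafe_value`
#' @param coverage_fraction fraction of observations inside the 5th-95th band
#' @return an object of class `verification_report`
#' @export
verification_report <- function(prediction_ratios, aafe_value, n_pairs,
                                coverage_fraction = NA_real_) {
  structure(list(
    prediction_ratios = prediction_ratios,
    aafe = aafe_value,
    n_pairs = n_pairs,
    coverage_fraction = coverage_fraction,
    ratios_acceptable = all(prediction_ratios >= 0.7 & prediction_ratios <= 1.3),
    aafe_acceptable = aafe_value < 2
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<verification_report>\n")
  cat("  prediction ratios:",
      paste(names(x$prediction_ratios), round(x$prediction_ratios, 3),
            collapse = ", "),
      if (x$ratios_acceptable) "[within 0.7-1.3]" else "[OUTSIDE 0.7-1.3]",
      "\n")
  cat("  AAFE:", round(x$aafe, 3), "on", x$n_pairs, "pairs",
      if (x$aafe_acceptable) "[< 2]" else "[>= 2]", "\n")
  if (!is.na(x$coverage_fraction))
    cat("  band coverage:", round(x$coverage_fraction, 3), "\n")
  invisible(x)
}
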