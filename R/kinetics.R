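# Reduction of cAMP assay plates to activities, turnover numbers and
# fold-changes.
#
# cAMP produced by sAC in a fixed reaction time is quantified against a
# fluorescent standard curve; dividing by reaction time gives activity
# (pmol min^-1) and further by the enzyme amount gives the turnover number
# (mol cAMP per mol enzyme per second). Condition contrasts (pH, metal,
# bicarbonate, mutants) are summarized as ratios of condition means.

#' Assay configuration
#'
#' Units and plate geometry shared by the plate-reduction helpers.
#'
#' @param well_volume_ul Reaction volume per well in microliters.
#' @param reaction_time_min Reaction time in minutes.
#' @param enzyme_pmol Amount of purified enzyme per well in pmol (ignored
#'   for lysate assays).
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(well_volume_ul = 100, reaction_time_min = 10,
                         enzyme_pmol = 0.01) {
  stopifnot(well_volume_ul > 0, reaction_time_min > 0)
  structure(list(well_volume_ul = well_volume_ul,
                 reaction_time_min = reaction_time_min,
                 enzyme_pmol = enzyme_pmol),
            class = "assay_config")
}

#' Fit a four-parameter-logistic standard curve
#'
#' Fits reading = A + (B - A) / (1 + exp((xmid - log10(conc)) / scal)) to
#' calibrator points by least squares (self-started, Levenberg-Marquardt
#' refined). The inverse is defined on the monotone calibrated range.
#'
#' @param concentration Calibrator concentrations (nM), strictly positive,
#'   at least 5 points spanning at least two decades.
#' @param reading Calibrator readings (arbitrary units).
#' @return An object of class `standard_curve` with the fitted coefficients
#'   (`A`, `B`, `xmid`, `scal`), residuals, and the calibrated range.
#' @export
fit_standard_curve <- function(concentration, reading) {
  stopifnot(length(concentration) == length(reading))
  if (any(concentration <= 0))
    stop("calibrator concentrations must be positive", call. = FALSE)
  if (length(concentration) < 5)
    stop("need at least 5 calibrator points", call. = FALSE)
  o <- order(concentration)
  concentration <- concentration[o]; reading <- reading[o]
  if (max(concentration) / min(concentration) < 100)
    stop("calibrators must span at least two decades", call. = FALSE)
  if (is.unsorted(reading) && is.unsorted(rev(reading)))
    warning("calibrator readings are not monotone in concentration")
  x <- log10(concentration)
  df <- data.frame(x = x, y = reading)
  # quartile-based initialization: asymptotes from the data extremes,
  # midpoint where the response crosses half-range
  y0 <- min(reading); y1 <- max(reading)
  start <- list(A = y0, B = y1,
                xmid = x[which.min(abs(reading - (y0 + y1) / 2))],
                scal = diff(range(x)) / 4 *
                  (if (reading[length(reading)] >= reading[1]) 1 else -1))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp((xmid - x) / scal)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("singular standard-curve fit: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  structure(list(A = cf[["A"]], B = cf[["B"]], xmid = cf[["xmid"]],
                 scal = cf[["scal"]],
                 concentration = concentration, reading = reading,
                 residuals = unname(residuals(fit)),
                 range = range(concentration)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> 4PL: A=%.3g B=%.3g xmid=%.3g scal=%.3g (%d points)\n",
    x$A, x$B, x$xmid, x$scal, length(x$reading)))
  invisible(x)
}

#' Predict a reading from a concentration (forward 4PL)
#'
#' @param curve A [fit_standard_curve()] result.
#' @param concentration Concentrations in nM.
#' @return Predicted readings.
#' @export
curve_reading <- function(curve, concentration) {
  x <- log10(concentration)
  curve$A + (curve$B - curve$A) / (1 + exp((curve$xmid - x) / curve$scal))
}

#' Convert a reading to a cAMP concentration (inverse 4PL)
#'
#' Readings outside the open interval between the fitted asymptotes are
#' flagged as out of range and returned as `NA` rather than extrapolated.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param reading Readings to invert.
#' @param config [assay_config()] supplying the well volume for the pmol
#'   conversion.
#' @return A data frame with `reading`, `camp_nM`, `camp_pmol` and
#'   `in_range`.
#' @export
reading_to_camp <- function(curve, reading, config = assay_config()) {
  lo <- min(curve$A, curve$B); hi <- max(curve$A, curve$B)
  margin <- 1e-9 * (hi - lo)
  in_range <- reading > lo + margin & reading < hi - margin
  x <- rep(NA_real_, length(reading))
  r <- reading[in_range]
  x[in_range] <- curve$xmid -
    curve$scal * log((curve$B - curve$A) / (r - curve$A) - 1)
  camp_nm <- 10^x
  # nM * uL: 1 nM in 1 uL = 1e-3 pmol
  camp_pmol <- camp_nm * config$well_volume_ul * 1e-3
  data.frame(reading = reading, camp_nM = camp_nm, camp_pmol = camp_pmol,
             in_range = in_range)
}

#' Enzymatic activity from cAMP amount and reaction time
#'
#' @param camp_pmol cAMP produced (pmol).
#' @param time_min Reaction time (minutes), positive.
#' @return Activity in pmol min^-1.
#' @export
activity <- function(camp_pmol, time_min) {
  if (any(time_min <= 0)) stop("reaction time must be positive",
                               call. = FALSE)
  camp_pmol / time_min
}

#' Turnover number from cAMP amount, time and enzyme amount
#'
#' @param camp_pmol cAMP produced (pmol).
#' @param time_s Reaction time (seconds), positive.
#' @param enzyme_pmol Enzyme amount (pmol), positive.
#' @return Turnover number k in mol cAMP per mol enzyme per second.
#' @export
#' @examples
#' turnover(0.636, 600, 0.01)  # 0.106 s^-1
turnover <- function(camp_pmol, time_s, enzyme_pmol) {
  if (any(time_s <= 0)) stop("time must be positive", call. = FALSE)
  if (any(enzyme_pmol <= 0)) stop("enzyme amount must be positive",
                                  call. = FALSE)
  (camp_pmol / time_s) / enzyme_pmol
}

#' Summarize turnover replicates per condition
#'
#' @param plate A plate data frame with columns `condition` (or any set of
#'   grouping columns), `camp_pmol`, and optionally `time_s`, `enzyme_pmol`
#'   (defaults from `config`).
#' @param by Names of the grouping columns (default `"condition"`).
#' @param config [assay_config()].
#' @return A data frame with per-condition `k_mean`, `k_sd` and `n`.
#' @export
turnover_table <- function(plate, by = "condition",
                           config = assay_config()) {
  time_s <- plate$time_s %||% (config$reaction_time_min * 60)
  enz <- plate$enzyme_pmol %||% config$enzyme_pmol
  k <- turnover(plate$camp_pmol, time_s, enz)
  key <- interaction(plate[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(k), key), function(ix) {
    cbind(plate[ix[1], by, drop = FALSE],
          data.frame(k_mean = mean(k[ix]), k_sd = sd(k[ix]),
                     n = length(ix)))
  }))
  rownames(out) <- NULL
  out
}

#' Fold-change between two condition groups
#'
#' @param a,b Numeric readings of the denominator (`a`) and numerator (`b`)
#'   groups.
#' @param estimator `"ratio_of_means"` (default, the bar-chart convention)
#'   or `"median_of_ratios"` (median of all pairwise b/a ratios).
#' @return The fold-change b relative to a.
#' @export
fold_change <- function(a, b,
                        estimator = c("ratio_of_means",
                                      "median_of_ratios")) {
  estimator <- match.arg(estimator)
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (estimator == "ratio_of_means") {
    if (mean(a) <= 0) stop("denominator group mean must be positive",
                           call. = FALSE)
    mean(b) / mean(a)
  } else {
    if (any(a <= 0)) stop("denominator values must be positive",
                          call. = FALSE)
    median(outer(b, a, "/"))
  }
}

#' Shape descriptor of a pH-activity profile
#'
#' Orders (pH, k) pairs, averages duplicate pH values, and reports interior
#' local maxima (peaks), minima (troughs) and the max/min activity ratio.
#' Used to summarize the biphasic pH dependence of sAC activity (first peak
#' near pH 7.0, trough at 7.2, surge above 7.8).
#'
#' @param ph pH values (at least 3 points).
#' @param k Activities or turnover numbers at each pH.
#' @return A list of class `ph_profile` with the ordered `table`, `peaks`,
#'   `troughs` (pH values of interior extrema) and `max_min_ratio`.
#' @export
ph_profile <- function(ph, k) {
  stopifnot(length(ph) == length(k))
  if (anyDuplicated(ph)) {
    warning("duplicate pH values averaged")
    k <- tapply(k, ph, mean)
    ph <- as.numeric(names(k))
    k <- unname(k)
  }
  if (length(ph) < 3) stop("need at least 3 pH points", call. = FALSE)
  o <- order(ph)
  ph <- ph[o]; k <- k[o]
  n <- length(k)
  interior <- seq(2, n - 1)
  peaks <- ph[interior][k[interior] > k[interior - 1] &
                          k[interior] > k[interior + 1]]
  troughs <- ph[interior][k[interior] < k[interior - 1] &
                            k[interior] < k[interior + 1]]
  structure(list(table = data.frame(ph = ph, k = k),
                 peaks = peaks, troughs = troughs,
                 max_min_ratio = if (min(k) > 0) max(k) / min(k) else Inf),
            class = "ph_profile")
}

#' Compare a mutant activity panel against wild type
#'
#' For every (mutant, pH, metal) stratum with wild-type wells, computes the
#' fold-change versus wild type and a Mann-Whitney U test, then adjusts the
#' p-values across the whole panel by Benjamini-Hochberg.
#'
#' @param plate Data frame with columns `construct`, `ph`, `metal`,
#'   `value` (activity or reading).
#' @param wild_type Construct label of the wild type.
#' @return A data frame of class `comparison_result`: one row per
#'   (mutant, pH, metal) with `fold`, `U`, `p`, `p_adj`, `n_mut`, `n_wt`.
#'   Strata lacking wild-type wells are skipped with a warning.
#' @export
compare_mutant_panel <- function(plate, wild_type = "WT") {
  stopifnot(all(c("construct", "ph", "metal", "value") %in% names(plate)))
  muts <- setdiff(unique(plate$construct), wild_type)
  rows <- list()
  for (m in muts) for (ph in unique(plate$ph[plate$construct == m]))
    for (metal in unique(plate$metal[plate$construct == m &
                                     plate$ph == ph])) {
      wt <- plate$value[plate$construct == wild_type & plate$ph == ph &
                          plate$metal == metal]
      mv <- plate$value[plate$construct == m & plate$ph == ph &
                          plate$metal == metal]
      if (!length(wt)) {
        warning(sprintf("no wild-type wells for pH %s / %s: skipped",
                        ph, metal))
        next
      }
      mw <- mann_whitney_u(mv, wt)
      rows[[length(rows) + 1L]] <- data.frame(
        construct = m, ph = ph, metal = metal,
        fold = fold_change(wt, mv), U = mw$U, p = mw$p,
        n_mut = length(mv), n_wt = length(wt))
    }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(construct = character(0), ph = numeric(0),
               metal = character(0), fold = numeric(0), U = numeric(0),
               p = numeric(0), n_mut = integer(0), n_wt = integer(0))
  out$p_adj <- if (nrow(out)) benjamini_hochberg(out$p) else numeric(0)
  class(out) <- c("comparison_result", "data.frame")
  out
}
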