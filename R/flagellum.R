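# Flagellar cAMP budget: how many cAMP molecules per second the membrane
# pool of sAC can add when intracellular pH rises, what concentration that
# corresponds to in the ~2 fL flagellum, and how far it occupies the cAMP
# targets (PKA, HCN channels).

AVOGADRO <- 6.02214076e23

#' Flagellar compartment parameters
#'
#' @param n_sac Number of sAC molecules in the flagellum (default 7000).
#' @param volume_fl Flagellar volume in femtoliters (default 2).
#' @return A list of class `compartment_params`.
#' @export
compartment_params <- function(n_sac = 7000, volume_fl = 2) {
  stopifnot(n_sac >= 0, volume_fl > 0)
  structure(list(n_sac = n_sac, volume_fl = volume_fl),
            class = "compartment_params")
}

#' Net cAMP synthesis rate from a turnover change
#'
#' The additional synthesis when every sAC molecule steps from turnover
#' `k_low` to `k_high`: `n_sac * (k_high - k_low)` molecules per second.
#' With the default 7000 copies and the measured MgATP turnover numbers at
#' pH 7.2 (0.035 s^-1) and pH 8.0 (0.106 s^-1) this is 497 molecules s^-1.
#'
#' @param comp [compartment_params()].
#' @param k_low,k_high Turnover numbers (s^-1 per enzyme),
#'   `0 <= k_low <= k_high`.
#' @return Molecules per second.
#' @export
#' @examples
#' synthesis_rate(compartment_params(), 0.035, 0.106)  # 497
synthesis_rate <- function(comp, k_low, k_high) {
  if (k_low < 0 || k_high < k_low)
    stop("require 0 <= k_low <= k_high", call. = FALSE)
  comp$n_sac * (k_high - k_low)
}

#' Convert a molecule count to a concentration
#'
#' Exact by default: `count / (N_A * V)`. One molecule in 2 fL is 0.830 nM.
#' `paper_convention = TRUE` applies the rounded 1 molecule = 1 nM rule
#' often used in back-of-envelope flagellar budgets.
#'
#' @param count Number of molecules (>= 0).
#' @param comp [compartment_params()].
#' @param paper_convention If `TRUE`, return `count` nM instead of the
#'   exact conversion.
#' @return Concentration in nM.
#' @export
molecules_to_concentration <- function(count, comp = compartment_params(),
                                       paper_convention = FALSE) {
  stopifnot(all(count >= 0))
  if (paper_convention) return(as.numeric(count))
  count / (AVOGADRO * comp$volume_fl * 1e-15) * 1e9
}

#' cAMP target affinity
#'
#' @param name Target name (e.g. `"PKA"`, `"HCN"`).
#' @param k_nM Dissociation or half-activation concentration in nM.
#' @param hill Hill coefficient (default 1).
#' @return A list of class `target_affinity`.
#' @export
target_affinity <- function(name, k_nM, hill = 1) {
  stopifnot(k_nM > 0, hill > 0)
  structure(list(name = name, k_nM = k_nM, hill = hill),
            class = "target_affinity")
}

#' Fractional occupancy of a cAMP target
#'
#' Hill binding curve `c^n / (c^n + K^n)`, monotone in concentration and
#' bounded in `[0, 1]`.
#'
#' @param conc_nM cAMP concentration(s) in nM (>= 0).
#' @param target A [target_affinity()].
#' @return Fractional occupancy.
#' @export
#' @examples
#' fractional_occupancy(497, target_affinity("HCN", 740))  # 0.402
fractional_occupancy <- function(conc_nM, target) {
  stopifnot(all(conc_nM >= 0))
  cn <- conc_nM^target$hill
  cn / (cn + target$k_nM^target$hill)
}

#' Nernst equilibrium potential for potassium
#'
#' `(RT/F) * ln([K+]_o / [K+]_i)` in millivolts.
#'
#' @param k_out_mM,k_in_mM External and internal potassium (mM), positive.
#' @param temperature_c Temperature in degrees Celsius (default 18, sea
#'   water).
#' @return Potential in mV.
#' @export
nernst <- function(k_out_mM, k_in_mM, temperature_c = 18) {
  if (any(k_out_mM <= 0) || any(k_in_mM <= 0))
    stop("concentrations must be positive", call. = FALSE)
  R <- 8.31446; FARADAY <- 96485.332
  1000 * R * (temperature_c + 273.15) / FARADAY * log(k_out_mM / k_in_mM)
}

#' Steady-state cAMP concentration under constant synthesis
#'
#' The fixed point of `dc/dt = s - c/tau` is `s * tau` molecules, converted
#' to nM in the compartment. With 497 molecules s^-1 and the 350 ms
#' hydrolysis time constant in 2 fL this is about 144 nM.
#'
#' @param rate Synthesis rate (molecules s^-1, >= 0).
#' @param tau_s Hydrolysis time constant (s), positive.
#' @param comp [compartment_params()].
#' @return Concentration in nM.
#' @export
steady_state_camp <- function(rate, tau_s, comp = compartment_params()) {
  stopifnot(all(rate >= 0), tau_s > 0)
  molecules_to_concentration(rate * tau_s, comp)
}

#' pH-activity curve of sAC
#'
#' Piecewise-linear interpolant through (pH, turnover) anchor points. The
#' default anchors encode the biphasic MgATP profile of purified truncated
#' sea urchin sAC: baseline 0.035 s^-1 at pH 6.7, a twofold first peak at
#' pH 7.0, return to baseline at pH 7.2, and the surge to 0.106 s^-1 at
#' pH 8.0.
#'
#' @param ph Strictly increasing pH anchors.
#' @param k Non-negative turnover numbers at the anchors (s^-1).
#' @return A list of class `ph_activity_curve`; call it via
#'   [eval_activity()].
#' @export
ph_activity_curve <- function(ph = c(6.5, 6.7, 7.0, 7.2, 7.8, 8.0),
                              k = c(0.035, 0.035, 0.070, 0.035, 0.045,
                                    0.106)) {
  stopifnot(length(ph) == length(k), !is.unsorted(ph, strictly = TRUE),
            all(k >= 0))
  structure(list(ph = ph, k = k), class = "ph_activity_curve")
}

#' Evaluate a pH-activity curve
#'
#' @param curve A [ph_activity_curve()].
#' @param ph pH values; outside the anchor range the end values are held.
#' @return Turnover numbers (s^-1).
#' @export
eval_activity <- function(curve, ph) {
  approx(curve$ph, curve$k, xout = ph, rule = 2)$y
}

#' Half-time of an exponential rise to plateau
#'
#' Least-squares fit of `v(t) = plateau - (plateau - baseline) *
#' exp(-t / tau)`; the half-time is `ln(2) * tau`. Traces that do not
#' approach a plateau (fitted span not resolved from noise, or tau beyond
#' the record length) are flagged.
#'
#' @param time,value The trace.
#' @return A list of class `halftime_fit` with `t_half`, `tau`, `baseline`,
#'   `plateau` and `ok` (fit-quality flag).
#' @export
fit_halftime <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 4)
  o <- order(time); time <- time[o]; value <- value[o]
  span <- diff(range(value))
  if (span <= 0 || span < 4 * sd(diff(value)) / sqrt(2) * 0.5) {
    return(structure(list(t_half = NA_real_, tau = NA_real_,
                          baseline = mean(value), plateau = mean(value),
                          ok = FALSE, reason = "no resolvable rise"),
                     class = "halftime_fit"))
  }
  start <- list(plateau = max(value), baseline = min(value),
                tau = diff(range(time)) / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ plateau - (plateau - baseline) * exp(-time / tau),
      start = start, lower = c(-Inf, -Inf, 1e-9)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(t_half = NA_real_, tau = NA_real_,
                          baseline = NA_real_, plateau = NA_real_,
                          ok = FALSE, reason = "fit failed"),
                     class = "halftime_fit"))
  }
  cf <- coef(fit)
  ok <- cf[["tau"]] < 2 * diff(range(time)) &&
    cf[["plateau"]] > cf[["baseline"]]
  structure(list(t_half = log(2) * cf[["tau"]], tau = cf[["tau"]],
                 baseline = cf[["baseline"]], plateau = cf[["plateau"]],
                 ok = ok, reason = if (ok) "" else "plateau not reached"),
            class = "halftime_fit")
}

#' @export
print.halftime_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<halftime_fit> t1/2 = %.2f s (tau = %.2f s)\n",
                x$t_half, x$tau))
  else cat("<halftime_fit> flagged:", x$reason, "\n")
  invisible(x)
}
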