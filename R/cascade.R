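# Deterministic model of the spawning cascade of sea urchin sperm:
# dilution out of seminal fluid drops external K+, the membrane
# hyperpolarizes toward the K+ Nernst potential, hyperpolarization opens the
# voltage-gated Na+/H+ exchanger SLC9C1, the cytosol alkalizes, the
# pH-controlled sAC raises cAMP, and sustained PKA occupancy switches
# motility on after a phosphorylation delay.
#
# The model is a set of first-order relaxations with a threshold gate,
# integrated with a fixed-step explicit Euler scheme (no randomness). Event
# times (hyperpolarization, alkalization onset, cAMP half-rise, motility
# onset) are read off the trace.

#' Spawning-cascade parameters
#'
#' Defaults describe 1:2 mixing of sperm in artificial seminal fluid
#' (ASF, 27 mM K+, resting intracellular pH 6.84) with K+-free artificial
#' sea water, dropping external K+ to 10 mM; the 30K control mixes into
#' 30 mM K+ instead, leaving the resting potential in place.
#'
#' @param k_out_before_mM External K+ before mixing (mM; ASF).
#' @param k_out_after_mM External K+ after mixing (mM; 10 for the 0K mix,
#'   30 for the 30K control).
#' @param k_in_mM Internal K+ (mM; not measured, chosen to give a plausible
#'   resting potential near -45 mV).
#' @param temperature_c Temperature (degrees Celsius).
#' @param tau_vm_s Membrane-potential relaxation time constant (s).
#' @param vm_threshold_mV SLC9C1 activation threshold: the exchanger gate is
#'   open while V_m is below this value.
#' @param ph_rest,ph_post Resting and post-spawning intracellular pH.
#' @param tau_ph_s Alkalization time constant (s) while the gate is open.
#' @param tau_pde_s cAMP hydrolysis time constant (s).
#' @param pka_k_nM,pka_hill PKA cAMP affinity (nM) and Hill coefficient.
#' @param occupancy_threshold PKA occupancy that must be exceeded
#'   continuously for `phospho_delay_s` before motility switches on.
#' @param phospho_delay_s Phosphorylation delay (s).
#' @param camp_baseline_pmol,camp_plateau_pmol Printed bulk-biochemistry
#'   anchors (pmol per 1e8 cells) carried for reporting; the simulation
#'   itself works in flagellar molecule counts.
#' @param duration_s,dt_s Simulated duration and time step (s).
#' @param camp_init_molecules Initial flagellar cAMP (molecules). `NULL`
#'   (default) starts at the resting synthesis/hydrolysis balance
#'   `n_sac * k(ph_rest) * tau_pde`.
#' @return A list of class `cascade_params`.
#' @export
cascade_params <- function(k_out_before_mM = 27, k_out_after_mM = 10,
                           k_in_mM = 160, temperature_c = 18,
                           tau_vm_s = 0.5, vm_threshold_mV = -55,
                           ph_rest = 6.84, ph_post = 7.2, tau_ph_s = 100,
                           tau_pde_s = 0.35, pka_k_nM = 10, pka_hill = 1,
                           occupancy_threshold = 0.92,
                           phospho_delay_s = 25,
                           camp_baseline_pmol = 0.23,
                           camp_plateau_pmol = 15.1,
                           duration_s = 300, dt_s = 0.01,
                           camp_init_molecules = NULL) {
  stopifnot(tau_vm_s > 0, tau_ph_s > 0, tau_pde_s > 0, dt_s > 0,
            duration_s > dt_s, ph_rest >= 6, ph_rest <= 9, ph_post >= 6,
            ph_post <= 9, phospho_delay_s >= 0)
  structure(as.list(environment()), class = "cascade_params")
}

#' Simulate the spawning cascade
#'
#' Integrates membrane potential, intracellular pH and flagellar cAMP from
#' resting conditions in seminal fluid through the mixing step at t = 0,
#' with a fixed-step explicit scheme:
#' \itemize{
#'   \item `dVm/dt = (E_K(K_out) - Vm) / tau_vm`
#'   \item `dpHi/dt = (target - pHi) / tau_ph`, target = `ph_post` while the
#'     SLC9C1 gate is open (`Vm < vm_threshold`), else `ph_rest`
#'   \item `dc/dt = n_sac * k(pHi) - c / tau_pde` (molecules)
#' }
#' Motility switches on once PKA occupancy exceeds the threshold
#' continuously for the phosphorylation delay.
#'
#' @param params [cascade_params()].
#' @param curve [ph_activity_curve()] covering the simulated pH range.
#' @param comp [compartment_params()].
#' @return A list of class `cascade_trace` with the time `grid` data frame
#'   (`time`, `vm_mV`, `ph_i`, `camp_molecules`, `camp_nM`, `pka_occupancy`,
#'   `motile`) and `events`, the timestamps (s, `NA` if the event did not
#'   occur) of `hyperpolarization` (V_m crosses the gate threshold),
#'   `alkalization` (pH_i exceeds rest by 0.01), `camp_half_rise` (cAMP
#'   crosses the midpoint of initial value and trace maximum) and
#'   `motility_onset`.
#' @export
simulate_spawning <- function(params = cascade_params(),
                              curve = ph_activity_curve(),
                              comp = compartment_params()) {
  p <- params
  nt <- floor(p$duration_s / p$dt_s) + 1L
  time <- (seq_len(nt) - 1L) * p$dt_s
  vm <- numeric(nt); ph <- numeric(nt); c_mol <- numeric(nt)
  vm[1] <- nernst(p$k_out_before_mM, p$k_in_mM, p$temperature_c)
  ph[1] <- p$ph_rest
  # start at the resting balance between synthesis and hydrolysis
  c_mol[1] <- p$camp_init_molecules %||%
    (comp$n_sac * eval_activity(curve, ph[1]) * p$tau_pde_s)
  e_k <- nernst(p$k_out_after_mM, p$k_in_mM, p$temperature_c)
  for (i in seq_len(nt - 1L)) {
    gate_open <- vm[i] < p$vm_threshold_mV
    ph_target <- if (gate_open) p$ph_post else p$ph_rest
    s <- comp$n_sac * eval_activity(curve, ph[i])
    vm[i + 1] <- vm[i] + p$dt_s * (e_k - vm[i]) / p$tau_vm_s
    ph[i + 1] <- ph[i] + p$dt_s * (ph_target - ph[i]) / p$tau_ph_s
    c_mol[i + 1] <- c_mol[i] + p$dt_s * (s - c_mol[i] / p$tau_pde_s)
    if (c_mol[i + 1] < 0) c_mol[i + 1] <- 0
  }
  camp_nm <- molecules_to_concentration(c_mol, comp)
  occ <- fractional_occupancy(camp_nm,
                              target_affinity("PKA", p$pka_k_nM,
                                              p$pka_hill))
  # motility: occupancy above threshold continuously for the delay
  above <- occ > p$occupancy_threshold
  run <- 0
  motile <- logical(nt)
  onset <- NA_real_
  for (i in seq_len(nt)) {
    run <- if (above[i]) run + p$dt_s else 0
    if (is.na(onset) && run >= p$phospho_delay_s) onset <- time[i]
    motile[i] <- !is.na(onset) && time[i] >= onset
  }
  first_time <- function(cond) {
    w <- which(cond)
    if (length(w)) time[w[1]] else NA_real_
  }
  half <- (c_mol[1] + max(c_mol)) / 2
  events <- c(
    hyperpolarization = first_time(vm < p$vm_threshold_mV),
    alkalization = first_time(ph > p$ph_rest + 0.01),
    camp_half_rise = if (max(c_mol) > c_mol[1] * 1.001)
      first_time(c_mol >= half) else NA_real_,
    motility_onset = onset)
  structure(list(
    grid = data.frame(time = time, vm_mV = vm, ph_i = ph,
                      camp_molecules = c_mol, camp_nM = camp_nm,
                      pka_occupancy = occ, motile = motile),
    events = events, params = p),
    class = "cascade_trace")
}

#' @export
print.cascade_trace <- function(x, ...) {
  cat("<cascade_trace>", nrow(x$grid), "steps\n")
  print(round(x$events, 2))
  invisible(x)
}

#' Caged-cAMP photorelease parameters
#'
#' Saturating release model `released = c_max * (1 - exp(-alpha * E))` for
#' a flash of relative energy E, anchored so that the default energy range
#' spans the 5.3-342 nM window released from 20 uM loaded caged cAMP.
#'
#' @param loaded_uM Loaded caged cAMP (uM).
#' @param c_max_nM Maximal released concentration (nM).
#' @param c_min_nM Released concentration at the weakest calibrated flash
#'   (nM).
#' @param alpha Release coefficient per relative flash-energy unit.
#' @return A list of class `uncaging_params`.
#' @export
uncaging_params <- function(loaded_uM = 20, c_max_nM = 342,
                            c_min_nM = 5.3, alpha = 6) {
  stopifnot(alpha > 0, c_max_nM > c_min_nM, c_min_nM > 0)
  structure(list(loaded_uM = loaded_uM, c_max_nM = c_max_nM,
                 c_min_nM = c_min_nM, alpha = alpha,
                 # energy of the weakest calibrated flash
                 e_min = -log(1 - c_min_nM / c_max_nM) / alpha),
            class = "uncaging_params")
}

#' Released cAMP for a flash energy
#'
#' @param flash_energy Relative flash energy (>= 0; 1 is saturating).
#' @param params [uncaging_params()].
#' @return Released cAMP in nM.
#' @export
uncaging_release <- function(flash_energy, params = uncaging_params()) {
  stopifnot(all(flash_energy >= 0))
  params$c_max_nM * (1 - exp(-params$alpha * flash_energy))
}

#' Motility latency after a cAMP step
#'
#' Simulates an instantaneous cAMP injection decaying with the hydrolysis
#' time constant, drives a first-order PKA phosphorylation variable toward
#' the instantaneous occupancy, and reports the first threshold crossing.
#' Latency is non-increasing in the released amount; cells whose activation
#' never crosses the threshold get `Inf`.
#'
#' @param released_nM Released cAMP (nM).
#' @param pka_k_nM PKA affinity (nM).
#' @param tau_camp_s Decay time constant of the released cAMP (s).
#' @param tau_act_s Phosphorylation time constant (s).
#' @param act_threshold Activation level that triggers motility.
#' @param duration_s,dt_s Integration window and step (s).
#' @return Latency in seconds (possibly `Inf`).
#' @export
motility_latency <- function(released_nM, pka_k_nM = 10, tau_camp_s = 5,
                             tau_act_s = 0.2, act_threshold = 0.25,
                             duration_s = 30, dt_s = 0.001) {
  stopifnot(all(released_nM >= 0))
  vapply(released_nM, function(c0) {
    nt <- floor(duration_s / dt_s)
    a <- 0
    for (i in seq_len(nt)) {
      t <- i * dt_s
      conc <- c0 * exp(-t / tau_camp_s)
      occ <- conc / (conc + pka_k_nM)
      a <- a + dt_s * (occ - a) / tau_act_s
      if (a >= act_threshold) return(t)
    }
    Inf
  }, numeric(1))
}
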