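#' Per-group leaky integrate-and-fire parameters
#'
#' Bundles the electrophysiological constants of one cell group. Units follow
#' the package-wide table: potentials in mV, capacitance in pF, conductance in
#' nS, times in ms, currents in pA, rates in spikes/s. The derived membrane
#' time constant is `tau_m = C_m / g_L` (ms).
#'
#' @param group_id Group label (see [column_groups()]).
#' @param V_rest Resting potential, mV.
#' @param V_th Firing threshold, mV; must exceed `V_rest`.
#' @param C_m Membrane capacitance, pF.
#' @param g_L Leak conductance, nS.
#' @param tau_ref Absolute refractory period, ms.
#' @param nu_bg Rate of the neuron's private background Poisson generator,
#'   spikes/s.
#' @return Object of class `cell_type_params`.
#' @export
cell_type_params <- function(group_id, V_rest, V_th, C_m, g_L,
                             tau_ref = 2, nu_bg = 0) {
  stopifnot(is.character(group_id), length(group_id) == 1)
  if (!all(is.finite(c(V_rest, V_th, C_m, g_L, tau_ref, nu_bg))))
    stop("non-finite cell parameter for group ", group_id)
  if (V_th <= V_rest)
    stop("V_th must exceed V_rest for group ", group_id)
  if (C_m <= 0 || g_L <= 0)
    stop("C_m and g_L must be positive for group ", group_id)
  if (tau_ref < 0 || nu_bg < 0)
    stop("tau_ref and nu_bg must be non-negative for group ", group_id)
  structure(list(group_id = group_id, V_rest = V_rest, V_th = V_th,
                 C_m = C_m, g_L = g_L, tau_ref = tau_ref, nu_bg = nu_bg,
                 tau_m = C_m / g_L),
            class = "cell_type_params")
}

#' Receptor kinetics and conversion factors
#'
#' Time constants and conductance conversion factors of the three receptor
#' systems. AMPA and GABA-A gating is first-order with decay constants
#' `tau_AMPA` and `tau_GABA`; NMDA gating is second-order with rise constant
#' `tau_NMDA_rise`, decay constant `tau_NMDA_decay` and saturation rate
#' `alpha` (1/ms). The NMDA current carries the voltage-dependent magnesium
#' block (see [nmda_voltage_factor()]). The `g_*` factors convert the
#' dimensionless weighted gating sums into conductances (nS); `V_E` is the
#' excitatory reversal potential. The inhibitory reversal is each neuron's own
#' resting potential and therefore lives with the cell parameters, not here.
#'
#' @param tau_AMPA,tau_NMDA_decay,tau_NMDA_rise,tau_GABA Time constants, ms.
#' @param alpha NMDA saturation rate, 1/ms.
#' @param Mg Extracellular magnesium concentration, mM.
#' @param g_AMPA,g_NMDA,g_GABA Conversion factors, nS.
#' @param V_E Excitatory reversal potential, mV.
#' @return Object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_AMPA = 2, tau_NMDA_decay = 80,
                             tau_NMDA_rise = 2, alpha = 0.5, tau_GABA = 5,
                             Mg = 1, g_AMPA = 1, g_NMDA = 1, g_GABA = 1,
                             V_E = 0) {
  if (any(c(tau_AMPA, tau_NMDA_decay, tau_NMDA_rise, tau_GABA) <= 0))
    stop("receptor time constants must be positive")
  if (Mg < 0 || any(c(g_AMPA, g_NMDA, g_GABA) < 0))
    stop("Mg and conversion factors must be non-negative")
  structure(list(tau_AMPA = tau_AMPA, tau_NMDA_decay = tau_NMDA_decay,
                 tau_NMDA_rise = tau_NMDA_rise, alpha = alpha,
                 tau_GABA = tau_GABA, Mg = Mg, g_AMPA = g_AMPA,
                 g_NMDA = g_NMDA, g_GABA = g_GABA, V_E = V_E),
            class = "synapse_kinetics")
}

#' Per-neuron dynamical state
#'
#' Membrane potential, remaining refractory time, and the five gating
#' accumulators: background AMPA, recurrent AMPA, GABA, and the NMDA pair
#' (saturating fraction `s_NMDA` in \[0,1\] plus its auxiliary rise variable
#' `x_NMDA`). The recurrent accumulators hold the *weighted* summed
#' presynaptic drive of the neuron.
#'
#' @param V Membrane potential, mV.
#' @param refractory_remaining Remaining refractory time, ms.
#' @param s_AMPA_bg,s_AMPA,s_GABA,s_NMDA,x_NMDA Gating accumulators.
#' @return Object of class `neuron_state`.
#' @export
neuron_state <- function(V, refractory_remaining = 0, s_AMPA_bg = 0,
                         s_AMPA = 0, s_GABA = 0, s_NMDA = 0, x_NMDA = 0) {
  if (!is.finite(V)) stop("non-finite membrane potential")
  if (min(s_AMPA_bg, s_AMPA, s_GABA, s_NMDA, x_NMDA) < 0)
    stop("gating accumulators must be non-negative")
  if (s_NMDA > 1) stop("s_NMDA must lie in [0, 1]")
  if (refractory_remaining < 0) stop("negative refractory time")
  structure(list(V = V, refractory_remaining = refractory_remaining,
                 s_AMPA_bg = s_AMPA_bg, s_AMPA = s_AMPA, s_GABA = s_GABA,
                 s_NMDA = s_NMDA, x_NMDA = x_NMDA),
            class = "neuron_state")
}

#' One forward-Euler membrane step
#'
#' Advances the leaky integrate-and-fire membrane equation
#' `C_m dV/dt = -g_L (V - V_rest) + I_syn` by one step of length `dt`. During
#' the refractory period the potential is clamped at `V_rest` and inputs are
#' discarded. A threshold crossing emits a spike, resets `V` to `V_rest`
#' instantaneously and starts the refractory clock.
#'
#' @param state A [neuron_state()].
#' @param params A [cell_type_params()].
#' @param I_syn Total synaptic current, pA.
#' @param dt Step size, ms.
#' @return The updated `neuron_state`, with attribute `"spike"` set to `TRUE`
#'   when a spike was emitted in this step.
#' @export
membrane_step <- function(state, params, I_syn, dt) {
  stopifnot(dt > 0)
  if (!is.finite(state$V) || !is.finite(I_syn))
    stop("non-finite V or I_syn for neuron of group ", params$group_id)
  spike <- FALSE
  if (state$refractory_remaining > 0) {
    state$V <- params$V_rest
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
  } else {
    dV <- dt / params$C_m *
      (-params$g_L * (state$V - params$V_rest) + I_syn)
    V <- state$V + dV
    if (V >= params$V_th) {
      spike <- TRUE
      V <- params$V_rest
      state$refractory_remaining <- params$tau_ref
    }
    state$V <- V
  }
  attr(state, "spike") <- spike
  state
}

#' Voltage dependence of the NMDA magnesium block
#'
#' Multiplicative factor `1 / (1 + Mg * exp(-0.062 V) / 3.57)` applied to the
#' NMDA current: the magnesium block is relieved by depolarisation, so the
#' factor lies in (0, 1] and increases strictly with `V` whenever `Mg > 0`;
#' it is identically 1 in the magnesium-free limit.
#'
#' @param V Membrane potential, mV.
#' @param kin A [synapse_kinetics()] (only `Mg` is used).
#' @return Dimensionless factor in (0, 1].
#' @export
nmda_voltage_factor <- function(V, kin = synapse_kinetics()) {
  if (!all(is.finite(V))) stop("non-finite membrane potential")
  1 / (1 + kin$Mg * exp(-0.062 * V) / 3.57)
}

#' First-order gating update (AMPA and GABA channels)
#'
#' The gating accumulator decays exponentially toward zero with time constant
#' `tau`; every presynaptic spike in the step adds a unit delta pulse. The
#' decay is integrated exactly (`s * exp(-dt/tau)`), with the pulses applied
#' at the start of the step, so single-pulse responses reproduce the
#' closed-form exponential at machine precision.
#'
#' @param s Current accumulator value (>= 0).
#' @param tau Decay time constant, ms.
#' @param n_spikes Number of presynaptic spikes delivered this step (or a
#'   weighted spike sum, when used as an aggregated accumulator).
#' @param dt Step size, ms.
#' @return Updated accumulator value.
#' @export
gating_step_first_order <- function(s, tau, n_spikes, dt) {
  stopifnot(tau > 0, dt > 0, n_spikes >= 0)
  if (any(s < 0)) stop("negative gating accumulator")
  (s + n_spikes) * exp(-dt / tau)
}

#' Second-order saturating NMDA gating update
#'
#' The auxiliary variable `x` decays with the rise constant and gains one
#' unit per presynaptic spike; the channel fraction `s` decays with the decay
#' constant and is driven by `alpha * x * (1 - s)`, which keeps `s` in
#' \[0, 1\] for admissible step sizes. `x` is integrated with exact decay,
#' `s` with forward Euler (the drive term makes the equation nonlinear).
#'
#' @param s Channel open fraction in \[0, 1\].
#' @param x Auxiliary rise variable (>= 0).
#' @param kin A [synapse_kinetics()].
#' @param n_spikes Presynaptic spikes (or weighted spike sum) this step.
#' @param dt Step size, ms.
#' @return List with elements `s` and `x`.
#' @export
gating_step_nmda <- function(s, x, kin = synapse_kinetics(), n_spikes, dt) {
  stopifnot(dt > 0, n_spikes >= 0)
  if (any(s < 0) || any(s > 1)) stop("s_NMDA outside [0, 1]")
  if (any(x < 0)) stop("negative NMDA rise variable")
  x <- x + n_spikes
  s_new <- s + dt * (-s / kin$tau_NMDA_decay + kin$alpha * x * (1 - s))
  if (any(s_new < 0) || any(s_new > 1))
    stop("s_NMDA left [0, 1] after a step; dt too large for this input")
  list(s = s_new, x = x * exp(-dt / kin$tau_NMDA_rise))
}

#' Total synaptic current onto one neuron
#'
#' Sums the external DC current, the background AMPA current, the recurrent
#' AMPA and NMDA currents (the latter scaled by the magnesium-block factor)
#' and the GABA-A current. Currents are written as `g * s * (V_rev - V)` so
#' that excitatory channels depolarise whenever `V < V_E` and the GABA
#' channel pulls toward the neuron's own resting potential, which serves as
#' the inhibitory reversal.
#'
#' @param state A [neuron_state()].
#' @param kin A [synapse_kinetics()].
#' @param params A [cell_type_params()] (supplies `V_rest` as the inhibitory
#'   reversal).
#' @param I_ext External DC current, pA.
#' @return Total current, pA.
#' @export
total_synaptic_current <- function(state, kin = synapse_kinetics(), params,
                                   I_ext = 0) {
  if (!is.finite(state$V)) stop("non-finite membrane potential")
  V <- state$V
  drive_E <- kin$V_E - V
  I_ext +
    kin$g_AMPA * state$s_AMPA_bg * drive_E +
    kin$g_AMPA * state$s_AMPA * drive_E +
    kin$g_NMDA * nmda_voltage_factor(V, kin) * state$s_NMDA * drive_E +
    kin$g_GABA * state$s_GABA * (params$V_rest - V)
}
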