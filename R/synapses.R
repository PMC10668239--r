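#' NMDA magnesium-block factor
#'
#' Voltage dependence of the NMDA conductance produced by extracellular
#' magnesium, in the standard phenomenological form
#' \deqn{B(V) = \frac{1}{1 + e^{-0.062 V} \, [\mathrm{Mg}^{2+}]_o / 3.57}}
#' with `V` in mV and the magnesium concentration in mM. `B` lies in
#' (0, 1], increases with depolarization, and collapses to 1 when
#' magnesium is absent.
#'
#' @param V membrane potential (mV); vectorized.
#' @param mg_out external magnesium concentration (mM); vectorized.
#'
#' @return Unblocked fraction of the NMDA conductance.
#' @export
mg_block <- function(V, mg_out = 1) {
  if (any(!is.finite(mg_out)) || any(mg_out < 0)) {
    stop("`mg_out` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(V))) stop("`V` must be finite", call. = FALSE)
  1 / (1 + exp(-0.062 * V) * (mg_out / 3.57))
}

#' One forward-Euler step of an exponentially decaying conductance
#'
#' AMPA and GABA-A conductances jump by a quantal amount on each delayed
#' presynaptic spike and decay exponentially in between. `arrivals` is the
#' summed quantal conductance delivered during this step (nS); increments
#' are discrete jumps.
#'
#' @param G current conductance (nS); vectorized.
#' @param tau decay time constant (ms).
#' @param dt step size (ms).
#' @param arrivals summed quantal conductance arriving this step (nS).
#'
#' @return Updated conductance (nS).
#' @export
step_exponential <- function(G, tau, dt, arrivals = 0) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  G - (G / tau) * dt + arrivals
}

#' One forward-Euler step of the biexponential NMDA gating pair
#'
#' The gating fraction `s` (dimensionless, in \[0, 1\]) activates at rate
#' `alpha * x * (1 - s)` and decays with `tau_decay`; the auxiliary
#' variable `x` integrates presynaptic spike counts and decays with
#' `tau_rise`. The saturating `(1 - s)` factor bounds `s` below 1 in the
#' exact dynamics; after the Euler update `s` is clipped to \[0, 1\]
#' because a forward-Euler step can overshoot the saturating ODE when `x`
#' is large.
#'
#' @param s gating fraction.
#' @param x auxiliary gating variable.
#' @param dt step size (ms).
#' @param spike_count number of presynaptic spikes delivered this step.
#' @param tau_rise rise time constant (ms).
#' @param tau_decay decay time constant (ms).
#' @param alpha activation rate (1/ms).
#'
#' @return List with updated `s` and `x`.
#' @export
step_nmda <- function(s, x, dt, spike_count = 0, tau_rise = 2,
                      tau_decay = 200, alpha = 0.5) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  s_new <- s + (-s / tau_decay + alpha * x * (1 - s)) * dt
  x_new <- x - (x / tau_rise) * dt + spike_count
  s_new <- pmin(pmax(s_new, 0), 1)
  list(s = s_new, x = x_new)
}

#' Synaptic currents of the three receptor channels
#'
#' Given the instantaneous conductances and gating of a postsynaptic
#' neuron, returns the AMPA, GABA-A and NMDA currents
#' \deqn{I_{AMPA} = G_{AMPA}(V - E_{AMPA}), \quad
#'       I_{GABA_A} = G_{GABA_A}(V - E_{GABA_A}), \quad
#'       I_{NMDA} = Q_{NMDA}\, s\, (V - E_{NMDA})\, B(V)}
#' With this sign convention (currents are subtracted in the membrane
#' equation) excitatory currents are negative at subthreshold voltages.
#'
#' @param V membrane potential (mV).
#' @param g_ampa,g_gabaa instantaneous conductances (nS).
#' @param s_nmda NMDA gating fraction.
#' @param q_nmda NMDA quantal strength onto this neuron (nS).
#' @param params a [synapse_params()].
#'
#' @return Named list `I_AMPA`, `I_GABAA`, `I_NMDA`, `I_total` (pA).
#' @export
synaptic_currents <- function(V, g_ampa, g_gabaa, s_nmda, q_nmda,
                              params = synapse_params()) {
  B <- mg_block(V, params$mg_out)
  i_ampa <- g_ampa * (V - params$e_ampa)
  i_gabaa <- g_gabaa * (V - params$e_gabaa)
  i_nmda <- q_nmda * s_nmda * (V - params$e_nmda) * B
  list(I_AMPA = i_ampa, I_GABAA = i_gabaa, I_NMDA = i_nmda,
       I_total = i_ampa + i_gabaa + i_nmda)
}
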