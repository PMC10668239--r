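#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Container for the AdEx single-neuron parameters. Units are fixed
#' package-wide: mV, ms, nS, pF, pA (so that 1 nS x 1 mV = 1 pA).
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV).
#' @param V_th effective spike threshold of the exponential term (mV).
#' @param Delta spike slope factor (mV).
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param tau_w adaptation time constant (ms).
#' @param T_ref absolute refractory period (ms).
#' @param V_rest reset potential (mV).
#' @param label cell-class label, `"RS"` or `"FS"`.
#'
#' @return An object of class `neuron_params` (a named list).
#' @seealso [rs_params()], [fs_params()] for the two cell-class presets.
#' @export
neuron_params <- function(C, g_L, E_L, V_th, Delta, a, b, tau_w, T_ref,
                          V_rest, label = "custom") {
  stopifnot_scalar(C, "C", positive = TRUE)
  stopifnot_scalar(g_L, "g_L", positive = TRUE)
  stopifnot_scalar(E_L, "E_L")
  stopifnot_scalar(V_th, "V_th")
  stopifnot_scalar(Delta, "Delta", positive = TRUE)
  stopifnot_scalar(a, "a")
  stopifnot_scalar(b, "b")
  stopifnot_scalar(tau_w, "tau_w", positive = TRUE)
  stopifnot_scalar(T_ref, "T_ref", nonneg = TRUE)
  stopifnot_scalar(V_rest, "V_rest")
  structure(list(C = C, g_L = g_L, E_L = E_L, V_th = V_th, Delta = Delta,
                 a = a, b = b, tau_w = tau_w, T_ref = T_ref,
                 V_rest = V_rest, label = label),
            class = "neuron_params")
}

#' Regular-spiking (RS) excitatory cell preset
#'
#' AdEx parameter set for the excitatory regular-spiking class:
#' spike-frequency adaptation (a = 4 nS, b = 20 pA), a shallow
#' spike-initiation slope (Delta = 2 mV) and an effective threshold of
#' -50 mV. With the leak at -65 mV and ~10 nS, this threshold keeps the
#' class in the fluctuation-driven regime under the default external
#' drive: the balanced network then supports sparse self-sustained
#' activity rather than being locked into silence (threshold out of
#' reach) or a refractory-limited paroxysm.
#'
#' @return A `neuron_params` object.
#' @export
rs_params <- function() {
  neuron_params(C = 150, g_L = 10, E_L = -65, V_th = -50, Delta = 2,
                a = 4, b = 20, tau_w = 500, T_ref = 5, V_rest = -65,
                label = "RS")
}

#' Fast-spiking (FS) inhibitory cell preset
#'
#' AdEx parameter set for the inhibitory fast-spiking class: no adaptation
#' (a = 0, b = 0), low threshold (-47.5 mV) and a sharp spike-initiation
#' slope (Delta = 0.5 mV).
#'
#' @return A `neuron_params` object.
#' @export
fs_params <- function() {
  neuron_params(C = 150, g_L = 10, E_L = -65, V_th = -47.5, Delta = 0.5,
                a = 0, b = 0, tau_w = 500, T_ref = 5, V_rest = -65,
                label = "FS")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("AdEx neuron parameters (%s)\n", x$label))
  cat(sprintf("  C = %g pF, g_L = %g nS, E_L = %g mV\n", x$C, x$g_L, x$E_L))
  cat(sprintf("  V_th = %g mV, Delta = %g mV, V_rest = %g mV, T_ref = %g ms\n",
              x$V_th, x$Delta, x$V_rest, x$T_ref))
  cat(sprintf("  a = %g nS, b = %g pA, tau_w = %g ms\n", x$a, x$b, x$tau_w))
  invisible(x)
}

#' Synaptic model parameters
#'
#' Conductance-based synapse parameters for the three receptor channels.
#' AMPA and GABA-A conductances jump by a quantal amount on each delayed
#' presynaptic spike and decay exponentially; NMDA conductances follow a
#' biexponential gating scheme with saturating activation, multiplied by
#' the magnesium-block factor [mg_block()] at the postsynaptic voltage.
#'
#' The NMDA quantal strengths `q_nmda_rs` / `q_nmda_fs` (onto RS and FS
#' cells respectively) are the handle used to emulate NMDA-receptor
#' antagonists: the blocked condition lowers both, more strongly on FS
#' cells. The defaults correspond to the healthy reference condition.
#'
#' The fast quantal strengths (AMPA 2.3 nS, GABA-A 4.75 nS) are set so
#' that, at the default in-degrees (~400 excitatory, ~100 inhibitory),
#' recurrent inhibition dominates recurrent fast excitation and the
#' network has a stable sparse balanced regime; with substantially
#' stronger AMPA (or weaker GABA-A) quanta a refractory-locked
#' runaway attractor becomes reachable from the working state.
#'
#' @param q_ampa quantal AMPA conductance, recurrent synapses (nS).
#' @param q_gabaa quantal GABA-A conductance (nS).
#' @param q_nmda_rs quantal NMDA conductance onto RS cells (nS).
#' @param q_nmda_fs quantal NMDA conductance onto FS cells (nS).
#' @param tau_ampa AMPA decay time constant (ms).
#' @param tau_gabaa GABA-A decay time constant (ms).
#' @param tau_rise_nmda NMDA rise time constant (ms).
#' @param tau_decay_nmda NMDA decay time constant (ms).
#' @param alpha NMDA activation rate (1/ms).
#' @param e_ampa,e_gabaa,e_nmda reversal potentials (mV).
#' @param mg_out external magnesium concentration (mM).
#' @param delay synaptic transmission delay, all chemical synapses (ms).
#'
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(q_ampa = 2.3, q_gabaa = 4.75,
                           q_nmda_rs = 0.8, q_nmda_fs = 1.0,
                           tau_ampa = 1.5, tau_gabaa = 7.5,
                           tau_rise_nmda = 2, tau_decay_nmda = 200,
                           alpha = 0.5,
                           e_ampa = 0, e_gabaa = -80, e_nmda = 0,
                           mg_out = 1, delay = 1.5) {
  stopifnot_scalar(q_ampa, "q_ampa", nonneg = TRUE)
  stopifnot_scalar(q_gabaa, "q_gabaa", nonneg = TRUE)
  stopifnot_scalar(q_nmda_rs, "q_nmda_rs", nonneg = TRUE)
  stopifnot_scalar(q_nmda_fs, "q_nmda_fs", nonneg = TRUE)
  stopifnot_scalar(tau_ampa, "tau_ampa", positive = TRUE)
  stopifnot_scalar(tau_gabaa, "tau_gabaa", positive = TRUE)
  stopifnot_scalar(tau_rise_nmda, "tau_rise_nmda", positive = TRUE)
  stopifnot_scalar(tau_decay_nmda, "tau_decay_nmda", positive = TRUE)
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  stopifnot_scalar(mg_out, "mg_out", nonneg = TRUE)
  stopifnot_scalar(delay, "delay", nonneg = TRUE)
  structure(list(q_ampa = q_ampa, q_gabaa = q_gabaa,
                 q_nmda_rs = q_nmda_rs, q_nmda_fs = q_nmda_fs,
                 tau_ampa = tau_ampa, tau_gabaa = tau_gabaa,
                 tau_rise_nmda = tau_rise_nmda,
                 tau_decay_nmda = tau_decay_nmda, alpha = alpha,
                 e_ampa = e_ampa, e_gabaa = e_gabaa, e_nmda = e_nmda,
                 mg_out = mg_out, delay = delay),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Synapse parameters (nS, ms, mV, mM)\n")
  cat(sprintf("  AMPA:   Q = %g, tau = %g, E = %g\n",
              x$q_ampa, x$tau_ampa, x$e_ampa))
  cat(sprintf("  GABA-A: Q = %g, tau = %g, E = %g\n",
              x$q_gabaa, x$tau_gabaa, x$e_gabaa))
  cat(sprintf("  NMDA:   Q_RS = %g, Q_FS = %g, tau_rise = %g, tau_decay = %g, alpha = %g/ms, E = %g\n",
              x$q_nmda_rs, x$q_nmda_fs, x$tau_rise_nmda, x$tau_decay_nmda,
              x$alpha, x$e_nmda))
  cat(sprintf("  [Mg2+]_o = %g mM, delay = %g ms\n", x$mg_out, x$delay))
  invisible(x)
}
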