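#' Create a single-neuron dynamical state
#'
#' @param V membrane potential (mV).
#' @param w adaptation current (pA).
#' @param refractory_until absolute time until which the neuron is clamped
#'   at its reset potential (ms); `-Inf` when not refractory.
#' @param last_spike time of the most recent spike (ms), or `NA`.
#'
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V, w = 0, refractory_until = -Inf,
                         last_spike = NA_real_) {
  stopifnot_scalar(V, "V")
  stopifnot_scalar(w, "w")
  structure(list(V = V, w = w, refractory_until = refractory_until,
                 last_spike = last_spike),
            class = "neuron_state")
}

#' AdEx membrane and adaptation drift
#'
#' Evaluates the deterministic right-hand side of the adaptive exponential
#' integrate-and-fire model for a non-refractory neuron:
#' \deqn{C \dot V = -g_L (V - E_L) + g_L \Delta e^{(V - V_{th})/\Delta}
#'       - w - I_{syn}}
#' \deqn{\tau_w \dot w = a (V - E_L) - w}
#' The synaptic current enters with the convention that a positive
#' `I_syn` hyperpolarizes (it is subtracted), matching
#' [synaptic_currents()], where excitatory currents are negative at
#' subthreshold voltages.
#'
#' @param state a [neuron_state()] (non-refractory).
#' @param params a [neuron_params()].
#' @param I_syn total synaptic current (pA), subtracted from the membrane
#'   equation.
#'
#' @return Named numeric vector `c(dV = mV/ms, dw = pA/ms)`.
#' @export
adex_drift <- function(state, params, I_syn = 0) {
  V <- state$V
  w <- state$w
  if (!is.finite(V) || !is.finite(w)) {
    stop("non-finite neuron state (numerical blow-up): clamp V before the exponential term",
         call. = FALSE)
  }
  p <- params
  dV <- (-p$g_L * (V - p$E_L) +
           p$g_L * p$Delta * exp((V - p$V_th) / p$Delta) -
           w - I_syn) / p$C
  dw <- (p$a * (V - p$E_L) - w) / p$tau_w
  c(dV = dV, dw = dw)
}

#' Spike detection, reset and refractory entry
#'
#' After an Euler step, checks the membrane potential against the spike
#' cut potential. On a spike the potential is reset to `V_rest` and held
#' there for the refractory period `T_ref`, and the adaptation current is
#' incremented by `b`. By default the cut potential equals the effective
#' threshold `V_th`; a different numerical cutoff can be supplied through
#' `v_cut`.
#'
#' @param state a [neuron_state()] just advanced by one step.
#' @param params a [neuron_params()].
#' @param t current time (ms).
#' @param v_cut spike detection potential (mV); defaults to `params$V_th`.
#'
#' @return A list with `state` (updated `neuron_state`) and `spiked`
#'   (logical flag).
#' @export
detect_and_reset <- function(state, params, t, v_cut = NULL) {
  if (is.null(v_cut)) v_cut <- params$V_th
  spiked <- FALSE
  if (t >= state$refractory_until && state$V >= v_cut) {
    spiked <- TRUE
    state$V <- params$V_rest
    state$w <- state$w + params$b
    state$refractory_until <- t + params$T_ref
    state$last_spike <- t
  }
  list(state = state, spiked = spiked)
}
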