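#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Bundles the parameters of the AdEx point-neuron model with two
#' conductance-based synaptic input channels (one excitatory, one inhibitory,
#' each with a single exponential decay constant — mirroring substrates with
#' one input circuit per receptor class). Setting `delta_t = 0` disconnects the
#' exponential spike-initiation term, reducing the model to a leaky
#' integrate-and-fire neuron whose spike threshold is `v_t`.
#'
#' The membrane obeys
#' \deqn{C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'   - g_e (V - E_e) - g_i (V - E_i) - w + I_{ext}}
#' with adaptation \eqn{\tau_w \dot w = a (V - E_L) - w}; on a spike,
#' \eqn{V \to V_{reset}}, \eqn{w \to w + b}, and \eqn{V} is clamped to
#' \eqn{V_{reset}} for `tau_ref` ms.
#'
#' @param c_m Membrane capacitance (nF).
#' @param g_l Leak conductance (nS).
#' @param e_l Leak (resting) potential (mV).
#' @param v_t Spike-initiation threshold (mV); the firing threshold itself when
#'   `delta_t = 0`.
#' @param delta_t Threshold slope factor (mV); `0` for the LIF reduction.
#' @param tau_w Adaptation time constant (ms).
#' @param a Subthreshold adaptation conductance (nS).
#' @param b Spike-triggered adaptation increment (pA).
#' @param v_reset Reset potential (mV).
#' @param v_spike Spike detection threshold (mV); used only when `delta_t > 0`.
#' @param tau_ref Absolute refractory period (ms).
#' @param tau_e,tau_i Excitatory / inhibitory synaptic decay constants (ms).
#' @param e_e,e_i Excitatory / inhibitory reversal potentials (mV).
#' @param i_ext Constant current injection (pA).
#' @param v_init Initial membrane potential (mV); defaults to `e_l`.
#' @return An object of class `adex_params`.
#' @export
adex_params <- function(c_m = 0.25, g_l = 25, e_l = -70, v_t = -57,
                        delta_t = 0, tau_w = 600, a = 0, b = 0,
                        v_reset = -70, v_spike = -40, tau_ref = 2,
                        tau_e = 1.5, tau_i = 5, e_e = 0, e_i = -80,
                        i_ext = 0, v_init = NULL) {
  assert_that(c_m > 0, "c_m must be > 0")
  assert_that(g_l > 0, "g_l must be > 0")
  assert_that(tau_w > 0, "tau_w must be > 0")
  assert_that(tau_ref >= 0, "tau_ref must be >= 0")
  assert_that(delta_t >= 0, "delta_t must be >= 0")
  assert_that(tau_e > 0 && tau_i > 0, "synaptic time constants must be > 0")
  structure(
    list(c_m = c_m, g_l = g_l, e_l = e_l, v_t = v_t, delta_t = delta_t,
         tau_w = tau_w, a = a, b = b, v_reset = v_reset, v_spike = v_spike,
         tau_ref = tau_ref, tau_e = tau_e, tau_i = tau_i, e_e = e_e,
         e_i = e_i, i_ext = i_ext, v_init = v_init %||% e_l),
    class = "adex_params"
  )
}

#' @export
print.adex_params <- function(x, ...) {
  kind <- if (x$delta_t > 0) "AdEx" else "LIF"
  cat(sprintf("<%s neuron> tau_m = %.2f ms, E_L = %g mV, V_T = %g mV",
              kind, x$c_m / x$g_l * 1000 / 1000 * 1000, x$e_l, x$v_t), "\n")
  invisible(x)
}

#' Short-term plasticity parameters (Tsodyks-Markram)
#'
#' Per-synapse utilization/recovery dynamics evaluated spike-by-spike. The two
#' modes are exclusive: depression keeps the utilization fixed at `u` while the
#' recovered resource depletes and recovers with `tau_rec`; facilitation lets
#' the utilization grow with each spike and relax back with `tau_facil`
#' (resource recovery stays active in both modes).
#'
#' @param u Baseline utilization, in \[0, 1\].
#' @param tau_rec Resource recovery time constant (ms).
#' @param tau_facil Facilitation time constant (ms).
#' @param mode `"depression"` or `"facilitation"`.
#' @return An object of class `stp_params`.
#' @export
stp_params <- function(u, tau_rec = 500, tau_facil = 50,
                       mode = c("depression", "facilitation")) {
  mode <- match.arg(mode)
  assert_that(u >= 0 && u <= 1, "u must lie in [0, 1]")
  assert_that(tau_rec > 0 && tau_facil > 0, "STP time constants must be > 0")
  structure(list(u = u, tau_rec = tau_rec, tau_facil = tau_facil, mode = mode),
            class = "stp_params")
}

#' Synapse parameter template
#'
#' Describes the synapses of one projection: peak conductance, reversal
#' potential, decay constant and optional short-term plasticity. Weights are
#' non-negative; the sign of the effect is carried by the reversal potential
#' (synapses with `e_rev >= -40` mV are routed to the excitatory input channel
#' of the target, others to the inhibitory one).
#'
#' @param weight Peak conductance g_max (nS), `>= 0`.
#' @param e_rev Reversal potential (mV).
#' @param tau_syn Exponential decay constant (ms); must equal the matching
#'   channel constant of the target neurons.
#' @param stp Optional [stp_params()].
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(weight, e_rev = 0, tau_syn = 5, stp = NULL) {
  assert_that(weight >= 0, "weight must be >= 0 (sign lives in e_rev)")
  assert_that(tau_syn > 0, "tau_syn must be > 0")
  if (!is.null(stp)) assert_that(inherits(stp, "stp_params"), "stp must be stp_params()")
  structure(list(weight = weight, e_rev = e_rev, tau_syn = tau_syn, stp = stp),
            class = "synapse_params")
}

receptor_of <- function(e_rev) if (e_rev >= -40) "exc" else "inh"

#' Pulse packet description
#'
#' A stimulus in which `n_sources` spike sources each emit on average `a`
#' spikes drawn from a Gaussian around `t_center` with spread `sigma`.
#'
#' @param n_sources Number of spike sources.
#' @param a Spikes per source (may be fractional; the total is rounded and the
#'   extra spikes distributed round-robin across sources).
#' @param sigma Temporal spread (ms).
#' @param t_center Packet center time (ms).
#' @return An object of class `pulse_packet`.
#' @export
pulse_packet <- function(n_sources, a, sigma, t_center) {
  assert_that(n_sources >= 1, "n_sources must be >= 1")
  assert_that(a >= 0, "a must be >= 0")
  assert_that(sigma >= 0, "sigma must be >= 0")
  structure(list(n_sources = as.integer(n_sources), a = a, sigma = sigma,
                 t_center = t_center),
            class = "pulse_packet")
}
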