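#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter container for the LIF neurons used in both the driven and the
#' autonomous reservoirs (and their spiking readouts).  Units are
#' milliseconds and millivolts; `dt` is the integration step, and one input
#' spike frame is consumed per step.
#'
#' @param tau_mem Membrane time constant (ms).
#' @param v_rest Resting potential (mV).
#' @param v_th Spike threshold (mV).
#' @param v_reset Post-spike reset potential (mV); the membrane is clamped
#'   here for the whole refractory period.
#' @param t_ref Absolute refractory period (ms).
#' @param dt Integration step (ms).
#'
#' @return An object of class `lif_params`.
#' @examples
#' lif_params()
#' @export
lif_params <- function(tau_mem = 20, v_rest = -70, v_th = -50,
                       v_reset = -70, t_ref = 5, dt = 1) {
  check_scalar_num(tau_mem, "tau_mem", lower = 0, strict_lower = TRUE)
  check_scalar_num(t_ref, "t_ref", lower = 0)
  check_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar_num(v_rest, "v_rest")
  check_scalar_num(v_th, "v_th")
  check_scalar_num(v_reset, "v_reset")
  if (!(v_reset <= v_rest && v_rest < v_th)) {
    stop_arg("LIF parameters must satisfy v_reset <= v_rest < v_th")
  }
  structure(list(tau_mem = tau_mem, v_rest = v_rest, v_th = v_th,
                 v_reset = v_reset, t_ref = t_ref, dt = dt),
            class = "lif_params")
}

#' Synaptic trace parameters
#'
#' Every reservoir neuron carries a fast trace `f(t)` and a slow trace `s(t)`:
#' both jump by 1 when the neuron spikes and decay exponentially otherwise
#' (time constants `tau_fast`, `tau_slow`).  The presynaptic trace used by the
#' supervised STDP readout rule decays with `tau_pre`, of the same order as
#' `tau_fast`.
#'
#' @param tau_fast Fast synaptic time constant (ms).
#' @param tau_slow Slow synaptic time constant (ms); must exceed `tau_fast`.
#' @param tau_pre Presynaptic STDP trace time constant (ms); defaults to
#'   `tau_fast`.
#'
#' @return An object of class `synapse_params`.
#' @examples
#' synapse_params()
#' @export
synapse_params <- function(tau_fast = 5, tau_slow = 100, tau_pre = tau_fast) {
  check_scalar_num(tau_fast, "tau_fast", lower = 0, strict_lower = TRUE)
  check_scalar_num(tau_slow, "tau_slow", lower = 0, strict_lower = TRUE)
  check_scalar_num(tau_pre, "tau_pre", lower = 0, strict_lower = TRUE)
  if (tau_slow <= tau_fast) {
    stop_arg("`tau_slow` must be greater than `tau_fast`")
  }
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow, tau_pre = tau_pre),
            class = "synapse_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF parameters: tau_mem=%g ms, V_rest=%g mV, V_th=%g mV, V_reset=%g mV, t_ref=%g ms, dt=%g ms\n",
    x$tau_mem, x$v_rest, x$v_th, x$v_reset, x$t_ref, x$dt))
  invisible(x)
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("Synapse traces: tau_fast=%g ms, tau_slow=%g ms, tau_pre=%g ms\n",
              x$tau_fast, x$tau_slow, x$tau_pre))
  invisible(x)
}
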