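#' Initialise reservoir state at rest
#'
#' @param n Number of neurons.
#' @param lif [lif_params()] giving the resting potential.
#' @return A `reservoir_state` list with membrane potentials `v` (at rest),
#'   remaining refractory times `ref_left`, fast/slow traces `f_trace`,
#'   `s_trace` (zero) and the spike indicator of the last step `spikes_t`.
#' @export
reservoir_state <- function(n, lif = lif_params()) {
  n <- check_count(n, "n")
  structure(list(v = rep(lif$v_rest, n),
                 ref_left = rep(0, n),
                 f_trace = rep(0, n),
                 s_trace = rep(0, n),
                 spikes_t = rep(0L, n)),
            class = "reservoir_state")
}

#' One leaky integrate-and-fire step
#'
#' Advances the membrane potentials by one step `dt` of
#' `tau_mem dV/dt = V_rest - V + I` using exponential-Euler integration
#' (exact for input current held constant over the step; forward Euler is
#' available for cross-checks).  Neurons reaching `v_th` emit a spike, are
#' reset to `v_reset` and stay clamped there while their refractory clock
#' runs; refractory neurons cannot spike.
#'
#' @param state A `reservoir_state`.
#' @param input_current Per-neuron input current (mV drive units).
#' @param lif [lif_params()].
#' @param method `"exponential"` (default) or `"euler"`.
#' @return The updated state; `state$spikes_t` holds the 0/1 spike indicator
#'   of this step.
#' @examples
#' st <- reservoir_state(1)
#' st <- lif_step(st, input_current = 25)
#' @export
lif_step <- function(state, input_current, lif = lif_params(),
                     method = c("exponential", "euler")) {
  method <- match.arg(method)
  if (anyNA(input_current) || any(!is.finite(input_current))) {
    bad <- which(!is.finite(input_current))
    stop(errorCondition(
      paste0("non-finite input current at neuron(s) ",
             paste(head(bad, 5L), collapse = ", ")),
      class = c("dar_numeric_error", "error")))
  }
  v <- state$v
  # run the refractory clock first: a neuron that spiked at step t is blocked
  # at steps t+1 ... t+t_ref-1 and may integrate (and spike) again t_ref steps
  # after the crossing
  ref <- pmax(state$ref_left - lif$dt, 0)
  active <- ref <= 0
  if (method == "exponential") {
    decay <- exp(-lif$dt / lif$tau_mem)
    v_inf <- lif$v_rest + input_current
    v[active] <- v_inf[active] + (v[active] - v_inf[active]) * decay
  } else {
    dv <- (lif$v_rest - v + input_current) * (lif$dt / lif$tau_mem)
    v[active] <- v[active] + dv[active]
  }
  v[!active] <- lif$v_reset
  spikes <- active & (v >= lif$v_th)
  v[spikes] <- lif$v_reset
  ref[spikes] <- lif$t_ref
  state$v <- v
  state$ref_left <- ref
  state$spikes_t <- as.integer(spikes)
  state
}

#' Update fast/slow synaptic traces
#'
#' Both traces decay exponentially (`tau_fast`, `tau_slow`) and jump by 1 for
#' every neuron that spiked this step.
#'
#' @param state A `reservoir_state`.
#' @param spike_indicator 0/1 vector of this step's spikes (defaults to
#'   `state$spikes_t`).
#' @param syn [synapse_params()].
#' @param dt Integration step (ms).
#' @return Updated state.
#' @export
update_traces <- function(state, spike_indicator = state$spikes_t,
                          syn = synapse_params(), dt = 1) {
  check_binary(spike_indicator, "spike_indicator")
  state$f_trace <- state$f_trace * exp(-dt / syn$tau_fast) + spike_indicator
  state$s_trace <- state$s_trace * exp(-dt / syn$tau_slow) + spike_indicator
  state
}

# Recurrent current of one network kind at one step.
#   driven: J_fast f(t) + u_D f_D(t)   (f_D column supplied as `drive`)
#   auto:   J_fast f(t) + J_slow s(t) + u f_in(t)
# For auto networks J_slow = u_D B w is rank <= Y, so its current is computed
# through the factors as (u_D B) (w s): O(NY) instead of O(N^2).
step_current <- function(net, state, drive_t) {
  i_fast <- as.vector(net$topology$j_fast %*% state$f_trace)
  if (!is.null(net$m_slow)) {
    i_slow <- as.vector(net$m_slow %*% as.vector(net$w %*% state$s_trace))
    i_fast + i_slow + drive_t
  } else {
    i_fast + drive_t
  }
}

#' Run a reservoir open loop on an input stream
#'
#' Steps the network for `n_steps` (default 300, one spike frame per step).
#' The input stream may be shorter than `n_steps`: it is zero-padded, and the
#' reservoir keeps running on its own recurrent activity.  State is reset to
#' rest, with traces zeroed, before the run.
#'
#' For a driven network the drive is `u_D %*% input_stream` (a continuous
#' rate-domain drive `f_D`); for an autonomous network it is
#' `u %*% input_stream` with a binary spike stream, plus the slow-synapse
#' recurrent current.
#'
#' @param network A `driven_network` or `auto_network`.
#' @param input_stream X x T numeric matrix (columns are time steps), or
#'   `NULL` for no input.
#' @param n_steps Trial length in steps.
#' @param record Which histories to keep: any of `"spikes"`, `"f"`, `"s"`,
#'   `"v"`.
#' @param reset Reset membrane and traces before running (default TRUE).
#' @return A list with `raster` (N x T 0/1 integer matrix) and, if requested,
#'   `f`, `s`, `v` histories (N x T), plus the final `state`.
#' @export
run_reservoir <- function(network, input_stream = NULL, n_steps = 300L,
                          record = c("spikes"), reset = TRUE) {
  n_steps <- check_count(n_steps, "n_steps")
  top <- network$topology
  is_driven <- inherits(network, "driven_network")
  u_in <- if (is_driven) network$u_d else network$u
  drive <- precompute_drive(u_in, input_stream, top$n_in, top$n_res, n_steps)
  if (!is_driven && !is.null(input_stream)) {
    # spiking input: synaptic filtering (driven f_D is already a rate drive)
    drive <- filter_drive(drive, network$syn$tau_fast, network$lif$dt)
  }
  st <- if (reset || is.null(network$state)) {
    reservoir_state(top$n_res, network$lif)
  } else {
    network$state
  }
  lif <- network$lif
  syn <- network$syn
  raster <- matrix(0L, top$n_res, n_steps)
  keep_f <- "f" %in% record
  keep_s <- "s" %in% record
  keep_v <- "v" %in% record
  f_hist <- if (keep_f) matrix(0, top$n_res, n_steps)
  s_hist <- if (keep_s) matrix(0, top$n_res, n_steps)
  v_hist <- if (keep_v) matrix(0, top$n_res, n_steps)
  for (t in seq_len(n_steps)) {
    cur <- step_current(network, st, drive[, t])
    st <- lif_step(st, cur, lif)
    st <- update_traces(st, st$spikes_t, syn, lif$dt)
    raster[, t] <- st$spikes_t
    if (keep_f) f_hist[, t] <- st$f_trace
    if (keep_s) s_hist[, t] <- st$s_trace
    if (keep_v) v_hist[, t] <- st$v
  }
  out <- list(raster = raster, state = st)
  if (keep_f) out$f <- f_hist
  if (keep_s) out$s <- s_hist
  if (keep_v) out$v <- v_hist
  out
}

# u_in %*% input as one BLAS product, zero-padded to n_steps columns.
precompute_drive <- function(u_in, input_stream, n_in, n_res, n_steps) {
  if (is.null(input_stream)) {
    return(matrix(0, n_res, n_steps))
  }
  if (!is.matrix(input_stream) || nrow(input_stream) != n_in) {
    stop_arg("`input_stream` must be a matrix with ", n_in,
             " rows (one per input channel); got ",
             if (is.matrix(input_stream)) nrow(input_stream) else "a non-matrix")
  }
  t_in <- min(ncol(input_stream), n_steps)
  drive <- matrix(0, n_res, n_steps)
  if (t_in > 0) {
    drive[, seq_len(t_in)] <- u_in %*% input_stream[, seq_len(t_in), drop = FALSE]
  }
  drive
}

# Input spikes reach the reservoir through fast synapses: the binary stream
# is filtered into a tau_fast trace before the input weights are applied.
# Filtering commutes with the linear map u, so the recursion runs on the
# N-dimensional drive.
filter_drive <- function(drive, tau, dt) {
  decay <- exp(-dt / tau)
  for (t in 2:ncol(drive)) {
    drive[, t] <- drive[, t - 1] * decay + drive[, t]
  }
  drive
}
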