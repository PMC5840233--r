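#' Derive an autonomous spiking network from a trained driven network
#'
#' The autonomous model inherits the driven reservoir unchanged
#' (`J_fast` is copied bitwise) and gains a second, slow set of recurrent
#' connections `J_slow = u_D %*% B %*% w` plus input weights
#' `u = u_D * u_r` (`u_r = 1` by default, so `u = u_D`).  `B` is an X x Y
#' matrix with i.i.d. Uniform(0, `b_max`) entries; because `J_slow` is the
#' product of N x X, X x Y and Y x N factors its rank is at most Y, and its
#' recurrent current is computed through the factors (never materialising
#' the N x N matrix unless [j_slow()] is asked for it).
#'
#' @param driven A trained [driven_network()].
#' @param b_max Upper bound of the uniform draw for `B` (default 0.15).
#' @param seed Seed for `B` and the readout initialisation.
#' @param u_r Scalar input gain on `u_D` (default 1).
#' @param b_scalar If `TRUE`, `B` is a single Uniform(0, `b_max`) scalar
#'   replicated across the X x Y matrix.
#' @param w_init_sd SD of the small random initial spiking readout `w'`.
#' @return An object of class `auto_network`.
#' @export
derive_auto <- function(driven, b_max = 0.15, seed = 1L, u_r = 1,
                        b_scalar = FALSE, w_init_sd = 0.1) {
  stopifnot(inherits(driven, "driven_network"))
  if (!isTRUE(driven$trained) || all(driven$w == 0)) {
    stop_arg("train driven first: derive_auto() needs a trained driven network")
  }
  check_scalar_num(b_max, "b_max", lower = 0)
  top <- driven$topology
  drawn <- with_seed(seed + 2L, {
    b <- if (b_scalar) {
      matrix(stats::runif(1, 0, b_max), top$n_in, top$n_out)
    } else {
      matrix(stats::runif(top$n_in * top$n_out, 0, b_max),
             top$n_in, top$n_out)
    }
    wp <- matrix(stats::rnorm(top$n_out * top$n_res, sd = w_init_sd),
                 top$n_out, top$n_res)
    list(b = b, wp = wp)
  })
  structure(list(topology = top, lif = driven$lif, syn = driven$syn,
                 u = driven$u_d * u_r,
                 b = drawn$b, w = driven$w,
                 m_slow = driven$u_d %*% drawn$b,  # N x Y factor of J_slow
                 w_prime = drawn$wp,
                 b_max = b_max, trained = FALSE, train_log = NULL,
                 seed = as.integer(seed)),
            class = "auto_network")
}

#' Materialise the slow recurrent weight matrix
#'
#' @param auto An [derive_auto()] network.
#' @return The dense N x N matrix `J_slow = u_D B w` (rank at most Y).
#' @export
j_slow <- function(auto) {
  stopifnot(inherits(auto, "auto_network"))
  auto$m_slow %*% auto$w
}

#' One supervised STDP update of the spiking readout
#'
#' For each output neuron j the weight change is
#' `dw'_j = eta * x_trace * (target_j(t) - actual_j(t))`: weights are
#' potentiated at desired-spike instants, depressed at actual-spike instants,
#' and untouched when both or neither occur, each scaled by the presynaptic
#' trace of the reservoir neurons.  Learning therefore stops exactly when the
#' actual readout spikes coincide with the target.
#'
#' @param w_prime Y x N readout weight matrix.
#' @param pre_trace Length-N presynaptic trace `x_trace`.
#' @param target_spikes_t,actual_spikes_t 0/1 vectors of length Y for this
#'   step.
#' @param eta Learning rate.
#' @param w_clip Optional bound: weights are clipped to `[-w_clip, w_clip]`.
#' @return Updated `w_prime`.
#' @export
stdp_step <- function(w_prime, pre_trace, target_spikes_t, actual_spikes_t,
                      eta = 5e-3, w_clip = NULL) {
  check_binary(target_spikes_t, "target_spikes_t")
  check_binary(actual_spikes_t, "actual_spikes_t")
  err <- as.numeric(target_spikes_t) - as.numeric(actual_spikes_t)
  if (any(err != 0)) {
    w_prime <- w_prime + eta * tcrossprod(err, pre_trace)
    if (!is.null(w_clip)) {
      w_prime[] <- pmin(pmax(w_prime, -w_clip), w_clip)
    }
  }
  w_prime
}

# Shared forward run of an autonomous network on one spike input, optionally
# with STDP plasticity against a spike target.  Returns readout spikes,
# counts, the updated w', and optionally the reservoir raster/rates.
auto_forward <- function(auto, spike_input, n_steps = 300L, target = NULL,
                         eta = 5e-3, w_clip = NULL, plastic = FALSE,
                         record_raster = FALSE) {
  top <- auto$topology
  lif <- auto$lif
  syn <- auto$syn
  drive <- precompute_drive(auto$u, spike_input, top$n_in, top$n_res, n_steps)
  if (!is.null(spike_input)) {
    drive <- filter_drive(drive, syn$tau_fast, lif$dt)
  }
  st <- reservoir_state(top$n_res, lif)
  ro_v <- rep(lif$v_rest, top$n_out)
  ro_ref <- rep(0, top$n_out)
  x_trace <- rep(0, top$n_res)
  wp <- auto$w_prime
  w <- auto$w
  m_slow <- auto$m_slow
  jf <- top$j_fast
  decay_pre <- exp(-lif$dt / syn$tau_pre)
  decay_mem <- exp(-lif$dt / lif$tau_mem)
  out_spikes <- matrix(0L, top$n_out, n_steps)
  raster <- if (record_raster) matrix(0L, top$n_res, n_steps)
  tgt <- if (!is.null(target)) target$spike_target
  for (t in seq_len(n_steps)) {
    cur <- as.vector(jf %*% st$f_trace) +
      as.vector(m_slow %*% as.vector(w %*% st$s_trace)) + drive[, t]
    st <- lif_step(st, cur, lif)
    st <- update_traces(st, st$spikes_t, syn, lif$dt)
    x_trace <- x_trace * decay_pre + st$spikes_t
    # spiking readout: integrates w' %*% f(t) with the same LIF dynamics
    ro_cur <- as.vector(wp %*% st$f_trace)
    ro_ref <- pmax(ro_ref - lif$dt, 0)
    ro_active <- ro_ref <= 0
    v_inf <- lif$v_rest + ro_cur
    ro_v[ro_active] <- v_inf[ro_active] +
      (ro_v[ro_active] - v_inf[ro_active]) * decay_mem
    ro_v[!ro_active] <- lif$v_reset
    ro_sp <- ro_active & (ro_v >= lif$v_th)
    ro_v[ro_sp] <- lif$v_reset
    ro_ref[ro_sp] <- lif$t_ref
    actual <- as.integer(ro_sp)
    out_spikes[, t] <- actual
    if (record_raster) raster[, t] <- st$spikes_t
    if (plastic) {
      wp <- stdp_step(wp, x_trace, tgt[, t], actual, eta = eta,
                      w_clip = w_clip)
    }
  }
  list(out_spikes = out_spikes, counts = rowSums(out_spikes),
       w_prime = wp, raster = raster)
}

#' Train the autonomous readout with supervised STDP
#'
#' Per epoch, the labelled input patterns of all classes are presented
#' sequentially in class order (Class 1 -> Class 2 -> ...).  Each pattern is
#' presented for `n_steps` steps (default 300); inputs shorter than that are
#' zero-padded, so the network keeps training on its own recurrent activity
#' after the input ends.  Reservoir and readout are reset to rest before
#' every pattern.  At every step the presynaptic trace is updated, the
#' spiking readout integrates `w' %*% f(t)`, and [stdp_step()] moves `w'`
#' toward the one-hot spike target of the pattern's class.
#'
#' @param auto An [derive_auto()] network.
#' @param inputs List of X x T binary spike matrices (T <= `n_steps`).
#' @param labels Integer class labels (0-based) parallel to `inputs`.
#' @param targets List of [make_one_hot_target()] patterns indexed by class
#'   (element `c + 1` is the target of class `c`).
#' @param n_epochs Training epochs (default 30).
#' @param eta Initial STDP learning rate.
#' @param eta_decay Per-epoch multiplicative decay of `eta` (annealing the
#'   rule lets the readout lock spike timing precisely; 1 = constant rate).
#' @param w_clip Optional readout weight bound.
#' @param n_steps Presentation length per pattern.
#' @return The trained network; `$train_log` holds one row per epoch with
#'   the mean van Rossum distance (tau = 10 ms) between the actual readout
#'   spikes and the target trains.
#' @export
train_auto <- function(auto, inputs, labels, targets, n_epochs = 30,
                       eta = 2, eta_decay = 0.92, w_clip = NULL,
                       n_steps = 300L) {
  stopifnot(inherits(auto, "auto_network"))
  n_epochs <- check_count(n_epochs, "n_epochs", min = 0L)
  if (length(inputs) != length(labels)) {
    stop_arg("`inputs` and `labels` must have the same length")
  }
  missing_lab <- setdiff(unique(labels), seq_along(targets) - 1L)
  if (length(missing_lab) > 0) {
    stop(errorCondition(
      paste0("no target pattern for class label(s) ",
             paste(missing_lab, collapse = ", ")),
      class = c("dar_key_error", "error")))
  }
  # class-sequential presentation: patterns cycle Class 1 -> Class 2 -> ...
  # round-robin (one pattern per class per round), so no class is massed at
  # the end of an epoch
  within_idx <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  ord <- order(within_idx, labels)
  log <- data.frame(epoch = integer(0), mean_vr = numeric(0))
  for (ep in seq_len(n_epochs)) {
    eta_ep <- eta * eta_decay^(ep - 1)
    vr <- numeric(0)
    for (i in ord) {
      tgt <- targets[[labels[i] + 1L]]
      res <- auto_forward(auto, inputs[[i]], n_steps = n_steps, target = tgt,
                          eta = eta_ep, w_clip = w_clip, plastic = TRUE)
      auto$w_prime <- res$w_prime
      vr <- c(vr, mean(vapply(seq_len(nrow(tgt$spike_target)), function(j) {
        van_rossum(res$out_spikes[j, ], tgt$spike_target[j, ], tau = 10)
      }, 0)))
    }
    log <- rbind(log, data.frame(epoch = ep, mean_vr = mean(vr)))
  }
  auto$trained <- n_epochs > 0
  auto$train_log <- log
  auto
}

#' Classify one spike input with a single autonomous model
#'
#' Runs the network for `n_steps` steps and assigns the class of the output
#' neuron with the highest spike count; ties go to the lowest class index.
#'
#' @param auto A trained [train_auto()] network.
#' @param spike_input X x T binary spike matrix.
#' @param n_steps Presentation length.
#' @return List with `class_id` (0-based) and `counts` (per-class readout
#'   spike counts).
#' @export
predict_single <- function(auto, spike_input, n_steps = 300L) {
  stopifnot(inherits(auto, "auto_network"))
  if (all(auto$w_prime == 0)) {
    warning("readout weights are all zero (untrained network); counts will be zero")
  }
  res <- auto_forward(auto, spike_input, n_steps = n_steps, plastic = FALSE)
  list(class_id = which.max(res$counts) - 1L, counts = res$counts)
}

#' van Rossum distance between two spike trains
#'
#' Both 0/1 trains are filtered with a causal exponential kernel
#' `exp(-t / tau)` and the distance is
#' `sqrt(dt / tau * sum((h1 - h2)^2))`.
#'
#' @param s1,s2 0/1 spike indicator vectors of equal length.
#' @param tau Kernel time constant (ms), default 10.
#' @param dt Step (ms).
#' @return Non-negative scalar distance.
#' @export
van_rossum <- function(s1, s2, tau = 10, dt = 1) {
  if (length(s1) != length(s2)) stop_arg("spike trains must have equal length")
  decay <- exp(-dt / tau)
  h1 <- stats::filter(as.numeric(s1), decay, method = "recursive")
  h2 <- stats::filter(as.numeric(s2), decay, method = "recursive")
  sqrt(dt / tau * sum((as.numeric(h1) - as.numeric(h2))^2))
}

#' @export
print.auto_network <- function(x, ...) {
  cat(sprintf("Autonomous network: %d x %d -> %d, b_max=%g, %s\n",
              x$topology$n_in, x$topology$n_res, x$topology$n_out, x$b_max,
              if (isTRUE(x$trained)) {
                sprintf("trained (final mean van Rossum %.3f)",
                        tail(x$train_log$mean_vr, 1))
              } else "readout untrained"))
  invisible(x)
}
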