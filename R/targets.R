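#' Bump specification for one-hot targets
#'
#' Describes the "high activity" bump the labelled class's output neuron must
#' produce while all other outputs stay silent.  The rate-domain bump is a
#' raised cosine of amplitude `amplitude` over `[t0, t0 + dur - 1]` (smooth,
#' so the driven input derivative is well behaved); the spike-domain target
#' places one spike every `spike_period` steps inside the same window.
#'
#' @param t0 First step of the bump window (1-based).
#' @param dur Bump duration in steps.
#' @param amplitude Peak rate amplitude (normalized rate units).
#' @param spike_period Target inter-spike interval in steps; must not beat
#'   the readout refractory period.
#' @param n_steps Trial length T (steps).
#' @return A `bump_spec` list.
#' @export
bump_spec <- function(t0 = 51, dur = 250, amplitude = 1, spike_period = 5,
                      n_steps = 300) {
  t0 <- check_count(t0, "t0")
  dur <- check_count(dur, "dur")
  n_steps <- check_count(n_steps, "n_steps")
  check_scalar_num(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  spike_period <- check_count(spike_period, "spike_period")
  if (t0 + dur - 1 > n_steps) {
    stop_arg("bump window [", t0, ", ", t0 + dur - 1,
             "] exceeds the trial length T = ", n_steps)
  }
  structure(list(t0 = t0, dur = dur, amplitude = amplitude,
                 spike_period = spike_period, n_steps = n_steps),
            class = "bump_spec")
}

#' One-hot target pattern for a class
#'
#' Builds the desired output of a `n_classes`-way problem for the pattern
#' labelled `class_id`: the class's row of `f_out` carries the rate bump, all
#' other rows are zero; `spike_target` is the matching one-hot spike-train
#' target used for supervised STDP training of the spiking readout.
#'
#' @param class_id Class label in `0 ... n_classes - 1`.
#' @param n_classes Number of classes Y.
#' @param bump A [bump_spec()].
#' @return A `target_pattern` with fields `f_out` (Y x T), `spike_target`
#'   (Y x T, 0/1) and `class_id`.
#' @examples
#' tp <- make_one_hot_target(0, 3)
#' rowSums(tp$f_out > 0)  # only row 1 active
#' @export
make_one_hot_target <- function(class_id, n_classes, bump = bump_spec()) {
  n_classes <- check_count(n_classes, "n_classes")
  if (!is.numeric(class_id) || length(class_id) != 1L ||
      class_id != round(class_id) || class_id < 0 || class_id >= n_classes) {
    stop_arg("`class_id` must be an integer in 0 ... ", n_classes - 1)
  }
  T <- bump$n_steps
  f_out <- matrix(0, n_classes, T)
  spike_target <- matrix(0L, n_classes, T)
  win <- seq(bump$t0, bump$t0 + bump$dur - 1)
  phase <- (win - bump$t0) / (bump$dur - 1)
  f_out[class_id + 1L, win] <- bump$amplitude * 0.5 * (1 - cos(2 * pi * phase))
  spike_times <- win[(win - bump$t0) %% bump$spike_period == 0]
  spike_target[class_id + 1L, spike_times] <- 1L
  structure(list(f_out = f_out, spike_target = spike_target,
                 class_id = as.integer(class_id), bump = bump),
            class = "target_pattern")
}

#' Apportion the fast synaptic delay across input channels
#'
#' Splits `tau_fast` into `n_parts` positive parts summing to `tau_fast`
#' exactly, one per driven input channel.  `"equal"` gives `tau_fast /
#' n_parts` everywhere; `"random"` draws positive proportions and rescales
#' (the last part absorbs rounding so the sum is exact in floating point).
#'
#' @param tau_fast Total fast time constant (ms).
#' @param n_parts Number of parts (normally the input count X; the
#'   reservoir-size variant is obtained by passing N).
#' @param mode `"equal"` or `"random"`.
#' @param seed Seed for the random split.
#' @return Numeric vector of length `n_parts`, summing to `tau_fast` exactly.
#' @export
apportion_tau <- function(tau_fast, n_parts, mode = c("equal", "random"),
                          seed = 1L) {
  check_scalar_num(tau_fast, "tau_fast", lower = 0, strict_lower = TRUE)
  n_parts <- check_count(n_parts, "n_parts")
  mode <- match.arg(mode)
  parts <- if (mode == "equal") {
    rep(tau_fast / n_parts, n_parts)
  } else {
    with_seed(seed, {
      p <- stats::runif(n_parts, min = 0.2, max = 1)
      tau_fast * p / sum(p)
    })
  }
  # force the sum to be exact in floating point
  parts[n_parts] <- tau_fast - sum(parts[-n_parts])
  stopifnot(all(parts > 0))
  parts
}

# Default (k, j) pairing of driven input channels to output rows: output row
# j owns a contiguous block of floor(X/Y) channels; the remainder channels
# are assigned round-robin.
channel_row_map <- function(n_in, n_out) {
  base <- n_in %/% n_out
  map <- rep(seq_len(n_out), each = base)
  rem <- n_in - base * n_out
  if (rem > 0) map <- c(map, seq_len(rem))
  map
}

#' Derive the driven input from a target pattern
#'
#' The driven network is fed a high-pass filtered copy of its own desired
#' output: channel k carries `f_D^k = f_out_j + tau_fast^k * d f_out_j / dt`,
#' where `tau_fast^k` are the apportioned delays (summing to `tau_fast`) and
#' j is the output row the channel is mapped to.  With a single input channel
#' and `tau^1 = tau_fast` this reduces to the unapportioned drive
#' `f_D = f_out + tau_fast * d f_out / dt`.  The derivative is taken by
#' central finite differences at the integration step (one-sided at the
#' ends).
#'
#' @param target A [make_one_hot_target()] pattern (or any object with an
#'   `f_out` matrix).
#' @param apportionment Vector of per-channel delay parts from
#'   [apportion_tau()]; its length sets the input count X.
#' @param dt Integration step (ms).
#' @param row_map Optional integer vector mapping each channel to an output
#'   row; defaults to [contiguous blocks][channel_row_map].
#' @return X x T numeric matrix of driven drive `f_D`.
#' @export
derive_driven_input <- function(target, apportionment, dt = 1,
                                row_map = NULL) {
  f_out <- target$f_out
  n_out <- nrow(f_out)
  T <- ncol(f_out)
  n_in <- length(apportionment)
  if (is.null(row_map)) row_map <- channel_row_map(n_in, n_out)
  if (length(row_map) != n_in) {
    stop_arg("`row_map` length (", length(row_map),
             ") must equal the apportionment length (", n_in, ")")
  }
  # central differences, one-sided at the boundaries
  d_out <- matrix(0, n_out, T)
  if (T >= 3) {
    d_out[, 2:(T - 1)] <- (f_out[, 3:T, drop = FALSE] -
                             f_out[, 1:(T - 2), drop = FALSE]) / (2 * dt)
  }
  if (T >= 2) {
    d_out[, 1] <- (f_out[, 2] - f_out[, 1]) / dt
    d_out[, T] <- (f_out[, T] - f_out[, T - 1]) / dt
  }
  f_d <- matrix(0, n_in, T)
  for (k in seq_len(n_in)) {
    j <- row_map[k]
    f_d[k, ] <- f_out[j, ] + apportionment[k] * d_out[j, ]
  }
  f_d
}
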