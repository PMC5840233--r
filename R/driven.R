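#' Construct an (untrained) driven network
#'
#' The driven network is the rate-readout half of the driven/autonomous
#' construction: a spiking reservoir (topology `J_fast`) driven through input
#' weights `u_D` by a filtered copy of the desired output, with a linear
#' readout `w` trained by recursive least squares (RLS) so that
#' `w %*% f(t) ~ f_out(t)`, where `f(t)` are the fast synaptic traces of the
#' reservoir spikes.
#'
#' `u_D` entries are i.i.d. Normal(0, `u_scale^2 / X`): the summed drive at a
#' reservoir neuron then has standard deviation `u_scale` (mV per unit target
#' rate) independent of the input count, which keeps the reservoir in its
#' spiking regime for any X.
#'
#' @param topology A [build_topology()] object.
#' @param lif,syn Neuron and synapse parameters.
#' @param u_scale Input drive scale (mV); see Details.
#' @param alpha RLS regularizer: `P` is initialised to `I / alpha`.
#' @param seed Seed for the `u_D` draw.
#' @return An object of class `driven_network`.
#' @export
driven_network <- function(topology, lif = lif_params(),
                           syn = synapse_params(), u_scale = 30,
                           alpha = 1, seed = 1L) {
  stopifnot(inherits(topology, "topology"))
  check_scalar_num(u_scale, "u_scale", lower = 0, strict_lower = TRUE)
  check_scalar_num(alpha, "alpha", lower = 0, strict_lower = TRUE)
  u_d <- with_seed(seed + 1L, {
    matrix(stats::rnorm(topology$n_res * topology$n_in,
                        sd = u_scale / sqrt(topology$n_in)),
           topology$n_res, topology$n_in)
  })
  structure(list(topology = topology, lif = lif, syn = syn,
                 u_d = u_d, u_scale = u_scale,
                 w = matrix(0, topology$n_out, topology$n_res),
                 p_mat = diag(topology$n_res) / alpha,
                 alpha = alpha, trained = FALSE,
                 rls_log = NULL, seed = as.integer(seed)),
            class = "driven_network")
}

#' Train the driven readout with recursive least squares
#'
#' Presents each target pattern for `n_epochs` epochs.  At every step the
#' reservoir is driven by the apportioned copy of the target
#' ([derive_driven_input()]), the readout basis is the vector of fast traces
#' `x(t) = f(t)`, and the RLS rule updates `w` and the inverse-correlation
#' matrix `P` toward `w %*% x(t) = f_out(t)`.  Membrane potentials and traces
#' are reset to rest before every pattern presentation.
#'
#' @param driven A [driven_network()].
#' @param targets A single [make_one_hot_target()] pattern or a list of them.
#' @param n_epochs Training epochs (default 15).
#' @param apportionment Per-channel delay split; defaults to the equal split
#'   of `tau_fast` over the X input channels.
#' @param n_steps Trial length (defaults to the target length).
#' @return The trained network; `$rls_log` holds the per-epoch normalized
#'   RMSE (RMSE of the online readout against the target, divided by the
#'   target's dynamic range).
#' @export
train_driven <- function(driven, targets, n_epochs = 15,
                         apportionment = NULL, n_steps = NULL) {
  stopifnot(inherits(driven, "driven_network"))
  if (inherits(targets, "target_pattern")) targets <- list(targets)
  if (length(targets) == 0) stop_arg("`targets` must be non-empty")
  n_epochs <- check_count(n_epochs, "n_epochs", min = 0L)
  top <- driven$topology
  if (is.null(apportionment)) {
    apportionment <- apportion_tau(driven$syn$tau_fast, top$n_in)
  }
  drives <- lapply(targets, derive_driven_input, apportionment = apportionment,
                   dt = driven$lif$dt)
  if (is.null(n_steps)) n_steps <- ncol(targets[[1]]$f_out)
  w <- driven$w
  P <- driven$p_mat
  log <- data.frame(epoch = integer(0), nrmse = numeric(0))
  rng <- max(vapply(targets, function(tp) max(tp$f_out), 0)) -
    min(vapply(targets, function(tp) min(tp$f_out), 0))
  for (ep in seq_len(n_epochs)) {
    sq_err <- 0
    n_err <- 0
    for (i in seq_along(targets)) {
      f_out <- targets[[i]]$f_out
      drive <- precompute_drive(driven$u_d, drives[[i]], top$n_in,
                                top$n_res, n_steps)
      st <- reservoir_state(top$n_res, driven$lif)
      for (t in seq_len(n_steps)) {
        cur <- as.vector(top$j_fast %*% st$f_trace) + drive[, t]
        st <- lif_step(st, cur, driven$lif)
        st <- update_traces(st, st$spikes_t, driven$syn, driven$lif$dt)
        x <- st$f_trace
        px <- as.vector(P %*% x)
        xpx <- sum(x * px)
        if (!is.finite(xpx) || 1 + xpx <= 0) {
          warning("RLS inverse-correlation matrix lost positive-definiteness at epoch ",
                  ep, "; resetting P")
          P <- diag(top$n_res) / driven$alpha
          px <- as.vector(P %*% x)
          xpx <- sum(x * px)
        }
        k <- px / (1 + xpx)
        err <- as.vector(w %*% x) - f_out[, t]
        w <- w - tcrossprod(err, k)
        P <- P - tcrossprod(k, px)
        sq_err <- sq_err + sum(err^2)
        n_err <- n_err + length(err)
      }
    }
    log <- rbind(log, data.frame(epoch = ep,
                                 nrmse = sqrt(sq_err / n_err) / rng))
  }
  driven$w <- w
  driven$p_mat <- P
  driven$trained <- n_epochs > 0 && any(w != 0)
  driven$rls_log <- log
  driven$apportionment <- apportionment
  driven
}

#' Frozen-weight readout of a driven network on a target
#'
#' Runs the driven reservoir on the target's own derived drive with the
#' trained `w` frozen and returns the readout trace and its normalized RMSE
#' against `f_out` (RMSE over all outputs and steps, divided by the target's
#' dynamic range).
#'
#' @inheritParams train_driven
#' @param target A single [make_one_hot_target()] pattern.
#' @return List with `readout` (Y x T), `nrmse`, and the reservoir `raster`.
#' @export
driven_readout <- function(driven, target, apportionment = NULL,
                           n_steps = NULL) {
  stopifnot(inherits(driven, "driven_network"))
  top <- driven$topology
  if (is.null(apportionment)) {
    apportionment <- driven$apportionment %||%
      apportion_tau(driven$syn$tau_fast, top$n_in)
  }
  if (is.null(n_steps)) n_steps <- ncol(target$f_out)
  drive_in <- derive_driven_input(target, apportionment, dt = driven$lif$dt)
  run <- run_reservoir(driven, drive_in, n_steps = n_steps, record = c("spikes", "f"))
  readout <- driven$w %*% run$f
  rng <- max(target$f_out) - min(target$f_out)
  nrmse <- sqrt(mean((readout - target$f_out)^2)) / rng
  list(readout = readout, nrmse = nrmse, raster = run$raster)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.driven_network <- function(x, ...) {
  cat(sprintf("Driven network: %d x %d -> %d, %s\n",
              x$topology$n_in, x$topology$n_res, x$topology$n_out,
              if (x$trained) {
                sprintf("trained (final NRMSE %.3f)", tail(x$rls_log$nrmse, 1))
              } else "untrained"))
  invisible(x)
}
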