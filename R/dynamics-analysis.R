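#' Eigenvalue spectrum of a recurrent weight matrix
#'
#' Full complex spectrum of a (fast or slow) recurrent weight matrix, the
#' number of modes whose real part exceeds 1 — modes that sustain
#' long-lasting oscillatory activity — and the spectral radius.  The
#' criterion is applied to the raw weight matrix.
#'
#' @param weight_matrix Square numeric matrix (dense or sparse).
#' @return An `ev_report`: `eigenvalues` (complex), `n_modes` (count with
#'   `Re > 1`), `spectral_radius`.
#' @examples
#' ev_spectrum(diag(c(1.5, 0.2, -3)))$n_modes  # 1
#' @export
ev_spectrum <- function(weight_matrix) {
  m <- as.matrix(weight_matrix)
  if (nrow(m) != ncol(m)) stop_arg("`weight_matrix` must be square")
  ev <- eigen(m, only.values = TRUE)$values
  structure(list(eigenvalues = ev,
                 n_modes = sum(Re(ev) > 1),
                 spectral_radius = max(Mod(ev))),
            class = "ev_report")
}

#' Fast/slow spectra of an autonomous network
#'
#' @param auto An `auto_network`.
#' @return List of two `ev_report`s, `fast` and `slow`.
#' @export
auto_spectra <- function(auto) {
  stopifnot(inherits(auto, "auto_network"))
  list(fast = ev_spectrum(auto$topology$j_fast),
       slow = ev_spectrum(j_slow(auto)))
}

#' @export
print.ev_report <- function(x, ...) {
  cat(sprintf("EV spectrum: %d eigenvalues, %d modes with Re > 1, spectral radius %.3f\n",
              length(x$eigenvalues), x$n_modes, x$spectral_radius))
  invisible(x)
}

#' Per-neuron firing-rate trajectories from a spike raster
#'
#' Causal exponential filtering of the spikes (kernel
#' `exp(-t / tau) / tau`, unit area), scaled to spikes per second.
#'
#' @param spike_raster N x T 0/1 matrix.
#' @param smoothing_tau Filter time constant (ms), default 20.
#' @param dt Step (ms).
#' @param label Optional class/instance label carried along.
#' @return A `trajectory_record`: `rates` (N x T, spikes/s), `label`.
#' @export
rates_from_raster <- function(spike_raster, smoothing_tau = 20, dt = 1,
                              label = NA) {
  check_binary(spike_raster, "spike_raster")
  if (!is.matrix(spike_raster)) spike_raster <- matrix(spike_raster, nrow = 1)
  decay <- exp(-dt / smoothing_tau)
  scale <- 1000 / smoothing_tau  # spikes/ms kernel height -> spikes/s
  rates <- t(apply(spike_raster, 1, function(s) {
    as.numeric(stats::filter(as.numeric(s) * scale, decay,
                             method = "recursive"))
  }))
  structure(list(rates = rates, label = label), class = "trajectory_record")
}

#' Euclidean distance between two reservoir trajectories
#'
#' Per-step population distance
#' `d(t) = sqrt(mean_i (r_i1(t) - r_i2(t))^2)` between the firing-rate
#' trajectories of two trials, plus its time mean.  Large distances between
#' classes and small distances within a class indicate a reservoir that
#' discriminates while generalizing.
#'
#' @param rec1,rec2 [rates_from_raster()] records with matching dimensions.
#' @return List with `d` (length-T series) and `mean` (time average).
#' @export
trajectory_distance <- function(rec1, rec2) {
  r1 <- rec1$rates
  r2 <- rec2$rates
  if (!all(dim(r1) == dim(r2))) {
    stop_arg("trajectories must have matching N and T")
  }
  d <- sqrt(colMeans((r1 - r2)^2))
  list(d = d, mean = mean(d))
}

#' Inter- vs intra-class trajectory separation
#'
#' Runs every labelled spike input through the (fixed) autonomous reservoir,
#' smooths the rasters into rate trajectories and averages the pairwise
#' trajectory distance within and between classes.
#'
#' @param auto An `auto_network` (readout training is irrelevant here: the
#'   trajectories depend only on the fixed reservoir weights).
#' @param inputs List of X x T binary spike inputs.
#' @param labels Parallel 0-based class labels.
#' @param n_steps Trial length.
#' @param smoothing_tau Rate filter constant (ms).
#' @return List with `intra`, `inter` (mean distances) and the full pair
#'   table `pairs` (i, j, same_class, distance).
#' @export
trajectory_separation <- function(auto, inputs, labels, n_steps = 300L,
                                  smoothing_tau = 20) {
  stopifnot(inherits(auto, "auto_network"))
  recs <- lapply(seq_along(inputs), function(i) {
    run <- auto_forward(auto, inputs[[i]], n_steps = n_steps,
                        plastic = FALSE, record_raster = TRUE)
    rates_from_raster(run$raster, smoothing_tau = smoothing_tau,
                      dt = auto$lif$dt, label = labels[i])
  })
  pairs <- utils::combn(length(recs), 2)
  tab <- data.frame(i = pairs[1, ], j = pairs[2, ],
                    same_class = labels[pairs[1, ]] == labels[pairs[2, ]],
                    distance = apply(pairs, 2, function(p) {
                      trajectory_distance(recs[[p[1]]], recs[[p[2]]])$mean
                    }))
  list(intra = mean(tab$distance[tab$same_class]),
       inter = mean(tab$distance[!tab$same_class]),
       pairs = tab)
}
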