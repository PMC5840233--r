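# Small shared fixtures, built in code.  Networks are deliberately tiny so
# the unit suite stays fast; the acceptance tests build the full-size ones.

tiny_topology <- function(n_res = 60, n_in = 2, n_out = 1, p_conn = 0.2,
                          seed = 11) {
  build_topology(n_res, n_in, n_out, p_conn, seed = seed)
}

tiny_trained_driven <- function(n_res = 60, n_in = 2, n_out = 1, seed = 11,
                                n_epochs = 3, u_scale = 60,
                                bump = bump_spec(
                                  t0 = 11, dur = 80, spike_period = 5,
                                  n_steps = 100)) {
  top <- tiny_topology(n_res, n_in, n_out, seed = seed)
  targets <- lapply(seq_len(n_out) - 1, make_one_hot_target,
                    n_classes = n_out, bump = bump)
  dn <- driven_network(top, u_scale = u_scale, seed = seed)
  train_driven(dn, targets, n_epochs = n_epochs)
}

random_spike_input <- function(n_in = 2, n_steps = 100, rate = 0.3,
                               seed = 21) {
  withr::with_seed(seed, {
    matrix(stats::rbinom(n_in * n_steps, 1, rate), n_in, n_steps)
  })
}

# Tiny encoded 2-class scan data (built once per test run): 30x30 clips,
# 11x11 scan windows, 2 clips per class.
.tiny_scan_cache <- new.env(parent = emptyenv())
tiny_scan_data <- function() {
  if (is.null(.tiny_scan_cache$data)) {
    specs <- list(
      horiz = scene_spec(image_size = c(30, 30), n_frames = 40,
                         object_shape = "square", object_size = 8,
                         motion_class = "oscillate_x", speed = 2),
      vert = scene_spec(image_size = c(30, 30), n_frames = 40,
                        object_shape = "square", object_size = 8,
                        motion_class = "translate_y", speed = 2))
    ds <- generate_dataset(specs, n_train_per_class = 2,
                           n_test_per_class = 0, seed = 5)
    enc <- encoder_params(bb_size = 11, stride = 3, min_active_frac = 0)
    .tiny_scan_cache$data <- list(
      train = lapply(ds$train, function(cl) video_to_scans(cl$frames, enc)),
      labels_train = ds$labels_train)
  }
  .tiny_scan_cache$data
}

# Independent scalar LIF oracle: forward simulation written separately from
# the package's vectorized implementation (used to cross-check spike times).
oracle_lif_first_spike <- function(current, tau_mem = 20, v_rest = -70,
                                   v_th = -50, dt = 1, t_max = 500) {
  # closed form: threshold crossing of V(t) = v_rest + I (1 - exp(-t/tau))
  if (current <= v_th - v_rest) return(Inf)
  -tau_mem * log(1 - (v_th - v_rest) / current)
}
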