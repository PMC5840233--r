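config_defaults <- function() {
  list(
    # topology
    n_res = 400L, p_conn = 0.1, weight_scale = 30, u_scale = 30,
    # neuron / synapse constants (ms, mV)
    tau_mem = 20, tau_fast = 5, tau_slow = 100, tau_pre = 5,
    v_th = -50, v_rest = -70, v_reset = -70, t_ref = 5, dt = 1,
    # D/A construction and training
    b_max = 0.15, eta = 2, eta_decay = 0.92,
    epochs_driven = 15L, epochs_auto = 30L,
    trial_steps = 300L,
    # one-hot bump target
    bump_t0 = 51L, bump_dur = 250L, bump_amplitude = 1, spike_period = 5L,
    # encoder
    thresholds = c(1, 2, 4, 8, 16, 32), binarize_theta = 0.1,
    bb_size = 41L, stride = 10L,
    min_active_frac = 0.08, max_active_frac = 0.75,
    # seeds
    seed = 1L
  )
}

#' Experiment configuration
#'
#' Single configuration object shared by all pipeline stages, holding the
#' reservoir topology, LIF/synapse constants, D/A construction and training
#' schedule, one-hot bump target, encoder settings and the master seed.
#' Unknown keys are rejected.  A master seed fans out to per-stage seeds
#' through a fixed counter scheme (`stage_seed = (master * 31 + stage) mod
#' (2^31 - 1)`), so each stage is independently reproducible.
#'
#' @param ... Named overrides of the defaults (see [config_defaults()] via
#'   `experiment_config()` with no arguments for the full key list).
#' @return An `experiment_config` list.
#' @examples
#' cfg <- experiment_config(n_res = 200, b_max = 0.1)
#' @export
experiment_config <- function(...) {
  overrides <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(errorCondition(
      paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = c("dar_config_error", "error")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  check_count(cfg$n_res, "n_res")
  check_scalar_num(cfg$p_conn, "p_conn", lower = 0, upper = 1,
                   strict_lower = TRUE)
  check_scalar_num(cfg$b_max, "b_max", lower = 0)
  check_scalar_num(cfg$eta, "eta", lower = 0, strict_lower = TRUE)
  check_count(cfg$epochs_driven, "epochs_driven", min = 0L)
  check_count(cfg$epochs_auto, "epochs_auto", min = 0L)
  check_count(cfg$trial_steps, "trial_steps")
  # delegate the rest to the domain constructors
  config_lif(cfg)
  config_syn(cfg)
  config_bump(cfg)
  config_encoder(cfg)
  invisible(cfg)
}

config_lif <- function(cfg) {
  lif_params(tau_mem = cfg$tau_mem, v_rest = cfg$v_rest, v_th = cfg$v_th,
             v_reset = cfg$v_reset, t_ref = cfg$t_ref, dt = cfg$dt)
}

config_syn <- function(cfg) {
  synapse_params(tau_fast = cfg$tau_fast, tau_slow = cfg$tau_slow,
                 tau_pre = cfg$tau_pre)
}

config_bump <- function(cfg) {
  bump_spec(t0 = cfg$bump_t0, dur = cfg$bump_dur,
            amplitude = cfg$bump_amplitude, spike_period = cfg$spike_period,
            n_steps = cfg$trial_steps)
}

config_encoder <- function(cfg) {
  encoder_params(thresholds = cfg$thresholds,
                 binarize_theta = cfg$binarize_theta, bb_size = cfg$bb_size,
                 stride = cfg$stride, min_active_frac = cfg$min_active_frac,
                 max_active_frac = cfg$max_active_frac)
}

#' Read / write an experiment config as JSON
#'
#' `write_config()` serializes the resolved config; `read_config()` parses
#' and re-validates it (unknown keys are rejected), so
#' `read_config(write_config(cfg))` round-trips canonically.
#'
#' @param config An [experiment_config()].
#' @param path JSON file path.
#' @return `read_config()` returns an `experiment_config`; `write_config()`
#'   the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, raw)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "Experiment config: N=%d, p=%g, b_max=%g, epochs D/A=%d/%d, T=%d, bb=%d, seed=%d\n",
    x$n_res, x$p_conn, x$b_max, x$epochs_driven, x$epochs_auto,
    x$trial_steps, x$bb_size, x$seed))
  invisible(x)
}

#' Run a full experiment from a config
#'
#' End-to-end pipeline on pre-generated clips: encode every clip to CRLTB
#' scans, train the five-scan ensemble on the training split, evaluate on
#' the test split, and compute the dynamical diagnostics (fast/slow spectra
#' of the C-scan autonomous model).  If `out_dir` is given, the resolved
#' config (JSON), the metrics and confusion matrix (CSV), the training logs
#' (CSV) and the model (RDS) are written there.
#'
#' @param config An [experiment_config()] or a path to its JSON file.
#' @param data A [generate_dataset()] result (or a list with the same
#'   `train` / `test` / labels fields holding `frames` arrays).
#' @param out_dir Optional output directory.
#' @param k_list Top-k levels for evaluation.
#' @return List with `model`, `evaluation`, `spectra` and `paths` (written
#'   files, if any).
#' @export
run_experiment <- function(config, data, out_dir = NULL, k_list = c(1, 3, 5)) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "experiment_config"))
  enc <- config_encoder(config)
  train_scans <- lapply(data$train, function(cl) video_to_scans(cl$frames, enc))
  test_scans <- lapply(data$test, function(cl) video_to_scans(cl$frames, enc))
  model <- train_ensemble(train_scans, data$labels_train, config)
  evaluation <- evaluate_ensemble(model, test_scans, data$labels_test,
                                  k_list = k_list,
                                  seed = derive_seed(config$seed, 90))
  spectra <- auto_spectra(model$autos$C)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      config = file.path(out_dir, "config.json"),
      metrics = file.path(out_dir, "metrics.csv"),
      confusion = file.path(out_dir, "confusion.csv"),
      model = file.path(out_dir, "model.rds"),
      train_log = file.path(out_dir, "training_log.csv"))
    write_config(config, paths$config)
    write.csv(evaluation$metrics, paths$metrics, row.names = FALSE)
    write.csv(evaluation$confusion, paths$confusion)
    save_model(model, paths$model)
    logs <- do.call(rbind, lapply(names(model$autos), function(key) {
      cbind(scan = key, model$autos[[key]]$train_log)
    }))
    write.csv(logs, paths$train_log, row.names = FALSE)
  }
  list(model = model, evaluation = evaluation, spectra = spectra,
       paths = paths)
}
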