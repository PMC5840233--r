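#' Save / load trained models
#'
#' Models (driven, autonomous or ensemble) are serialized with R's native
#' RDS format, which preserves every field (topology, weights, seeds,
#' parameters, logs) bitwise.
#'
#' @param model A `driven_network`, `auto_network` or `ensemble_model`.
#' @param path File path (`.rds`).
#' @return `load_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}

#' Write a spike raster as a CSV event list
#'
#' One row per spike: `neuron_id` (1-based) and `t_ms`.
#'
#' @param raster N x T 0/1 matrix.
#' @param path CSV path.
#' @param dt Step (ms).
#' @return The path, invisibly.
#' @export
write_spike_events <- function(raster, path, dt = 1) {
  idx <- which(raster != 0, arr.ind = TRUE)
  events <- data.frame(neuron_id = idx[, 1], t_ms = (idx[, 2] - 1) * dt)
  events <- events[order(events$t_ms, events$neuron_id), ]
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read a spike event CSV back into a raster
#'
#' @param path CSV written by [write_spike_events()].
#' @param n_neurons,n_steps Raster dimensions.
#' @param dt Step (ms).
#' @return N x T 0/1 integer matrix.
#' @export
read_spike_events <- function(path, n_neurons, n_steps, dt = 1) {
  events <- read.csv(path)
  raster <- matrix(0L, n_neurons, n_steps)
  if (nrow(events) > 0) {
    raster[cbind(events$neuron_id, round(events$t_ms / dt) + 1)] <- 1L
  }
  raster
}

#' Load a clip from a directory of grayscale PNG frames
#'
#' Frames are read in lexicographic filename order and rescaled from PNG's
#' 0-1 range to 0-255 grey levels.
#'
#' @param dir Directory containing `.png` frames.
#' @return H x W x T numeric array.
#' @export
load_frames_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop_arg("no .png frames found in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)  # to grayscale
    img * 255
  })
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write a clip as a directory of grayscale PNG frames
#'
#' @param frames H x W x T array of 0-255 grey levels.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
save_frames_dir <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(dim(frames)[3])) {
    png::writePNG(frames[, , t] / 255,
                  file.path(dir, sprintf("frame_%04d.png", t)))
  }
  invisible(dir)
}

#' Write / read target patterns as CSV
#'
#' Row per output neuron, column per time step.
#'
#' @param target A [make_one_hot_target()] pattern.
#' @param path CSV path.
#' @return `read_target_csv()` returns a matrix; `write_target_csv()` the
#'   path, invisibly.
#' @export
write_target_csv <- function(target, path) {
  write.csv(target$f_out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_csv
#' @export
read_target_csv <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}
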