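#' Encoder parameters
#'
#' Settings of the microsaccade-inspired video-to-spike encoder: the
#' multi-threshold set used for weighted frame differencing, the
#' binarization level, the bounding-box size and stride of the five CRLTB
#' scans, and the per-frame activity bounds of the jitter/flash deletion
#' rule.
#'
#' @param thresholds Strictly increasing positive intensity thresholds
#'   `epsilon_i` (grey levels).
#' @param binarize_theta Binarization level on the weighted spike map in
#'   (0, 1].  The default 0.1 requires an intensity change of at least 4
#'   grey levels ((1+2+4)/63 ~ 0.111), suppressing single-grey-level sensor
#'   noise.
#' @param bb_size Bounding-box side in pixels (odd).
#' @param stride Scan stride in pixels; the default 10 is half the distance
#'   from the box centre to its edge for a 41-pixel box.
#' @param min_active_frac,max_active_frac Frames whose active-pixel fraction
#'   falls outside `[min, max]` are deleted (flash/jitter filter).
#' @param abs_diff If `TRUE`, threshold `|P_diff|` instead of the signed
#'   difference (darkening edges then also spike).
#' @return An `encoder_params` object.
#' @export
encoder_params <- function(thresholds = c(1, 2, 4, 8, 16, 32),
                           binarize_theta = 0.1, bb_size = 41, stride = 10,
                           min_active_frac = 0.08, max_active_frac = 0.75,
                           abs_diff = FALSE) {
  if (length(thresholds) < 1 || any(thresholds <= 0) ||
      any(diff(thresholds) <= 0)) {
    stop_arg("`thresholds` must be strictly increasing and positive")
  }
  check_scalar_num(binarize_theta, "binarize_theta", lower = 0, upper = 1,
                   strict_lower = TRUE)
  bb_size <- check_count(bb_size, "bb_size")
  if (bb_size %% 2 == 0) stop_arg("`bb_size` must be odd")
  stride <- check_count(stride, "stride")
  check_scalar_num(min_active_frac, "min_active_frac", lower = 0, upper = 1)
  check_scalar_num(max_active_frac, "max_active_frac", lower = 0, upper = 1)
  if (min_active_frac >= max_active_frac) {
    stop_arg("`min_active_frac` must be below `max_active_frac`")
  }
  structure(list(thresholds = thresholds, binarize_theta = binarize_theta,
                 bb_size = bb_size, stride = stride,
                 min_active_frac = min_active_frac,
                 max_active_frac = max_active_frac,
                 abs_diff = isTRUE(abs_diff)),
            class = "encoder_params")
}

check_gray <- function(frame, name) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop_arg("`", name, "` must be a numeric grayscale matrix; convert ",
             "colour input to grayscale first (e.g. rowMeans over channels)")
  }
  invisible(frame)
}

#' Weighted multi-threshold spike frame from two consecutive frames
#'
#' Computes the pixelwise intensity difference `P_diff = curr - prev`,
#' thresholds it against every `epsilon_i`, and fuses the per-threshold spike
#' maps into the weighted map
#' `WSpike = sum_i epsilon_i * [P_diff >= epsilon_i] / sum_i epsilon_i`,
#' which is then binarized at `binarize_theta` to give the spike frame.
#'
#' @param frame_prev,frame_curr Grayscale intensity matrices (same shape).
#' @param params [encoder_params()].
#' @return List with `spikes` (0/1 integer matrix) and `wspike` (the weighted
#'   map in `[0, 1]`).
#' @examples
#' prev <- matrix(0, 4, 4); curr <- prev; curr[2, 2] <- 3
#' weighted_spike_frame(prev, curr)$wspike[2, 2]  # (1+2)/63
#' @export
weighted_spike_frame <- function(frame_prev, frame_curr,
                                 params = encoder_params()) {
  check_gray(frame_prev, "frame_prev")
  check_gray(frame_curr, "frame_curr")
  if (!all(dim(frame_prev) == dim(frame_curr))) {
    stop_arg("frames must have identical dimensions")
  }
  p_diff <- frame_curr - frame_prev
  if (params$abs_diff) p_diff <- abs(p_diff)
  wspike <- matrix(0, nrow(p_diff), ncol(p_diff))
  for (eps in params$thresholds) {
    wspike <- wspike + eps * (p_diff >= eps)
  }
  wspike <- wspike / sum(params$thresholds)
  spikes <- matrix(as.integer(wspike >= params$binarize_theta),
                   nrow(p_diff), ncol(p_diff))
  list(spikes = spikes, wspike = wspike)
}

#' Encode a grayscale clip into binary spike frames
#'
#' Applies [weighted_spike_frame()] to every consecutive frame pair, so T
#' input frames yield T - 1 spike frames in temporal order.
#'
#' @param frames H x W x T numeric array of grayscale frames (T >= 2).
#' @param params [encoder_params()].
#' @return A `spike_video`: list with `frames` (H x W x (T-1) 0/1 array).
#' @export
encode_video <- function(frames, params = encoder_params()) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop_arg("`frames` must be an H x W x T array")
  }
  T <- dim(frames)[3]
  if (T < 2) stop_arg("need at least 2 frames to difference")
  out <- array(0L, dim = c(dim(frames)[1], dim(frames)[2], T - 1))
  for (j in 2:T) {
    out[, , j - 1] <- weighted_spike_frame(frames[, , j - 1], frames[, , j],
                                           params)$spikes
  }
  structure(list(frames = out), class = "spike_video")
}

#' Centre of gravity of a binary spike frame
#'
#' Mean location of the active pixels, rounded to the nearest pixel; an
#' empty frame fixates the image centre.
#'
#' @param spike_frame 0/1 matrix.
#' @return Integer vector `c(x_g, y_g)` (x = column, y = row).
#' @export
center_of_gravity <- function(spike_frame) {
  idx <- which(spike_frame != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(c(x_g = round((ncol(spike_frame) + 1) / 2),
             y_g = round((nrow(spike_frame) + 1) / 2)))
  }
  c(x_g = round(mean(idx[, 2])), y_g = round(mean(idx[, 1])))
}

# bb_size x bb_size window centred at (xc, yc), zero-padded at borders.
crop_window <- function(frame, xc, yc, bb_size) {
  half <- (bb_size - 1) %/% 2
  out <- matrix(0L, bb_size, bb_size)
  rows <- (yc - half):(yc + half)
  cols <- (xc - half):(xc + half)
  rok <- rows >= 1 & rows <= nrow(frame)
  cok <- cols >= 1 & cols <= ncol(frame)
  if (any(rok) && any(cok)) {
    out[which(rok), which(cok)] <- frame[rows[rok], cols[cok], drop = FALSE]
  }
  out
}

#' Extract the five CRLTB scan windows from a spike video
#'
#' Emulates a fixed microsaccade sequence: per frame, the centre (C) window
#' is a `bb_size` box at the activity centre of gravity, and the
#' Right/Left/Top/Bottom windows are the same box shifted by `stride` pixels
#' in the four cardinal directions.  Windows are clipped and zero-padded at
#' image borders so every window is exactly `bb_size x bb_size`.
#'
#' @param spike_video An [encode_video()] result.
#' @param params [encoder_params()].
#' @return A `scan_set`: list with `scans` (named list C/R/L/T/B of
#'   bb x bb x T arrays), `cog_track` (T x 2 matrix of `(x_g, y_g)`) and
#'   `deleted_frames` (empty; filled by [delete_bad_frames()]).
#' @export
extract_scans <- function(spike_video, params = encoder_params()) {
  stopifnot(inherits(spike_video, "spike_video"))
  fr <- spike_video$frames
  T <- dim(fr)[3]
  bb <- params$bb_size
  s <- params$stride
  scans <- lapply(c(C = 1, R = 2, L = 3, T = 4, B = 5),
                  function(i) array(0L, dim = c(bb, bb, T)))
  cog <- matrix(0L, T, 2, dimnames = list(NULL, c("x_g", "y_g")))
  for (t in seq_len(T)) {
    g <- center_of_gravity(fr[, , t])
    cog[t, ] <- g
    scans$C[, , t] <- crop_window(fr[, , t], g[1], g[2], bb)
    scans$R[, , t] <- crop_window(fr[, , t], g[1] + s, g[2], bb)
    scans$L[, , t] <- crop_window(fr[, , t], g[1] - s, g[2], bb)
    scans$T[, , t] <- crop_window(fr[, , t], g[1], g[2] - s, bb)
    scans$B[, , t] <- crop_window(fr[, , t], g[1], g[2] + s, bb)
  }
  structure(list(scans = scans, cog_track = cog,
                 deleted_frames = list(C = integer(0), R = integer(0),
                                       L = integer(0), T = integer(0),
                                       B = integer(0)),
                 params = params),
            class = "scan_set")
}

#' Delete jitter/flash-contaminated frames from a scan set
#'
#' Two rules, applied in order:
#' 1. (whole-frame, pre-scan) any spike frame whose active-pixel fraction is
#'    below `min_active_frac` or above `max_active_frac` is removed from all
#'    five streams — this catches empty frames and whole-frame flashes from
#'    camera shake;
#' 2. (per-scan) for each surviving frame i and each directional scan
#'    S in R, L, T, B: if `|count(C_i) - count(S_i)|` exceeds the mean
#'    active count of the C stream (over surviving frames), frame i is
#'    removed from stream S only.  The C stream is never touched by rule 2.
#'
#' Deleted frame indices (relative to the original spike video) are recorded
#' per stream.
#'
#' @param scan_set An [extract_scans()] result.
#' @param spike_video The [encode_video()] output the scans came from.
#' @param params [encoder_params()].
#' @return The filtered `scan_set`; each scan array keeps only surviving
#'   frames, and `deleted_frames` lists the removed indices per stream.
#' @export
delete_bad_frames <- function(scan_set, spike_video,
                              params = encoder_params()) {
  stopifnot(inherits(scan_set, "scan_set"), inherits(spike_video, "spike_video"))
  fr <- spike_video$frames
  T <- dim(fr)[3]
  if (dim(scan_set$scans$C)[3] != T) {
    stop_arg("`scan_set` is inconsistent with `spike_video` (frame counts differ)")
  }
  n_px <- dim(fr)[1] * dim(fr)[2]
  frac <- apply(fr, 3, sum) / n_px
  bad1 <- which(frac < params$min_active_frac | frac > params$max_active_frac)
  keep1 <- setdiff(seq_len(T), bad1)

  counts <- lapply(scan_set$scans, function(a) apply(a, 3, sum))
  mean_c <- if (length(keep1) > 0) mean(counts$C[keep1]) else 0

  deleted <- list(C = bad1)
  surviving <- list(C = keep1)
  for (key in c("R", "L", "T", "B")) {
    dev <- abs(counts$C - counts[[key]])
    bad2 <- keep1[dev[keep1] > mean_c]
    deleted[[key]] <- sort(unique(c(bad1, bad2)))
    surviving[[key]] <- setdiff(keep1, bad2)
  }
  scan_set$scans <- lapply(stats::setNames(names(scan_set$scans),
                                           names(scan_set$scans)),
                           function(key) {
    scan_set$scans[[key]][, , surviving[[key]], drop = FALSE]
  })
  scan_set$deleted_frames <- deleted[c("C", "R", "L", "T", "B")]
  scan_set$cog_track <- scan_set$cog_track[keep1, , drop = FALSE]
  scan_set
}

#' Full encoding pipeline: grayscale clip to filtered CRLTB scans
#'
#' Convenience wrapper chaining [encode_video()], [extract_scans()] and
#' [delete_bad_frames()].
#'
#' @param frames H x W x T grayscale array.
#' @param params [encoder_params()].
#' @return A filtered `scan_set`.
#' @export
video_to_scans <- function(frames, params = encoder_params()) {
  sv <- encode_video(frames, params)
  ss <- extract_scans(sv, params)
  delete_bad_frames(ss, sv, params)
}

#' Flatten one scan stream into a reservoir spike input
#'
#' @param scan_set A `scan_set`.
#' @param key One of `"C"`, `"R"`, `"L"`, `"T"`, `"B"`.
#' @return X x T binary matrix with X = `bb_size^2` (column-major pixel
#'   order), ready for [train_auto()] / [predict_single()].
#' @export
scan_input <- function(scan_set, key) {
  stopifnot(inherits(scan_set, "scan_set"))
  key <- match.arg(key, c("C", "R", "L", "T", "B"))
  a <- scan_set$scans[[key]]
  d <- dim(a)
  matrix(as.integer(a), d[1] * d[2], d[3])
}

#' @export
print.scan_set <- function(x, ...) {
  lens <- vapply(x$scans, function(a) dim(a)[3], 0L)
  cat("CRLTB scan set:", paste(names(lens), lens, sep = "=", collapse = ", "),
      "frames\n")
  invisible(x)
}
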