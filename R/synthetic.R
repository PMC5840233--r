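#' Scene specification for a synthetic action clip
#'
#' Describes one clip of the synthetic benchmark: a bright foreground object
#' moving over a (possibly textured) background with a class-specific motion
#' signature, optional independently moving clutter, whole-frame jitter
#' (camera shake) and salt-and-pepper pixel noise.  Frames are 8-bit
#' grayscale so the multi-threshold encoder's threshold set (1 ... 32 grey
#' levels) is meaningful.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param n_frames Number of frames; the default 120 is deliberately below
#'   the 300-step trial so the reservoir's run-on-without-input behaviour is
#'   exercised by every clip.
#' @param object_shape `"square"`, `"disc"` or `"bar"`.
#' @param object_size Object side/diameter in pixels.
#' @param motion_class `"oscillate_x"`, `"translate_y"`, `"circular"` or
#'   `"expand"`.
#' @param speed Motion speed in px/frame (for `expand`: px/frame change of
#'   the radius envelope).
#' @param jitter_sigma SD (px) of the global per-frame camera shake.
#' @param clutter_density Fraction of the frame area covered by small
#'   independently drifting distractor squares.
#' @param noise_flip_prob Per-pixel probability of being replaced by a
#'   random grey level (sensor noise), applied last.
#' @param contrast Object/background intensity difference (grey levels).
#' @param bg_level Background base intensity.
#' @param bg_texture Amplitude of static per-pixel background texture
#'   (0 = flat background).
#' @param seed RNG seed; rendering is deterministic given the seed.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(image_size = c(200, 300), n_frames = 120,
                       object_shape = c("square", "disc", "bar"),
                       object_size = 30,
                       motion_class = c("oscillate_x", "translate_y",
                                        "circular", "expand"),
                       speed = 2, jitter_sigma = 0, clutter_density = 0,
                       noise_flip_prob = 0, contrast = 96, bg_level = 60,
                       bg_texture = 0, seed = 1L) {
  object_shape <- match.arg(object_shape)
  motion_class <- match.arg(motion_class)
  check_scalar_num(speed, "speed", lower = 0)
  check_scalar_num(jitter_sigma, "jitter_sigma", lower = 0)
  check_scalar_num(clutter_density, "clutter_density", lower = 0, upper = 1)
  check_scalar_num(noise_flip_prob, "noise_flip_prob", lower = 0, upper = 1)
  object_size <- check_count(object_size, "object_size")
  if (object_size >= min(image_size)) {
    stop_arg("object (", object_size, " px) does not fit in a ",
             image_size[1], " x ", image_size[2], " frame")
  }
  structure(list(image_size = as.integer(image_size),
                 n_frames = check_count(n_frames, "n_frames"),
                 object_shape = object_shape, object_size = object_size,
                 motion_class = motion_class, speed = speed,
                 jitter_sigma = jitter_sigma,
                 clutter_density = clutter_density,
                 noise_flip_prob = noise_flip_prob, contrast = contrast,
                 bg_level = bg_level, bg_texture = bg_texture,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# object mask stamped into a frame, clipped at borders
stamp_object <- function(frame, xc, yc, size, shape, value) {
  h <- nrow(frame)
  w <- ncol(frame)
  half <- size / 2
  if (shape == "bar") {
    rows <- round(yc - size):round(yc + size)
    cols <- round(xc - half / 2):round(xc + half / 2)
  } else {
    rows <- round(yc - half):round(yc + half)
    cols <- round(xc - half):round(xc + half)
  }
  rows <- rows[rows >= 1 & rows <= h]
  cols <- cols[cols >= 1 & cols <= w]
  if (length(rows) == 0 || length(cols) == 0) return(frame)
  if (shape == "disc") {
    dist2 <- outer((rows - yc)^2, (cols - xc)^2, `+`)
    sel <- dist2 <= half^2
    block <- frame[rows, cols, drop = FALSE]
    block[sel] <- value
    frame[rows, cols] <- block
  } else {
    frame[rows, cols] <- value
  }
  frame
}

object_path <- function(spec, t) {
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  half <- spec$object_size / 2
  switch(spec$motion_class,
    oscillate_x = {
      amp <- min(w / 4, (w - spec$object_size) / 2 - 2)
      period <- max(8, 2 * amp / max(spec$speed, 1e-9))
      list(x = cx + amp * sin(2 * pi * t / period), y = cy,
           size = spec$object_size)
    },
    translate_y = {
      lo <- half + 2
      hi <- h - half - 2
      span <- hi - lo
      pos <- (spec$speed * t) %% (2 * span)     # bounce between lo and hi
      y <- lo + ifelse(pos <= span, pos, 2 * span - pos)
      list(x = cx, y = y, size = spec$object_size)
    },
    circular = {
      r <- min(h, w) / 4 - half / 2
      omega <- spec$speed / r
      list(x = cx + r * cos(omega * t), y = cy + r * sin(omega * t),
           size = spec$object_size)
    },
    expand = {
      base <- spec$object_size
      amp <- base / 2
      period <- max(8, 2 * amp / max(spec$speed, 1e-9))
      list(x = cx, y = cy,
           size = max(4, round(base + amp * sin(2 * pi * t / period))))
    })
}

#' Render a synthetic grayscale action clip
#'
#' Deterministically renders the scene described by a [scene_spec()]:
#' background (plus optional static texture), the class-signature object
#' trajectory, drifting clutter distractors, whole-frame jitter shifts drawn
#' per frame from Normal(0, `jitter_sigma^2`), and salt-and-pepper noise
#' applied last.  Intensities are clamped to 0 ... 255.
#'
#' @param spec A [scene_spec()].
#' @return List with `frames` (H x W x T array), `label`
#'   (the motion class) and `spec`.
#' @export
generate_clip <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  with_seed(spec$seed, {
    bg <- matrix(spec$bg_level, h, w)
    if (spec$bg_texture > 0) {
      bg <- bg + matrix(stats::runif(h * w, -spec$bg_texture,
                                     spec$bg_texture), h, w)
    }
    n_clut <- round(spec$clutter_density * h * w / 9)
    clut <- if (n_clut > 0) {
      data.frame(x = stats::runif(n_clut, 4, w - 3),
                 y = stats::runif(n_clut, 4, h - 3),
                 vx = stats::runif(n_clut, -1, 1),
                 vy = stats::runif(n_clut, -1, 1))
    }
    jit_x <- round(stats::rnorm(spec$n_frames, 0, spec$jitter_sigma))
    jit_y <- round(stats::rnorm(spec$n_frames, 0, spec$jitter_sigma))
    off <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    render_frame <- function(t) {
      fr <- bg
      if (!is.null(clut)) {
        cx <- round(((clut$x + clut$vx * t - 1) %% w) + 1)
        cy <- round(((clut$y + clut$vy * t - 1) %% h) + 1)
        # 3x3 distractor squares stamped in one vectorized assignment
        rows <- rep(cy, each = 9) + off[, "dy"]
        cols <- rep(cx, each = 9) + off[, "dx"]
        ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
        fr[cbind(rows[ok], cols[ok])] <- spec$bg_level + spec$contrast / 2
      }
      p <- object_path(spec, t - 1)
      fr <- stamp_object(fr, p$x, p$y, p$size, spec$object_shape,
                         spec$bg_level + spec$contrast)
      # whole-frame jitter: shift with zero-order hold at the borders
      if (jit_x[t] != 0 || jit_y[t] != 0) {
        fr <- shift_frame(fr, jit_x[t], jit_y[t])
      }
      if (spec$noise_flip_prob > 0) {
        n_flip <- stats::rbinom(1, h * w, spec$noise_flip_prob)
        if (n_flip > 0) {
          fr[sample.int(h * w, n_flip)] <- stats::runif(n_flip, 0, 255)
        }
      }
      fr
    }
    frames <- vapply(seq_len(spec$n_frames), render_frame, matrix(0, h, w))
    frames <- round(pmin(pmax(frames, 0), 255))
    list(frames = frames, label = spec$motion_class, spec = spec)
  })
}

shift_frame <- function(fr, dx, dy) {
  h <- nrow(fr)
  w <- ncol(fr)
  rows <- pmin(pmax(seq_len(h) - dy, 1), h)
  cols <- pmin(pmax(seq_len(w) - dx, 1), w)
  fr[rows, cols, drop = FALSE]
}

#' Generate a labelled synthetic train/test video dataset
#'
#' For each class a template [scene_spec()] is perturbed per clip —
#' object size, speed and phase are drawn within the stated within-class
#' ranges so intra-class variation exists — and disjoint seed streams keep
#' train and test sets independent.
#'
#' @param class_specs Named list of template [scene_spec()]s; class names
#'   must be unique and motion classes should differ between classes.
#' @param n_train_per_class,n_test_per_class Clip counts.
#' @param seed Master seed.
#' @param speed_jitter Relative half-width of the within-class speed range
#'   (speed is drawn uniformly in `speed * (1 +/- speed_jitter)`).
#' @param size_jitter Absolute half-width (px) of the object-size range.
#' @param transform Optional function applied to each rendered clip; its
#'   result is stored instead of the clip.  Passing the encoder here keeps
#'   peak memory at one raw clip instead of the whole corpus.
#' @return List with `train`, `test` (each: list of clips from
#'   [generate_clip()], or of `transform` results), and `labels_train`,
#'   `labels_test` (0-based integer labels in the order of `class_specs`).
#' @export
generate_dataset <- function(class_specs, n_train_per_class = 8,
                             n_test_per_class = 20, seed = 1L,
                             speed_jitter = 0.25, size_jitter = 4,
                             transform = NULL) {
  if (is.null(names(class_specs)) || anyDuplicated(names(class_specs))) {
    stop_arg("`class_specs` must be a uniquely named list")
  }
  if (length(class_specs) < 2) stop_arg("need at least 2 classes")
  motions <- vapply(class_specs, function(s) s$motion_class, "")
  if (anyDuplicated(motions)) {
    warning("classes ", paste(names(class_specs)[duplicated(motions)],
                              collapse = ", "),
            " share a motion class with another class; they are ",
            "indistinguishable by design")
  }
  make_split <- function(n_per_class, split_id) {
    clips <- list()
    labels <- integer(0)
    for (ci in seq_along(class_specs)) {
      tmpl <- class_specs[[ci]]
      for (r in seq_len(n_per_class)) {
        clip_seed <- derive_seed(seed, split_id * 100000 + ci * 1000 + r)
        sp <- with_seed(clip_seed, {
          s <- tmpl
          s$speed <- stats::runif(1, tmpl$speed * (1 - speed_jitter),
                                  tmpl$speed * (1 + speed_jitter))
          s$object_size <- max(4L, round(tmpl$object_size +
                                           stats::runif(1, -size_jitter,
                                                        size_jitter)))
          s$seed <- clip_seed
          s
        })
        clip <- generate_clip(sp)
        if (!is.null(transform)) clip <- transform(clip)
        clips[[length(clips) + 1L]] <- clip
        labels <- c(labels, ci - 1L)
      }
    }
    list(clips = clips, labels = labels)
  }
  train <- make_split(n_train_per_class, 1)
  test <- make_split(n_test_per_class, 2)
  list(train = train$clips, labels_train = train$labels,
       test = test$clips, labels_test = test$labels,
       class_names = names(class_specs))
}
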