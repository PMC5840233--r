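#' Train the five-scan driven/autonomous ensemble
#'
#' One driven network is trained (RLS, `epochs_driven` epochs) to produce the
#' one-hot targets of all classes; five autonomous networks — one per CRLTB
#' scan — are then derived from it (they share `J_fast` bitwise) and each is
#' trained with supervised STDP on its own scan stream of every training
#' video.
#'
#' @param scan_sets List of `scan_set` objects (one per training video).
#' @param labels Integer 0-based class labels parallel to `scan_sets`.
#' @param config An [experiment_config()]; `n_in` is forced to `bb_size^2`.
#' @return An `ensemble_model` with fields `driven`, `autos` (named list
#'   C/R/L/T/B), `classes`, `targets` and `config`.
#' @export
train_ensemble <- function(scan_sets, labels, config = experiment_config()) {
  if (length(scan_sets) == 0) stop_arg("`scan_sets` must be non-empty")
  if (length(scan_sets) != length(labels)) {
    stop_arg("`scan_sets` and `labels` must have the same length")
  }
  classes <- sort(unique(as.integer(labels)))
  if (!all(tabulate(as.integer(labels) + 1L) >= 1)) {
    stop_arg("every class needs at least one training video")
  }
  scan_keys <- c("C", "R", "L", "T", "B")
  n_classes <- length(classes)
  x <- config$bb_size^2
  lif <- config_lif(config)
  syn <- config_syn(config)
  bump <- config_bump(config)

  top <- build_topology(config$n_res, x, n_classes, config$p_conn,
                        config$weight_scale, seed = derive_seed(config$seed, 1))
  targets <- lapply(classes, make_one_hot_target, n_classes = n_classes,
                    bump = bump)
  driven <- driven_network(top, lif, syn, u_scale = config$u_scale,
                           seed = derive_seed(config$seed, 2))
  driven <- train_driven(driven, targets, n_epochs = config$epochs_driven)

  usable <- vapply(seq_along(scan_sets), function(i) {
    ok <- all(scan_keys %in% names(scan_sets[[i]]$scans)) &&
      all(vapply(scan_sets[[i]]$scans[scan_keys],
                 function(a) dim(a)[3] > 0, TRUE))
    if (!ok) warning("skipping training video ", i,
                     ": missing or empty scan stream")
    ok
  }, TRUE)
  if (!any(usable)) stop_arg("no usable training videos")
  scan_sets <- scan_sets[usable]
  labels <- as.integer(labels)[usable]

  autos <- list()
  for (k in seq_along(scan_keys)) {
    key <- scan_keys[k]
    auto <- derive_auto(driven, b_max = config$b_max,
                        seed = derive_seed(config$seed, 10 + k))
    inputs <- lapply(scan_sets, scan_input, key = key)
    autos[[key]] <- train_auto(auto, inputs, labels, targets,
                               n_epochs = config$epochs_auto,
                               eta = config$eta,
                               n_steps = config$trial_steps)
  }
  structure(list(driven = driven, autos = autos, classes = classes,
                 targets = targets, config = config),
            class = "ensemble_model")
}

# Plurality vote with the documented tie-break: among vote-count ties, the
# class with the larger summed readout spike count across all models wins;
# remaining ties go to the lowest class index.
resolve_vote <- function(votes, count_matrix, classes) {
  tab <- table(factor(votes, levels = classes))
  top <- max(tab)
  tied <- as.integer(names(tab)[tab == top])
  if (length(tied) == 1) {
    final <- tied
  } else {
    sums <- colSums(count_matrix)[match(tied, classes)]
    final <- tied[sums == max(sums)]
    final <- min(final)
  }
  list(final_class = final, vote_margin = as.integer(top))
}

#' Classify a scan set with the ensemble
#'
#' Each autonomous model votes via [predict_single()] on its own scan; the
#' final class is the plurality of the five votes, ties broken first by the
#' larger summed spike count of the tied classes across all five models,
#' then by the lowest class index.
#'
#' @param object A trained `ensemble_model`.
#' @param scan_set A `scan_set` of the test video.
#' @param ... Unused.
#' @return A `prediction` list: `per_model_votes`, `per_model_counts`
#'   (5 x Y matrix), `final_class`, `vote_margin`.
#' @export
predict.ensemble_model <- function(object, scan_set, ...) {
  keys <- names(object$autos)
  counts <- matrix(0, length(keys), length(object$classes),
                   dimnames = list(keys, object$classes))
  votes <- stats::setNames(integer(length(keys)), keys)
  for (key in keys) {
    pr <- predict_single(object$autos[[key]], scan_input(scan_set, key),
                         n_steps = object$config$trial_steps)
    counts[key, ] <- pr$counts
    votes[key] <- object$classes[pr$class_id + 1L]
  }
  res <- resolve_vote(votes, counts, object$classes)
  structure(list(per_model_votes = votes, per_model_counts = counts,
                 final_class = res$final_class,
                 vote_margin = res$vote_margin),
            class = "prediction")
}

#' Evaluate an ensemble on a labelled test set
#'
#' Runs `n_repeats` full evaluation passes over the test set and reports
#' Top-k accuracy for each k (classes ranked by total readout spike count
#' summed across the five models), the mean and SD over passes, and the
#' Top-1 confusion matrix.  Inference is deterministic, so the SD is zero
#' unless `jitter_rate > 0`, which deletes each input spike independently
#' with that probability per pass (evaluation-noise mode).
#'
#' @param ensemble A trained `ensemble_model`.
#' @param scan_sets List of test `scan_set`s.
#' @param labels True 0-based labels.
#' @param k_list Top-k levels to report.
#' @param n_repeats Evaluation passes.
#' @param jitter_rate Per-spike deletion probability for stochastic passes.
#' @param seed Seed for the jitter draws.
#' @return List with `metrics` (data frame: k, mean accuracy in %, sd),
#'   `confusion` (Y x Y matrix, true x predicted), `predictions` (final
#'   classes of the last pass).
#' @export
evaluate_ensemble <- function(ensemble, scan_sets, labels,
                              k_list = c(1, 3, 5), n_repeats = 10,
                              jitter_rate = 0, seed = 1L) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  if (length(scan_sets) == 0) stop_arg("empty test set")
  if (length(scan_sets) != length(labels)) {
    stop_arg("`scan_sets` and `labels` must have the same length")
  }
  labels <- as.integer(labels)
  classes <- ensemble$classes
  k_list <- unique(pmin(k_list, length(classes)))
  acc <- matrix(0, n_repeats, length(k_list))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  preds <- integer(length(scan_sets))
  deterministic <- jitter_rate <= 0
  for (rep in seq_len(n_repeats)) {
    if (deterministic && rep > 1) {
      acc[rep, ] <- acc[1, ]       # identical pass; reuse
      next
    }
    hits <- matrix(FALSE, length(scan_sets), length(k_list))
    for (i in seq_along(scan_sets)) {
      ss <- scan_sets[[i]]
      if (!deterministic) {
        ss <- jitter_scan_set(ss, jitter_rate,
                              derive_seed(seed, rep * 1000 + i))
      }
      pr <- predict(ensemble, ss)
      preds[i] <- pr$final_class
      ranked <- classes[order(colSums(pr$per_model_counts),
                              decreasing = TRUE)]
      # Top-1 follows the vote rule; deeper k follow the count ranking
      ranked <- unique(c(pr$final_class, ranked))
      for (j in seq_along(k_list)) {
        hits[i, j] <- labels[i] %in% ranked[seq_len(k_list[j])]
      }
      if ((deterministic && rep == 1) || (!deterministic && rep == n_repeats)) {
        ti <- match(labels[i], classes)
        pi <- match(pr$final_class, classes)
        confusion[ti, pi] <- confusion[ti, pi] + 1L
      }
    }
    acc[rep, ] <- 100 * colMeans(hits)
  }
  metrics <- data.frame(k = k_list,
                        accuracy = colMeans(acc),
                        sd = apply(acc, 2, stats::sd))
  list(metrics = metrics, confusion = confusion, predictions = preds)
}

jitter_scan_set <- function(scan_set, rate, seed) {
  with_seed(seed, {
    scan_set$scans <- lapply(scan_set$scans, function(a) {
      drop_mask <- array(stats::runif(length(a)) < rate, dim = dim(a))
      a[drop_mask & a == 1L] <- 0L
      a
    })
    scan_set
  })
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("D/A ensemble: %d classes, N=%d, scans %s\n",
              length(x$classes), x$config$n_res,
              paste(names(x$autos), collapse = "")))
  invisible(x)
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("Prediction: class %d (votes %s, margin %d)\n",
              x$final_class,
              paste(x$per_model_votes, collapse = ","), x$vote_margin))
  invisible(x)
}
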