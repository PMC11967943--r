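#' Annotate a whole recording
#'
#' Runs the three-step pipeline: the recording is min-max normalised, cut
#' into non-overlapping windows of length `d`, each window is transformed
#' with the model's feature contract and classified, the predicted label of
#' each window is replicated across its `d` timesteps, and the concatenated
#' sequence is truncated to the recording length (so an 8-hour 100 Hz
#' recording receives exactly 2,880,000 labels) and run-length encoded into
#' an annotation track. Predicted interval boundaries therefore fall on
#' multiples of `d / rate` seconds, except the final one.
#'
#' @param model an `epg_model` (including [epg_oracle_model()]).
#' @param rec an [epg_recording()].
#' @param d window length in samples (default 1024).
#' @return list with `labels` (per-timestep factor, length = recording
#'   length) and `track` (the run-length encoded [epg_track()]).
#' @export
annotate_recording <- function(model, rec, d = 1024) {
  n <- length(rec$samples)
  segs <- segment_recording(normalize_recording(rec), d = d, s = d)
  pred <- if (model$family == "oracle") {
    truth <- track_to_labels(model$track, n, rec$rate)
    label_segments(segs, truth)
  } else {
    feats <- segment_features(segs, kind = model$feature_kind, rate = rec$rate)
    predict(model, feats, type = "class")
  }
  labels <- rep(as.character(pred), each = d)[seq_len(n)]
  labels <- factor(labels, levels = EPG_LABELS)
  attr(labels, "rate") <- rec$rate
  list(labels = labels, track = labels_to_track(labels, rec$rate))
}

#' Confusion matrix over the seven waveform classes
#'
#' Rows are true labels, columns predicted labels, both in canonical order.
#'
#' @param true,pred equally long label vectors.
#' @return 7x7 integer matrix of class `epg_confusion`.
#' @export
confusion_matrix <- function(true, pred) {
  true <- as_epg_label(true)
  pred <- as_epg_label(pred)
  if (length(true) != length(pred)) {
    stopf("true (%d) and pred (%d) differ in length", length(true), length(pred))
  }
  m <- table(true = true, pred = pred)
  m <- matrix(as.integer(m), 7, 7, dimnames = list(true = EPG_LABELS,
                                                   pred = EPG_LABELS))
  structure(m, class = c("epg_confusion", "matrix"))
}

#' @export
print.epg_confusion <- function(x, ...) {
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Row-normalised confusion matrix
#'
#' Divides each row by its sum (the true-class support), so the diagonal
#' holds the per-class accuracies. Empty rows stay zero.
#'
#' @param cm an `epg_confusion`.
#' @return 7x7 numeric matrix.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- unclass(cm) / ifelse(rs == 0, 1, rs)
  out
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the diagonal mass over the total. Per-class accuracy
#' is the row-normalised diagonal (the recall of each class). Per-class F1
#' combines precision `TP / (TP + FP)` and recall `TP / (TP + FN)`; the
#' macro F1 averages over the classes present in the ground truth, with a
#' warning naming any absent classes (datasets with virtually no F or G
#' would otherwise drag the mean to zero).
#'
#' @param cm an `epg_confusion`.
#' @return list of class `epg_metrics`: `overall_accuracy`, `macro_f1`,
#'   `per_class_accuracy`, `per_class_f1`, `n`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  tp <- diag(unclass(cm))
  support <- rowSums(cm)
  predicted <- colSums(cm)
  recall <- ifelse(support == 0, NA_real_, tp / support)
  precision <- ifelse(predicted == 0, NA_real_, tp / predicted)
  f1 <- ifelse(is.na(recall) | is.na(precision) | (precision + recall) == 0,
               ifelse(is.na(recall), NA_real_, 0),
               2 * precision * recall / (precision + recall))
  present <- support > 0
  absent <- EPG_LABELS[!present]
  if (length(absent) > 0) {
    warning("classes absent from ground truth excluded from macro F1: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  structure(list(
    overall_accuracy = sum(tp) / total,
    macro_f1 = mean(f1[present], na.rm = TRUE),
    per_class_accuracy = recall,
    per_class_f1 = f1,
    n = total), class = "epg_metrics")
}

#' @export
print.epg_metrics <- function(x, ...) {
  cat(sprintf("overall accuracy: %.4f   macro F1: %.4f   (n = %d)\n",
              x$overall_accuracy, x$macro_f1, x$n))
  df <- data.frame(accuracy = round(x$per_class_accuracy, 4),
                   f1 = round(x$per_class_f1, 4))
  rownames(df) <- EPG_LABELS
  print(df)
  invisible(x)
}

#' Overlap rate between two per-timestep annotations
#'
#' The fraction of timesteps at which the two label sequences agree - the
#' whole-recording analogue of classification accuracy, and the headline
#' metric for the annotation task.
#'
#' @param true,pred equally long per-timestep label vectors.
#' @return scalar in \[0, 1\].
#' @export
overlap_rate <- function(true, pred) {
  if (length(true) != length(pred)) {
    stopf("label sequences differ in length (%d vs %d)",
          length(true), length(pred))
  }
  mean(as.character(true) == as.character(pred))
}

#' k-fold cross-validated evaluation
#'
#' Assigns segments to `k` seeded folds, trains on `k - 1` folds and
#' evaluates on the held-out fold, and reports the mean and standard
#' deviation of overall accuracy and macro F1 across folds. Folds are drawn
#' at the segment level by default; pass `groups` (one id per segment, e.g.
#' the source recording) to fold at the recording level instead, which
#' avoids leaking within-recording correlation.
#'
#' @param x feature matrix (segments x features).
#' @param y segment labels.
#' @param family classifier family, see [epg_train()].
#' @param k number of folds (default 10).
#' @param config an [epg_model_config()].
#' @param groups optional grouping vector for group-level folding.
#' @param seed fold-assignment seed.
#' @return list with `folds` (per-fold data frame) and `summary`
#'   (mean/sd of overall accuracy and macro F1).
#' @export
kfold_evaluate <- function(x, y, family = "gbt", k = 10,
                           config = epg_model_config(), groups = NULL,
                           seed = 1) {
  y <- as_epg_label(y)
  n <- nrow(x)
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k (%d) exceeds the number of segments (%d)", k, n)
  fold_of <- with_seed(mix_seed(seed, 41L), {
    if (is.null(groups)) {
      sample(rep(seq_len(k), length.out = n))
    } else {
      ug <- unique(groups)
      if (k > length(ug)) stopf("k exceeds the number of groups")
      gf <- sample(rep(seq_len(k), length.out = length(ug)))
      gf[match(groups, ug)]
    }
  })
  rows <- lapply(seq_len(k), function(fi) {
    te <- fold_of == fi
    model <- epg_train(x[!te, , drop = FALSE], y[!te], family = family,
                       config = config)
    pred <- predict(model, x[te, , drop = FALSE])
    met <- suppressWarnings(classification_metrics(confusion_matrix(y[te], pred)))
    data.frame(fold = fi, n_test = sum(te),
               overall_accuracy = met$overall_accuracy,
               macro_f1 = met$macro_f1)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       fold_assignment = fold_of,
       summary = data.frame(
         metric = c("overall_accuracy", "macro_f1"),
         mean = c(mean(folds$overall_accuracy), mean(folds$macro_f1)),
         sd = c(stats::sd(folds$overall_accuracy), stats::sd(folds$macro_f1))))
}
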