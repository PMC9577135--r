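#' Masked categorical cross-entropy
#'
#' Mean over labeled (non-avoid) pixels of `-log p(true class)`. Avoid-class
#' pixels carry no annotation and are excluded entirely, so predictions there
#' can never contribute loss or gradient. Probabilities below `eps` are
#' clamped with a warning (a hard zero at a true class would otherwise give an
#' infinite loss).
#'
#' @param probabilities matrix `n_pixels` x `n_classes` of per-pixel class
#'   probabilities (rows sum to 1), or an H x W x C array.
#' @param labels integer matrix/vector of 0-based legend indices, flattened in
#'   the same (column-major) order as the probabilities.
#' @param avoid_index label value marking unlabeled pixels.
#' @param eps clamp for vanishing probabilities.
#' @return scalar loss.
#' @export
masked_cross_entropy <- function(probabilities, labels, avoid_index,
                                 eps = 1e-12) {
  if (length(dim(probabilities)) == 3L) {
    d <- dim(probabilities)
    probabilities <- matrix(probabilities, nrow = d[1] * d[2], ncol = d[3])
  }
  y <- as.integer(labels)
  if (length(y) != nrow(probabilities))
    stop("labels and probabilities disagree on pixel count")
  keep <- y != avoid_index
  if (!any(keep)) stop("all pixels are avoid-class; loss is undefined")
  p <- probabilities[cbind(which(keep), y[keep] + 1L)]
  if (any(p < eps)) {
    warning("zero probability at a true class; clamped")
    p <- pmax(p, eps)
  }
  -mean(log(p))
}

#' Accumulate pooled per-class confusion counts
#'
#' Pools pixel-level TP/FP/FN/TN per tissue class over one or more images
#' ("micro-pooling": counts are summed across the whole evaluation set before
#' any metric is computed). Pixels whose ground truth is avoid are skipped;
#' predictions never contain the avoid index.
#'
#' @param pred integer label map of predictions (0-based tissue indices).
#' @param truth integer label map of ground truth (may contain `avoid_index`).
#' @param legend a `class_legend` (defines class count and avoid index).
#' @param running optional `confusion_counts` to add into.
#' @return object of class `confusion_counts`: integer matrix `n_classes` x 4
#'   (TP, FP, FN, TN) plus `n_evaluated` and class names.
#' @export
accumulate_confusion <- function(pred, truth, legend, running = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have the same shape")
  k <- n_classes(legend)
  t <- as.integer(truth); p <- as.integer(pred)
  keep <- t != legend$avoid_index
  t <- t[keep]; p <- p[keep]
  if (any(p >= k)) stop("predictions contain indices outside the tissue classes")
  n <- length(t)
  tp <- tabulate(t[p == t] + 1L, nbins = k)
  fp <- tabulate(p + 1L, nbins = k) - tp
  fn <- tabulate(t + 1L, nbins = k) - tp
  tn <- n - tp - fp - fn
  m <- cbind(TP = tp, FP = fp, FN = fn, TN = tn)
  rownames(m) <- legend$name
  out <- structure(list(counts = m, n_evaluated = n, class_names = legend$name),
                   class = "confusion_counts")
  if (!is.null(running)) {
    if (!identical(running$class_names, legend$name))
      stop("running counts were accumulated against a different legend")
    out$counts <- out$counts + running$counts
    out$n_evaluated <- out$n_evaluated + running$n_evaluated
  }
  out
}

#' Per-class Sorensen-Dice coefficients from pooled counts
#'
#' `dice_c = 2*TP_c / (2*TP_c + FP_c + FN_c)`. A class that never occurs in
#' truth or prediction (TP+FP+FN = 0) has no defined overlap and is returned
#' as `NA`, not 0.
#'
#' @param counts a [accumulate_confusion()] result.
#' @return named numeric vector in `[0, 1]` (NA where undefined).
#' @export
dice_per_class <- function(counts) {
  m <- counts$counts
  denom <- 2 * m[, "TP"] + m[, "FP"] + m[, "FN"]
  d <- ifelse(denom > 0, 2 * m[, "TP"] / denom, NA_real_)
  names(d) <- counts$class_names
  d
}

#' One-vs-all ROC AUC for one class
#'
#' Treats the class's predicted probability as a score, that class's pixels
#' as positives and all other labeled pixels as negatives. Computed by the
#' rank (Mann-Whitney) statistic with the standard tie correction, which
#' equals trapezoidal integration of the ROC curve: the returned value is the
#' probability that a random positive outranks a random negative, ties
#' counting one half.
#'
#' @param scores numeric vector of per-pixel scores for the class.
#' @param truth logical (or 0/1) vector, `TRUE` for pixels of the class.
#'   Avoid pixels must already be excluded.
#' @return AUC in `[0, 1]`, or `NA` when truth is single-class.
#' @export
roc_auc_one_vs_all <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)  # midranks handle ties
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Smooth a loss curve with a centered moving average
#'
#' Each point becomes the mean of a centered window of `window` epochs,
#' truncated at the series edges, so the output has the input's length.
#'
#' @param series numeric per-epoch values.
#' @param window odd window length in epochs (default 3).
#' @return smoothed series, same length.
#' @export
smooth_loss_curve <- function(series, window = 3L) {
  if (length(series) == 0) stop("empty loss series")
  if (window < 1) stop("window must be >= 1")
  h <- floor(window / 2)
  n <- length(series)
  vapply(seq_len(n), function(i)
    mean(series[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Evaluate a trained classifier on a holdout set
#'
#' Predicts every holdout ROI, pools confusion counts across the whole set,
#' and reports per-class Dice and one-vs-all AUC for classes present in the
#' holdout ground truth, plus the pooled masked cross-entropy and the
#' unweighted mean Dice over defined classes.
#'
#' @param holdout non-empty list of `roi_sample`.
#' @param model a trained model (see [train_unet()]).
#' @param stats frozen training-pool [compute_stats()].
#' @param legend the `class_legend`.
#' @param version_tag label for this classifier version (e.g. `"C0"`).
#' @return object of class `metrics_report` with fields `version_tag`,
#'   `dice`, `auc`, `mean_dice`, `cross_entropy`, `present_classes`,
#'   `classes_absent`, `counts`.
#' @export
build_report <- function(holdout, model, stats, legend, version_tag = "C") {
  if (length(holdout) == 0) stop("holdout set is empty")
  counts <- NULL
  k <- n_classes(legend)
  score_list <- vector("list", length(holdout))
  truth_list <- vector("list", length(holdout))
  ce_num <- 0; ce_den <- 0
  for (i in seq_along(holdout)) {
    s <- holdout[[i]]
    probs <- predict_probs(model, s, stats)
    pred <- probs_to_labels(probs)
    counts <- accumulate_confusion(pred, s$labels, legend, running = counts)
    y <- as.integer(s$labels)
    keep <- y != legend$avoid_index
    if (any(keep)) {
      pk <- probs[keep, , drop = FALSE]
      ce_num <- ce_num + sum(-log(pmax(pk[cbind(seq_len(nrow(pk)),
                                                y[keep] + 1L)], 1e-12)))
      ce_den <- ce_den + sum(keep)
      score_list[[i]] <- pk
      truth_list[[i]] <- y[keep]
    }
  }
  scores <- do.call(rbind, score_list)
  truths <- do.call(c, truth_list)
  truth_count <- counts$counts[, "TP"] + counts$counts[, "FN"]
  present <- truth_count > 0
  dice <- dice_per_class(counts)
  dice[!present] <- NA_real_
  auc <- rep(NA_real_, k)
  names(auc) <- legend$name
  for (c in which(present)) {
    auc[c] <- roc_auc_one_vs_all(scores[, c], truths == (c - 1L))
  }
  defined <- present & !is.na(dice)
  structure(list(
    version_tag = version_tag,
    dice = dice, auc = auc,
    mean_dice = mean(dice[defined]),
    cross_entropy = ce_num / ce_den,
    present_classes = legend$name[present],
    classes_absent = legend$name[!present],
    counts = counts), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s: mean Dice %.3f over %d present classes, CE %.4f\n",
              x$version_tag, x$mean_dice, length(x$present_classes),
              x$cross_entropy))
  invisible(x)
}

#' Tabulate reports across classifier versions
#'
#' Arranges per-class Dice (or AUC) of several reports as a table with one row
#' per class plus an unweighted `Average` row and one column per classifier
#' version, the layout used to compare active-learning and random-learning
#' versions side by side.
#'
#' @param reports list of `metrics_report`.
#' @param metric `"dice"` or `"auc"`.
#' @return data.frame, rownames = classes (present in at least one report)
#'   then `"Average"`.
#' @export
report_table <- function(reports, metric = c("dice", "auc")) {
  metric <- match.arg(metric)
  vals <- lapply(reports, function(r) r[[metric]])
  tags <- vapply(reports, function(r) r$version_tag, character(1))
  m <- do.call(cbind, vals)
  colnames(m) <- tags
  keep <- rowSums(!is.na(m)) > 0
  m <- m[keep, , drop = FALSE]
  avg <- colMeans(m, na.rm = TRUE)
  out <- as.data.frame(rbind(m, Average = avg))
  out
}
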