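# Shared fixtures and independent brute-force oracles. Everything is built in
# code at test time; there are no stored fixtures.

legend <- tissue_legend()

# A minimal ROI with a constant-colored image; labels supplied or all-stroma.
tiny_roi <- function(roi_id, patient_id, labels = NULL, n = 4L, value = 128,
                     mpp = 2) {
  if (is.null(labels)) labels <- matrix(0L, n, n)
  img <- array(value, dim = c(dim(labels), 3L))
  roi_sample(roi_id, patient_id, img, labels, mpp)
}

# A 24-ROI / 23-patient skeleton cohort (one patient contributes two ROIs)
# with trivial images, for split and bookkeeping tests.
skeleton_cohort <- function(n = 4L) {
  ids <- sprintf("R%03d", 1:24)
  patients <- sprintf("P%02d", c(1L, 1:23))
  lapply(1:24, function(i) tiny_roi(ids[i], patients[i], n = n,
                                    value = i * 10))
}

# Brute-force per-class confusion by explicit pixel loops (the oracle for
# accumulate_confusion / dice_per_class).
brute_confusion <- function(pred, truth, n_cls, avoid) {
  m <- matrix(0, n_cls, 4, dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (i in seq_along(truth)) {
    if (truth[i] == avoid) next
    for (c in 0:(n_cls - 1)) {
      p <- pred[i] == c; t <- truth[i] == c
      if (p && t) m[c + 1, "TP"] <- m[c + 1, "TP"] + 1
      else if (p) m[c + 1, "FP"] <- m[c + 1, "FP"] + 1
      else if (t) m[c + 1, "FN"] <- m[c + 1, "FN"] + 1
      else m[c + 1, "TN"] <- m[c + 1, "TN"] + 1
    }
  }
  m
}

brute_dice <- function(pred, truth, n_cls, avoid) {
  m <- brute_confusion(pred, truth, n_cls, avoid)
  den <- 2 * m[, "TP"] + m[, "FP"] + m[, "FN"]
  ifelse(den > 0, 2 * m[, "TP"] / den, NA_real_)
}

# Exhaustive positive/negative pair counting (the AUC oracle).
brute_auc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!truth]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Function-model returning the ground truth as one-hot probabilities (an
# ideal predictor; avoid pixels get class 0).
oracle_predictor <- function(n_cls, avoid) {
  function(sample, stats) {
    y <- as.integer(sample$labels)
    y[y == avoid] <- 0L
    p <- matrix(0, length(y), n_cls)
    p[cbind(seq_along(y), y + 1L)] <- 1
    p
  }
}

# Function-model always predicting one class with certainty.
constant_predictor <- function(cls, n_cls) {
  function(sample, stats) {
    p <- matrix(0, length(sample$labels), n_cls)
    p[, cls + 1L] <- 1
    p
  }
}

# Cheap experiment settings for bookkeeping tests: tiny images, 1 epoch.
cheap_cohort <- function(seed = 7L) {
  generate_cohort(cohort_config(n_patients = 23L,
                                rois_per_patient = c(2L, rep(1L, 22L)),
                                image_size = 32L, seed = seed))
}

cheap_spec <- function() model_spec(n_classes = 11L, base_channels = 2L,
                                    dropout_rate = 0)
cheap_config <- function() train_config(epochs = 1L, learning_rate = 1e-3)
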