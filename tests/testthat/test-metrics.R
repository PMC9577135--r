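test_that("masked cross-entropy matches analytic values and ignores avoid pixels", {
  # perfect one-hot prediction
  y <- c(0L, 1L, 2L)
  p <- diag(3)
  expect_equal(masked_cross_entropy(p, y, avoid_index = 3L), 0)

  # uniform prediction over C classes
  pu <- matrix(1 / 11, 5, 11)
  expect_equal(masked_cross_entropy(pu, rep(0L, 5), avoid_index = 11L),
               log(11), tolerance = 1e-12)

  # hand softmax: logits (2,0,0), true class 0 -> -log(e^2/(e^2+2)), i.e.
  # log(1 + 2 exp(-2)) ~ 0.2395
  z <- exp(c(2, 0, 0)); pz <- matrix(z / sum(z), 1)
  expect_equal(masked_cross_entropy(pz, 0L, avoid_index = 3L),
               log(1 + 2 * exp(-2)), tolerance = 1e-12)

  # avoid pixels contribute nothing: perturbing them leaves the loss unchanged
  set.seed(1)
  probs <- matrix(runif(40), 10, 4)
  probs <- probs / rowSums(probs)
  y2 <- c(rep(0:3, 2), 4L, 4L)
  base <- masked_cross_entropy(probs, y2, avoid_index = 4L)
  probs2 <- probs
  probs2[y2 == 4L, ] <- rep(c(1, 0, 0, 0), each = sum(y2 == 4L))
  expect_identical(masked_cross_entropy(probs2, y2, avoid_index = 4L), base)

  expect_error(masked_cross_entropy(probs, rep(4L, 10), avoid_index = 4L),
               "undefined")
  expect_warning(
    masked_cross_entropy(matrix(c(0, 1, 1, 0), 1), 0L, avoid_index = 9L),
    "clamped")
})

test_that("confusion accumulation pools micro-counts and skips avoid truth", {
  tum <- legend$index[legend$name == "Tumor"]
  str <- legend$index[legend$name == "Stroma"]
  truth <- matrix(c(tum, tum, str, legend$avoid_index), 1)
  pred <- matrix(c(tum, str, str, tum), 1)
  cc <- accumulate_confusion(pred, truth, legend)
  expect_identical(cc$n_evaluated, 3L)
  expect_identical(unname(cc$counts["Tumor", c("TP", "FP", "FN")]),
                   c(1L, 0L, 1L))
  expect_identical(unname(cc$counts["Stroma", c("TP", "FP", "FN")]),
                   c(1L, 1L, 0L))

  perfect <- accumulate_confusion(truth * 0L + str,
                                  truth * 0L + str, legend)
  expect_true(all(perfect$counts[, c("FP", "FN")] == 0))

  # additivity: two images == their concatenation
  set.seed(3)
  t1 <- matrix(sample(0:11, 36, replace = TRUE), 6, 6)
  t2 <- matrix(sample(0:11, 36, replace = TRUE), 6, 6)
  p1 <- matrix(sample(0:10, 36, replace = TRUE), 6, 6)
  p2 <- matrix(sample(0:10, 36, replace = TRUE), 6, 6)
  two <- accumulate_confusion(p2, t2, legend,
                              running = accumulate_confusion(p1, t1, legend))
  cat12 <- accumulate_confusion(rbind(p1, p2), rbind(t1, t2), legend)
  expect_identical(two$counts, cat12$counts)

  expect_error(accumulate_confusion(matrix(0L, 2, 2), matrix(0L, 3, 2),
                                    legend), "same shape")
  expect_error(accumulate_confusion(matrix(11L, 2, 2), matrix(0L, 2, 2),
                                    legend), "outside")
})

test_that("Dice follows the pooled-count formula with NA for undefined classes", {
  counts <- structure(list(
    counts = cbind(TP = c(6L, 5L, 0L, 0L), FP = c(2L, 0L, 3L, 0L),
                   FN = c(2L, 0L, 2L, 0L), TN = c(0L, 5L, 5L, 10L)),
    n_evaluated = 10L, class_names = c("a", "b", "c", "d")),
    class = "confusion_counts")
  d <- dice_per_class(counts)
  expect_equal(unname(d), c(0.75, 1, 0, NA))

  # symmetry: swapping pred and truth leaves Dice unchanged
  set.seed(8)
  p <- matrix(sample(0:10, 100, replace = TRUE), 10, 10)
  t <- matrix(sample(0:10, 100, replace = TRUE), 10, 10)
  d1 <- dice_per_class(accumulate_confusion(p, t, legend))
  d2 <- dice_per_class(accumulate_confusion(t, p, legend))
  expect_equal(d1, d2)
})

test_that("one-vs-all AUC equals the probability a positive outranks a negative", {
  expect_equal(roc_auc_one_vs_all(c(0.9, 0.8, 0.1, 0.2),
                                  c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc_one_vs_all(rep(0.4, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(roc_auc_one_vs_all(c(0.8, 0.3, 0.6, 0.2),
                                  c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_true(is.na(roc_auc_one_vs_all(c(0.1, 0.2), c(TRUE, TRUE))))

  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), sample(c(1, 3), 1))  # coarse rounding forces ties
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    expect_equal(roc_auc_one_vs_all(scores, truth), brute_auc(scores, truth))
  }
})

test_that("loss-curve smoothing is a centered, edge-truncated moving average", {
  expect_equal(smooth_loss_curve(c(3, 2, 1), 3), c(2.5, 2, 1.5))
  expect_equal(smooth_loss_curve(rep(4, 7), 3), rep(4, 7))
  expect_equal(smooth_loss_curve(c(5, 1, 3), 1), c(5, 1, 3))
  expect_error(smooth_loss_curve(numeric(0)), "empty")
  s <- c(9, 7, 2, 4, 8, 1)
  expect_length(smooth_loss_curve(s, 5), length(s))
  expect_equal(smooth_loss_curve(s, 5)[3], mean(s[1:5]))
})

test_that("holdout reports pool confusion across images and average present classes", {
  coh <- generate_cohort(cohort_config(n_patients = 3L, image_size = 32L,
                                       seed = 14L))
  st <- compute_stats(coh$samples)

  perfect <- build_report(coh$samples, oracle_predictor(11L, legend$avoid_index),
                          st, legend, version_tag = "oracle")
  expect_equal(perfect$mean_dice, 1)
  expect_true(all(perfect$dice[perfect$present_classes] == 1))
  expect_true(all(perfect$auc[perfect$present_classes] == 1))
  expect_equal(perfect$cross_entropy, 0, tolerance = 1e-9)

  # constant predictor: Dice = 2p/(1+p) for the predicted class, 0 elsewhere
  stroma <- build_report(coh$samples, constant_predictor(0L, 11L), st, legend)
  labs <- unlist(lapply(coh$samples, function(s) as.integer(s$labels)))
  labs <- labs[labs != legend$avoid_index]
  p <- mean(labs == 0L)
  expect_equal(unname(stroma$dice["Stroma"]), 2 * p / (1 + p))
  other <- setdiff(stroma$present_classes, "Stroma")
  expect_true(all(stroma$dice[other] == 0))

  # micro-pooling: two images equal their concatenation
  s1 <- coh$samples[[1]]; s2 <- coh$samples[[2]]
  img <- array(0, c(64, 32, 3))
  img[1:32, , ] <- s1$image
  img[33:64, , ] <- s2$image
  merged <- roi_sample("cat", "p", img, rbind(s1$labels, s2$labels), 2)
  r2 <- build_report(list(s1, s2), constant_predictor(1L, 11L), st, legend)
  r1 <- build_report(list(merged), constant_predictor(1L, 11L), st, legend)
  expect_equal(r1$dice, r2$dice)
  expect_equal(r1$auc, r2$auc)

  tab <- report_table(list(perfect, stroma))
  expect_identical(colnames(tab), c("oracle", "C"))
  expect_identical(rownames(tab)[nrow(tab)], "Average")
  expect_equal(tab["Average", "oracle"], 1)
})
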