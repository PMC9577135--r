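test_that("bootstrap selection draws without replacement, deterministically", {
  pool <- sprintf("R%03d", 1:21)
  d0 <- bootstrap_selection(pool, 4L, seed = 77)
  expect_length(d0, 4L)
  expect_length(unique(d0), 4L)
  expect_true(all(d0 %in% pool))
  expect_identical(bootstrap_selection(pool, 4L, seed = 77), d0)
  expect_setequal(bootstrap_selection(pool, 21L, seed = 1), pool)
  expect_error(bootstrap_selection(pool, 22L, seed = 1), "pool of 21")
})

test_that("the simulated QA grade maps per-class Dice onto the 0-5 scale", {
  tum <- legend$index[legend$name == "Tumor"]
  str <- legend$index[legend$name == "Stroma"]

  truth <- matrix(c(rep(tum, 8), rep(str, 8)), 4, 4)
  g <- oracle_grade(truth, truth, legend, roi_id = "x")
  expect_true(all(g$per_class_grade == 5))
  expect_equal(g$aggregate, 5)

  # a completely missed class grades 0
  pred_miss <- matrix(str, 4, 4)
  g0 <- oracle_grade(pred_miss, truth, legend)
  expect_identical(unname(g0$per_class_grade["Tumor"]), 0L)

  # Dice 6/13 = 0.4615 -> round(2.31) = 2; built from TP=3, FP=3, FN=4
  truth2 <- matrix(c(rep(tum, 7), rep(str, 9)), 4, 4)
  pred2 <- matrix(c(rep(tum, 3), rep(str, 4), rep(c(tum, str), c(3, 6))), 4, 4)
  cc <- accumulate_confusion(pred2, truth2, legend)
  expect_identical(unname(cc$counts["Tumor", c("TP", "FP", "FN")]),
                   c(3L, 3L, 4L))
  g2 <- oracle_grade(pred2, truth2, legend)
  expect_identical(unname(g2$per_class_grade["Tumor"]), 2L)

  # noise is integer, clamped, and reproducible under its seed
  gn1 <- oracle_grade(pred_miss, truth, legend, noise_sd = 2, seed = 5)
  gn2 <- oracle_grade(pred_miss, truth, legend, noise_sd = 2, seed = 5)
  expect_identical(gn1$per_class_grade, gn2$per_class_grade)
  expect_true(all(gn1$per_class_grade %in% 0:5))

  all_avoid <- matrix(legend$avoid_index, 4, 4)
  expect_error(oracle_grade(pred_miss, all_avoid, legend), "ungradeable")
})

test_that("lowest-grade selection sorts by aggregate with lexicographic ties", {
  mk <- function(id, agg) structure(list(roi_id = id, aggregate = agg),
                                    class = "qa_grade")
  grades <- list(mk("A", 3.2), mk("B", 1.0), mk("C", 4.5), mk("D", 1.0),
                 mk("E", 2.0))
  expect_identical(select_lowest(grades, 4L), c("B", "D", "E", "A"))
  expect_identical(select_lowest(grades, 1L), "B")
  tied <- list(mk("c", 2), mk("a", 2), mk("b", 2))
  expect_identical(select_lowest(tied, 2L), c("a", "b"))
  expect_warning(out <- select_lowest(tied, 5L), "only 3")
  expect_length(out, 3L)
  expect_error(select_lowest(list(), 2L), "no grades")
})

test_that("the AL loop keeps nested, budget-true training sets", {
  coh <- cheap_cohort()
  split <- split_by_patient(coh$samples, 3L, seed = 11)
  recs <- run_al(coh, split, cheap_spec(), cheap_config(),
                 n_iterations = 3L, experiment_seed = 3L)
  expect_length(recs, 4L)
  sizes <- vapply(recs, function(r) length(r$training_ids), integer(1))
  expect_identical(sizes, c(4L, 8L, 12L, 16L))
  for (i in 2:4) {
    expect_true(all(recs[[i - 1]]$training_ids %in% recs[[i]]$training_ids))
    expect_length(recs[[i]]$selected_ids, 4L)
    expect_true(all(recs[[i]]$selected_ids %in% split$train_pool_ids))
    # selected ROIs come from the never-selected remainder
    expect_length(intersect(recs[[i]]$selected_ids,
                            recs[[i - 1]]$training_ids), 0L)
    # and they are the worst-graded ones
    expect_setequal(recs[[i]]$selected_ids,
                    select_lowest(recs[[i]]$grades, 4L))
  }
  # every graded candidate at iteration i was outside D_{i-1}
  expect_length(recs[[2]]$grades, length(split$train_pool_ids) - 4L)

  solo <- run_al(coh, split, cheap_spec(), cheap_config(),
                 n_iterations = 0L, experiment_seed = 3L)
  expect_length(solo, 1L)
  expect_identical(sort(solo[[1]]$training_ids),
                   sort(recs[[1]]$training_ids))
})

test_that("RL batches share D0, never reselect, and match AL budgets", {
  coh <- cheap_cohort()
  split <- split_by_patient(coh$samples, 3L, seed = 11)
  al <- run_al(coh, split, cheap_spec(), cheap_config(),
               n_iterations = 2L, experiment_seed = 3L)
  rl <- run_rl(coh, split, cheap_spec(), cheap_config(),
               n_iterations = 2L, n_batches = 3L, experiment_seed = 3L)
  expect_length(rl, 3L)
  for (b in 1:3) {
    expect_setequal(rl[[b]][[1]]$training_ids, al[[1]]$training_ids)
    for (i in seq_along(rl[[b]])) {
      expect_identical(length(rl[[b]][[i]]$training_ids),
                       length(al[[i]]$training_ids))
      expect_length(unique(rl[[b]][[i]]$training_ids),
                    length(rl[[b]][[i]]$training_ids))
    }
  }
  # batches draw different random additions (overwhelmingly likely)
  expect_false(identical(sort(rl[[1]][[3]]$training_ids),
                         sort(rl[[2]][[3]]$training_ids)) &&
               identical(sort(rl[[2]][[3]]$training_ids),
                         sort(rl[[3]][[3]]$training_ids)))

  res <- compare_strategies(al, rl)
  expect_s3_class(res, "experiment_result")
  expect_length(res$rl_mean_dice, 3L)
  expect_identical(nrow(res$per_class) >= 1, TRUE)
  expect_length(res$al_added_px, 2L)
})

test_that("strategy comparison gives p = 1 on identical runs and exact extremes", {
  fake_report <- function(dice) {
    structure(list(dice = dice, mean_dice = mean(dice, na.rm = TRUE)),
              class = "metrics_report")
  }
  fake_rec <- function(dice, i) {
    structure(list(iteration = i, training_ids = character(4 * (i + 1)),
                   report = fake_report(dice),
                   history = data.frame(epoch = 1, train_loss = 1,
                                        val_loss = 0.5),
                   added_gt_pixels = 100), class = "iteration_record")
  }
  classes <- paste0("c", 1:8)
  d <- stats::setNames(seq(0.1, 0.8, length.out = 8), classes)
  al <- list(fake_rec(d, 0), fake_rec(d, 1))
  rl_same <- list(al, al, al)
  res <- compare_strategies(al, rl_same)
  expect_equal(res$comparison_p, 1)
  expect_equal(res$mean_dice_delta, 0)

  # AL strictly above RL on all 8 classes: two-sided exact Wilcoxon floor
  al_hi <- list(fake_rec(d, 0), fake_rec(d + 0.05 * seq_len(8), 1))
  res2 <- compare_strategies(al_hi, rl_same)
  expect_equal(res2$comparison_p, 2 / 2^8, tolerance = 1e-12)
  expect_equal(res2$mean_dice_delta,
               mean(d + 0.05 * seq_len(8)) - mean(d))

  # fewer than 3 paired classes: test skipped with a notice
  d2 <- stats::setNames(c(0.5, 0.6), c("c1", "c2"))
  al2 <- list(fake_rec(d2, 0))
  expect_message(res3 <- compare_strategies(al2, list(list(fake_rec(d2 + 0.1, 0)))),
                 "fewer than 3")
  expect_true(is.na(res3$comparison_p))
})

test_that("noise-free oracle selection equals the k-argmin of recomputed grades", {
  coh <- generate_cohort(cohort_config(n_patients = 8L, image_size = 32L,
                                       seed = 31L))
  st <- compute_stats(coh$samples)
  # a deterministic but imperfect predictor: stride-2 blur of the truth
  blurry <- function(sample, stats) {
    y <- sample$labels
    y2 <- y[rep(seq(1, nrow(y), by = 2), each = 2),
            rep(seq(1, ncol(y), by = 2), each = 2)]
    y2[y2 == legend$avoid_index] <- 0L
    p <- matrix(1e-3, length(y2), 11)
    p[cbind(seq_along(y2), as.integer(y2) + 1L)] <- 1
    p / rowSums(p)
  }
  grades <- lapply(coh$samples, function(s) {
    pred <- matrix(alseg:::probs_to_labels(blurry(s, st)), nrow(s$labels))
    oracle_grade(pred, s$labels, legend, roi_id = s$roi_id)
  })
  picked <- select_lowest(grades, 3L)

  # independent recomputation: brute-force per-image mean of quantized
  # per-class Dice grades, k-argmin with lexicographic ties
  agg <- vapply(coh$samples, function(s) {
    pred <- matrix(alseg:::probs_to_labels(blurry(s, st)), nrow(s$labels))
    d <- brute_dice(as.integer(pred), as.integer(s$labels), 11L,
                    legend$avoid_index)
    present <- !is.na(d) & tabulate(as.integer(s$labels)[
      as.integer(s$labels) != legend$avoid_index] + 1L, 11L) > 0
    mean(floor(5 * d[present] + 0.5))
  }, numeric(1))
  ids <- vapply(coh$samples, function(s) s$roi_id, character(1))
  expected <- ids[order(agg, ids)][1:3]
  expect_identical(picked, expected)
})
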