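#' Bootstrap training-set selection
#'
#' Draws `n` ROIs uniformly without replacement from the training pool to form
#' the first training set D0, shared by the active-learning run and every
#' random-learning batch.
#'
#' @param pool character vector of candidate roi_ids.
#' @param n number to draw (default 4).
#' @param seed integer; the draw is deterministic under it.
#' @return character vector of selected roi_ids.
#' @export
bootstrap_selection <- function(pool, n = 4L, seed = 1L) {
  if (n > length(pool))
    stop(sprintf("cannot bootstrap %d ROIs from a pool of %d", n, length(pool)))
  with_seed(seed, sample(pool, n))
}

#' Simulated tissue-map quality-assurance grade
#'
#' Stands in for the human QA step in which each predicted tissue map is
#' graded 0-5 per class (5 = ideal segmentation, 0 = poor). The simulated
#' grader computes the per-image Dice `d_c` for every class present in the
#' ground truth and assigns `round(5 * d_c)` (half-up), optionally perturbed
#' by integer-rounded Gaussian noise and clamped to 0..5 to emulate grader
#' variability. The image-level aggregate is the unweighted mean of the class
#' grades.
#'
#' @param pred predicted label map (tissue indices only).
#' @param truth ground-truth label map (may contain avoid).
#' @param legend the `class_legend`.
#' @param noise_sd standard deviation of the grade noise (0 = noise-free).
#' @param seed RNG seed for the noise.
#' @param roi_id identifier recorded in the grade.
#' @return object of class `qa_grade`: `roi_id`, `per_class_grade` (named
#'   integer vector over classes present in truth), `aggregate`.
#' @export
oracle_grade <- function(pred, truth, legend, noise_sd = 0, seed = 1L,
                         roi_id = "") {
  counts <- accumulate_confusion(pred, truth, legend)
  present <- (counts$counts[, "TP"] + counts$counts[, "FN"]) > 0
  if (!any(present)) stop("ground truth is entirely avoid-class; ungradeable")
  d <- dice_per_class(counts)[present]
  grades <- half_up(5 * d)
  if (noise_sd > 0) {
    noise <- with_seed(seed, half_up(rnorm(length(grades), 0, noise_sd)))
    grades <- grades + noise
  }
  grades <- as.integer(pmin(pmax(grades, 0), 5))
  names(grades) <- names(d)
  structure(list(roi_id = roi_id, per_class_grade = grades,
                 aggregate = mean(grades)),
            class = "qa_grade")
}

#' Select the lowest-graded ROIs
#'
#' Orders grades by ascending aggregate score (ties broken by lexicographic
#' roi_id, so selection is fully deterministic) and returns the `k` worst.
#' When fewer than `k` grades remain, all are returned with a warning.
#'
#' @param grades list of [oracle_grade()] results.
#' @param k number to select (default 4).
#' @return character vector of roi_ids, worst first.
#' @export
select_lowest <- function(grades, k = 4L) {
  if (length(grades) == 0) stop("no grades to select from")
  if (k < 1) stop("k must be >= 1")
  ids <- vapply(grades, function(g) g$roi_id, character(1))
  agg <- vapply(grades, function(g) g$aggregate, numeric(1))
  ord <- order(agg, ids)
  if (length(ids) < k) {
    warning(sprintf("only %d graded ROIs remain (%d requested)",
                    length(ids), k))
    k <- length(ids)
  }
  ids[ord][seq_len(k)]
}

# Deterministic validation split: a fixed fraction of the current training
# set (at least 1 ROI, and at least 1 ROI left for gradients) held out from
# gradient updates to measure per-epoch validation loss.
validation_split <- function(training_ids, fraction, seed) {
  n_val <- min(max(1L, floor(fraction * length(training_ids))),
               length(training_ids) - 1L)
  if (n_val < 1L) return(character(0))
  with_seed(seed, sample(sort(training_ids), n_val))
}

new_iteration_record <- function(iteration, strategy, batch_id, training_ids,
                                 selected_ids, grades, report, history,
                                 validation_ids, added_gt_pixels) {
  structure(list(iteration = iteration, strategy = strategy,
                 batch_id = batch_id, training_ids = training_ids,
                 selected_ids = selected_ids, grades = grades,
                 report = report, history = history,
                 validation_ids = validation_ids,
                 added_gt_pixels = added_gt_pixels),
            class = "iteration_record")
}

#' @export
print.iteration_record <- function(x, ...) {
  cat(sprintf("<iteration_record> %s i=%d%s |D|=%d mean Dice %.3f\n",
              x$strategy, x$iteration,
              if (!is.na(x$batch_id)) sprintf(" batch %d", x$batch_id) else "",
              length(x$training_ids), x$report$mean_dice))
  invisible(x)
}

count_gt_pixels <- function(samples, ids, avoid_index) {
  sum(vapply(cohort_subset(samples, ids),
             function(s) sum(s$labels != avoid_index), numeric(1)))
}

# One training round shared by the AL and RL drivers: fresh initialization,
# internal validation split, training, holdout evaluation.
train_and_evaluate <- function(iteration, strategy, batch_id, training_ids,
                               selected_ids, grades, cohort, holdout_ids,
                               model_spec, config, stats, legend,
                               experiment_seed, val_fraction, verbose) {
  tag <- if (strategy == "AL") sprintf("C%d", iteration)
         else sprintf("C%d_rl%d", iteration, batch_id)
  init_seed <- derive_seed(experiment_seed, "init", iteration)
  model <- build_unet(model_spec, seed = init_seed, version_tag = tag)
  val_ids <- validation_split(training_ids, val_fraction,
                              derive_seed(experiment_seed, "val", iteration,
                                          strategy,
                                          if (is.na(batch_id)) 0L else batch_id))
  grad_ids <- setdiff(training_ids, val_ids)
  cfg <- config
  cfg$seed <- derive_seed(experiment_seed, "train", iteration, strategy,
                          if (is.na(batch_id)) 0L else batch_id)
  model <- train_unet(model, cohort_subset(cohort$samples, grad_ids), cfg,
                      stats, legend,
                      validation_samples = cohort_subset(cohort$samples,
                                                         val_ids))
  report <- build_report(cohort_subset(cohort$samples, holdout_ids), model,
                         stats, legend, version_tag = tag)
  if (verbose)
    message(sprintf("[%s] iter=%d%s |D|=%d mean_dice=%.3f val_loss=%.4f",
                    strategy, iteration,
                    if (!is.na(batch_id)) sprintf(" batch=%d", batch_id) else "",
                    length(training_ids), report$mean_dice,
                    utils::tail(model$train_history$val_loss, 1)))
  list(model = model,
       record = new_iteration_record(
         iteration, strategy, batch_id, sort(training_ids), selected_ids,
         grades, report, model$train_history, val_ids,
         count_gt_pixels(cohort$samples, selected_ids, legend$avoid_index)))
}

#' Run the active-learning pipeline
#'
#' Bootstrap: D0 is a random draw of `n_bootstrap` ROIs from the training
#' pool; classifier C0 is trained on it. Each iteration then (1) predicts
#' tissue maps for every never-selected pool ROI with the current classifier,
#' (2) grades each map with the simulated QA oracle, (3) promotes the
#' `select_per_iter` worst-graded ROIs into the training set, and (4) retrains
#' from a fresh initialization and evaluates on the holdout set. Training-pool
#' statistics ([compute_stats()]) are computed once over the full pool and
#' frozen.
#'
#' @param cohort a [generate_cohort()] result (or list with `samples`,
#'   `legend`).
#' @param split a [split_by_patient()] result.
#' @param model_spec a [model_spec()].
#' @param train_cfg a [train_config()]; its seed field is re-derived per
#'   round from `experiment_seed`.
#' @param n_iterations selection/retraining rounds after the bootstrap
#'   (default 3).
#' @param oracle_config list with `noise_sd` for [oracle_grade()].
#' @param experiment_seed master seed; bootstrap, per-round initialization,
#'   validation splits, oracle noise and RL draws are derived from it (see
#'   [derive_seed()]).
#' @param n_bootstrap size of D0 (default 4).
#' @param select_per_iter ROIs promoted per iteration (default 4).
#' @param val_fraction fraction of the current training set held out as the
#'   validation set (default 0.25, at least one ROI).
#' @param stats optional precomputed [compute_stats()] (shared with RL runs).
#' @param verbose log one line per round.
#' @return list of `iteration_record`, one per classifier version C0..Cn.
#' @export
run_al <- function(cohort, split, model_spec, train_cfg, n_iterations = 3L,
                   oracle_config = list(noise_sd = 0), experiment_seed = 1L,
                   n_bootstrap = 4L, select_per_iter = 4L,
                   val_fraction = 0.25, stats = NULL, verbose = FALSE) {
  legend <- cohort$legend
  pool <- sort(split$train_pool_ids)
  if (is.null(stats))
    stats <- compute_stats(cohort_subset(cohort$samples, pool))
  d_i <- bootstrap_selection(pool, n_bootstrap,
                             derive_seed(experiment_seed, "bootstrap"))
  remaining <- setdiff(pool, d_i)
  records <- list()
  res <- train_and_evaluate(0L, "AL", NA_integer_, d_i, d_i, NULL, cohort,
                            split$holdout_ids, model_spec, train_cfg, stats,
                            legend, experiment_seed, val_fraction, verbose)
  records[[1]] <- res$record
  model <- res$model
  for (i in seq_len(n_iterations)) {
    if (length(remaining) == 0) {
      warning(sprintf("training pool exhausted after iteration %d", i - 1L))
      break
    }
    grades <- lapply(remaining, function(id) {
      s <- cohort_subset(cohort$samples, id)[[1]]
      pred <- predict_tissue_map(model, s, stats,
                                 mode = train_cfg$standardize_mode)
      oracle_grade(pred, s$labels, legend,
                   noise_sd = oracle_config$noise_sd %||% 0,
                   seed = derive_seed(experiment_seed, "oracle", i, id),
                   roi_id = id)
    })
    picked <- select_lowest(grades, k = min(select_per_iter,
                                            length(remaining)))
    d_i <- c(d_i, picked)
    remaining <- setdiff(remaining, picked)
    res <- train_and_evaluate(i, "AL", NA_integer_, d_i, picked, grades,
                              cohort, split$holdout_ids, model_spec,
                              train_cfg, stats, legend, experiment_seed,
                              val_fraction, verbose)
    records[[i + 1L]] <- res$record
    model <- res$model
  }
  records
}

#' Run the random-learning control
#'
#' Identical to [run_al()] except that promoted ROIs are drawn uniformly
#' without replacement from the never-selected pool, and the whole procedure
#' is repeated `n_batches` times. Every batch shares the AL run's D0 exactly
#' (same bootstrap seed derivation), so AL and every RL batch train on the
#' same number of ROIs at every iteration.
#'
#' @inheritParams run_al
#' @param n_batches number of independent random batches (default 3).
#' @return list of `n_batches` lists of `iteration_record`.
#' @export
run_rl <- function(cohort, split, model_spec, train_cfg, n_iterations = 3L,
                   n_batches = 3L, experiment_seed = 1L, n_bootstrap = 4L,
                   select_per_iter = 4L, val_fraction = 0.25, stats = NULL,
                   verbose = FALSE) {
  legend <- cohort$legend
  pool <- sort(split$train_pool_ids)
  if (is.null(stats))
    stats <- compute_stats(cohort_subset(cohort$samples, pool))
  d0 <- bootstrap_selection(pool, n_bootstrap,
                            derive_seed(experiment_seed, "bootstrap"))
  lapply(seq_len(n_batches), function(b) {
    d_i <- d0
    remaining <- setdiff(pool, d_i)
    records <- list()
    res <- train_and_evaluate(0L, "RL", b, d_i, d_i, NULL, cohort,
                              split$holdout_ids, model_spec, train_cfg,
                              stats, legend, experiment_seed, val_fraction,
                              verbose)
    records[[1]] <- res$record
    for (i in seq_len(n_iterations)) {
      if (length(remaining) == 0) {
        warning(sprintf("RL batch %d: pool exhausted after iteration %d",
                        b, i - 1L))
        break
      }
      k <- min(select_per_iter, length(remaining))
      picked <- with_seed(derive_seed(experiment_seed, "rl", b, i),
                          sample(remaining, k))
      d_i <- c(d_i, picked)
      remaining <- setdiff(remaining, picked)
      res <- train_and_evaluate(i, "RL", b, d_i, picked, NULL, cohort,
                                split$holdout_ids, model_spec, train_cfg,
                                stats, legend, experiment_seed, val_fraction,
                                verbose)
      records[[i + 1L]] <- res$record
    }
    records
  })
}

rl_metric_summary <- function(rl_batches, extract) {
  vals <- vapply(rl_batches, function(recs)
    vapply(recs, extract, numeric(1)), numeric(length(rl_batches[[1]])))
  vals <- matrix(vals, ncol = length(rl_batches))
  list(mean = rowMeans(vals), sd = apply(vals, 1, sd))
}

final_val_loss <- function(rec) {
  v <- rec$history$val_loss
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else v[length(v)]
}

#' Compare active learning against the random-learning control
#'
#' Pairs the final AL classifier's per-class holdout Dice with the mean over
#' RL batches of the final RL classifiers' per-class Dice, and tests the
#' paired differences with a two-sided Wilcoxon signed-rank test. Also
#' summarizes mean Dice and final validation loss per version (RL as
#' mean +/- sd over batches).
#'
#' @param al_records [run_al()] output.
#' @param rl_batches [run_rl()] output (same iteration count).
#' @return object of class `experiment_result`: `al_records`, `rl_batches`,
#'   `per_class` (final-iteration paired Dice), `comparison_p`,
#'   `mean_dice_delta`, per-version summaries `al_mean_dice`,
#'   `rl_mean_dice` (+ `rl_mean_dice_sd`), validation-loss summaries, and the
#'   annotation-budget bookkeeping (`al_added_px`, `rl_added_px`).
#' @export
compare_strategies <- function(al_records, rl_batches) {
  n_iter <- length(al_records)
  if (any(vapply(rl_batches, length, integer(1)) != n_iter))
    stop("AL and RL runs must have matching iteration counts")
  final_al <- al_records[[n_iter]]$report$dice
  final_rl <- rowMeans(vapply(rl_batches,
                              function(recs) recs[[n_iter]]$report$dice,
                              numeric(length(final_al))))
  paired <- !is.na(final_al) & !is.na(final_rl)
  comparison_p <- NA_real_
  if (sum(paired) >= 3) {
    deltas <- final_al[paired] - final_rl[paired]
    if (all(deltas == 0)) {
      comparison_p <- 1
    } else {
      comparison_p <- suppressWarnings(
        wilcox.test(final_al[paired], final_rl[paired], paired = TRUE,
                    alternative = "two.sided")$p.value)
    }
  } else {
    message("fewer than 3 paired classes; significance test skipped")
  }
  al_mean_dice <- vapply(al_records, function(r) r$report$mean_dice,
                         numeric(1))
  rl_md <- rl_metric_summary(rl_batches, function(r) r$report$mean_dice)
  al_val <- vapply(al_records, final_val_loss, numeric(1))
  rl_val <- rl_metric_summary(rl_batches, final_val_loss)
  al_added <- vapply(al_records[-1], function(r) r$added_gt_pixels, numeric(1))
  rl_added <- lapply(rl_batches, function(recs)
    vapply(recs[-1], function(r) r$added_gt_pixels, numeric(1)))
  structure(list(
    al_records = al_records, rl_batches = rl_batches,
    per_class = data.frame(class = names(final_al)[paired],
                           al = final_al[paired], rl_mean = final_rl[paired]),
    comparison_p = comparison_p,
    mean_dice_delta = al_mean_dice[n_iter] - rl_md$mean[n_iter],
    al_mean_dice = al_mean_dice,
    rl_mean_dice = rl_md$mean, rl_mean_dice_sd = rl_md$sd,
    al_final_val_loss = al_val, rl_final_val_loss = rl_val$mean,
    rl_final_val_loss_sd = rl_val$sd,
    al_added_px = al_added, rl_added_px = rl_added),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  n <- length(x$al_mean_dice)
  cat(sprintf("<experiment_result> %d versions\n", n))
  cat(sprintf("  final mean Dice: AL %.3f vs RL %.3f (delta %+.3f, p = %s)\n",
              x$al_mean_dice[n], x$rl_mean_dice[n], x$mean_dice_delta,
              format(x$comparison_p, digits = 3)))
  cat(sprintf("  final val loss:  AL %.4f vs RL %.4f\n",
              x$al_final_val_loss[n], x$rl_final_val_loss[n]))
  invisible(x)
}

#' Ground-truth annotation budget parity test
#'
#' Compares the total number of annotated (non-avoid) ground-truth pixels
#' added per iteration by AL against RL with a two-sided Wilcoxon rank-sum
#' test. Active learning is only interesting if its gain is not explained by
#' promoting more annotated pixels; parity means this test should usually not
#' reject.
#'
#' @param result an [compare_strategies()] result.
#' @return list with `p_value`, `al_added`, `rl_added`.
#' @export
gt_pixel_parity <- function(result) {
  al <- result$al_added_px
  rl <- unlist(result$rl_added_px)
  p <- if (length(unique(c(al, rl))) == 1L) 1  # identical budgets everywhere
  else suppressWarnings(wilcox.test(al, rl,
                                    alternative = "two.sided")$p.value)
  list(p_value = p, al_added = al, rl_added = rl)
}

#' Run the full AL-vs-RL experiment
#'
#' Convenience driver: patient-level split, shared frozen stats, one AL run,
#' `n_batches` RL runs, then [compare_strategies()].
#'
#' @inheritParams run_al
#' @param n_holdout_patients patients held out for testing.
#' @param n_batches RL batches.
#' @return an `experiment_result`.
#' @export
run_experiment <- function(cohort, model_spec, train_cfg,
                           n_holdout_patients = 3L, n_iterations = 3L,
                           n_batches = 3L, oracle_config = list(noise_sd = 0),
                           experiment_seed = 1L, val_fraction = 0.25,
                           verbose = FALSE) {
  split <- split_by_patient(cohort$samples, n_holdout_patients,
                            derive_seed(experiment_seed, "split"))
  stats <- compute_stats(cohort_subset(cohort$samples, split$train_pool_ids))
  al <- run_al(cohort, split, model_spec, train_cfg,
               n_iterations = n_iterations, oracle_config = oracle_config,
               experiment_seed = experiment_seed, stats = stats,
               val_fraction = val_fraction, verbose = verbose)
  rl <- run_rl(cohort, split, model_spec, train_cfg,
               n_iterations = n_iterations, n_batches = n_batches,
               experiment_seed = experiment_seed, stats = stats,
               val_fraction = val_fraction, verbose = verbose)
  compare_strategies(al, rl)
}
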