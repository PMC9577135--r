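test_that("network construction is deterministic and mirrors encoder/decoder widths", {
  spec <- model_spec(n_classes = 11, base_channels = 4, dropout_rate = 0.25)
  m1 <- build_unet(spec, seed = 33)
  m2 <- build_unet(spec, seed = 33)
  expect_identical(m1$params, m2$params)
  m3 <- build_unet(spec, seed = 34)
  expect_false(identical(m1$params, m3$params))

  lay <- m1$layout
  expect_identical(lay$enc_out, c(4L, 8L, 16L, 32L))
  # decoder block k consumes the upsampled deeper map + encoder skip k,
  # which mirror each other in width at every level
  expect_identical(lay$dec_in, 2L * lay$enc_out)
  expect_identical(ncol(m1$params[["head.W"]]), 11L)

  expect_error(model_spec(n_classes = 1), "n_classes")
  expect_error(model_spec(dropout_rate = 1), "dropout_rate")
})

test_that("forward pass honors softmax and shape contracts", {
  spec <- model_spec(n_classes = 11, base_channels = 2, dropout_rate = 0)
  m <- build_unet(spec, seed = 5)
  set.seed(6)
  x <- matrix(rnorm(32 * 32 * 3), 32 * 32, 3)
  fw <- alseg:::unet_forward(m, x, 32, 32)
  expect_identical(dim(fw$probs), c(32L * 32L, 11L))
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-5))

  # encoder/decoder spatial symmetry: the bottleneck of a depth-4 net on a
  # 256-pixel side sits at 256 / 2^4 = 16, and every decoder level matches
  # its mirror encoder level (otherwise concatenation would fail)
  sizes <- 32 / 2^(1:4)
  for (k in 1:4) {
    skip_rows <- nrow(fw$cache[[sprintf("enc%d", k)]]$skip)
    expect_identical(skip_rows, as.integer((32 / 2^(k - 1))^2))
  }

  # repeated inference is bitwise identical (dropout off at inference)
  fw2 <- alseg:::unet_forward(m, x, 32, 32)
  expect_identical(fw$probs, fw2$probs)

  # indivisible input names the required divisor
  expect_error(alseg:::unet_forward(m, matrix(0, 40 * 40, 3), 40, 40),
               "divisible by 16")

  # zeroed final projection -> exactly uniform probabilities, and the argmax
  # tie-break picks the lowest class index
  m$params[["head.W"]][] <- 0
  m$params[["head.b"]][] <- 0
  fw0 <- alseg:::unet_forward(m, x, 32, 32)
  expect_equal(fw0$probs, matrix(1 / 11, 32 * 32, 11), tolerance = 1e-12)
  expect_true(all(alseg:::probs_to_labels(fw0$probs) == 0L))
})

test_that("analytic gradients match central differences through every layer", {
  spec <- model_spec(n_classes = 3, depth = 2, base_channels = 2,
                     dropout_rate = 0)
  m <- build_unet(spec, seed = 7)
  set.seed(42)
  H <- 8; W <- 8
  x <- matrix(rnorm(H * W * 3), H * W, 3)
  y <- sample(c(0:2, 3L), H * W, replace = TRUE)

  fw <- alseg:::unet_forward(m, x, H, W, train = TRUE)
  lg <- alseg:::masked_ce_with_grad(fw$probs, y, 3L)
  g <- alseg:::unet_backward(m, fw, lg$dlogits)

  loss_at <- function(mm) {
    f <- alseg:::unet_forward(mm, x, H, W, train = TRUE)
    alseg:::masked_ce_with_grad(f$probs, y, 3L)$loss
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mn)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training reduces loss on separable data and keeps exact bookkeeping", {
  # two-class blobs distinguishable by color
  lab <- matrix(0L, 32, 32)
  lab[9:24, 9:24] <- 1L
  img <- array(40, c(32, 32, 3))
  img[, , 1][lab == 1L] <- 220
  set.seed(10)
  img <- img + array(rnorm(32 * 32 * 3, 0, 5), c(32, 32, 3))
  s <- roi_sample("blob", "p1", img, lab, 2)
  st <- compute_stats(list(s))
  spec <- model_spec(n_classes = 3, depth = 2, base_channels = 4,
                     dropout_rate = 0)
  m <- build_unet(spec, seed = 2)
  cfg <- train_config(epochs = 20, learning_rate = 1e-3, seed = 4)
  tm <- train_unet(m, list(s), cfg, st, legend)
  expect_identical(nrow(tm$train_history), 20L)
  expect_lt(tail(tm$train_history$train_loss, 1),
            tm$train_history$train_loss[1])
  expect_true(tm$trained)

  # deterministic under the config seed
  tm2 <- train_unet(build_unet(spec, seed = 2), list(s), cfg, st, legend)
  expect_identical(tm$train_history, tm2$train_history)
  expect_equal(tm$params, tm2$params)

  # validation overlap is a configuration error
  expect_error(train_unet(build_unet(spec, seed = 2), list(s), cfg, st,
                          legend, validation_samples = list(s)),
               "overlap")

  # avoid-only map warns (no gradient signal)
  s_avoid <- roi_sample("av", "p1", img,
                        matrix(legend$avoid_index, 32, 32), 2)
  expect_warning(
    train_unet(build_unet(spec, seed = 2), list(s, s_avoid),
               train_config(epochs = 1, learning_rate = 1e-3), st, legend),
    "avoid")

  # prediction: shapes, no avoid index, history with a validation series
  pred <- predict_tissue_map(tm, s, st)
  expect_identical(dim(pred), dim(lab))
  expect_false(any(pred == legend$avoid_index))

  s2 <- roi_sample("blob2", "p2", img + 1, lab, 2)
  tv <- train_unet(build_unet(spec, seed = 2), list(s),
                   train_config(epochs = 3, learning_rate = 1e-3), st, legend,
                   validation_samples = list(s2))
  expect_identical(sum(!is.na(tv$train_history$val_loss)), 3L)
})

test_that("checkpoints round-trip through disk", {
  spec <- model_spec(n_classes = 3, depth = 2, base_channels = 2,
                     dropout_rate = 0)
  m <- build_unet(spec, seed = 9, version_tag = "C2")
  dir <- tempfile()
  save_model(m, dir)
  back <- load_model(dir)
  expect_equal(back$params, m$params)
  expect_identical(back$version_tag, "C2")
  expect_identical(back$spec$base_channels, 2L)
  set.seed(1)
  x <- matrix(rnorm(16 * 16 * 3), 256, 3)
  expect_identical(alseg:::unet_forward(back, x, 16, 16)$probs,
                   alseg:::unet_forward(m, x, 16, 16)$probs)
  unlink(dir, recursive = TRUE)
})
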