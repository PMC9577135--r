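#' Segmentation network specification
#'
#' A compact encoder-decoder (U-net style) fully convolutional network:
#' `depth` down-sampling blocks, each one space-preserving 3x3 convolution,
#' batch normalization and ReLU followed by 2x2 max pooling (dropout applied
#' after each pool during training), mirrored by `depth` up-sampling blocks
#' (nearest-neighbour 2x upsample, then convolution/batch-norm/ReLU) with skip
#' concatenation from the matching encoder block, and a final 1x1 projection
#' to `n_classes` softmax outputs. Encoder channel widths double per level
#' starting from `base_channels`.
#'
#' @param n_classes number of tissue classes (softmax outputs, >= 2).
#' @param depth number of pooling levels (input sides must be divisible by
#'   `2^depth`).
#' @param base_channels width of the first encoder block.
#' @param kernel_size convolution kernel (odd; only 3 is implemented).
#' @param dropout_rate drop probability applied after each max pool during
#'   training (0 disables).
#' @param upsample_mode decoder upsampling (`"nearest"`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(n_classes = 11L, depth = 4L, base_channels = 16L,
                       kernel_size = 3L, dropout_rate = 0.8,
                       upsample_mode = "nearest") {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (kernel_size != 3L) stop("only kernel_size = 3 is implemented")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (depth < 1) stop("depth must be >= 1")
  upsample_mode <- match.arg(upsample_mode, "nearest")
  structure(list(n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 kernel_size = 3L, dropout_rate = dropout_rate,
                 upsample_mode = upsample_mode),
            class = "model_spec")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: 300 epochs, learning rate
#' 1e-4, batch size 1, dropout per the model spec, Adam optimizer. Validation
#' ROIs (held out from gradient updates, used for the per-epoch validation
#' loss) are passed to [train_unet()] separately.
#'
#' @param epochs training epochs (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size only 1 is implemented (the recipe trains sample-wise).
#' @param seed RNG seed for sample order and dropout masks.
#' @param optimizer_name recorded for audit; only `"adam"` is implemented.
#' @param standardize_mode passed to [standardize()].
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, learning_rate = 1e-4, batch_size = 1L,
                         seed = 1L, optimizer_name = "adam",
                         standardize_mode = "standardize") {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size != 1L) stop("only batch_size = 1 is implemented")
  if (optimizer_name != "adam") stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = 1L, seed = as.integer(seed),
                 optimizer_name = optimizer_name,
                 standardize_mode = standardize_mode),
            class = "train_config")
}

# Channel plan: encoder widths double per level; decoder block k consumes the
# upsampled deeper map concatenated with encoder block k's pre-pool output.
unet_layout <- function(spec) {
  d <- spec$depth
  enc_out <- as.integer(spec$base_channels * 2^(seq_len(d) - 1L))
  enc_in <- c(3L, enc_out[-d])
  dec_out <- as.integer(c(enc_out[1], enc_out[-d]))
  dec_in <- integer(d)
  below <- enc_out[d]  # bottleneck = pooled deepest encoder map
  for (k in rev(seq_len(d))) {
    dec_in[k] <- below + enc_out[k]
    below <- dec_out[k]
  }
  list(enc_in = enc_in, enc_out = enc_out, dec_in = dec_in, dec_out = dec_out)
}

#' Build an (untrained) segmentation network
#'
#' Allocates parameters with He-normal initialization for convolutions, unit
#' batch-norm scale and zero shift. Initialization is deterministic under the
#' seed: two builds with the same spec and seed have identical parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer initialization seed.
#' @param version_tag classifier version label (e.g. `"C0"`).
#' @return object of class `unet_model` (untrained).
#' @export
build_unet <- function(spec, seed = 1L, version_tag = "C0") {
  lay <- unet_layout(spec)
  params <- list(); bn <- list()
  init_conv <- function(cin_cols, cout) {
    list(W = matrix(rnorm(cin_cols * cout, sd = sqrt(2 / cin_cols)),
                    cin_cols, cout),
         b = numeric(cout))
  }
  with_seed(seed, {
    for (k in seq_len(spec$depth)) {
      nm <- sprintf("enc%d", k)
      cv <- init_conv(9L * lay$enc_in[k], lay$enc_out[k])
      params[[paste0(nm, ".W")]] <- cv$W
      params[[paste0(nm, ".b")]] <- cv$b
      params[[paste0(nm, ".gamma")]] <- rep(1, lay$enc_out[k])
      params[[paste0(nm, ".beta")]] <- rep(0, lay$enc_out[k])
      bn[[nm]] <- list(rmean = rep(0, lay$enc_out[k]),
                       rvar = rep(1, lay$enc_out[k]))
    }
    for (k in seq_len(spec$depth)) {
      nm <- sprintf("dec%d", k)
      cv <- init_conv(9L * lay$dec_in[k], lay$dec_out[k])
      params[[paste0(nm, ".W")]] <- cv$W
      params[[paste0(nm, ".b")]] <- cv$b
      params[[paste0(nm, ".gamma")]] <- rep(1, lay$dec_out[k])
      params[[paste0(nm, ".beta")]] <- rep(0, lay$dec_out[k])
      bn[[nm]] <- list(rmean = rep(0, lay$dec_out[k]),
                       rvar = rep(1, lay$dec_out[k]))
    }
    cv <- init_conv(lay$dec_out[1], spec$n_classes)
    params[["head.W"]] <- cv$W
    params[["head.b"]] <- cv$b
  })
  structure(list(spec = spec, layout = lay, params = params, bn = bn,
                 seed = as.integer(seed), version_tag = version_tag,
                 trained = FALSE, train_history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<unet_model> %s: depth %d, base %d, %d classes, %s (%d parameters)\n",
              x$version_tag, x$spec$depth, x$spec$base_channels,
              x$spec$n_classes, if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Batch statistics (train) or frozen running statistics (eval) for one
# batch-norm layer; with batch size 1 the batch statistics are per-channel
# spatial moments. Running stats use exponential-average momentum 0.1.
bn_stats <- function(a, state, train) {
  if (train) {
    mu <- colMeans(a)
    v <- pmax(colMeans(a * a) - mu^2, 0)
    state$rmean <- (1 - bn_momentum) * state$rmean + bn_momentum * mu
    state$rvar <- (1 - bn_momentum) * state$rvar + bn_momentum * v
  } else {
    mu <- state$rmean
    v <- state$rvar
  }
  list(mu = mu, invstd = 1 / sqrt(v + bn_eps), state = state)
}

softmax_rows <- function(logits) softmax_rows_cpp(logits)

# Full forward pass. x is an (H*W) x 3 standardized matrix (column-major
# spatial flattening). In train mode, returns the caches the backward pass
# needs and updated batch-norm running stats; dropout masks are drawn from
# the current RNG stream.
unet_forward <- function(model, x, H, W, train = FALSE) {
  spec <- model$spec; p <- model$params
  div <- 2^spec$depth
  if (H %% div != 0 || W %% div != 0)
    stop(sprintf("input spatial size %dx%d must be divisible by %d", H, W, div))
  cache <- list(H = H, W = W)
  bn_new <- model$bn
  keep <- 1 - spec$dropout_rate
  h <- H; w <- W
  for (k in seq_len(spec$depth)) {
    nm <- sprintf("enc%d", k)
    if (train) {
      G <- conv3_im2col(x, h, w)
      a <- mm_bias(G, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
    } else {
      a <- conv3_forward(x, h, w, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
    }
    st <- bn_stats(a, bn_new[[nm]], train)
    bn_new[[nm]] <- st$state
    br <- bn_relu_forward(a, st$mu, st$invstd, p[[paste0(nm, ".gamma")]],
                          p[[paste0(nm, ".beta")]])
    pl <- maxpool2_forward(br$act, h, w)
    out <- pl$y
    drop_mask <- NULL
    if (train && spec$dropout_rate > 0) {
      drop_mask <- matrix(runif(length(out)) >= spec$dropout_rate,
                          nrow(out), ncol(out))
      out <- out * drop_mask / keep
    }
    if (train)
      cache[[nm]] <- list(G = G, h = h, w = w, xhat = br$xhat,
                          invstd = st$invstd, act = br$act,
                          pool_idx = pl$idx, drop = drop_mask,
                          skip = br$act)
    else cache[[nm]] <- list(skip = br$act, h = h, w = w)
    x <- out
    h <- h %/% 2L; w <- w %/% 2L
  }
  for (k in rev(seq_len(spec$depth))) {
    nm <- sprintf("dec%d", k)
    u <- upsample2_forward(x, h, w)
    h <- h * 2L; w <- w * 2L
    z <- cbind(u, cache[[sprintf("enc%d", k)]]$skip)
    if (train) {
      G <- conv3_im2col(z, h, w)
      a <- mm_bias(G, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
    } else {
      a <- conv3_forward(z, h, w, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
    }
    st <- bn_stats(a, bn_new[[nm]], train)
    bn_new[[nm]] <- st$state
    br <- bn_relu_forward(a, st$mu, st$invstd, p[[paste0(nm, ".gamma")]],
                          p[[paste0(nm, ".beta")]])
    if (train)
      cache[[nm]] <- list(G = G, h = h, w = w, xhat = br$xhat,
                          invstd = st$invstd, act = br$act,
                          n_up = ncol(u))
    x <- br$act
  }
  logits <- conv1_forward(x, p[["head.W"]], p[["head.b"]])
  probs <- softmax_rows(logits)
  if (train) cache$head_in <- x
  list(probs = probs, cache = cache, bn = bn_new)
}

# Backward pass from dlogits; returns gradients named like the parameters.
# Reuses the im2col matrices cached by the forward pass.
unet_backward <- function(model, fw, dlogits) {
  spec <- model$spec; p <- model$params; cache <- fw$cache
  lay <- model$layout
  g <- list()
  g[["head.W"]] <- crossprod(cache$head_in, dlogits)
  g[["head.b"]] <- colSums(dlogits)
  d <- dlogits %*% t(p[["head.W"]])
  conv_bwd <- function(nm, cc, dx, c_in) {
    g[[paste0(nm, ".W")]] <<- crossprod(cc$G, dx)
    g[[paste0(nm, ".b")]] <<- colSums(dx)
    conv3_col2im(dx %*% t(p[[paste0(nm, ".W")]]), cc$h, cc$w, c_in)
  }
  skip_grads <- list()
  for (k in seq_len(spec$depth)) {
    nm <- sprintf("dec%d", k)
    cc <- cache[[nm]]
    bnb <- bn_relu_backward(d, cc$act, cc$xhat, p[[paste0(nm, ".gamma")]],
                            cc$invstd)
    g[[paste0(nm, ".gamma")]] <- as.numeric(bnb$dgamma)
    g[[paste0(nm, ".beta")]] <- as.numeric(bnb$dbeta)
    dz <- conv_bwd(nm, cc, bnb$dx, lay$dec_in[k])
    skip_grads[[k]] <- dz[, (cc$n_up + 1L):ncol(dz), drop = FALSE]
    d <- upsample2_backward(dz[, seq_len(cc$n_up), drop = FALSE], cc$h, cc$w)
  }
  keep <- 1 - spec$dropout_rate
  for (k in rev(seq_len(spec$depth))) {
    nm <- sprintf("enc%d", k)
    cc <- cache[[nm]]
    if (!is.null(cc$drop)) d <- d * cc$drop / keep
    d <- maxpool2_backward(cc$pool_idx, d, cc$h * cc$w)
    d <- d + skip_grads[[k]]
    bnb <- bn_relu_backward(d, cc$act, cc$xhat, p[[paste0(nm, ".gamma")]],
                            cc$invstd)
    g[[paste0(nm, ".gamma")]] <- as.numeric(bnb$dgamma)
    g[[paste0(nm, ".beta")]] <- as.numeric(bnb$dbeta)
    d <- conv_bwd(nm, cc, bnb$dx, lay$enc_in[k])
  }
  g
}

# Masked cross-entropy value and logit gradient in one pass.
masked_ce_with_grad <- function(probs, y, avoid_index) {
  keep <- y != avoid_index
  n <- sum(keep)
  if (n == 0) return(NULL)
  rows <- which(keep)
  pt <- pmax(probs[cbind(rows, y[rows] + 1L)], 1e-12)
  dlogits <- probs
  dlogits[!keep, ] <- 0
  dlogits[cbind(rows, y[rows] + 1L)] <-
    dlogits[cbind(rows, y[rows] + 1L)] - 1
  list(loss = -mean(log(pt)), dlogits = dlogits / n)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat * gmat
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

sample_to_matrix <- function(sample, stats, mode = "standardize") {
  xs <- standardize(sample$image, stats, mode = mode)
  matrix(xs, ncol = 3)
}

#' Train the segmentation network
#'
#' Minimizes masked categorical cross-entropy (avoid pixels contribute
#' nothing) with Adam at batch size 1, recording per-epoch training loss and,
#' when validation ROIs are supplied, per-epoch validation loss (evaluation
#' mode: dropout off, frozen batch-norm running statistics). Training starts
#' from the model's current (freshly initialized) parameters; the sample
#' order and dropout masks are reproducible under `config$seed`.
#'
#' @param model an untrained [build_unet()] model.
#' @param train_samples non-empty list of `roi_sample` used for gradient
#'   updates.
#' @param config a [train_config()].
#' @param stats frozen training-pool [compute_stats()].
#' @param legend the `class_legend` (defines the avoid index).
#' @param validation_samples list of `roi_sample` held out from gradient
#'   updates (must not overlap `train_samples`).
#' @return the trained `unet_model`, with `train_history` (data.frame with
#'   `epoch`, `train_loss`, `val_loss`) of exactly `config$epochs` rows.
#' @export
train_unet <- function(model, train_samples, config, stats, legend,
                       validation_samples = list()) {
  if (length(train_samples) == 0) stop("train_samples is empty")
  tr_ids <- vapply(train_samples, function(s) s$roi_id, character(1))
  va_ids <- vapply(validation_samples, function(s) s$roi_id, character(1))
  if (length(intersect(tr_ids, va_ids)) > 0)
    stop("validation ROIs overlap the gradient training set: ",
         paste(intersect(tr_ids, va_ids), collapse = ", "))
  avoid <- legend$avoid_index
  xs <- lapply(train_samples, sample_to_matrix, stats = stats,
               mode = config$standardize_mode)
  ys <- lapply(train_samples, function(s) as.integer(s$labels))
  if (any(vapply(ys, function(y) all(y == avoid), logical(1))))
    warning("a training label map is entirely avoid-class; it contributes no gradient")
  vx <- lapply(validation_samples, sample_to_matrix, stats = stats,
               mode = config$standardize_mode)
  vy <- lapply(validation_samples, function(s) as.integer(s$labels))
  dims <- lapply(train_samples, function(s) dim(s$labels))
  vdims <- lapply(validation_samples, function(s) dim(s$labels))
  opt <- adam_init(model$params)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = NA_real_, val_loss = NA_real_)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      order_ep <- sample.int(length(xs))
      losses <- numeric(0)
      for (i in order_ep) {
        fw <- unet_forward(model, xs[[i]], dims[[i]][1], dims[[i]][2],
                           train = TRUE)
        model$bn <- fw$bn
        lg <- masked_ce_with_grad(fw$probs, ys[[i]], avoid)
        if (is.null(lg)) next
        losses <- c(losses, lg$loss)
        grads <- unet_backward(model, fw, lg$dlogits)
        st <- adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- st$params
        opt <- st$state
      }
      history$train_loss[ep] <- mean(losses)
      if (length(vx) > 0) {
        vnum <- 0; vden <- 0
        for (j in seq_along(vx)) {
          fw <- unet_forward(model, vx[[j]], vdims[[j]][1], vdims[[j]][2],
                             train = FALSE)
          yv <- vy[[j]]; kp <- yv != avoid
          if (!any(kp)) next
          pt <- pmax(fw$probs[cbind(which(kp), yv[kp] + 1L)], 1e-12)
          vnum <- vnum + sum(-log(pt)); vden <- vden + sum(kp)
        }
        history$val_loss[ep] <- if (vden > 0) vnum / vden else NA_real_
      }
    }
  })
  model$train_history <- history
  model$trained <- TRUE
  model
}

#' Per-pixel class probabilities for an ROI
#'
#' Standardizes the image with the frozen training-pool stats and runs the
#' network in evaluation mode (dropout disabled, running batch-norm
#' statistics), so repeated calls are bitwise identical.
#'
#' @param model a `unet_model`, or a function `(sample, stats) ->` probability
#'   matrix (useful as a reference predictor in evaluations).
#' @param sample an `roi_sample`.
#' @param stats frozen [compute_stats()].
#' @param mode passed to [standardize()].
#' @return matrix `(H*W)` x `n_classes`; rows sum to 1.
#' @export
predict_probs <- function(model, sample, stats, mode = "standardize") {
  if (is.function(model)) return(model(sample, stats))
  x <- sample_to_matrix(sample, stats, mode = mode)
  unet_forward(model, x, nrow(sample$labels), ncol(sample$labels),
               train = FALSE)$probs
}

probs_to_labels <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}

#' Predict a tissue map
#'
#' Argmax over per-pixel class probabilities (ties broken toward the lowest
#' class index). The output contains tissue class indices only, never the
#' avoid index: the network has no "unlabeled" output.
#'
#' @inheritParams predict_probs
#' @return integer matrix H x W of 0-based tissue class indices.
#' @export
predict_tissue_map <- function(model, sample, stats, mode = "standardize") {
  probs <- predict_probs(model, sample, stats, mode = mode)
  matrix(probs_to_labels(probs), nrow = nrow(sample$labels))
}

#' Save / load a model checkpoint
#'
#' Writes the parameter set (RDS), a JSON sidecar (spec, version tag, seed)
#' and the training history as CSV.
#'
#' @param model a `unet_model`.
#' @param dir checkpoint directory.
#' @return `load_model` returns the `unet_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model[c("params", "bn")], file.path(dir, "params.rds"))
  jsonlite::write_json(
    list(spec = unclass(model$spec), version_tag = model$version_tag,
         seed = model$seed, trained = model$trained),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model$train_history))
    write.csv(model$train_history, file.path(dir, "history.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  spec <- do.call(model_spec, meta$spec[c("n_classes", "depth",
                                          "base_channels", "kernel_size",
                                          "dropout_rate", "upsample_mode")])
  model <- build_unet(spec, seed = meta$seed, version_tag = meta$version_tag)
  pk <- readRDS(file.path(dir, "params.rds"))
  model$params <- pk$params
  model$bn <- pk$bn
  model$trained <- meta$trained
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path))
    model$train_history <- utils::read.csv(hist_path)
  model
}
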