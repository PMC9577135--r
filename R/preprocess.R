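#' Resample an ROI to a target physical resolution
#'
#' Rescales both image and label map so the output has `target_mpp` microns
#' per pixel, preserving aspect ratio. The image is resampled bilinearly;
#' labels use nearest-neighbour so no new class index can appear.
#'
#' @param sample an [roi_sample()].
#' @param target_mpp target resolution in microns per pixel (> 0).
#' @return a resampled `roi_sample` with `microns_per_pixel = target_mpp`.
#' @export
resize_to_mpp <- function(sample, target_mpp) {
  if (target_mpp <= 0) stop("target_mpp must be positive")
  scale <- sample$microns_per_pixel / target_mpp
  if (abs(scale - 1) < 1e-12) {
    sample$microns_per_pixel <- target_mpp
    return(sample)
  }
  h <- max(1L, as.integer(round(nrow(sample$labels) * scale)))
  w <- max(1L, as.integer(round(ncol(sample$labels) * scale)))
  sample$image <- resize_bilinear(sample$image, h, w)
  sample$labels <- resize_nearest(sample$labels, h, w)
  sample$microns_per_pixel <- target_mpp
  sample
}

# Nearest-neighbour index map: output pixel centers projected into the source.
nearest_index <- function(n_out, n_in) {
  pmin(pmax(ceiling((seq_len(n_out) - 0.5) * n_in / n_out), 1L), n_in)
}

resize_nearest <- function(m, h, w) {
  m[nearest_index(h, nrow(m)), nearest_index(w, ncol(m)), drop = FALSE]
}

resize_bilinear <- function(img, h, w) {
  d <- dim(img)
  # source coordinates of output pixel centers (center-aligned sampling)
  coord <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    lo <- pmin(pmax(floor(x), 1), n_in)
    hi <- pmin(lo + 1, n_in)
    list(lo = lo, hi = hi, t = pmin(pmax(x - lo, 0), 1))
  }
  rc <- coord(h, d[1]); cc <- coord(w, d[2])
  wc <- matrix(cc$t, h, w, byrow = TRUE)   # column-fraction weights
  wr <- matrix(rc$t, h, w)                 # row-fraction weights
  out <- array(0, dim = c(h, w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    top <- m[rc$lo, cc$lo, drop = FALSE] * (1 - wc) +
           m[rc$lo, cc$hi, drop = FALSE] * wc
    bot <- m[rc$hi, cc$lo, drop = FALSE] * (1 - wc) +
           m[rc$hi, cc$hi, drop = FALSE] * wc
    out[, , ch] <- top * (1 - wr) + bot * wr
  }
  out
}

#' Crop (or pad) an ROI to fixed pixel dimensions
#'
#' Takes the centered `height` x `width` window. When the input is smaller
#' along a dimension, `pad_policy = "pad"` pads symmetrically (extra pixel on
#' the bottom/right when odd): labels with the avoid index, image with the
#' dataset mean color (or this image's own mean when no stats are given);
#' `pad_policy = "reject"` raises an error instead.
#'
#' @param sample an [roi_sample()].
#' @param height,width output dimensions (> 0).
#' @param pad_policy `"reject"` (default) or `"pad"`.
#' @param avoid_index label index used for padded pixels.
#' @param stats optional [compute_stats()] result supplying the pad color.
#' @return a `roi_sample` of exactly `height` x `width`.
#' @export
center_crop <- function(sample, height, width, pad_policy = c("reject", "pad"),
                        avoid_index = NULL, stats = NULL) {
  pad_policy <- match.arg(pad_policy)
  if (height <= 0 || width <= 0) stop("crop dimensions must be positive")
  h <- nrow(sample$labels); w <- ncol(sample$labels)
  if ((h < height || w < width)) {
    if (pad_policy == "reject")
      stop(sprintf("input %dx%d smaller than crop %dx%d", h, w, height, width))
    if (is.null(avoid_index)) stop("padding requires avoid_index")
    pad_color <- if (!is.null(stats)) stats$mean
                 else apply(sample$image, 3, mean)
    H <- max(h, height); W <- max(w, width)
    img <- array(rep(pad_color, each = H * W), dim = c(H, W, 3))
    lab <- matrix(as.integer(avoid_index), H, W)
    top <- floor((H - h) / 2); left <- floor((W - w) / 2)
    img[top + seq_len(h), left + seq_len(w), ] <- sample$image
    lab[top + seq_len(h), left + seq_len(w)] <- sample$labels
    sample$image <- img; sample$labels <- lab
    h <- H; w <- W
  }
  r0 <- floor((h - height) / 2)
  c0 <- floor((w - width) / 2)
  sample$image <- sample$image[r0 + seq_len(height), c0 + seq_len(width), ,
                               drop = FALSE]
  sample$labels <- sample$labels[r0 + seq_len(height), c0 + seq_len(width),
                                 drop = FALSE]
  sample
}

#' Per-channel intensity statistics of a training pool
#'
#' Pools every pixel of every training image and returns the per-channel mean
#' and standard deviation, the quantities [standardize()] removes. Stats must
#' be computed on the training pool only and frozen for validation and holdout
#' images, so no information leaks across the split. The accumulation is by
#' exact sums, hence independent of sample order.
#'
#' @param train_samples non-empty list of `roi_sample`.
#' @param eps lower clamp for the standard deviation (degenerate constant
#'   inputs otherwise divide by zero).
#' @return object of class `dataset_stats`: `mean` (3), `sd` (3, clamped),
#'   `computed_over` (roi_ids).
#' @export
compute_stats <- function(train_samples, eps = 1e-6) {
  if (length(train_samples) == 0) stop("compute_stats needs a non-empty list")
  s1 <- s2 <- c(0, 0, 0); n <- 0
  for (s in train_samples) {
    m <- matrix(s$image, ncol = 3)
    s1 <- s1 + colSums(m)
    s2 <- s2 + colSums(m^2)
    n <- n + nrow(m)
  }
  mu <- s1 / n
  sdv <- sqrt(pmax(s2 / n - mu^2, 0))
  structure(list(mean = mu, sd = pmax(sdv, eps),
                 computed_over = vapply(train_samples, function(s) s$roi_id,
                                        character(1))),
            class = "dataset_stats")
}

#' Standardize an image to dataset statistics
#'
#' Subtracts the per-channel training-pool mean and (in the default mode)
#' divides by the per-channel standard deviation. `mode = "center"` subtracts
#' the mean only.
#'
#' @param image numeric array H x W x 3.
#' @param stats a [compute_stats()] result.
#' @param mode `"standardize"` (default) or `"center"`.
#' @return numeric array of the same shape.
#' @export
standardize <- function(image, stats, mode = c("standardize", "center")) {
  mode <- match.arg(mode)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- image[, , ch] - stats$mean[ch]
    if (mode == "standardize") out[, , ch] <- out[, , ch] / stats$sd[ch]
  }
  out
}

#' @rdname standardize
#' @export
unstandardize <- function(image, stats, mode = c("standardize", "center")) {
  mode <- match.arg(mode)
  out <- image
  for (ch in 1:3) {
    if (mode == "standardize") out[, , ch] <- image[, , ch] * stats$sd[ch]
    out[, , ch] <- out[, , ch] + stats$mean[ch]
  }
  out
}

#' Serialize / read dataset statistics as JSON
#' @param stats a `dataset_stats`.
#' @param path file path.
#' @export
write_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, sd = stats$sd,
                            computed_over = stats$computed_over),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = j$mean, sd = j$sd, computed_over = j$computed_over),
            class = "dataset_stats")
}
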