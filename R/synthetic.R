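#' Configuration for a synthetic ROI cohort
#'
#' The generator emulates the statistical structure of an annotated oral
#' cavity carcinoma ROI dataset: stroma-dominant label maps with tumor nests
#' (optionally keratinized cores), lymphocyte infiltrates bordering tumor,
#' rare classes (mucosa, blood, nerves, necrosis, muscle, junk) present in
#' only a subset of ROIs, a background/adipose margin, an unlabeled avoid
#' band along annotation boundaries, patient grouping with a shared per-patient
#' color shift, and H&E-like class colors corrupted by spatially correlated
#' noise whose amplitude grows with `hardness`.
#'
#' @param n_patients number of patients.
#' @param rois_per_patient ROIs per patient (integer, or vector recycled over
#'   patients).
#' @param image_size square ROI side in pixels (must suit the paired model's
#'   `2^depth` divisibility).
#' @param mpp microns per pixel of the rendered ROI.
#' @param class_prevalence named target area fractions (see
#'   [default_prevalence()]); stroma absorbs the remainder.
#' @param presence_prob named per-ROI presence probability for occasional
#'   classes; prevalence targets are conditional on presence scaled so the
#'   cohort-level expectation matches the target.
#' @param avoid_fraction fraction of labeled pixels re-masked to avoid by
#'   eroding annotation borders.
#' @param hardness in `[0, 1]`: scales the correlated noise that makes class
#'   appearance ambiguous (0 = nearly clean colors).
#' @param seed generator seed; the cohort is bit-reproducible under it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 23L, rois_per_patient = 1L,
                          image_size = 128L, mpp = 2,
                          class_prevalence = default_prevalence(),
                          presence_prob = default_presence(),
                          avoid_fraction = 0.1, hardness = 0.5,
                          seed = 1L) {
  if (image_size < 32) stop("image_size must be at least 32")
  if (avoid_fraction < 0 || avoid_fraction >= 1)
    stop("avoid_fraction must be in [0, 1)")
  if (hardness < 0 || hardness > 1) stop("hardness must be in [0, 1]")
  if (sum(class_prevalence) > 1)
    stop("class prevalences must sum to at most 1 (stroma takes the rest)")
  structure(list(n_patients = as.integer(n_patients),
                 rois_per_patient = rois_per_patient,
                 image_size = as.integer(image_size), mpp = mpp,
                 class_prevalence = class_prevalence,
                 presence_prob = presence_prob,
                 avoid_fraction = avoid_fraction, hardness = hardness,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default class area fractions
#'
#' Skewed prevalences mirroring the qualitative rarity pattern of annotated
#' head-and-neck resections: tumor, stroma and lymphocytes dominate; mucosa,
#' blood, nerves, necrosis, muscle and junk are rare. Stroma is the
#' background class and absorbs whatever the listed classes do not claim.
#'
#' @return named numeric vector of target fractions (stroma excluded).
#' @export
default_prevalence <- function() {
  c("Tumor" = 0.22, "Lymphocytes" = 0.10, "Background/Adipose" = 0.06,
    "Keratin Pearl" = 0.02, "Mucosa" = 0.015, "Blood" = 0.01,
    "Nerves" = 0.008, "Necrosis" = 0.015, "Muscle" = 0.01, "Junk" = 0.008)
}

#' @rdname default_prevalence
#' @export
default_presence <- function() {
  c("Tumor" = 1, "Lymphocytes" = 1, "Background/Adipose" = 0.7,
    "Keratin Pearl" = 0.5, "Mucosa" = 0.4, "Blood" = 0.45, "Nerves" = 0.4,
    "Necrosis" = 0.45, "Muscle" = 0.4, "Junk" = 0.4)
}

# H&E-like mean RGB per class (0..255). Chosen for visual plausibility and
# learnability: pink stroma, purple tumor, dark lymphocytes, near-white
# background.
class_colors_hne <- function() {
  rbind("Stroma" = c(231, 161, 180), "Tumor" = c(130, 90, 165),
        "Lymphocytes" = c(88, 62, 130), "Mucosa" = c(205, 145, 205),
        "Background/Adipose" = c(246, 246, 246), "Blood" = c(190, 45, 55),
        "Nerves" = c(225, 175, 140), "Necrosis" = c(205, 175, 160),
        "Keratin Pearl" = c(240, 135, 160), "Muscle" = c(200, 105, 120),
        "Junk" = c(120, 120, 120))
}

#' Cohort preset mirroring the reference study's shape
#'
#' 23 patients with one ROI each except one patient contributing two (24 ROIs
#' total), 11 tissue classes plus avoid, prevalence skewed so several rare
#' classes are missing from any given ROI. The full-scale variant renders
#' 2048-pixel ROIs at 2 microns per pixel; [desk_preset()] is the identical
#' cohort at 128 pixels for CPU-scale runs.
#'
#' @param image_size ROI side in pixels.
#' @param seed generator seed.
#' @return a [cohort_config()].
#' @export
paper_like_preset <- function(image_size = 2048L, seed = 1L) {
  cohort_config(n_patients = 23L,
                rois_per_patient = c(2L, rep(1L, 22L)),
                image_size = image_size, mpp = 2, seed = seed)
}

#' @rdname paper_like_preset
#' @export
desk_preset <- function(seed = 1L) paper_like_preset(image_size = 128L,
                                                     seed = seed)

# Paint an irregular blob (union of 2-3 jittered ellipses) of roughly
# target_area pixels centered at (cy, cx); returns the logical mask.
blob_mask <- function(n, cy, cx, target_area, elong = 1) {
  r0 <- sqrt(target_area / pi)
  xs <- matrix(rep(seq_len(n), each = n), n, n)  # column index
  ys <- matrix(rep(seq_len(n), n), n, n)         # row index
  mask <- matrix(FALSE, n, n)
  n_ell <- sample(2:3, 1)
  for (j in seq_len(n_ell)) {
    ry <- r0 * runif(1, 0.6, 1.1) * elong
    rx <- r0 * runif(1, 0.6, 1.1) / elong
    oy <- cy + rnorm(1, 0, r0 * 0.35)
    ox <- cx + rnorm(1, 0, r0 * 0.35)
    mask <- mask | (((ys - oy) / ry)^2 + ((xs - ox) / rx)^2 <= 1)
  }
  mask
}

# 4-neighbour binary dilation.
dilate4 <- function(mask, iter = 1L) {
  n <- nrow(mask); m <- ncol(mask)
  for (i in seq_len(iter)) {
    up <- rbind(mask[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, mask[-n, , drop = FALSE])
    lf <- cbind(mask[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, mask[, -m, drop = FALSE])
    mask <- mask | up | dn | lf | rt
  }
  mask
}

# TRUE where a pixel touches (4-neighbourhood) a different label.
boundary_mask <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  b <- matrix(FALSE, n, m)
  b[-n, ] <- b[-n, ] | (lab[-n, ] != lab[-1, ])
  b[-1, ] <- b[-1, ] | (lab[-1, ] != lab[-n, ])
  b[, -m] <- b[, -m] | (lab[, -m] != lab[, -1])
  b[, -1] <- b[, -1] | (lab[, -1] != lab[, -m])
  b
}

# Paint blobs of class `cls` over pixels where `allowed` is TRUE until the
# class covers ~target_frac of the image.
paint_class <- function(lab, cls, target_frac, allowed, n, elong = 1,
                        near = NULL) {
  target_px <- round(target_frac * n * n)
  guard <- 0L
  while (sum(lab == cls) < target_px && guard < 80L) {
    guard <- guard + 1L
    deficit <- target_px - sum(lab == cls)
    area <- min(deficit * runif(1, 0.8, 1.4), (n * n) * 0.08)
    if (!is.null(near) && any(near)) {
      pick <- which(near)[sample.int(sum(near), 1)]
      cy <- (pick - 1) %% n + 1; cx <- (pick - 1) %/% n + 1
    } else {
      cy <- runif(1, n * 0.1, n * 0.9); cx <- runif(1, n * 0.1, n * 0.9)
    }
    m <- blob_mask(n, cy, cx, area, elong = elong) & allowed
    lab[m] <- cls
  }
  lab
}

# Generate one label map; `targets` are this ROI's area fractions (0 for
# classes absent from this ROI).
generate_label_map <- function(n, targets, legend) {
  idx <- function(nm) legend$index[match(nm, legend$name)]
  lab <- matrix(idx("Stroma"), n, n)
  free <- function() lab == idx("Stroma")
  # background/adipose margin along one edge
  if (targets[["Background/Adipose"]] > 0) {
    side <- sample(1:4, 1)
    width <- max(2L, round(targets[["Background/Adipose"]] * n /
                             runif(1, 0.8, 1.2)))
    wobble <- round(cumsum(rnorm(n, 0, 0.6)))
    w_at <- pmin(pmax(width + wobble - mean(wobble), 1L), n %/% 2L)
    for (i in seq_len(n)) {
      k <- w_at[i]
      if (side == 1) lab[i, seq_len(k)] <- idx("Background/Adipose")
      if (side == 2) lab[i, n - seq_len(k) + 1] <- idx("Background/Adipose")
      if (side == 3) lab[seq_len(k), i] <- idx("Background/Adipose")
      if (side == 4) lab[n - seq_len(k) + 1, i] <- idx("Background/Adipose")
    }
    # mucosa lines the margin when present
    if (targets[["Mucosa"]] > 0) {
      band <- dilate4(lab == idx("Background/Adipose"),
                      iter = max(1L, round(targets[["Mucosa"]] * n)))
      lab[band & free()] <- idx("Mucosa")
    }
  } else if (targets[["Mucosa"]] > 0) {
    lab <- paint_class(lab, idx("Mucosa"), targets[["Mucosa"]], free(), n,
                       elong = 2.5)
  }
  for (nm in c("Muscle", "Nerves")) {
    if (targets[[nm]] > 0)
      lab <- paint_class(lab, idx(nm), targets[[nm]], free(), n, elong = 2)
  }
  # tumor nests; keratin cores and necrosis carve into painted tumor, so
  # overshoot tumor by their share to keep the net tumor fraction on target
  tum_extra <- targets[["Keratin Pearl"]] + targets[["Necrosis"]]
  if (targets[["Tumor"]] > 0)
    lab <- paint_class(lab, idx("Tumor"), targets[["Tumor"]] + tum_extra,
                       free() | lab == idx("Mucosa"), n)
  tumor_now <- lab == idx("Tumor")
  if (targets[["Keratin Pearl"]] > 0 && any(tumor_now)) {
    inner <- tumor_now & !boundary_mask(lab)
    lab <- paint_class(lab, idx("Keratin Pearl"), targets[["Keratin Pearl"]],
                       tumor_now, n, near = inner)
  }
  if (targets[["Necrosis"]] > 0 && any(lab == idx("Tumor")))
    lab <- paint_class(lab, idx("Necrosis"), targets[["Necrosis"]],
                       lab == idx("Tumor"), n, near = lab == idx("Tumor"))
  # lymphocyte infiltrates hug the tumor border, spilling into stroma
  if (targets[["Lymphocytes"]] > 0) {
    rim <- dilate4(lab == idx("Tumor"), iter = 2L) & free()
    lab[rim & matrix(runif(n * n) < 0.85, n, n)] <- idx("Lymphocytes")
    lab <- paint_class(lab, idx("Lymphocytes"), targets[["Lymphocytes"]],
                       free(), n,
                       near = dilate4(lab == idx("Lymphocytes"), 1L) & free())
  }
  for (nm in c("Blood", "Junk")) {
    if (targets[[nm]] > 0)
      lab <- paint_class(lab, idx(nm), targets[[nm]], free(), n)
  }
  lab
}

# Re-mask ~avoid_fraction of labeled pixels to avoid by eroding annotation
# borders (annotators label only confident interiors), topping up with random
# specks if borders alone fall short.
apply_avoid <- function(lab, avoid_index, avoid_fraction) {
  if (avoid_fraction <= 0) return(lab)
  n_total <- length(lab)
  target <- round(avoid_fraction * n_total)
  av <- boundary_mask(lab)
  it <- 0L
  while (sum(av) < target && it < 6L) {
    av <- dilate4(av, 1L)
    it <- it + 1L
  }
  if (sum(av) > target) {
    drop <- sample(which(av), sum(av) - target)
    av[drop] <- FALSE
  } else if (sum(av) < target) {
    extra <- sample(which(!av), target - sum(av))
    av[extra] <- TRUE
  }
  lab[av] <- avoid_index
  lab
}

# Smooth noise field: white noise blurred with a separable box kernel.
correlated_noise <- function(n, sd_target, passes = 2L) {
  z <- matrix(rnorm(n * n), n, n)
  for (i in seq_len(passes)) {
    z <- (rbind(z[1, ], z[-n, ]) + z + rbind(z[-1, ], z[n, ])) / 3
    z <- (cbind(z[, 1], z[, -n]) + z + cbind(z[, -1], z[, n])) / 3
  }
  z * (sd_target / stats::sd(as.vector(z)))
}

render_image <- function(lab, legend, hardness, patient_shift) {
  n <- nrow(lab)
  pal <- class_colors_hne()
  pal <- pal[match(legend$name, rownames(pal)), , drop = FALSE]
  img <- array(0, dim = c(n, n, 3))
  noise_sd <- 4 + 26 * hardness
  lymph <- legend$index[match("Lymphocytes", legend$name)]
  dots <- matrix(runif(n * n) < 0.3, n, n) & (lab == lymph)
  for (ch in 1:3) {
    base <- matrix(pal[lab + 1L, ch], n, n)
    base[dots] <- base[dots] - 45
    img[, , ch] <- base + patient_shift[ch] +
      correlated_noise(n, noise_sd) + rnorm(n * n, 0, noise_sd / 3)
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a synthetic ROI cohort
#'
#' Builds label maps from a layered blob grammar (see [cohort_config()]),
#' renders H&E-like images, erodes annotation borders into the avoid class,
#' and groups ROIs by patient with a shared per-patient color shift. Fully
#' deterministic under `config$seed`. Per-ROI class targets are jittered and
#' occasional classes appear in only some ROIs, so ROIs genuinely differ in
#' informativeness.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory: when given, the cohort is also written
#'   via [write_cohort()].
#' @return list with `samples` (list of [roi_sample()]), `legend`, and
#'   `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  legend <- tissue_legend()
  n <- config$image_size
  rpp <- rep_len(config$rois_per_patient, config$n_patients)
  samples <- list()
  roi_num <- 0L
  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("P%02d", p)
    shift <- with_seed(derive_seed(config$seed, "patient", p),
                       rnorm(3, 0, 7))
    for (r in seq_len(rpp[p])) {
      roi_num <- roi_num + 1L
      roi_id <- sprintf("R%03d", roi_num)
      sample_seed <- derive_seed(config$seed, "roi", roi_num)
      s <- with_seed(sample_seed, {
        pres <- config$presence_prob
        targ <- config$class_prevalence
        on <- runif(length(pres)) < pres
        names(on) <- names(pres)
        targets <- ifelse(on[names(targ)], targ / pmax(pres[names(targ)], 1e-9),
                          0)
        names(targets) <- names(targ)
        targets <- targets * runif(length(targets), 0.7, 1.3)
        lab <- generate_label_map(n, as.list(targets), legend)
        img <- render_image(lab, legend, config$hardness, shift)
        # annotator thoroughness varies by ROI: jitter the unlabeled share
        lab <- apply_avoid(lab, legend$avoid_index,
                           config$avoid_fraction * runif(1, 0.75, 1.25))
        roi_sample(roi_id, patient_id, img, lab, config$mpp)
      })
      samples[[roi_num]] <- s
    }
  }
  if (!is.null(out_dir)) write_cohort(samples, legend, out_dir)
  list(samples = samples, legend = legend, config = config)
}

#' Desk-scale model and training settings
#'
#' Companion settings for [desk_preset()] cohorts: a narrow network
#' (base width 4, dropout 0.25) and 30 epochs at learning rate 1e-3 per
#' round. The full-scale recipe (300 epochs at 1e-4, dropout 0.8) is scaled
#' by 10x fewer epochs with a 10x larger step and lighter dropout, keeping a
#' CPU training round tractable while leaving the optimization in the same
#' regime.
#'
#' @return a [model_spec()] / [train_config()].
#' @export
desk_model_spec <- function() {
  model_spec(n_classes = 11L, depth = 4L, base_channels = 4L,
             dropout_rate = 0.25)
}

#' @rdname desk_model_spec
#' @export
desk_train_config <- function() {
  train_config(epochs = 30L, learning_rate = 1e-3)
}
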