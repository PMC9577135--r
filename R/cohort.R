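#' Construct an ROI sample
#'
#' An ROI sample pairs an RGB image with its ground-truth label map, the
#' patient it came from, and its physical resolution. All pipeline stages pass
#' these around.
#'
#' @param roi_id unique ROI identifier.
#' @param patient_id patient identifier (several ROIs may share one).
#' @param image numeric array H x W x 3, intensities in 0..255.
#' @param labels integer matrix H x W of legend indices.
#' @param microns_per_pixel physical resolution (microns per pixel, > 0).
#' @return an object of class `roi_sample`.
#' @export
roi_sample <- function(roi_id, patient_id, image, labels, microns_per_pixel) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (!all(dim(image)[1:2] == dim(labels)))
    stop("image and label map must have the same height/width")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  structure(list(roi_id = as.character(roi_id),
                 patient_id = as.character(patient_id),
                 image = image, labels = labels,
                 microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("<roi_sample> %s (patient %s) %dx%d @ %g um/px\n",
              x$roi_id, x$patient_id, nrow(x$labels), ncol(x$labels),
              x$microns_per_pixel))
  invisible(x)
}

read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    a <- tiff::readTIFF(path)
  } else {
    a <- png::readPNG(path)
  }
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  else if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  a * 255
}

write_rgb_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Write a cohort to disk (images, label PNGs, legend, manifest)
#'
#' Lays a cohort out as the on-disk interchange format: one RGB PNG and one
#' legend-encoded label PNG per ROI, a `legend.json`, and a `manifest.json`
#' listing `roi_id`, `patient_id`, relative image/label paths and
#' `microns_per_pixel` for every ROI.
#'
#' @param samples list of [roi_sample()] objects.
#' @param legend the `class_legend` the label maps use.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(samples, legend, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_legend(legend, file.path(dir, "legend.json"))
  rows <- lapply(samples, function(s) {
    img <- sprintf("%s_image.png", s$roi_id)
    lab <- sprintf("%s_labels.png", s$roi_id)
    write_rgb_png(s$image, file.path(dir, img))
    write_rgb_png(encode_label_png(s$labels, legend), file.path(dir, lab))
    list(roi_id = s$roi_id, patient_id = s$patient_id, image = img,
         labels = lab, microns_per_pixel = s$microns_per_pixel)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(legend = "legend.json", rois = rows), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifest path to a `manifest.json` written by [write_cohort()].
#' @param strict passed to [decode_label_png()].
#' @return list with `samples` (list of `roi_sample`) and `legend`.
#' @export
read_cohort <- function(manifest, strict = TRUE) {
  dir <- dirname(manifest)
  j <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  legend <- read_legend(file.path(dir, j$legend))
  samples <- lapply(j$rois, function(r) {
    img <- read_rgb_image(file.path(dir, r$image))
    lab <- decode_label_png(read_rgb_image(file.path(dir, r$labels)),
                            legend, strict = strict)
    roi_sample(r$roi_id, r$patient_id, img, lab, r$microns_per_pixel)
  })
  list(samples = samples, legend = legend)
}

#' Split a cohort at the patient level
#'
#' Randomly assigns `n_holdout_patients` whole patients (all of their ROIs)
#' to a holdout testing set; everything else forms the training pool. ROIs of
#' one patient never appear on both sides, so holdout performance is not
#' inflated by within-patient appearance correlation.
#'
#' @param samples list of `roi_sample`.
#' @param n_holdout_patients number of patients to hold out (must be fewer
#'   than the number of distinct patients).
#' @param seed integer; the draw is deterministic given the seed.
#' @return object of class `cohort_split`: `train_pool_ids`, `holdout_ids`,
#'   plus the patient assignment.
#' @export
split_by_patient <- function(samples, n_holdout_patients, seed) {
  patients <- vapply(samples, function(s) s$patient_id, character(1))
  ids <- vapply(samples, function(s) s$roi_id, character(1))
  if (anyDuplicated(ids)) stop("roi_id values must be unique within a cohort")
  unique_patients <- sort(unique(patients))
  if (n_holdout_patients >= length(unique_patients))
    stop(sprintf("n_holdout_patients (%d) must be < number of patients (%d)",
                 n_holdout_patients, length(unique_patients)))
  holdout_patients <- if (n_holdout_patients > 0)
    with_seed(seed, sample(unique_patients, n_holdout_patients))
  else character(0)
  hold <- patients %in% holdout_patients
  structure(list(train_pool_ids = ids[!hold], holdout_ids = ids[hold],
                 holdout_patients = holdout_patients, seed = seed),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d train-pool ROIs / %d holdout ROIs (%d holdout patients)\n",
              length(x$train_pool_ids), length(x$holdout_ids),
              length(x$holdout_patients)))
  invisible(x)
}

cohort_subset <- function(samples, ids) {
  all_ids <- vapply(samples, function(s) s$roi_id, character(1))
  samples[match(ids, all_ids)]
}
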