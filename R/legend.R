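#' Class legends: colors, names and integer indices
#'
#' A `class_legend` maps between annotation colors, tissue class names and the
#' integer indices used in label maps. Indices are contiguous from 0; one
#' extra index (`avoid_index`, always the largest) is reserved for unlabeled
#' "avoid" pixels, which annotators leave wherever they are not highly
#' confident. The avoid class has a reserved color (pure white by default)
#' that must not collide with any tissue color.
#'
#' @param names character vector of tissue class names (unique).
#' @param colors integer matrix `length(names)` x 3 of RGB values in 0..255,
#'   rows unique.
#' @param avoid_color RGB triple reserved for unlabeled pixels.
#' @return an object of class `class_legend` with fields `name`, `color`
#'   (matrix), `index` (0-based), `avoid_index`, `avoid_color`.
#' @export
class_legend <- function(names, colors, avoid_color = c(255L, 255L, 255L)) {
  colors <- matrix(as.integer(colors), ncol = 3)
  if (length(names) != nrow(colors)) stop("one color per class name required")
  if (anyDuplicated(names)) stop("class names must be unique")
  key <- color_key(colors)
  if (anyDuplicated(key)) stop("class colors must be unique")
  if (color_key(matrix(as.integer(avoid_color), ncol = 3)) %in% key)
    stop("avoid color collides with a tissue class color")
  if (any(colors < 0 | colors > 255)) stop("colors must be 8-bit (0..255)")
  structure(
    list(name = as.character(names), color = colors,
         index = seq_along(names) - 1L,
         avoid_index = length(names),
         avoid_color = as.integer(avoid_color)),
    class = "class_legend")
}

#' @export
print.class_legend <- function(x, ...) {
  cat(sprintf("<class_legend> %d tissue classes + avoid (index %d)\n",
              n_classes(x), x$avoid_index))
  for (i in seq_along(x$name))
    cat(sprintf("  %2d  %-22s rgb(%3d,%3d,%3d)\n", x$index[i], x$name[i],
                x$color[i, 1], x$color[i, 2], x$color[i, 3]))
  invisible(x)
}

#' Number of tissue classes in a legend (avoid excluded)
#' @param legend a `class_legend`.
#' @export
n_classes <- function(legend) length(legend$name)

color_key <- function(colors) {
  colors[, 1] * 65536L + colors[, 2] * 256L + colors[, 3]
}

# Canonical RGB values for the named annotation colors. The annotation
# protocol names colors only; these RGB values are the repository's fixed
# convention and are written into every manifest.
.palette <- c(
  Red = "255,0,0", Blue = "0,0,255", Yellow = "255,255,0",
  `Sky blue` = "135,206,235", Gray = "128,128,128", Silver = "192,192,192",
  Green = "0,128,0", Orange = "255,165,0", Black = "0,0,0",
  `Dark blue` = "0,0,139", Olive = "128,128,0", Pink = "255,192,203")

named_color <- function(nm) {
  v <- .palette[[nm]]
  if (is.null(v)) stop("unknown palette color: ", nm)
  as.integer(strsplit(v, ",")[[1]])
}

#' The working 11-class tissue legend
#'
#' The standard legend used throughout: 11 tissue classes (slide background
#' and adipose already merged into one super-class) plus the avoid index.
#' Colors follow the annotation protocol's named palette; RGB values are the
#' package's fixed convention.
#'
#' @return a `class_legend` with 11 tissue classes, avoid index 11.
#' @export
tissue_legend <- function() {
  nm <- c("Stroma", "Tumor", "Lymphocytes", "Mucosa", "Background/Adipose",
          "Blood", "Nerves", "Necrosis", "Keratin Pearl", "Muscle", "Junk")
  cols <- c("Red", "Blue", "Yellow", "Sky blue", "Gray", "Green", "Orange",
            "Black", "Dark blue", "Olive", "Pink")
  class_legend(nm, t(vapply(cols, named_color, integer(3))))
}

#' The pre-merge 12-class legend
#'
#' The legend as originally annotated, with slide background (Gray) and
#' adipose tissue (Silver) as separate classes. [merge_classes()] with
#' `c("Background", "Adipose")` reproduces [tissue_legend()]'s class set.
#'
#' @return a `class_legend` with 12 tissue classes, avoid index 12.
#' @export
premerge_legend <- function() {
  nm <- c("Stroma", "Tumor", "Lymphocytes", "Mucosa", "Background", "Adipose",
          "Blood", "Nerves", "Necrosis", "Keratin Pearl", "Muscle", "Junk")
  cols <- c("Red", "Blue", "Yellow", "Sky blue", "Gray", "Silver", "Green",
            "Orange", "Black", "Dark blue", "Olive", "Pink")
  class_legend(nm, t(vapply(cols, named_color, integer(3))))
}

#' Decode an RGB label raster to an integer label map
#'
#' Each pixel whose color exactly matches a legend entry (or the reserved
#' avoid color) receives that index. Matching is exact by design: label
#' rasters are lossless PNG, so an unknown color indicates a corrupt input
#' rather than compression noise. With `strict = FALSE` unknown colors fall
#' back to the avoid index.
#'
#' @param raster numeric or integer array H x W x 3 with values in 0..255.
#' @param legend a `class_legend`.
#' @param strict if `TRUE`, unknown colors raise an error naming the color
#'   and the number of affected pixels.
#' @return integer matrix H x W of legend indices (avoid included).
#' @export
decode_label_png <- function(raster, legend, strict = FALSE) {
  if (length(dim(raster)) != 3L || dim(raster)[3] != 3L)
    stop("label raster must be a 3-channel (RGB) array")
  d <- dim(raster)
  rgb <- matrix(as.integer(round(raster)), ncol = 3L)
  key <- rgb[, 1] * 65536L + rgb[, 2] * 256L + rgb[, 3]
  legend_keys <- c(color_key(legend$color),
                   color_key(matrix(legend$avoid_color, ncol = 3)))
  codes <- c(legend$index, legend$avoid_index)
  pos <- match(key, legend_keys)
  if (anyNA(pos)) {
    if (strict) {
      bad <- which(is.na(pos))
      cols <- unique(rgb[bad, , drop = FALSE])
      stop(sprintf(
        "unknown label color%s %s (%d pixel%s not in legend)",
        if (nrow(cols) > 1) "s" else "",
        paste(apply(cols, 1, function(v) sprintf("(%d,%d,%d)", v[1], v[2], v[3])),
              collapse = ", "),
        length(bad), if (length(bad) > 1) "s" else ""))
    }
    pos[is.na(pos)] <- length(codes)  # avoid fallback
  }
  matrix(codes[pos], nrow = d[1], ncol = d[2])
}

#' Encode an integer label map as an RGB raster
#'
#' Inverse of [decode_label_png()]: tissue indices map to their legend color,
#' the avoid index to the reserved avoid color. Round-trips exactly for every
#' valid label map.
#'
#' @param labels integer matrix of legend indices.
#' @param legend a `class_legend`.
#' @return numeric array H x W x 3 with values in 0..255.
#' @export
encode_label_png <- function(labels, legend) {
  codes <- c(legend$index, legend$avoid_index)
  pos <- match(as.vector(labels), codes)
  if (anyNA(pos) && length(labels) > 0)
    stop("label map contains indices outside the legend: ",
         paste(unique(labels[is.na(pos)]), collapse = ", "))
  pal <- rbind(legend$color, legend$avoid_color)
  array(as.numeric(pal[pos, ]), dim = c(dim(labels), 3L))
}

#' Merge two tissue classes into a super-class
#'
#' Relabels pixels of either source class to a new super-class (which inherits
#' the first source class's color), removes both sources from the legend, and
#' re-compacts indices so they stay contiguous from 0. Used to fuse slide
#' background with adipose tissue, which present identically (light gray/white
#' areas) on H&E.
#'
#' @param labels integer label map valid against `legend`.
#' @param legend a `class_legend`.
#' @param from_names character vector of length 2: the classes to merge.
#' @param to_name name of the resulting super-class.
#' @return list with `labels` (remapped map) and `legend` (one class fewer).
#' @export
merge_classes <- function(labels, legend, from_names, to_name) {
  miss <- setdiff(from_names, legend$name)
  if (length(miss)) stop("unknown class name(s): ", paste(miss, collapse = ", "))
  if (length(from_names) != 2L) stop("exactly two classes are merged at a time")
  i1 <- match(from_names[1], legend$name)
  i2 <- match(from_names[2], legend$name)
  new_names <- legend$name
  new_names[i1] <- to_name
  keep <- setdiff(seq_along(legend$name), i2)
  new_legend <- class_legend(new_names[keep],
                             legend$color[keep, , drop = FALSE],
                             legend$avoid_color)
  # old index -> new index lookup (position k+1 holds new index for old k)
  remap <- integer(legend$avoid_index + 1L)
  old_kept <- legend$index[keep]
  remap[old_kept + 1L] <- new_legend$index
  remap[legend$index[i2] + 1L] <- remap[legend$index[i1] + 1L]
  remap[legend$avoid_index + 1L] <- new_legend$avoid_index
  new_labels <- matrix(remap[labels + 1L], nrow = nrow(labels))
  list(labels = new_labels, legend = new_legend)
}

#' Serialize / read a legend as JSON
#'
#' @param legend a `class_legend`.
#' @param path file path.
#' @return `read_legend` returns a `class_legend`.
#' @export
write_legend <- function(legend, path) {
  jsonlite::write_json(
    list(classes = data.frame(name = legend$name, index = legend$index,
                              r = legend$color[, 1], g = legend$color[, 2],
                              b = legend$color[, 3]),
         avoid = list(index = legend$avoid_index,
                      color = legend$avoid_color)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_legend
#' @export
read_legend <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- j$classes[order(j$classes$index), ]
  class_legend(cl$name, cbind(cl$r, cl$g, cl$b),
               avoid_color = unlist(j$avoid$color))
}
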