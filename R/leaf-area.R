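# Leaf area from scaled images: manual polygon outline (the classic ImageJ
# workflow: open image -> set scale -> outline polygon) plus an automatic
# greenness-segmentation path.
#
# Pixel convention: 0-based coordinates, origin at top-left, x = column,
# y = row; polygon vertices are pixel centers. Rasters are stored [row, col]
# (H x W), channel values in [0, 1].

#' Construct a leaf image
#'
#' @param pixels H x W x 3 numeric array. Values may be 8-bit (0-255) or
#'   already normalized to `[0, 1]`; 8-bit input is rescaled.
#' @param cm_per_px physical scale, cm per pixel (> 0).
#' @param outline optional two-column matrix of (x, y) pixel vertices
#'   outlining the blade.
#' @return An object of class `leaf_image`.
#' @export
leaf_image <- function(pixels, cm_per_px, outline = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    leafthz_error("`pixels` must be an H x W x 3 array", "leafthz_domain_error")
  }
  check_positive(cm_per_px, "cm_per_px")
  if (max(pixels) > 1) pixels <- pixels / 255
  if (!is.null(outline)) {
    outline <- as.matrix(outline)
    if (ncol(outline) != 2L || nrow(outline) < 3L) {
      leafthz_error("`outline` needs >= 3 (x, y) vertices", "leafthz_geometry_error")
    }
  }
  structure(list(pixels = pixels, cm_per_px = cm_per_px, outline = outline),
            class = "leaf_image")
}

#' Read a leaf image from PNG/TIFF/JPEG
#'
#' @param path image file path.
#' @param cm_per_px physical scale, cm per pixel.
#' @return A [leaf_image()].
#' @export
read_leaf_image <- function(path, cm_per_px) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  # EBImage stores [x, y, channel]; transpose to [row, col, channel]
  leaf_image(aperm(a, c(2L, 1L, 3L)), cm_per_px)
}

#' Physical scale from a reference length
#'
#' The "set scale" step: a ruler or reference object of known physical
#' length is measured in pixels.
#'
#' @param pixel_length length in pixels (> 0).
#' @param real_length the same length in cm (> 0).
#' @return Scale, cm per pixel.
#' @export
calibrate_scale <- function(pixel_length, real_length) {
  check_positive(pixel_length, "pixel_length")
  check_positive(real_length, "real_length")
  real_length / pixel_length
}

# TRUE when segments p1-p2 and p3-p4 properly intersect (shared endpoints
# between adjacent polygon edges are excluded by the caller).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next  # closing edge is adjacent to the first
      if (segments_intersect(v[i, ], v[i %% n + 1L, ], v[j, ], v[j %% n + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Area of a polygon outline
#'
#' Shoelace (surveyor's) formula on the vertex coordinates, scaled by
#' `cm_per_px^2`. Orientation-independent.
#'
#' @param outline two-column matrix or data frame of (x, y) pixel vertices;
#'   >= 3 vertices, simple (non-self-intersecting) polygon.
#' @param cm_per_px scale, cm per pixel.
#' @return Area, cm^2.
#' @export
polygon_area <- function(outline, cm_per_px) {
  check_positive(cm_per_px, "cm_per_px")
  v <- as.matrix(outline)
  if (ncol(v) != 2L || nrow(v) < 3L) {
    leafthz_error("polygon needs at least 3 (x, y) vertices", "leafthz_geometry_error")
  }
  if (!polygon_is_simple(v)) {
    leafthz_error("polygon outline self-intersects", "leafthz_geometry_error")
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 * cm_per_px^2
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(nl), find, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  lab
}

#' Automatic leaf segmentation
#'
#' Thresholds a greenness index -- excess-green `2G - R - B` (default) or the
#' raw green channel -- with Otsu's method, keeps the largest 8-connected
#' component, and fills interior holes (specular highlights must not punch
#' holes in a simply connected blade). The foreground class is the side of
#' the threshold whose mean index is farther from the image border, assumed
#' to be background.
#'
#' @param image a [leaf_image()].
#' @param method `"excess_green"` (default) or `"otsu_green"`.
#' @param min_component_px smallest acceptable component, pixels.
#' @return An object of class `leaf_mask`: list with logical `mask` (H x W)
#'   and `cm_per_px`.
#' @export
segment_leaf <- function(image, method = c("excess_green", "otsu_green"),
                         min_component_px = 25L) {
  method <- match.arg(method)
  stopifnot(inherits(image, "leaf_image"))
  px <- image$pixels
  idx <- switch(method,
    excess_green = (2 * px[, , 2] - px[, , 1] - px[, , 3] + 2) / 4,
    otsu_green   = px[, , 2]
  )
  thr <- EBImage::otsu(EBImage::Image(t(idx)), range = c(0, 1))
  border <- c(idx[1, ], idx[nrow(idx), ], idx[, 1], idx[, ncol(idx)])
  hi <- idx > thr
  fg <- if (mean(border) > thr) !hi else hi
  if (!any(fg)) {
    leafthz_error("segmentation found no foreground pixels",
                  "leafthz_segmentation_failure")
  }
  lab <- label_components8(fg)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_component_px) {
    leafthz_error(sprintf("no connected component of >= %d px", min_component_px),
                  "leafthz_segmentation_failure")
  }
  keep <- lab == which.max(sizes)
  filled <- EBImage::imageData(EBImage::fillHull(keep * 1L)) > 0
  structure(list(mask = filled, cm_per_px = image$cm_per_px),
            class = "leaf_mask")
}

#' Area of a segmentation mask
#'
#' Foreground pixel count times `cm_per_px^2`.
#'
#' @param mask a `leaf_mask` (from [segment_leaf()]) or a logical matrix, in
#'   which case `cm_per_px` must be given.
#' @param cm_per_px scale, cm per pixel; taken from the mask when omitted.
#' @return Area, cm^2.
#' @export
mask_area <- function(mask, cm_per_px = NULL) {
  if (inherits(mask, "leaf_mask")) {
    cm_per_px <- mask$cm_per_px
    mask <- mask$mask
  }
  check_positive(cm_per_px, "cm_per_px")
  n_fg <- sum(mask)
  if (n_fg == 0) {
    leafthz_error("mask has no foreground pixels", "leafthz_segmentation_failure")
  }
  n_fg * cm_per_px^2
}

#' Write a mask as a 0/255 PNG
#'
#' @param mask a `leaf_mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "leaf_mask"))
  EBImage::writeImage(EBImage::Image(t(mask$mask * 1)), path)
  invisible(path)
}
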