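# Single-slice measurements at the L1 vertebral level plus craniocaudal
# spleen length. Circumference follows the one-pixel boundary convention:
# holes are filled, the mask is eroded by one pixel (3x3 cross, so a pixel
# survives only if its 4-neighbourhood is inside) and the boundary is the
# difference — the 8-connected outer contour, a guaranteed one-pixel-wide
# line whose pixel count times the pixel length gives the circumference.

# pixel length for perimeter counting: isotropic spacing, or the geometric
# mean with a warning when the in-plane spacing is anisotropic
pixel_length <- function(dx, dy) {
  if (abs(dx - dy) / dx <= 0.01) return(dx)
  warning(sprintf(paste0("anisotropic pixels (%.4g x %.4g cm); using ",
                         "sqrt(dx*dy) as the pixel length"), dx, dy))
  sqrt(dx * dy)
}

#' One-pixel boundary circumference of a mask slice
#'
#' Fills interior holes, erodes the region by one pixel with the 3x3 cross
#' structuring element and counts the boundary pixels (mask minus erosion,
#' i.e. the pixels with a 4-neighbour outside — the 8-connected outer
#' contour); circumference is the count times the pixel length. The
#' boundary set is exactly one pixel wide by construction, and a digitized
#' `s x s` square yields exactly `4s - 4` boundary pixels. Pixel-count
#' perimeters carry a known direction-dependent digitization bias relative
#' to the true Euclidean perimeter (about -10% on a rasterized disk, since
#' diagonal runs are counted one pixel per step); the measurement is the
#' conventional contour pixel count, not a Crofton estimate.
#'
#' @param mask_slice binary matrix.
#' @param dx,dy pixel spacing, cm.
#' @return circumference in cm; 0 with a warning for an empty slice.
#' @export
boundary_circumference <- function(mask_slice, dx, dy) {
  m <- (mask_slice != 0) * 1
  if (sum(m) == 0) {
    warning("empty mask slice: circumference 0")
    return(0)
  }
  filled <- EBImage::fillHull(EBImage::Image(m))
  eroded <- EBImage::erode(filled, EBImage::makeBrush(3, shape = "diamond"))
  count <- sum(filled > 0) - sum(eroded > 0)
  count * pixel_length(dx, dy)
}

#' Anterior-posterior and transverse diameters of a mask slice
#'
#' Tight bounding-box extents along the image axes, the convention for AP
#' and transverse measurements on supine axial sections: the number of
#' occupied pixel rows (AP, image y) times `dy` and occupied pixel columns
#' (transverse, image x) times `dx`. `feret = TRUE` instead returns the
#' maximal and minimal caliper (Feret) diameters over rotation of the pixel
#' centres.
#'
#' @param mask_slice binary matrix (rows = AP axis, columns = transverse).
#' @param dx,dy pixel spacing, cm.
#' @param feret use caliper diameters instead of image-axis extents.
#' @return `c(ap =, tv =)` in cm.
#' @export
axis_diameters <- function(mask_slice, dx, dy, feret = FALSE) {
  idx <- which(mask_slice != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask slice: diameters undefined")
  if (feret) {
    pts <- cbind((idx[, 2] - 1) * dx, (idx[, 1] - 1) * dy)
    angles <- seq(0, pi / 2, length.out = 91)
    widths <- vapply(angles, function(a) {
      u <- pts %*% c(cos(a), sin(a)); v <- pts %*% c(-sin(a), cos(a))
      max(diff(range(u)), diff(range(v)))
    }, numeric(1))
    return(c(ap = min(widths) + dy, tv = max(widths) + dx))
  }
  c(ap = diff(range(idx[, 1]) + c(0, 1)) * dy,
    tv = diff(range(idx[, 2]) + c(0, 1)) * dx)
}

#' Pixel-count area of a mask slice
#'
#' Identical computation to [slice_area()], applied to L1-body and
#' spinal-canal masks; the result does not depend on the anatomical label.
#'
#' @inheritParams boundary_circumference
#' @return area in cm^2.
#' @export
region_area <- function(mask_slice, dx, dy) slice_area(mask_slice, dx, dy)

#' Craniocaudal spleen length from a segmentation
#'
#' The slice-extent convention for axial acquisitions: number of sections
#' with nonzero organ area times the slice spacing `d`. For a convex organ
#' aligned with the slicing axis the discretization error is bounded by one
#' slice spacing.
#'
#' @param mask a [seg_mask()].
#' @param series the matching [image_series()].
#' @return length in cm.
#' @export
spleen_length <- function(mask, series) {
  stopifnot(inherits(mask, "seg_mask"), inherits(series, "image_series"))
  if (!identical(dim(mask$data), dim(series$data)))
    stop("mask is not congruent with series")
  counts <- apply(mask$data, 3, sum)
  if (sum(counts) == 0) stop("empty mask: length undefined")
  sum(counts > 0) * series$slice_spacing
}
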