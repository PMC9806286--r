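# Scriptable stand-in for interactive intensity-threshold segmentation:
# threshold within an operator-supplied region of interest, then keep the
# largest connected component (the operator painting only the organ).
# A fully manual mask can always be supplied through read_mask() instead.

#' Region of interest
#'
#' A ROI is a list of axis-aligned rectangles in 0-based pixel coordinates:
#' each element is `list(x = c(x0, x1), y = c(y0, y1), slices = ...)` with
#' inclusive bounds; `slices = NULL` applies the rectangle to every slice.
#' `read_roi()` loads the same structure from a JSON sidecar.
#'
#' @param roi a ROI list, or `NULL` meaning the whole volume.
#' @param dims series dimensions `(rows, cols, slices)`.
#' @return logical array marking voxels inside the ROI.
#' @keywords internal
roi_to_array <- function(roi, dims) {
  inside <- array(is.null(roi), dim = dims)
  for (rect in roi %||% list()) {
    xs <- rect$x + 1L; ys <- rect$y + 1L
    if (xs[1] < 1 || xs[2] > dims[2] || ys[1] < 1 || ys[2] > dims[1] ||
        xs[1] > xs[2] || ys[1] > ys[2])
      stop("ROI rectangle outside raster bounds or empty")
    sl <- if (is.null(rect$slices)) seq_len(dims[3]) else rect$slices + 1L
    if (any(sl < 1 | sl > dims[3])) stop("ROI slice index out of range")
    inside[ys[1]:ys[2], xs[1]:xs[2], sl] <- TRUE
  }
  if (!any(inside)) stop("empty ROI")
  inside
}

#' @rdname roi_to_array
#' @param path JSON file holding a list of rectangles.
#' @export
read_roi <- function(path) {
  roi <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(roi, function(r) list(x = as.integer(r$x), y = as.integer(r$y),
                               slices = if (!is.null(r$slices))
                                 as.integer(r$slices)))
}

#' Intensity-threshold segmentation within a ROI
#'
#' A voxel enters the mask iff it lies inside the ROI and its intensity is
#' within `[low, high]`. Counting the thresholded pixels slice by slice is
#' what turns the image stack into the Cavalieri area profile downstream.
#'
#' @param series an [image_series()].
#' @param roi ROI rectangles (see [roi_to_array()]), or `NULL` for the whole
#'   volume.
#' @param low,high inclusive intensity bounds, `low <= high`.
#' @param label mask label.
#' @return a [seg_mask()].
#' @export
threshold_segment <- function(series, roi = NULL, low, high = Inf,
                              label = "spleen") {
  stopifnot(inherits(series, "image_series"), low <= high)
  keep <- roi_to_array(roi, dim(series$data)) &
    series$data >= low & series$data <= high
  seg_mask(keep, series, label = label)
}

#' Automatic threshold by between-class variance maximization
#'
#' Otsu's bimodal-histogram split over the intensities inside the ROI,
#' returning the lower bound and the ROI maximum as the upper bound.
#' Deterministic for fixed input.
#'
#' @inheritParams threshold_segment
#' @return `c(low =, high =)` intensity bounds.
#' @export
auto_threshold <- function(series, roi = NULL) {
  stopifnot(inherits(series, "image_series"))
  vals <- series$data[roi_to_array(roi, dim(series$data))]
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) stop("constant-intensity ROI: no threshold exists")
  v01 <- matrix((vals - lo) / (hi - lo), ncol = 1)
  t01 <- EBImage::otsu(EBImage::Image(v01), range = c(0, 1), levels = 256L)
  c(low = lo + t01 * (hi - lo), high = hi)
}

# 3D connected-component labeling by vectorized breadth-first flood fill
# over the chosen neighborhood; returns an integer label array.
label_components_3d <- function(data, connectivity = 26) {
  dims <- dim(data)
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- data != 0
  pd <- dim(pad)
  off <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0 & off$ds == 0), ]
  if (connectivity == 6)
    off <- off[abs(off$dr) + abs(off$dc) + abs(off$ds) == 1, ]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  deltas <- off$dr + off$dc * pd[1] + off$ds * pd[1] * pd[2]

  labels <- array(0L, pd)
  todo <- which(pad)
  next_label <- 0L
  while (length(todo) > 0) {
    next_label <- next_label + 1L
    frontier <- todo[1]
    labels[frontier] <- next_label
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, deltas, "+")))
      nb <- nb[pad[nb] & labels[nb] == 0L]
      labels[nb] <- next_label
      frontier <- nb
    }
    todo <- todo[labels[todo] == 0L]
  }
  labels[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1), drop = FALSE]
}

#' Keep only the largest connected component of a mask
#'
#' Retains the largest 26-connected (default) 3D component, emulating the
#' operator segmenting only the spleen out of a thresholded image. Size ties
#' are broken in favour of the component reaching the lowest slice index,
#' then the lowest in-slice (column-major) coordinate, and the choice is
#' reported via `message()`. An empty mask is returned unchanged with a
#' warning.
#'
#' @param mask a [seg_mask()].
#' @param connectivity 26 (default) or 6.
#' @return a [seg_mask()] containing a single component.
#' @export
keep_largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "seg_mask"))
  if (sum(mask$data) == 0) {
    warning("empty mask: no components to keep")
    return(mask)
  }
  labels <- label_components_3d(mask$data, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # earliest voxel in column-major order is in the lowest slice, then
    # lowest in-slice coordinate
    first_voxel <- vapply(best, function(lb) min(which(labels == lb)),
                          numeric(1))
    best <- best[which.min(first_voxel)]
    message("component size tie; keeping the one nearest slice 1")
  }
  out <- mask
  out$data <- array(as.integer(labels == best), dim = dim(mask$data))
  out
}
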