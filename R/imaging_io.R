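#' Image series container
#'
#' An ordered stack of 2D intensity rasters with the geometry needed for
#' stereology: in-plane pixel spacing, slice thickness, inter-slice gap and
#' centre-to-centre slice spacing `d`. All lengths are centimetres; any
#' millimetre input (DICOM) is converted exactly once at the I/O boundary.
#' Slice index 1 is the first slice in ascending order along the slicing
#' axis; array layout is `[row (y), column (x), slice (z)]`.
#'
#' @param data numeric 3D array of intensities, or a list of equal-size
#'   matrices (stacked in order).
#' @param dx,dy in-plane pixel spacing (column, row), cm.
#' @param slice_thickness slice thickness, cm.
#' @param slice_gap gap between slices, cm; `NA` if unknown.
#' @param slice_spacing centre-to-centre spacing `d`, cm; when `NULL`,
#'   computed as `slice_thickness + slice_gap`, or taken as the thickness
#'   alone (with a warning) when the gap is unknown.
#' @param subject_id identifier string.
#' @param provenance free-form source description (format, file list).
#' @return an object of class `image_series`.
#' @export
image_series <- function(data, dx, dy, slice_thickness, slice_gap = 0,
                         slice_spacing = NULL, subject_id = "",
                         provenance = "in-memory") {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1) stop("all slices must share raster dimensions")
    data <- array(unlist(data), dim = c(dims[[1]], length(data)))
  }
  stopifnot(is.array(data), length(dim(data)) == 3,
            dx > 0, dy > 0, slice_thickness > 0)
  if (is.null(slice_spacing)) {
    if (is.na(slice_gap)) {
      warning("inter-slice gap unknown; taking slice spacing = thickness")
      slice_spacing <- slice_thickness
    } else {
      stopifnot(slice_gap >= 0)
      slice_spacing <- slice_thickness + slice_gap
    }
  }
  stopifnot(slice_spacing > 0)
  structure(list(data = data, dx = dx, dy = dy,
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 slice_spacing = slice_spacing, subject_id = subject_id,
                 provenance = provenance),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("image_series '%s': %d x %d pixels x %d slices, ",
                     "dx=%.3g dy=%.3g cm, d=%.3g cm (%s)\n"),
              x$subject_id, d[1], d[2], d[3], x$dx, x$dy, x$slice_spacing,
              x$provenance))
  invisible(x)
}

#' Binary segmentation mask aligned to an image series
#'
#' @param data integer/logical 3D array congruent with the series, values
#'   in `{0, 1}`.
#' @param series the [image_series()] the mask annotates (geometry source).
#' @param label anatomical label: `"spleen"`, `"L1_body"`, `"spinal_canal"`
#'   or `"abdomen"`.
#' @return an object of class `seg_mask`.
#' @export
seg_mask <- function(data, series,
                     label = c("spleen", "L1_body", "spinal_canal", "abdomen")) {
  label <- match.arg(label)
  stopifnot(inherits(series, "image_series"))
  data <- array(as.integer(data != 0), dim = dim(data))
  if (!identical(dim(data), dim(series$data)))
    stop("mask shape ", paste(dim(data), collapse = "x"),
         " does not match series shape ",
         paste(dim(series$data), collapse = "x"))
  structure(list(data = data, label = label, dx = series$dx, dy = series$dy,
                 slice_spacing = series$slice_spacing),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("seg_mask [%s]: %s voxels set of %s\n", x$label,
              format(sum(x$data), big.mark = ","),
              paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Write / read a segmentation mask as NIfTI
#'
#' Masks are stored as NIfTI-1 with voxel dimensions in millimetres
#' (`dx, dy, d`); values round-trip losslessly as 0/1 integers.
#'
#' @param mask a [seg_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [seg_mask()] with geometry copied from `series`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(mask$data,
                         pixdim = c(mask$dy, mask$dx, mask$slice_spacing) * 10)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @param path path to a NIfTI mask.
#' @param series the [image_series()] the mask belongs to; raster dimensions
#'   must match.
#' @param label anatomical label to assign.
#' @export
read_mask <- function(path, series, label = "spleen") {
  arr <- as.array(RNifti::readNifti(path))
  if (!identical(dim(arr), dim(series$data)))
    stop("mask shape ", paste(dim(arr), collapse = "x"),
         " does not match series shape ",
         paste(dim(series$data), collapse = "x"))
  seg_mask(arr, series, label = label)
}

cohort_numeric_cols <- c("age", "spleen_volume", "spleen_ce", "spleen_length",
                         "l1_ap", "l1_tv", "l1_area", "abd_ap", "abd_tv",
                         "abd_circ", "canal_area")

#' Write / read a cohort measurement table as CSV
#'
#' One row per (subject, rater) with the measured spleen volume, coefficient
#' of error, spleen length, the single-slice L1/abdominal metrics, age, sex
#' and optional volume class. Missing values are written as empty fields and
#' read back as `NA`; rows are canonically sorted by subject then rater.
#'
#' @param records data.frame with at least `subject_id` and `rater_id`
#'   columns; measurement columns among
#'   `age, sex, spleen_volume, spleen_ce, spleen_length, l1_ap, l1_tv,
#'   l1_area, abd_ap, abd_tv, abd_circ, canal_area, volume_class`.
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "rater_id") %in% names(records)))
  check_dup_records(records)
  records <- records[order(records$subject_id, records$rater_id), ,
                     drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  if (!all(c("subject_id", "rater_id") %in% names(records)))
    stop("cohort CSV must have subject_id and rater_id columns")
  for (col in intersect(cohort_numeric_cols, names(records)))
    records[[col]] <- as.numeric(records[[col]])
  check_dup_records(records)
  records[order(records$subject_id, records$rater_id), , drop = FALSE]
}

check_dup_records <- function(records) {
  key <- paste(records$subject_id, records$rater_id, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- unique(sub("\r", "/", key[duplicated(key)]))
    stop("duplicate (subject, rater) rows: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
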