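# Minimal DICOM Part-10 codec (explicit VR little endian, single-frame
# monochrome MR). Covers exactly the subset the pipeline needs: geometry
# tags (PixelSpacing, SliceThickness, SpacingBetweenSlices,
# ImagePositionPatient), identification tags and uncompressed 16-bit
# PixelData. Not a general DICOM implementation.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_MR_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"
UID_ROOT <- "1.2.826.0.1.3680043.10.1474"

le_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

# deterministic numeric suffix for UID generation from a string id
uid_suffix <- function(s) {
  v <- utf8ToInt(s)
  sprintf("%d.%d", sum(v * seq_along(v)) %% 999999937L, length(v))
}

dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(le_uint(group, 2), le_uint(element, 2), charToRaw(vr),
    if (long_form) c(as.raw(c(0, 0)), le_uint(length(value), 4))
    else le_uint(length(value), 2),
    value)
}

dcm_str <- function(x) paste(x, collapse = "\\")
dcm_num <- function(x) dcm_str(sprintf("%.10g", x))

write_dicom_file <- function(path, pixels, dy_mm, dx_mm, thickness_mm,
                             spacing_mm, z_mm, series_uid, sop_uid,
                             study_uid, subject_id, instance) {
  stopifnot(is.matrix(pixels))
  px <- as.integer(round(pmin(pmax(pixels, 0), 32767)))
  px <- matrix(px, nrow(pixels), ncol(pixels))
  pixel_raw <- writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", UID_MR_STORAGE),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1")))
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_MR_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "MR"),
    dcm_element(0x0010, 0x0020, "LO", subject_id),
    dcm_element(0x0018, 0x0050, "DS", dcm_num(thickness_mm)),
    if (!is.na(spacing_mm))
      dcm_element(0x0018, 0x0088, "DS", dcm_num(spacing_mm)),
    dcm_element(0x0020, 0x000D, "UI", study_uid),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS", dcm_num(c(0, 0, z_mm))),
    dcm_element(0x0020, 0x0037, "DS", dcm_num(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", le_uint(1, 2)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", le_uint(nrow(px), 2)),
    dcm_element(0x0028, 0x0011, "US", le_uint(ncol(px), 2)),
    dcm_element(0x0028, 0x0030, "DS", dcm_num(c(dy_mm, dx_mm))),
    dcm_element(0x0028, 0x0100, "US", le_uint(16, 2)),
    dcm_element(0x0028, 0x0101, "US", le_uint(16, 2)),
    dcm_element(0x0028, 0x0102, "US", le_uint(15, 2)),
    dcm_element(0x0028, 0x0103, "US", le_uint(0, 2)),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_raw))
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", le_uint(length(meta), 4)),
           meta, body)
  writeBin(out, path)
  invisible(path)
}

#' Write an image series as a DICOM directory
#'
#' One explicit-VR little-endian MR Image Storage file per slice, with pixel
#' spacing, slice thickness, centre-to-centre spacing and slice positions
#' populated (all converted cm to mm). UIDs are derived deterministically
#' from the subject id so repeated runs are byte-identical.
#'
#' @param series an [image_series()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dicom_series <- function(series, dir) {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sfx <- uid_suffix(if (nzchar(series$subject_id)) series$subject_id else "anon")
  study_uid <- paste(UID_ROOT, "2", sfx, sep = ".")
  series_uid <- paste(UID_ROOT, "3", sfx, sep = ".")
  nz <- dim(series$data)[3]
  for (k in seq_len(nz)) {
    write_dicom_file(
      file.path(dir, sprintf("slice_%04d.dcm", k)),
      pixels = series$data[, , k],
      dy_mm = series$dy * 10, dx_mm = series$dx * 10,
      thickness_mm = series$slice_thickness * 10,
      spacing_mm = series$slice_spacing * 10,
      z_mm = (k - 1) * series$slice_spacing * 10,
      series_uid = series_uid, sop_uid = paste(series_uid, k, sep = "."),
      study_uid = study_uid, subject_id = series$subject_id, instance = k)
  }
  invisible(dir)
}

parse_dicom_file <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop(path, ": not a DICOM Part-10 file")
  pos <- 133L
  tags <- list()
  transfer_checked <- FALSE
  while (pos + 8L <= length(buf) + 1L) {
    group <- readBin(buf[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                     endian = "little")
    element <- readBin(buf[(pos + 2):(pos + 3)], "integer", size = 2,
                       signed = FALSE, endian = "little")
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(buf[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 12L
    } else {
      len <- readBin(buf[(pos + 6):(pos + 7)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      pos <- pos + 8L
    }
    if (len < 0 || vr == "SQ")
      stop(path, ": unsupported undefined-length or sequence element")
    value <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X%04X", group, element)
    tags[[key]] <- switch(vr,
      DS = , IS = as.numeric(strsplit(trimws(rawToChar(value)), "\\\\")[[1]]),
      UI = , CS = , LO = , SH = , PN = , DA = , TM = trimws(rawToChar(value)),
      US = readBin(value, "integer", n = len / 2, size = 2, signed = FALSE,
                   endian = "little"),
      UL = readBin(value, "integer", n = len / 4, size = 4, endian = "little"),
      value)
    if (!transfer_checked && !is.null(tags[["00020010"]])) {
      if (tags[["00020010"]] != UID_EXPLICIT_VR_LE)
        stop(path, ": unsupported transfer syntax ", tags[["00020010"]])
      transfer_checked <- TRUE
    }
  }
  rows <- tags[["00280010"]]; cols <- tags[["00280011"]]
  if (is.null(rows) || is.null(cols) || is.null(tags[["7FE00010"]]))
    stop(path, ": missing image pixel module")
  vals <- readBin(tags[["7FE00010"]], "integer", n = rows * cols, size = 2,
                  signed = FALSE, endian = "little")
  list(pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
       pixel_spacing = tags[["00280030"]],     # (row, col) mm
       thickness = tags[["00180050"]],
       spacing_between = tags[["00180088"]],
       position = tags[["00200032"]],
       series_uid = tags[["0020000E"]],
       subject_id = tags[["00100020"]])
}

#' Read a DICOM series from a directory
#'
#' Reads every `*.dcm` file, verifies they form one coherent series, sorts
#' slices by position along the normal and normalizes geometry to
#' centimetres. The centre-to-centre spacing `d` is taken from the
#' Spacing Between Slices tag when present; otherwise it is inferred from
#' consecutive slice positions (i.e. thickness plus gap as laid down);
#' otherwise it falls back to the slice thickness with a warning.
#' Inter-slice distances inconsistent beyond 1% are an error.
#'
#' @param dir directory containing one series.
#' @return an [image_series()].
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) stop("no DICOM files in ", dir)
  parsed <- lapply(files, parse_dicom_file)

  uids <- unique(vapply(parsed, function(p) p$series_uid %||% "", ""))
  if (length(uids) > 1)
    stop("directory holds multiple series: ", paste(uids, collapse = ", "))
  ps <- parsed[[1]]$pixel_spacing
  if (is.null(ps) || length(ps) != 2)
    stop("missing PixelSpacing metadata in ", files[1])

  z <- vapply(parsed, function(p) p$position[3], numeric(1))
  ord <- order(z)
  parsed <- parsed[ord]; z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(abs(dz - stats::median(dz)) > 0.01 * stats::median(dz)))
      stop("inconsistent inter-slice distances (beyond 1% tolerance)")
  }
  thickness_mm <- parsed[[1]]$thickness %||% NA_real_
  d_mm <- parsed[[1]]$spacing_between
  if (is.null(d_mm)) {
    if (length(z) > 1) d_mm <- stats::median(diff(z))
    else {
      warning("no spacing tag and a single slice; using thickness as spacing")
      d_mm <- thickness_mm
    }
  }
  if (is.na(thickness_mm)) thickness_mm <- d_mm
  gap_cm <- max(d_mm - thickness_mm, 0) / 10

  stack <- array(0, dim = c(dim(parsed[[1]]$pixels), length(parsed)))
  for (k in seq_along(parsed)) stack[, , k] <- parsed[[k]]$pixels
  if (abs(ps[1] - ps[2]) / ps[1] > 0.01)
    message("anisotropic in-plane pixel spacing: ", ps[1], " x ", ps[2], " mm")
  image_series(stack, dx = ps[2] / 10, dy = ps[1] / 10,
               slice_thickness = thickness_mm / 10, slice_gap = gap_cm,
               slice_spacing = d_mm / 10,
               subject_id = parsed[[1]]$subject_id %||% "",
               provenance = sprintf("DICOM: %d files from %s",
                                    length(files), dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
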