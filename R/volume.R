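#' CT volume in Hounsfield units
#'
#' Container for a 3D CT/CTA grid in calibrated Hounsfield units (HU) plus
#' the acquisition geometry the calcium score depends on. Slices are indexed
#' along the third array axis (axial stack); the first two axes are in-plane
#' rows and columns. The world position (mm) of voxel \code{(i, j, k)}
#' (1-based) is \code{origin + c((i-1)*pixel_spacing[1],
#' (j-1)*pixel_spacing[2], (k-1)*slice_spacing)}. No resampling is ever done
#' implicitly: the score depends on native slice thickness, so any thickness
#' change must go through \code{\link{simulate_acquisition}}.
#'
#' @param voxels 3D numeric array of Hounsfield units.
#' @param pixel_spacing length-2 numeric, in-plane spacing in mm (row, col).
#' @param slice_thickness slice thickness in mm.
#' @param slice_spacing distance between consecutive slice centers in mm;
#'   defaults to \code{slice_thickness} (contiguous acquisition).
#' @param origin world-mm position of voxel (1,1,1); length-3 numeric.
#' @return An object of class \code{ct_volume}.
#' @examples
#' vol <- ct_volume(array(-50, c(8, 8, 4)), pixel_spacing = c(0.7, 0.7),
#'                  slice_thickness = 0.8)
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, pixel_spacing = c(1, 1), slice_thickness = 1,
                      slice_spacing = slice_thickness, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("'voxels' must be finite (non-finite HU values found)")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("'pixel_spacing' must be two positive values (mm)")
  if (!is.numeric(slice_thickness) || slice_thickness <= 0)
    stop("'slice_thickness' must be > 0 (mm)")
  if (!is.numeric(slice_spacing) || slice_spacing <= 0)
    stop("'slice_spacing' must be > 0 (mm)")
  if (length(origin) != 3L) stop("'origin' must be a length-3 mm triple")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 4000)
    warning("HU values outside the plausible CT range [-1024, 4000]: [",
            round(rng[1], 1), ", ", round(rng[2], 1), "]")
  structure(list(voxels = voxels,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = as.numeric(slice_thickness),
                 slice_spacing = as.numeric(slice_spacing),
                 origin = as.numeric(origin),
                 axial_axis = 3L),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("CT volume:", d[1], "x", d[2], "x", d[3], "voxels (HU)\n")
  cat("  pixel spacing :", paste(signif(x$pixel_spacing, 4), collapse = " x "),
      "mm\n")
  cat("  slice thickness:", signif(x$slice_thickness, 4), "mm  (spacing",
      signif(x$slice_spacing, 4), "mm)\n")
  cat("  origin        :", paste(signif(x$origin, 5), collapse = ", "), "mm\n")
  cat("  HU range      : [", round(min(x$voxels), 1), ",",
      round(max(x$voxels), 1), "]\n")
  invisible(x)
}

#' World-mm coordinates of voxel centers
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param axis 1, 2 or 3 (axial/slice axis).
#' @return Numeric vector of world-mm center positions along the axis.
#' @keywords internal
axis_coords <- function(volume, axis) {
  n <- dim(volume$voxels)[axis]
  step <- if (axis == 3L) volume$slice_spacing else volume$pixel_spacing[axis]
  volume$origin[axis] + (seq_len(n) - 1) * step
}

#' Apply a DICOM-style linear HU rescale
#'
#' Converts stored raw values to Hounsfield units with the standard affine
#' rescale \code{HU = slope * raw + intercept}.
#'
#' @param raw numeric array of stored values.
#' @param slope rescale slope.
#' @param intercept rescale intercept.
#' @return Numeric array in HU.
#' @examples
#' hu_rescale(100, slope = 1, intercept = -1024)  # -924 HU
#' @export
hu_rescale <- function(raw, slope = 1, intercept = 0) {
  slope * raw + intercept
}

#' Read a CT volume from disk
#'
#' Supported formats are NIfTI (\code{.nii}, \code{.nii.gz}) and NRRD
#' (\code{.nrrd}). Voxel values are returned as stored after any NIfTI
#' scl_slope/scl_inter rescale (applied by \pkg{RNifti}), i.e. in HU for a
#' calibrated CT. Spacing and origin are taken from the image transform.
#' DICOM series directories are not read directly; convert the series to
#' NIfTI first (the error message says so explicitly rather than guessing).
#'
#' NIfTI stores a single per-axis grid spacing, so \code{slice_thickness} is
#' taken equal to the slice spacing and flagged in
#' \code{attr(, "thickness_assumed")}; supply the true thickness via
#' \code{\link{acquisition_meta}} when it differs.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"nifti"} or \code{"nrrd"}.
#' @return A \code{\link{ct_volume}}.
#' @seealso \code{\link{write_ct_volume}}
#' @export
read_ct_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series are not read directly. ",
         "Convert the series to NIfTI and load that file.")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
              else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
              else stop("cannot infer format from extension of '", path,
                        "'; pass format explicitly")
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    arr <- array(as.vector(arr), dim(arr))  # drop niftiImage attributes
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- arr[, , , 1, drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop("expected a 3D NIfTI volume, got dims ",
           paste(dim(arr), collapse = "x"))
    aff <- RNifti::xform(img)
    sp <- sqrt(colSums(aff[1:3, 1:3]^2))
    if (any(sp <= 0)) stop("non-positive spacing in NIfTI transform")
    vol <- ct_volume(arr, pixel_spacing = sp[1:2], slice_thickness = sp[3],
                     slice_spacing = sp[3], origin = aff[1:3, 4])
    attr(vol, "thickness_assumed") <- TRUE
    vol
  } else {
    read_nrrd_volume(path)
  }
}

#' Write a CT volume to disk
#'
#' NIfTI output stores voxels as float64 and encodes spacing and origin in
#' the sform transform; NRRD output uses a plain-text header with raw
#' little-endian float64 data. Either format round-trips voxel values
#' exactly and geometry to within float32 header precision (NIfTI) or
#' exactly (NRRD).
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param path output path ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.nrrd}.
#' @return \code{path}, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_volume(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$voxels, datatype = "double")
    aff <- diag(c(volume$pixel_spacing, volume$slice_spacing, 1))
    aff[1:3, 4] <- volume$origin
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
  } else stop("unsupported extension for '", path, "'")
  invisible(path)
}

#' Acquisition metadata for protocol comparison
#'
#' Collects the scan parameters that influence the calcium score (tube
#' voltage, slice thickness, pixel spacing, contrast use) from a header
#' list. Missing fields become explicit \code{NA}s with a warning, never
#' silent defaults, because the paired-protocol comparison report must show
#' which parameters were actually known.
#'
#' @param volume a \code{\link{ct_volume}} (geometry fallback).
#' @param headers named list; recognised names (case-insensitive):
#'   \code{KVP}/\code{tube_voltage}, \code{SliceThickness}/\code{slice_thickness},
#'   \code{PixelSpacing}/\code{pixel_spacing}, \code{has_contrast},
#'   \code{source_id}.
#' @return Object of class \code{acquisition_meta} with fields
#'   \code{tube_voltage} (kVp), \code{slice_thickness} (mm),
#'   \code{pixel_spacing} (mm pair), \code{has_contrast}, \code{source_id}.
#' @export
acquisition_meta <- function(volume = NULL, headers = list()) {
  key <- function(nm) {
    hit <- which(tolower(names(headers)) %in% tolower(nm))
    if (length(hit)) headers[[hit[1]]] else NULL
  }
  kvp <- key(c("KVP", "tube_voltage"))
  if (is.null(kvp)) {
    warning("tube voltage absent from headers; recorded as NA")
    kvp <- NA_real_
  } else {
    kvp <- as.numeric(kvp)
    if (!is.na(kvp) && !(kvp %in% c(70, 80, 90, 100, 120, 140)))
      stop("tube voltage ", kvp, " kVp is not a recognised CT setting")
  }
  st <- key(c("SliceThickness", "slice_thickness"))
  if (is.null(st)) st <- if (!is.null(volume)) volume$slice_thickness else NA_real_
  ps <- key(c("PixelSpacing", "pixel_spacing"))
  if (is.null(ps)) ps <- if (!is.null(volume)) volume$pixel_spacing
                         else c(NA_real_, NA_real_)
  ps <- as.numeric(ps)
  if (length(ps) == 1L) ps <- rep(ps, 2L)
  hc <- key("has_contrast")
  sid <- key("source_id")
  structure(list(tube_voltage = kvp,
                 slice_thickness = as.numeric(st),
                 pixel_spacing = ps,
                 has_contrast = if (is.null(hc)) NA else isTRUE(hc),
                 source_id = if (is.null(sid)) NA_character_
                             else as.character(sid)),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("Acquisition: ",
      if (is.na(x$tube_voltage)) "kVp ?" else paste0(x$tube_voltage, " kVp"),
      ", slice ", signif(x$slice_thickness, 3), " mm, pixel ",
      paste(signif(x$pixel_spacing, 3), collapse = "x"), " mm",
      if (isTRUE(x$has_contrast)) ", contrast-enhanced" else "",
      "\n", sep = "")
  invisible(x)
}
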