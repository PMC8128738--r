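#' Threshold a scoring region for calcium
#'
#' A voxel is calcium-candidate iff it lies inside the region mask and its
#' HU value is at or above the threshold (boundary inclusive). The default
#' 130 HU is the classic attenuation threshold for calcified plaque;
#' lowering it is not allowed because sub-130 voxels are not calcium by
#' definition, but it may be raised (e.g. to the aortic contrast density on
#' strongly enhanced scans) to suppress lumen leakage.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param region_mask logical array matching the volume.
#' @param threshold HU threshold, >= 130.
#' @return Logical array: \code{region_mask & (voxels >= threshold)}.
#' @export
calcium_mask <- function(volume, region_mask, threshold = 130) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!identical(dim(region_mask), dim(volume$voxels)))
    stop("region mask does not match volume dimensions")
  if (threshold < 130)
    stop("calcium threshold must be >= 130 HU (got ", threshold, ")")
  region_mask & (volume$voxels >= threshold)
}

# 8-connected labelling of a logical slice via union-find over the candidate
# pixels. Connectivity is per axial slice only: lesions never merge across
# slices, matching the per-slice area x weight definition of the score.
label_components_8 <- function(m) {
  idx <- which(m)
  n <- length(idx)
  out <- array(0L, dim(m))
  if (!n) return(out)
  nr <- nrow(m); nc <- ncol(m)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + d[1]; c2 <- cc + d[2]
    ok <- which(rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc)
    ni <- (c2[ok] - 1L) * nr + rr[ok]
    hit <- ok[m[ni]]
    if (!length(hit)) next
    nb <- pos[ni[m[ni]]]
    for (t in seq_along(hit)) {
      a <- find(hit[t]); b <- find(nb[t])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}

#' Extract per-slice calcified lesions
#'
#' Splits a calcium mask into lesions: 8-connected components within each
#' axial slice (diagonal contact joins a lesion; slices are never merged).
#' Components smaller than \code{min_area} are discarded — the classic
#' 1 mm2 minimum lesion footprint that suppresses single-pixel noise.
#'
#' @param calc_mask logical array from \code{\link{calcium_mask}}.
#' @param volume the \code{\link{ct_volume}} the mask came from.
#' @param min_area minimum lesion area in mm2 (components strictly below
#'   are dropped).
#' @return List of lesions; each has \code{slice_index}, \code{pixels}
#'   (n x 2 row/col matrix), \code{n_pixels}, \code{area_mm2},
#'   \code{max_hu}, \code{weight} and \code{score} (see
#'   \code{\link{lesion_score}}).
#' @export
extract_lesions <- function(calc_mask, volume, min_area = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!identical(dim(calc_mask), dim(volume$voxels)))
    stop("calcium mask does not match volume dimensions")
  pixel_area <- prod(volume$pixel_spacing)
  lesions <- list()
  for (k in seq_len(dim(calc_mask)[3])) {
    sl <- calc_mask[, , k]
    if (!any(sl)) next
    lab <- label_components_8(sl)
    for (lb in seq_len(max(lab))) {
      pix <- which(lab == lb, arr.ind = TRUE)
      area <- nrow(pix) * pixel_area
      if (area < min_area) next
      max_hu <- max(volume$voxels[, , k][lab == lb])
      w <- density_weight(max_hu)
      lesions[[length(lesions) + 1L]] <-
        structure(list(slice_index = k,
                       pixels = unname(pix),
                       n_pixels = nrow(pix),
                       area_mm2 = area,
                       max_hu = max_hu,
                       weight = w,
                       score = area * w * volume$slice_thickness / 3),
                  class = "macs_lesion")
    }
  }
  lesions
}

#' Agatston density weight
#'
#' Maps a lesion's peak attenuation to the classic 4-level density factor:
#' 130-199 HU -> 1, 200-299 -> 2, 300-399 -> 3, >= 400 -> 4. Values below
#' 130 HU are not calcium and violate the contract.
#'
#' @param max_hu peak HU within the lesion (per slice).
#' @return Integer weight in 1..4 (vectorised).
#' @examples
#' density_weight(c(130, 199, 200, 399, 400, 5000))
#' @export
density_weight <- function(max_hu) {
  if (any(max_hu < 130))
    stop("density_weight called with max HU < 130 (not a calcium lesion)")
  ifelse(max_hu >= 400, 4L, ifelse(max_hu >= 300, 3L,
         ifelse(max_hu >= 200, 2L, 1L)))
}

#' Score one lesion
#'
#' Per-slice Agatston contribution: in-plane area (mm2) x density weight x
#' (slice thickness / 3 mm). The thickness factor generalises the classic
#' 3 mm acquisition: at 3 mm it reduces to the textbook area x weight, and
#' on thinner slices it makes the score volume-proportional, so a lesion
#' spanning two 1.5 mm slices scores the same as on one 3 mm slice.
#'
#' @param lesion a lesion from \code{\link{extract_lesions}}, or any list
#'   with \code{area_mm2} and \code{weight}.
#' @param slice_thickness mm.
#' @return Score in Agatston units.
#' @export
lesion_score <- function(lesion, slice_thickness) {
  if (is.null(lesion$area_mm2) || lesion$area_mm2 <= 0)
    stop("lesion has no positive area")
  lesion$area_mm2 * lesion$weight * slice_thickness / 3
}

#' Agatston calcium score of one artery
#'
#' Thresholds the artery's scoring territory, extracts per-slice lesions
#' and sums their scores. Deterministic for fixed inputs. With
#' \code{adaptive_threshold = TRUE} the threshold is raised to the aortic
#' contrast density (never lowered below 130 HU) when the region carries an
#' aorta ROI — a guard against contrast lumen being scored as calcium on
#' strongly enhanced CTA; off by default and reported in the result.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param region a \code{\link{scoring_region}}.
#' @param threshold HU threshold (>= 130).
#' @param min_area minimum lesion area, mm2.
#' @param adaptive_threshold raise threshold to the measured aortic contrast
#'   density when that exceeds \code{threshold}.
#' @return Object of class \code{artery_score}: \code{artery}, \code{macs},
#'   \code{lesions}, \code{n_lesions}, \code{threshold_used},
#'   \code{contrast_density} (when measured).
#' @export
artery_macs <- function(volume, region, threshold = 130, min_area = 1,
                        adaptive_threshold = FALSE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(region, "scoring_region"))
  cd <- NULL
  thr <- threshold
  if (!is.null(region$aorta_roi))
    cd <- contrast_density(volume, region$aorta_roi)
  if (adaptive_threshold) {
    if (is.null(cd))
      stop("adaptive threshold requested but region has no aorta ROI")
    if (cd$density > thr) {
      message("threshold raised from ", thr, " to aortic contrast density ",
              round(cd$density, 1), " HU for ", region$artery)
      thr <- cd$density
    }
  }
  mask <- scoring_mask(region, volume)
  cmask <- calcium_mask(volume, mask, thr)
  lesions <- extract_lesions(cmask, volume, min_area = min_area)
  macs <- sum(vapply(lesions, function(l) l$score, numeric(1)))
  structure(list(artery = region$artery,
                 macs = macs,
                 lesions = lesions,
                 n_lesions = length(lesions),
                 threshold_used = thr,
                 min_area = min_area,
                 contrast_density = cd),
            class = "artery_score")
}

#' @export
print.artery_score <- function(x, ...) {
  cat(x$artery, "MACS:", round(x$macs, 1), "(", x$n_lesions,
      "lesions, threshold", round(x$threshold_used, 1), "HU )\n")
  invisible(x)
}

#' Assemble the per-scan MACS profile
#'
#' The combined scores are plain sums: CA+SMA (the best-performing screening
#' combination) and the total over all three mesenteric arteries.
#'
#' @param ca,sma,ima \code{artery_score} objects for the celiac, superior
#'   mesenteric and inferior mesenteric arteries (any order is rejected —
#'   labels must match the argument).
#' @return Object of class \code{macs_profile} with fields \code{ca},
#'   \code{sma}, \code{ima}, \code{ca_plus_sma}, \code{total}.
#' @export
macs_profile <- function(ca, sma, ima) {
  scores <- list(ca = ca, sma = sma, ima = ima)
  labels <- vapply(scores, function(s) s$artery, character(1))
  if (anyDuplicated(labels))
    stop("duplicate artery labels in profile: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  if (!identical(unname(labels), c("CA", "SMA", "IMA")))
    stop("arguments must be the CA, SMA and IMA scores in that order (got ",
         paste(labels, collapse = ", "), ")")
  structure(list(ca = ca, sma = sma, ima = ima,
                 ca_plus_sma = ca$macs + sma$macs,
                 total = ca$macs + sma$macs + ima$macs),
            class = "macs_profile")
}

#' @export
print.macs_profile <- function(x, ...) {
  cat("MACS profile\n")
  cat(sprintf("  CA      : %9.1f\n", x$ca$macs))
  cat(sprintf("  SMA     : %9.1f\n", x$sma$macs))
  cat(sprintf("  IMA     : %9.1f\n", x$ima$macs))
  cat(sprintf("  CA + SMA: %9.1f\n", x$ca_plus_sma))
  cat(sprintf("  Total   : %9.1f\n", x$total))
  invisible(x)
}

#' Aortic contrast density
#'
#' Characterises enhancement strength as mean + 2 x sd of the HU values in
#' a circular ROI at the center of the aorta at the artery-origin level.
#' The sample (n-1) standard deviation is used: the ROI is a finite
#' hand-drawn sample of the lumen.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param aorta_roi either a logical array ROI mask, or a list with
#'   \code{center_mm} (x, y), \code{radius_mm} and \code{slice_index}.
#' @return Object of class \code{contrast_density}: \code{mean_hu},
#'   \code{sd_hu}, \code{density} (= mean + 2 sd), \code{roi_voxel_count}.
#' @examples
#' vol <- ct_volume(array(rep(c(590, 610), 8), c(4, 4, 1)))
#' roi <- array(FALSE, c(4, 4, 1)); roi[1:2, 1, 1] <- TRUE
#' contrast_density(vol, roi)  # mean 600, density 628.28
#' @export
contrast_density <- function(volume, aorta_roi) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.array(aorta_roi)) {
    mask <- aorta_roi
    if (!identical(dim(mask), dim(volume$voxels)))
      stop("aorta ROI mask does not match volume dimensions")
  } else {
    k <- as.integer(aorta_roi$slice_index)
    if (k < 1L || k > dim(volume$voxels)[3])
      stop("aorta ROI slice_index outside volume")
    xs <- axis_coords(volume, 1L); ys <- axis_coords(volume, 2L)
    plane <- outer((xs - aorta_roi$center_mm[1])^2,
                   (ys - aorta_roi$center_mm[2])^2, `+`) <=
      aorta_roi$radius_mm^2
    mask <- array(FALSE, dim(volume$voxels))
    mask[, , k] <- plane
  }
  vals <- volume$voxels[mask]
  if (length(vals) < 2L)
    stop("aorta ROI must contain at least 2 voxels (got ", length(vals), ")")
  m <- mean(vals); s <- stats::sd(vals)
  structure(list(mean_hu = m, sd_hu = s, density = m + 2 * s,
                 roi_voxel_count = length(vals)),
            class = "contrast_density")
}

#' @export
print.contrast_density <- function(x, ...) {
  cat(sprintf("Contrast density %.1f HU (mean %.1f + 2 x sd %.1f, n = %d)\n",
              x$density, x$mean_hu, x$sd_hu, x$roi_voxel_count))
  invisible(x)
}
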