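#' Specify a digital CT phantom
#'
#' The phantom emulates an abdominal CTA around the mesenteric artery
#' origins: a soft-tissue background, a contrast-filled aorta running along
#' the slice axis, one tube per artery leaving the aorta, and uniform-HU
#' calcified lesions (balls or boxes). Uniform lesions keep the ground
#' truth analytic; texture, blooming and reconstruction-kernel effects are
#' deliberately not modelled.
#'
#' Defaults reflect a tertiary-center mesenteric CTA: 0.7 mm pixels, 0.8 mm
#' slices, soft tissue at 40 HU. Vascular enhancement defaults to 100 HU —
#' deliberately below the 130 HU calcium threshold — because the phantom's
#' auto-generated scoring territories are schematic balls that, unlike
#' hand-drawn clinical ROIs, include the vessel lumen; sub-threshold
#' enhancement keeps the analytic ground truth equal to the lesion scores.
#' Raise \code{aorta$hu} / branch \code{hu} above 130 together with
#' \code{adaptive_threshold} in \code{\link{artery_macs}} to exercise the
#' contrast-suppression path instead.
#'
#' @param grid_dim integer triple, voxels (rows, cols, slices).
#' @param pixel_spacing in-plane spacing, mm.
#' @param slice_thickness slice thickness = spacing, mm.
#' @param background_hu background soft-tissue attenuation.
#' @param aorta list: \code{center_mm} (x, y), \code{radius_mm}, \code{hu}
#'   (contrast level). \code{NULL} for no aorta.
#' @param branches named list per artery (\code{CA}, \code{SMA}, \code{IMA});
#'   each a list with \code{ostium_mm} (x, y, z), \code{diameter_mm},
#'   \code{direction} (unit xyz), \code{length_mm}, \code{hu}.
#' @param lesions list of \code{\link{lesion_spec}}s.
#' @param noise_sd Gaussian noise sd, HU.
#' @param seed RNG seed for the noise.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_dim = c(96, 96, 48),
                         pixel_spacing = c(0.7, 0.7),
                         slice_thickness = 0.8,
                         background_hu = 40,
                         aorta = list(center_mm = c(24, 32), radius_mm = 10,
                                      hu = 100),
                         branches = default_branches(),
                         lesions = list(),
                         noise_sd = 0,
                         seed = 1L) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 2),
            all(pixel_spacing > 0), slice_thickness > 0, noise_sd >= 0)
  for (l in lesions) stopifnot(inherits(l, "lesion_spec"))
  extent <- c((grid_dim[1] - 1) * pixel_spacing[1],
              (grid_dim[2] - 1) * pixel_spacing[2],
              (grid_dim[3] - 1) * slice_thickness)
  for (nm in names(branches)) {
    o <- branches[[nm]]$ostium_mm
    if (any(o < 0) || any(o > extent))
      stop("branch ", nm, " ostium lies outside the grid")
  }
  structure(list(grid_dim = as.integer(grid_dim),
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 background_hu = background_hu,
                 aorta = aorta, branches = branches, lesions = lesions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_branches <- function() {
  list(CA  = list(ostium_mm = c(34, 32, 30), diameter_mm = 8,
                  direction = c(1, 0, 0), length_mm = 20, hu = 100),
       SMA = list(ostium_mm = c(34, 32, 19), diameter_mm = 8,
                  direction = c(1, 0, 0), length_mm = 22, hu = 100),
       IMA = list(ostium_mm = c(34, 32, 8), diameter_mm = 4,
                  direction = c(1, 0, 0), length_mm = 16, hu = 100))
}

#' One synthetic calcified lesion
#'
#' @param artery artery the lesion belongs to (\code{CA}, \code{SMA},
#'   \code{IMA}).
#' @param center world-mm triple.
#' @param shape \code{"ball"} or \code{"box"}.
#' @param dimensions ball: diameter (mm); box: (x, y, z) edge lengths (mm).
#' @param hu uniform attenuation; lesions meant to be scored need
#'   \code{hu >= 130}.
#' @return Object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(artery = c("CA", "SMA", "IMA"), center, shape = c("ball", "box"),
                        dimensions, hu) {
  artery <- match.arg(artery)
  shape <- match.arg(shape)
  if (any(dimensions <= 0)) stop("lesion dimensions must be > 0")
  if (shape == "box" && length(dimensions) != 3L)
    stop("box lesions need (x, y, z) edge lengths")
  if (shape == "ball" && length(dimensions) != 1L)
    stop("ball lesions need a single diameter")
  structure(list(artery = artery, center = as.numeric(center), shape = shape,
                 dimensions = as.numeric(dimensions), hu = as.numeric(hu)),
            class = "lesion_spec")
}

lesion_voxel_mask <- function(lesion, xs, ys, zs) {
  if (lesion$shape == "ball") {
    r <- lesion$dimensions[1] / 2
    dx2 <- (xs - lesion$center[1])^2
    dy2 <- (ys - lesion$center[2])^2
    dz2 <- (zs - lesion$center[3])^2
    m <- array(FALSE, c(length(xs), length(ys), length(zs)))
    plane <- outer(dx2, dy2, `+`)
    for (k in which(dz2 <= r^2)) m[, , k] <- plane + dz2[k] <= r^2
    m
  } else {
    h <- lesion$dimensions / 2
    inx <- abs(xs - lesion$center[1]) <= h[1]
    iny <- abs(ys - lesion$center[2]) <= h[2]
    inz <- abs(zs - lesion$center[3]) <= h[3]
    outer(outer(inx, iny, `&`), inz, `&`)
  }
}

#' Generate a phantom volume with annotations and analytic ground truth
#'
#' Voxels start at the background level, are overwritten by the aorta and
#' branch contrast, then by the lesions; Gaussian noise is added last under
#' the spec's seed, so the same spec always yields the same volume. Two
#' lesions of different HU may not overlap (the ground truth would be
#' ambiguous). Annotations place each artery's origin region at its ostium
#' (radius = one origin diameter) and an aortic contrast ROI at the same
#' slice level.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List: \code{volume} (\code{\link{ct_volume}}),
#'   \code{annotations} (\code{\link{annotation_set}}), \code{truth}
#'   (from \code{\link{analytic_score}}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim
  xs <- (seq_len(d[1]) - 1) * spec$pixel_spacing[1]
  ys <- (seq_len(d[2]) - 1) * spec$pixel_spacing[2]
  zs <- (seq_len(d[3]) - 1) * spec$slice_thickness
  vox <- array(spec$background_hu, d)
  if (!is.null(spec$aorta)) {
    lumen <- outer((xs - spec$aorta$center_mm[1])^2,
                   (ys - spec$aorta$center_mm[2])^2, `+`) <=
      spec$aorta$radius_mm^2
    vox[rep(lumen, d[3])] <- spec$aorta$hu
  }
  for (br in spec$branches) {
    u <- br$direction / sqrt(sum(br$direction^2))
    # tube: distance from the ostium ray <= radius, 0 <= projection <= length
    gx <- rep(xs, times = d[2] * d[3])
    gy <- rep(rep(ys, each = d[1]), times = d[3])
    gz <- rep(zs, each = d[1] * d[2])
    px <- gx - br$ostium_mm[1]; py <- gy - br$ostium_mm[2]
    pz <- gz - br$ostium_mm[3]
    t <- px * u[1] + py * u[2] + pz * u[3]
    d2 <- px^2 + py^2 + pz^2 - t^2
    inside <- t >= 0 & t <= br$length_mm & d2 <= (br$diameter_mm / 2)^2
    vox[inside] <- br$hu
  }
  owner <- array(0L, d)
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    m <- lesion_voxel_mask(l, xs, ys, zs)
    clash <- owner != 0L & m
    if (any(clash)) {
      other <- spec$lesions[[owner[which(clash)[1]]]]
      if (other$hu != l$hu)
        stop("lesions ", owner[which(clash)[1]], " and ", i,
             " overlap with different HU; ground truth would be ambiguous")
    }
    vox[m] <- l$hu
    owner[m] <- i
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd), d)
  }
  volume <- ct_volume(vox, pixel_spacing = spec$pixel_spacing,
                      slice_thickness = spec$slice_thickness)
  regions <- lapply(names(spec$branches), function(nm) {
    br <- spec$branches[[nm]]
    slice_idx <- which.min(abs(zs - br$ostium_mm[3]))
    roi <- if (!is.null(spec$aorta))
      list(center_mm = spec$aorta$center_mm,
           radius_mm = spec$aorta$radius_mm / 2,
           slice_index = slice_idx)
    scoring_region(artery = nm, ostium_center = br$ostium_mm,
                   origin_diameter = br$diameter_mm, aorta_roi = roi)
  })
  annotations <- annotation_set(regions, observer_id = "phantom-generator")
  list(volume = volume, annotations = annotations,
       truth = analytic_score(spec))
}

#' Analytic Agatston score of a phantom spec
#'
#' Continuous-geometry counterpart of the discrete scorer: for every slice
#' center crossed by a lesion the exact geometric cross-section area (disc
#' for a ball, rectangle for a box) is multiplied by the density weight of
#' the lesion's uniform HU and by thickness/3, then summed. Lesions below
#' the threshold score zero.
#'
#' @param spec a \code{\link{phantom_spec}} (uniform-HU lesions only).
#' @param threshold HU threshold (>= 130).
#' @return Object of class \code{ground_truth}: data frame \code{lesions}
#'   (artery, hu, weight, analytic score) and named vector
#'   \code{per_artery} (CA, SMA, IMA analytic MACS).
#' @export
analytic_score <- function(spec, threshold = 130) {
  stopifnot(inherits(spec, "phantom_spec"))
  zs <- (seq_len(spec$grid_dim[3]) - 1) * spec$slice_thickness
  thick_factor <- spec$slice_thickness / 3
  rows <- lapply(spec$lesions, function(l) {
    if (l$hu < threshold) {
      s <- 0; w <- NA_integer_
    } else {
      w <- density_weight(l$hu)
      dz <- abs(zs - l$center[3])
      areas <- if (l$shape == "ball") {
        r <- l$dimensions[1] / 2
        a <- pi * (r^2 - dz^2)
        a[dz > r] <- 0
        a
      } else {
        ifelse(dz <= l$dimensions[3] / 2, l$dimensions[1] * l$dimensions[2], 0)
      }
      s <- sum(areas) * w * thick_factor
    }
    data.frame(artery = l$artery, hu = l$hu, weight = w, score = s)
  })
  lesions <- if (length(rows)) do.call(rbind, rows)
             else data.frame(artery = character(), hu = numeric(),
                             weight = integer(), score = numeric())
  per_artery <- vapply(c("CA", "SMA", "IMA"), function(a)
    sum(lesions$score[lesions$artery == a]), numeric(1))
  structure(list(lesions = lesions, per_artery = per_artery,
                 total = sum(per_artery)),
            class = "ground_truth")
}

#' Re-acquire a volume at a thicker slice protocol
#'
#' First-order partial-volume model of scanning the same anatomy at a
#' referring-hospital protocol: consecutive native slices are averaged into
#' slabs of \code{round(new_thickness / native spacing)} slices (a
#' non-integer ratio is rounded to the nearest slab size and reported via a
#' message), then Gaussian noise is added. Trailing slices that do not fill
#' a slab are dropped. Metadata is updated to the achieved thickness. Tube
#' voltage physics is not modelled.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param new_thickness target slice thickness, mm (>= native spacing).
#' @param noise_sd additive Gaussian noise sd, HU.
#' @param seed RNG seed for the noise.
#' @return A new \code{\link{ct_volume}} at the thicker protocol.
#' @export
simulate_acquisition <- function(volume, new_thickness, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(inherits(volume, "ct_volume"))
  if (new_thickness < volume$slice_spacing)
    stop("new thickness must be >= the native slice spacing")
  ratio <- new_thickness / volume$slice_spacing
  k <- max(1L, as.integer(round(ratio)))
  if (abs(k - ratio) > 1e-9)
    message("slab ratio ", signif(ratio, 4), " is not integer; using ", k,
            " slices per slab (achieved thickness ",
            signif(k * volume$slice_spacing, 4), " mm)")
  d <- dim(volume$voxels)
  if (k == 1L) {
    out <- volume$voxels
  } else {
    n_out <- d[3] %/% k
    if (n_out < 1L) stop("volume too thin for the requested slab size")
    out <- array(0, c(d[1], d[2], n_out))
    for (j in seq_len(n_out)) {
      sl <- volume$voxels[, , ((j - 1L) * k + 1L):(j * k), drop = FALSE]
      out[, , j] <- rowMeans(sl, dims = 2L)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
  }
  ct_volume(out, pixel_spacing = volume$pixel_spacing,
            slice_thickness = k * volume$slice_spacing,
            slice_spacing = k * volume$slice_spacing,
            origin = volume$origin +
              c(0, 0, (k - 1) / 2 * volume$slice_spacing))
}

#' Default cohort score-distribution parameters
#'
#' Per group and artery: the probability of a zero score (no calcium in the
#' territory) and the log-normal meanlog/sdlog of the non-zero scores.
#' The defaults were calibrated once so the implied quartiles of each
#' mixture match published per-artery median (IQR) summaries of a CMI
#' screening cohort; see the methods vignette for the calibration.
#'
#' @return Data frame with columns \code{group}, \code{artery}, \code{p_zero},
#'   \code{meanlog}, \code{sdlog}.
#' @export
cohort_distribution_defaults <- function() {
  data.frame(
    group   = rep(c("CMI", "nonCMI"), each = 3),
    artery  = rep(c("CA", "SMA", "IMA"), 2),
    p_zero  = c(0.05, 0.30, 0.30, 0.55, 0.55, 0.60),
    meanlog = c(5.3657, 6.6795, 3.7399, 5.1222, 5.0771, 3.4224),
    sdlog   = c(1.3709, 0.9573, 1.2286, 1.5, 1.5, 1.5))
}

#' Simulate a screening cohort with known score distributions
#'
#' Per-artery scores are drawn independently from zero-inflated log-normal
#' distributions: MACS is non-negative, has a point mass at zero
#' (especially in non-CMI patients) and a right-skewed positive part.
#'
#' @param n_cmi,n_non_cmi group sizes.
#' @param params distribution table as returned by
#'   \code{\link{cohort_distribution_defaults}}.
#' @param seed RNG seed.
#' @return Cohort data frame (\code{patient_id}, \code{group},
#'   \code{macs_ca}, \code{macs_sma}, \code{macs_ima}).
#' @export
make_cohort <- function(n_cmi = 49, n_non_cmi = 135,
                        params = cohort_distribution_defaults(), seed = 1L) {
  stopifnot(n_cmi > 0, n_non_cmi > 0)
  set.seed(seed)
  draw <- function(n, group, artery) {
    p <- params[params$group == group & params$artery == artery, ]
    if (nrow(p) != 1L) stop("no distribution parameters for ", group, "/", artery)
    zero <- stats::runif(n) < p$p_zero
    ifelse(zero, 0, stats::rlnorm(n, p$meanlog, p$sdlog))
  }
  build <- function(n, group, prefix) {
    data.frame(patient_id = sprintf("%s%03d", prefix, seq_len(n)),
               group = group,
               macs_ca = draw(n, group, "CA"),
               macs_sma = draw(n, group, "SMA"),
               macs_ima = draw(n, group, "IMA"))
  }
  rbind(build(n_cmi, "CMI", "cmi"), build(n_non_cmi, "nonCMI", "ctl"))
}
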