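#' Define one artery's scoring territory
#'
#' A scoring region is the only territory scored for an artery. It is the
#' union of (a) an origin region — all tissue within a distance of one
#' origin-diameter of the ostium, capturing the ostial plaque burden — and
#' (b) an operator-supplied distal extent drawn slice by slice out to the
#' artery's anatomical endpoint (the bifurcation for the celiac artery, the
#' first large jejunal branch for the superior mesenteric artery, the left
#' colic artery for the inferior mesenteric artery). Distal extents are
#' hand-drawn landmarks, never auto-detected.
#'
#' @param artery one of \code{"CA"}, \code{"SMA"}, \code{"IMA"}.
#' @param ostium_center world-mm triple of the artery origin on the aorta.
#' @param origin_diameter measured diameter of the artery origin, mm; the
#'   origin region radius equals this diameter (1x the diameter, not the
#'   radius).
#' @param distal_polygons list of per-slice polygons, each a list with
#'   \code{slice_index} (1-based) and \code{vertices_mm} (n x 2 matrix of
#'   in-plane world-mm vertices). May be empty.
#' @param mode \code{"ball"} treats the origin region as a 3D ball (lesions
#'   at an ostium span slices; the default, volumetric reading) or
#'   \code{"disc"} as a 2D disc on the slice nearest the ostium.
#' @param aorta_roi optional circular ROI for contrast-density measurement:
#'   list with \code{center_mm} (x, y), \code{radius_mm}, \code{slice_index}.
#' @return Object of class \code{scoring_region}.
#' @export
scoring_region <- function(artery = c("CA", "SMA", "IMA"), ostium_center,
                           origin_diameter, distal_polygons = list(),
                           mode = c("ball", "disc"), aorta_roi = NULL) {
  artery <- match.arg(artery)
  mode <- match.arg(mode)
  if (!is.numeric(ostium_center) || length(ostium_center) != 3L)
    stop("'ostium_center' must be a world-mm triple")
  if (!is.numeric(origin_diameter) || origin_diameter <= 0)
    stop("'origin_diameter' must be > 0 mm")
  for (p in distal_polygons) {
    if (is.null(p$slice_index) || is.null(p$vertices_mm))
      stop("each distal polygon needs 'slice_index' and 'vertices_mm'")
  }
  structure(list(artery = artery,
                 ostium_center = as.numeric(ostium_center),
                 origin_diameter = as.numeric(origin_diameter),
                 distal_polygons = distal_polygons,
                 mode = mode,
                 aorta_roi = aorta_roi),
            class = "scoring_region")
}

#' Origin-region voxel mask
#'
#' Marks every voxel whose center lies within one origin-diameter of the
#' ostium center. In \code{"ball"} mode the distance is 3D; in \code{"disc"}
#' mode only the slice whose center is nearest the ostium is marked, with a
#' 2D in-plane distance. A degenerate radius smaller than the voxel pitch
#' still yields at least the voxel nearest the center.
#'
#' @param ostium_center world-mm triple.
#' @param origin_diameter mm; the mask radius equals this value.
#' @param volume a \code{\link{ct_volume}} supplying the grid geometry.
#' @param mode \code{"ball"} or \code{"disc"}.
#' @return Logical array matching \code{dim(volume$voxels)}.
#' @export
origin_region_mask <- function(ostium_center, origin_diameter, volume,
                               mode = c("ball", "disc")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "ct_volume"))
  if (origin_diameter <= 0) stop("'origin_diameter' must be > 0")
  xs <- axis_coords(volume, 1L)
  ys <- axis_coords(volume, 2L)
  zs <- axis_coords(volume, 3L)
  c0 <- ostium_center
  inside_axis <- function(v, lo, hi) v >= lo - 1e-9 & v <= hi + 1e-9
  if (!inside_axis(c0[1], min(xs), max(xs)) ||
      !inside_axis(c0[2], min(ys), max(ys)) ||
      !inside_axis(c0[3], min(zs), max(zs)))
    stop("ostium center ", paste(signif(c0, 4), collapse = ", "),
         " lies outside the volume grid")
  r2 <- origin_diameter^2
  d <- dim(volume$voxels)
  dx2 <- (xs - c0[1])^2
  dy2 <- (ys - c0[2])^2
  mask <- array(FALSE, d)
  if (mode == "ball") {
    dz2 <- (zs - c0[3])^2
    keep <- which(dz2 <= r2)
    plane <- outer(dx2, dy2, `+`)
    for (k in keep) mask[, , k] <- plane + dz2[k] <= r2
  } else {
    k <- which.min(abs(zs - c0[3]))
    mask[, , k] <- outer(dx2, dy2, `+`) <= r2
  }
  if (!any(mask)) {
    # radius below voxel pitch: keep the nearest voxel so the mask is never empty
    i <- which.min(abs(xs - c0[1])); j <- which.min(abs(ys - c0[2]))
    k <- which.min(abs(zs - c0[3]))
    mask[i, j, k] <- TRUE
  }
  mask
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Points exactly on a horizontal edge follow the half-open ray convention.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE if segments p1-p2 and p3-p4 properly intersect (shared endpoints of
# adjacent polygon edges are excluded by the caller).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(vx, vy) {
  n <- length(vx)
  if (n < 4L) return(FALSE)
  pts <- cbind(vx, vy)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # closing edge adjacent to first edge
      a <- pts[i, ]; b <- pts[i %% n + 1L, ]
      c <- pts[j, ]; e <- pts[j %% n + 1L, ]
      if (segments_intersect(a, b, c, e)) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize per-slice polygons to a voxel mask
#'
#' A pixel is included iff its center lies inside the polygon under the
#' even-odd rule, so vertex orientation (clockwise vs counter-clockwise)
#' does not matter. Polygons must be simple; a self-intersecting outline is
#' rejected because its interior is ambiguous.
#'
#' @param per_slice_polygons list of lists with \code{slice_index} and
#'   \code{vertices_mm} (n x 2, world mm). An empty list gives an empty mask.
#' @param volume a \code{\link{ct_volume}} supplying the grid.
#' @return Logical array matching \code{dim(volume$voxels)}.
#' @export
rasterize_polygons <- function(per_slice_polygons, volume) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  mask <- array(FALSE, d)
  if (!length(per_slice_polygons)) return(mask)
  xs <- axis_coords(volume, 1L)
  ys <- axis_coords(volume, 2L)
  px <- rep(xs, times = d[2])
  py <- rep(ys, each = d[1])
  for (poly in per_slice_polygons) {
    k <- as.integer(poly$slice_index)
    if (k < 1L || k > d[3]) stop("polygon slice_index ", k, " outside volume")
    v <- poly$vertices_mm
    if (is.list(v)) v <- do.call(rbind, v)
    v <- as.matrix(v)
    if (nrow(v) < 3L) stop("polygon needs at least 3 vertices")
    if (polygon_self_intersects(v[, 1], v[, 2]))
      stop("self-intersecting polygon on slice ", k)
    inside <- point_in_polygon(px, py, v[, 1], v[, 2])
    mask[, , k] <- mask[, , k] | matrix(inside, d[1], d[2])
  }
  mask
}

#' Full scoring mask for one artery
#'
#' The union of the origin region and the rasterized distal extent; each
#' voxel is counted once however many components cover it.
#'
#' @param region a \code{\link{scoring_region}}.
#' @param volume a \code{\link{ct_volume}}.
#' @return Logical array matching \code{dim(volume$voxels)}.
#' @export
scoring_mask <- function(region, volume) {
  stopifnot(inherits(region, "scoring_region"))
  m <- origin_region_mask(region$ostium_center, region$origin_diameter,
                          volume, mode = region$mode)
  if (length(region$distal_polygons))
    m <- m | rasterize_polygons(region$distal_polygons, volume)
  m
}

#' Annotation set: all scoring regions for one scan
#'
#' @param regions list of \code{\link{scoring_region}}s, at most one per
#'   artery.
#' @param volume_path path of the volume the regions were drawn on; its MD5
#'   checksum is stored so a later load can detect a swapped volume.
#' @param observer_id free-text observer identifier.
#' @param created timestamp string.
#' @return Object of class \code{annotation_set}.
#' @export
annotation_set <- function(regions, volume_path = NA_character_,
                           observer_id = NA_character_,
                           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  arteries <- vapply(regions, function(r) r$artery, character(1))
  if (anyDuplicated(arteries))
    stop("duplicate scoring regions for artery: ",
         paste(unique(arteries[duplicated(arteries)]), collapse = ", "))
  checksum <- NA_character_
  if (!is.na(volume_path) && file.exists(volume_path))
    checksum <- unname(tools::md5sum(volume_path))
  structure(list(volume_ref = list(path = volume_path, checksum = checksum),
                 regions = regions,
                 observer_id = observer_id,
                 created = created,
                 schema_version = 1L),
            class = "annotation_set")
}

#' Save / load annotation sets (versioned JSON, world-mm coordinates)
#'
#' Coordinates are stored in world mm so the annotations survive volume
#' resampling. Loading re-validates the schema (one region per artery,
#' positive diameters) and compares the stored volume checksum against the
#' file on disk: a mismatch warns, a missing volume sets
#' \code{attr(, "unresolved_volume")} instead of failing.
#'
#' @param set an \code{\link{annotation_set}}.
#' @param path JSON file path.
#' @return \code{load_annotations} returns an \code{annotation_set};
#'   \code{save_annotations} returns \code{path} invisibly.
#' @export
save_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  regions <- lapply(set$regions, function(r) {
    list(artery = r$artery,
         ostium_center_mm = r$ostium_center,
         origin_diameter_mm = r$origin_diameter,
         mode = r$mode,
         aorta_roi = r$aorta_roi,
         distal_polygons = lapply(r$distal_polygons, function(p)
           list(slice_index = p$slice_index,
                vertices_mm = unname(as.matrix(p$vertices_mm)))))
  })
  obj <- list(schema = "macscore-annotations",
              schema_version = set$schema_version,
              volume_ref = set$volume_ref,
              observer_id = set$observer_id,
              created = set$created,
              regions = regions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_annotations
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed annotation file '",
                                           path, "': ", conditionMessage(e)))
  if (!identical(obj$schema, "macscore-annotations"))
    stop("'", path, "' is not a macscore annotation file")
  regions <- lapply(obj$regions, function(r) {
    polys <- lapply(r$distal_polygons, function(p)
      list(slice_index = as.integer(p$slice_index),
           vertices_mm = do.call(rbind, lapply(p$vertices_mm, unlist))))
    roi <- r$aorta_roi
    if (!is.null(roi))
      roi <- list(center_mm = unlist(roi$center_mm),
                  radius_mm = roi$radius_mm,
                  slice_index = as.integer(roi$slice_index))
    scoring_region(artery = r$artery,
                   ostium_center = unlist(r$ostium_center_mm),
                   origin_diameter = r$origin_diameter_mm,
                   distal_polygons = polys,
                   mode = r$mode,
                   aorta_roi = roi)
  })
  arteries <- vapply(regions, function(r) r$artery, character(1))
  if (anyDuplicated(arteries))
    stop("annotation file has duplicate regions for artery: ",
         paste(unique(arteries[duplicated(arteries)]), collapse = ", "))
  set <- structure(list(volume_ref = list(path = obj$volume_ref$path,
                                          checksum = obj$volume_ref$checksum),
                        regions = regions,
                        observer_id = if (is.null(obj$observer_id)) NA_character_
                                      else obj$observer_id,
                        created = obj$created,
                        schema_version = obj$schema_version),
                   class = "annotation_set")
  vp <- set$volume_ref$path
  if (is.character(vp) && length(vp) == 1L && !is.na(vp) && nzchar(vp)) {
    if (!file.exists(vp)) {
      attr(set, "unresolved_volume") <- TRUE
    } else if (!is.null(set$volume_ref$checksum) &&
               !is.na(set$volume_ref$checksum) &&
               !identical(unname(tools::md5sum(vp)), set$volume_ref$checksum)) {
      warning("checksum of '", vp, "' does not match the annotation file; ",
              "the volume may have changed since annotation")
    }
  }
  set
}
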