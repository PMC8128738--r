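# Independent brute-force oracles. These deliberately share no code with the
# package: the scorer walks pixels with an explicit flood fill, the AUC
# enumerates every diseased/healthy pair, and the cutoff search scans every
# candidate threshold.

# Brute-force Agatston scorer: per-voxel threshold test, stack-based
# 8-connected flood fill per slice, manual summation.
oracle_macs <- function(voxels, region_mask, pixel_spacing, slice_thickness,
                        threshold = 130, min_area = 1) {
  pa <- prod(pixel_spacing)
  total <- 0
  d <- dim(voxels)
  for (k in seq_len(d[3])) {
    cand <- matrix(FALSE, d[1], d[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      cand[i, j] <- region_mask[i, j, k] && voxels[i, j, k] >= threshold
    seen <- matrix(FALSE, d[1], d[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!cand[i, j] || seen[i, j]) next
      stack <- list(c(i, j))
      comp <- list()
      seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        comp[[length(comp) + 1L]] <- p
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi < 1 || qi > d[1] || qj < 1 || qj > d[2]) next
          if (cand[qi, qj] && !seen[qi, qj]) {
            seen[qi, qj] <- TRUE
            stack[[length(stack) + 1L]] <- c(qi, qj)
          }
        }
      }
      area <- length(comp) * pa
      if (area < min_area) next
      mx <- max(vapply(comp, function(p) voxels[p[1], p[2], k], numeric(1)))
      w <- if (mx >= 400) 4 else if (mx >= 300) 3 else if (mx >= 200) 2 else 1
      total <- total + area * w * slice_thickness / 3
    }
  }
  total
}

# AUC as the exhaustive Mann-Whitney pair count (ties worth 1/2).
oracle_auc <- function(scores, diseased) {
  sd_ <- scores[diseased]; sh <- scores[!diseased]
  tot <- 0
  for (a in sd_) for (b in sh)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sd_) * length(sh))
}

# Exhaustive Youden-J cutoff search over midpoint candidates; ties toward
# higher sensitivity (lower cutoff).
oracle_cutoff <- function(scores, diseased) {
  s <- sort(unique(scores))
  gap <- if (length(s) > 1) min(diff(s)) else 1
  cand <- c(s[1] - gap / 2,
            if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2,
            s[length(s)] + gap / 2)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[diseased] >= t)
    spec <- mean(scores[!diseased] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(cutoff = t, j = j, sens = sens)
    }
  }
  best$cutoff
}

# Brute-force even-odd point-in-polygon via angle-free crossing count,
# written independently (counts crossings of a rightward ray edge by edge,
# scalar arithmetic only).
oracle_point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- vy[i]; y2 <- vy[j]; x1 <- vx[i]; x2 <- vx[j]
    if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
      xc <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (xc > x) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# A small uniform-HU single-lesion phantom scored both ways; used by several
# convergence checks. Fixed non-lattice lesion center so rasterization error
# is generic, not knife-edge symmetric.
resolution_phantom <- function(pixel_mm) {
  n_xy <- as.integer(round(48 / pixel_mm)) + 1L
  phantom_spec(grid_dim = c(n_xy, n_xy, 25L),
               pixel_spacing = c(pixel_mm, pixel_mm),
               slice_thickness = 1,
               aorta = NULL,
               branches = list(CA = list(ostium_mm = c(24, 24, 12),
                                         diameter_mm = 6,
                                         direction = c(1, 0, 0),
                                         length_mm = 10, hu = 100)),
               lesions = list(lesion_spec("CA", center = c(26.3, 24.4, 12.3),
                                          shape = "ball", dimensions = 5,
                                          hu = 350)),
               noise_sd = 0)
}
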