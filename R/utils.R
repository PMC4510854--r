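# Internal geometry helpers. The whole package speaks physical nanometres at
# module boundaries; voxel indices are an implementation detail. Coordinates
# are 0-based voxel-centre: voxel i (1-based array index) has centre
# (i - 0.5) * pitch along its axis.

# nm centre coordinate of 1-based voxel indices
vox_centre_nm <- function(idx, pitch) (idx - 0.5) * pitch

# 1-based voxel index containing an nm coordinate (points exactly on a
# boundary belong to the higher voxel, matching floor semantics)
nm_to_vox <- function(coord_nm, pitch, n) {
  i <- floor(coord_nm / pitch) + 1L
  pmin(pmax(as.integer(i), 1L), as.integer(n))
}

# Convert a (z,y,x) index matrix to an nm coordinate matrix (columns x,y,z).
idx_to_nm <- function(idx, voxel_size) {
  cbind(
    x = vox_centre_nm(idx[, 3L], voxel_size[["x"]]),
    y = vox_centre_nm(idx[, 2L], voxel_size[["y"]]),
    z = vox_centre_nm(idx[, 1L], voxel_size[["z"]])
  )
}

# Surface-to-surface gap between two sets of voxels, in nm, using the
# axis-aligned voxel-box convention: per axis the gap between voxel i and j
# is max(0, |i - j| - 1) * pitch, so face-, edge- and corner-adjacent voxels
# have gap 0 and one empty voxel between them gives one pitch. `a`, `b` are
# (z,y,x) integer index matrices. Returns the minimum gap.
min_box_gap_nm <- function(a, b, voxel_size) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(NA_real_)
  vz <- voxel_size[["z"]]; vy <- voxel_size[["y"]]; vx <- voxel_size[["x"]]
  best <- Inf
  # loop over the smaller set, vectorise over the larger
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  for (k in seq_len(nrow(a))) {
    gz <- pmax(0, abs(b[, 1L] - a[k, 1L]) - 1) * vz
    gy <- pmax(0, abs(b[, 2L] - a[k, 2L]) - 1) * vy
    gx <- pmax(0, abs(b[, 3L] - a[k, 3L]) - 1) * vx
    d2 <- gx * gx + gy * gy + gz * gz
    m <- min(d2)
    if (m < best) best <- m
    if (best == 0) return(0)
  }
  sqrt(best)
}

# Minimum box gap between `idx` and the subset of `pts` within a bounding
# box of `idx` grown by `margin_nm` per axis (converted to voxels per axis,
# so anisotropy is honoured). Returns Inf when no point of `pts` lies inside
# the grown box; a finite return <= margin_nm is the exact global minimum
# (anything outside the box is farther than margin_nm by construction).
local_box_gap_nm <- function(idx, pts, voxel_size, margin_nm) {
  if (nrow(idx) == 0L || nrow(pts) == 0L) return(NA_real_)
  mz <- ceiling(margin_nm / voxel_size[["z"]]) + 1L
  my <- ceiling(margin_nm / voxel_size[["y"]]) + 1L
  mx <- ceiling(margin_nm / voxel_size[["x"]]) + 1L
  keep <- pts[, 1L] >= min(idx[, 1L]) - mz & pts[, 1L] <= max(idx[, 1L]) + mz &
    pts[, 2L] >= min(idx[, 2L]) - my & pts[, 2L] <= max(idx[, 2L]) + my &
    pts[, 3L] >= min(idx[, 3L]) - mx & pts[, 3L] <= max(idx[, 3L]) + mx
  if (!any(keep)) return(Inf)
  min_box_gap_nm(idx, pts[keep, , drop = FALSE], voxel_size)
}

# Distance from an nm point (x,y,z) to the nearest voxel box of an index set.
# Per axis: max(0, |p - centre| - pitch/2). Returns min over voxels, plus the
# row index of the argmin.
point_box_dist_nm <- function(p, idx, voxel_size) {
  if (nrow(idx) == 0L) return(list(dist = NA_real_, which = NA_integer_))
  gx <- pmax(0, abs(vox_centre_nm(idx[, 3L], voxel_size[["x"]]) - p[[1L]]) - voxel_size[["x"]] / 2)
  gy <- pmax(0, abs(vox_centre_nm(idx[, 2L], voxel_size[["y"]]) - p[[2L]]) - voxel_size[["y"]] / 2)
  gz <- pmax(0, abs(vox_centre_nm(idx[, 1L], voxel_size[["z"]]) - p[[3L]]) - voxel_size[["z"]] / 2)
  d2 <- gx * gx + gy * gy + gz * gz
  w <- which.min(d2)
  list(dist = sqrt(d2[w]), which = w)
}

# Dilate a (z,y,x) index set by one voxel in every direction (26-connectivity),
# clipped to the volume dimensions. Returns unique LINEAR indices (double, so
# volumes beyond 2^31 voxels are safe), suitable for x[lin] <- value.
dilate_lin_1 <- function(idx, dims) {
  if (nrow(idx) == 0L) return(numeric(0))
  out <- vector("list", 27L)
  s <- 0L
  for (dz in -1:1) {
    for (dy in -1:1) {
      for (dx in -1:1) {
        s <- s + 1L
        z <- idx[, 1L] + dz
        y <- idx[, 2L] + dy
        x <- idx[, 3L] + dx
        keep <- z >= 1L & z <= dims[1L] & y >= 1L & y <= dims[2L] &
          x >= 1L & x <= dims[3L]
        out[[s]] <- z[keep] + (y[keep] - 1L) * dims[1L] +
          (x[keep] - 1L) * as.double(dims[1L]) * dims[2L]
      }
    }
  }
  unique(unlist(out))
}

# Linear (1D) indices of a (z,y,x) index matrix into an array of dim dims.
idx_to_lin <- function(idx, dims) {
  idx[, 1L] + (idx[, 2L] - 1L) * dims[1L] + (idx[, 3L] - 1L) * as.double(dims[1L]) * dims[2L]
}

# Surface voxels of a logical mask: mask voxels with at least one
# 6-neighbour outside the mask (or on the volume border). Gap computations
# from outside an object only ever see its surface, so distance queries
# against large solid objects use this reduced set.
surface_of_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(FALSE, dim = d)
  if (all(d > 2L)) {
    core <- mask[2:(d[1L] - 1L), 2:(d[2L] - 1L), 2:(d[3L] - 1L)] &
      mask[1:(d[1L] - 2L), 2:(d[2L] - 1L), 2:(d[3L] - 1L)] &
      mask[3:d[1L], 2:(d[2L] - 1L), 2:(d[3L] - 1L)] &
      mask[2:(d[1L] - 1L), 1:(d[2L] - 2L), 2:(d[3L] - 1L)] &
      mask[2:(d[1L] - 1L), 3:d[2L], 2:(d[3L] - 1L)] &
      mask[2:(d[1L] - 1L), 2:(d[2L] - 1L), 1:(d[3L] - 2L)] &
      mask[2:(d[1L] - 1L), 2:(d[2L] - 1L), 3:d[3L]]
    interior[2:(d[1L] - 1L), 2:(d[2L] - 1L), 2:(d[3L] - 1L)] <- core
  }
  out <- which(mask & !interior, arr.ind = TRUE)
  colnames(out) <- c("z", "y", "x")
  unname_idx(out)
}

# Surface voxels of a sparse (z,y,x) index set: drop voxels whose six face
# neighbours are all in the set. Gap queries from outside only see the
# surface.
surface_of_idx <- function(idx, dims) {
  if (nrow(idx) <= 8L) return(idx)
  lin <- idx_to_lin(idx, dims)
  nz <- dims[1L]
  nyz <- as.double(dims[1L]) * dims[2L]
  interior <- ((lin + 1) %in% lin) & ((lin - 1) %in% lin) &
    ((lin + nz) %in% lin) & ((lin - nz) %in% lin) &
    ((lin + nyz) %in% lin) & ((lin - nyz) %in% lin)
  idx[!interior, , drop = FALSE]
}

# Moving average with partial windows at the edges (used for centre-line
# smoothing; window must be odd).
moving_average <- function(x, window) {
  stopifnot(window %% 2 == 1)
  h <- (window - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# Random unit vector in 3D (isotropic)
runit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v * v))
}

`%||%` <- rlang::`%||%`
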