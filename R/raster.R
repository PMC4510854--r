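# Internal rasterisation primitives for the synthetic generators. Geometry is
# specified in nm and rasterised onto the anisotropic voxel grid, so distance
# and size truths are exact in nm, independent of voxelisation.

# Voxel (z,y,x) index set of an axis-aligned ellipsoid.
# centre: c(x,y,z) nm; semi: c(x,y,z) nm; dims: volume dims (z,y,x);
# voxel_size: c(x,y,z) nm.
raster_ellipsoid <- function(centre, semi, dims, voxel_size) {
  rng <- function(c0, s, pitch, n) {
    lo <- max(1L, floor((c0 - s) / pitch) + 1L)
    hi <- min(as.integer(n), ceiling((c0 + s) / pitch))
    if (lo > hi) integer(0) else lo:hi
  }
  zi <- rng(centre[[3L]], semi[[3L]], voxel_size[["z"]], dims[1L])
  yi <- rng(centre[[2L]], semi[[2L]], voxel_size[["y"]], dims[2L])
  xi <- rng(centre[[1L]], semi[[1L]], voxel_size[["x"]], dims[3L])
  if (!length(zi) || !length(yi) || !length(xi)) {
    return(matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("z", "y", "x"))))
  }
  dz <- (vox_centre_nm(zi, voxel_size[["z"]]) - centre[[3L]]) / semi[[3L]]
  dy <- (vox_centre_nm(yi, voxel_size[["y"]]) - centre[[2L]]) / semi[[2L]]
  dx <- (vox_centre_nm(xi, voxel_size[["x"]]) - centre[[1L]]) / semi[[1L]]
  g <- expand.grid(z = seq_along(zi), y = seq_along(yi), x = seq_along(xi))
  keep <- dz[g$z]^2 + dy[g$y]^2 + dx[g$x]^2 <= 1
  out <- cbind(z = zi[g$z[keep]], y = yi[g$y[keep]], x = xi[g$x[keep]])
  out
}

raster_sphere <- function(centre, radius, dims, voxel_size) {
  raster_ellipsoid(centre, c(radius, radius, radius), dims, voxel_size)
}

# Voxel (z,y,x) index set of a straight segment from p to q (nm, c(x,y,z)),
# 1 voxel thick: every voxel visited by fine sampling along the segment.
raster_segment <- function(p, q, dims, voxel_size) {
  L <- sqrt(sum((q - p)^2))
  step <- min(voxel_size) / 4
  n <- max(2L, ceiling(L / step) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- p[[1L]] + t * (q[[1L]] - p[[1L]])
  ys <- p[[2L]] + t * (q[[2L]] - p[[2L]])
  zs <- p[[3L]] + t * (q[[3L]] - p[[3L]])
  idx <- cbind(
    z = nm_to_vox(zs, voxel_size[["z"]], dims[1L]),
    y = nm_to_vox(ys, voxel_size[["y"]], dims[2L]),
    x = nm_to_vox(xs, voxel_size[["x"]], dims[3L])
  )
  idx[!duplicated(idx), , drop = FALSE]
}

# Smooth random planar polyline of total arc length `length_nm`, starting at
# `start` (nm, c(x,y)), initial heading `theta0`, with gentle curvature.
# Returns a matrix of nm points (columns x, y) at `step_nm` spacing.
random_curve_2d <- function(start, length_nm, theta0 = runif(1, 0, 2 * pi),
                            step_nm = 40, wobble = 0.15) {
  n <- max(2L, ceiling(length_nm / step_nm) + 1L)
  theta <- numeric(n - 1L)
  theta[1L] <- theta0
  if (n > 2L) {
    dth <- rnorm(n - 2L, 0, wobble)
    theta[-1L] <- theta0 + cumsum(dth)
  }
  xs <- c(start[[1L]], start[[1L]] + cumsum(cos(theta) * step_nm))
  ys <- c(start[[2L]], start[[2L]] + cumsum(sin(theta) * step_nm))
  cbind(x = xs, y = ys)
}

# Arc length in nm of a polyline (columns x, y[, z])
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

# Rasterise a planar polyline (nm, columns x,y) onto section z (1-based) with
# an in-plane thickness of `thick_px` pixels (square brush). Returns a
# (z,y,x) index matrix.
raster_curve_section <- function(pts, z, thick_px, dims, voxel_size) {
  # sample finely along the polyline
  seg <- diff(pts)
  lens <- sqrt(rowSums(seg * seg))
  step <- min(voxel_size[["x"]], voxel_size[["y"]]) / 3
  xs <- ys <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    n <- max(2L, ceiling(lens[i] / step) + 1L)
    t <- seq(0, 1, length.out = n)
    xs[[i]] <- pts[i, 1L] + t * seg[i, 1L]
    ys[[i]] <- pts[i, 2L] + t * seg[i, 2L]
  }
  px <- nm_to_vox(unlist(xs), voxel_size[["x"]], dims[3L])
  py <- nm_to_vox(unlist(ys), voxel_size[["y"]], dims[2L])
  ny <- dims[2L]
  lin <- unique(py + (px - 1) * as.double(ny))
  # thicken with a square brush of side thick_px (offsets centred)
  if (thick_px > 1L) {
    off <- seq_len(thick_px) - 1L - (thick_px - 1L) %/% 2L
    py0 <- (lin - 1) %% ny + 1
    px0 <- (lin - 1) %/% ny + 1
    yy <- rep(py0, length(off)^2) + rep(rep(off, each = length(py0)), times = length(off))
    xx <- rep(px0, length(off)^2) + rep(off, each = length(py0) * length(off))
    keep <- yy >= 1 & yy <= ny & xx >= 1 & xx <= dims[3L]
    lin <- unique(yy[keep] + (xx[keep] - 1) * as.double(ny))
  }
  yv <- as.integer((lin - 1) %% ny + 1)
  xv <- as.integer((lin - 1) %/% ny + 1)
  cbind(z = rep(as.integer(z), length(lin)), y = yv, x = xv)
}
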