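# Point-counting stereology: grid construction, per-point classification
# against the label volume, and volume-fraction estimation with binomial
# standard errors. Grids are systematic-uniform-random by default: a seeded
# random offset inside one spacing cell removes alignment bias with the
# voxel raster; a fixed half-spacing offset mode gives exact reproducibility
# without a seed.

#' Build a stereology point grid
#'
#' Whole-cell mode places grids every `spacing_nm["z"]` along the sectioning
#' axis with `spacing_nm["x"]`/`spacing_nm["y"]` in-plane spacing (the
#' classic 200-nm pattern). Partial mode places a grid on every section
#' (spacing = one section) restricted to the 3-µm peri-nuclear window of a
#' [cell_frame()].
#'
#' @param lv A [label_volume()].
#' @param spacing_nm Named spacing `c(x=, y=, z=)` in nm; each must be at
#'   least the corresponding voxel size (sub-voxel sampling is meaningless).
#' @param mode `"whole"` or `"partial"`.
#' @param frame A [cell_frame()]; required for `mode = "partial"` (supplies
#'   the peri-nuclear window) and used to tag hemispheres in
#'   [classify_points()].
#' @param offset `"sur"` (systematic uniform random, needs `seed`) or
#'   `"fixed"` (half-spacing).
#' @param seed Seed for the random offset.
#' @return A tibble of class `point_grid` with columns `point_id`, `x_nm`,
#'   `y_nm`, `z_nm`; spacing, mode and offsets are kept as attributes.
#' @export
make_point_grid <- function(lv, spacing_nm = c(x = 200, y = 200, z = 200),
                            mode = c("whole", "partial"), frame = NULL,
                            offset = c("sur", "fixed"), seed = NULL) {
  mode <- match.arg(mode)
  offset <- match.arg(offset)
  spacing_nm <- unlist(spacing_nm)[c("x", "y", "z")]
  vs <- lv$voxel_size
  if (mode == "partial") spacing_nm[["z"]] <- vs[["z"]]
  if (any(spacing_nm < vs - 1e-9)) {
    abort(paste0(
      "Grid spacing below the voxel size (",
      paste(sprintf("%s=%g<%g", c("x", "y", "z"), spacing_nm, vs)[spacing_nm < vs],
        collapse = ", "
      ), "): sub-voxel sampling is meaningless."
    ))
  }
  ext <- volume_extent_nm(lv)
  off <- if (offset == "sur") {
    if (is.null(seed)) abort("`offset = \"sur\"` needs a seed for reproducibility.")
    set.seed(seed)
    runif(3) * spacing_nm
  } else {
    spacing_nm / 2
  }
  names(off) <- c("x", "y", "z")
  ax <- function(a) {
    v <- seq(off[[a]], ext[[a]], by = spacing_nm[[a]])
    v[v < ext[[a]]]
  }
  xs <- ax("x"); ys <- ax("y")
  zs <- if (mode == "partial") {
    if (is.null(frame)) abort("Partial mode needs a `frame` for the peri-nuclear window.")
    wz <- frame$infranuclear$window_z_range
    vox_centre_nm(wz[1L]:wz[2L], vs[["z"]])
  } else {
    ax("z")
  }
  g <- expand.grid(x_nm = xs, y_nm = ys, z_nm = zs, KEEP.OUT.ATTRS = FALSE)
  out <- tibble(point_id = seq_len(nrow(g)), x_nm = g$x_nm, y_nm = g$y_nm, z_nm = g$z_nm)
  structure(out,
    class = c("point_grid", class(out)),
    spacing_nm = spacing_nm, mode = mode, offset_nm = off
  )
}

#' Classify grid points against a label volume
#'
#' Each point takes the semantic class of its containing voxel, mapped
#' through the label table: organelle label wins over cytoplasm by
#' construction (labels are mutually exclusive). Terminals are external
#' boutons, so points landing on them count as `not_in_cell`. When a
#' [cell_frame()] is given, points are tagged with their hemispheres and
#' whether they fall in the infranuclear region and the peri-nuclear window.
#'
#' @param grid A [make_point_grid()] result (or any tibble with
#'   `x_nm`, `y_nm`, `z_nm`).
#' @param lv A [label_volume()].
#' @param frame Optional [cell_frame()].
#' @return The grid tibble with `class` (one of `not_in_cell`, `cytoplasm`,
#'   `nucleus`, `membrane`, `mitochondrion`, `ribbon`) plus hemisphere tags.
#' @export
classify_points <- function(grid, lv, frame = NULL) {
  ext <- volume_extent_nm(lv)
  if (any(grid$x_nm < 0 | grid$x_nm > ext[["x"]] |
    grid$y_nm < 0 | grid$y_nm > ext[["y"]] |
    grid$z_nm < 0 | grid$z_nm > ext[["z"]])) {
    abort("Grid contains points outside the volume extent.")
  }
  d <- dim(lv$voxels)
  iz <- nm_to_vox(grid$z_nm, lv$voxel_size[["z"]], d[1L])
  iy <- nm_to_vox(grid$y_nm, lv$voxel_size[["y"]], d[2L])
  ix <- nm_to_vox(grid$x_nm, lv$voxel_size[["x"]], d[3L])
  labs <- lv$voxels[cbind(iz, iy, ix)]
  lut <- rep("not_in_cell", max(lv$label_table$label) + 1L)
  cls <- lv$label_table$class
  cls_point <- dplyr::case_match(cls,
    "cell" ~ "cytoplasm",
    "terminal" ~ "not_in_cell",
    .default = cls
  )
  lut[lv$label_table$label + 1L] <- cls_point
  out <- dplyr::mutate(grid, class = lut[labs + 1L])
  if (!is.null(frame)) {
    tags <- frame_side_of(frame, out$x_nm, out$z_nm)
    out <- dplyr::bind_cols(out, tags)
    out$infranuclear <- iy <= frame$infranuclear$y_max_index
    wz <- frame$infranuclear$window_z_range
    out$in_window <- iz >= wz[1L] & iz <= wz[2L]
  }
  class(out) <- unique(c("point_grid", class(out)))
  for (a in c("spacing_nm", "mode", "offset_nm")) {
    attr(out, a) <- attr(grid, a)
  }
  out
}

#' Volume-fraction estimate from classified points
#'
#' The estimator of point-counting stereology: the volume fraction of a
#' structure equals the fraction of in-cell points hitting it,
#' `fraction = hits / points_in_cell`, with the binomial standard error
#' `sqrt(p (1 - p) / n)`. Optionally grouped (e.g. by hemisphere).
#'
#' @param points Classified points from [classify_points()], already
#'   filtered to the analysis region (e.g. infranuclear).
#' @param classes Classes counted as hits (default membrane +
#'   mitochondrion, the organelle network).
#' @param by Optional character vector of grouping columns.
#' @return A tibble with `n_points_count` (in-cell), `n_hits_count`,
#'   `fraction_frac` and `se_frac` per group.
#' @export
volume_fraction <- function(points, classes = c("membrane", "mitochondrion"),
                            by = NULL) {
  pts <- dplyr::filter(points, .data$class != "not_in_cell")
  if (nrow(pts) == 0L) abort("No in-cell points in the region.")
  if (!is.null(by)) pts <- group_by(pts, across(dplyr::all_of(by)))
  out <- summarise(pts,
    n_points_count = n(),
    n_hits_count = sum(.data$class %in% classes),
    .groups = "drop"
  )
  mutate(out,
    fraction_frac = .data$n_hits_count / .data$n_points_count,
    se_frac = sqrt(.data$fraction_frac * (1 - .data$fraction_frac) / .data$n_points_count)
  )
}

#' Per-class point fractions
#'
#' Long-format companion of [volume_fraction()]: the fraction of in-cell
#' points per class; fractions sum to 1 within each group.
#'
#' @inheritParams volume_fraction
#' @export
class_fractions <- function(points, by = NULL) {
  pts <- dplyr::filter(points, .data$class != "not_in_cell")
  if (nrow(pts) == 0L) abort("No in-cell points in the region.")
  grp <- c(by, "class")
  out <- pts |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(n_hits_count = n(), .groups = "drop_last") |>
    mutate(
      n_points_count = sum(.data$n_hits_count),
      fraction_frac = .data$n_hits_count / .data$n_points_count
    ) |>
    ungroup()
  out
}
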