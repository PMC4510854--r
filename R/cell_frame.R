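# Cell frame: dynamic centre line, hemisphere partitions, flatness profile,
# infranuclear extent. The longitudinal (apex-base) axis of the cell is y
# (in-plane); SBF-SEM sections advance along z across the cell width, so the
# flattened/rounded (and modiolar/pillar) split is an x-split guided by a
# per-section dynamic centre line, and the anterior/posterior split is a
# z-split at the cell's mid-section.

#' Dynamic centre line of a cell mask
#'
#' One point per z-section: the in-plane area centroid of the cell mask on
#' that section, smoothed with a moving average along z (default 5
#' sections). The centroid is the simplest asymmetry-aware centre; a cell
#' that bulges on one side pulls the line towards the bulge, which is what
#' makes the subsequent hemisphere split "dynamic" rather than a fixed
#' mid-plane. Equivariant under in-plane translation.
#'
#' @param lv A [label_volume()] (the `cell` class mask is used), or a
#'   logical 3D array.
#' @param smooth_window Odd integer, moving-average window in sections.
#' @param mask Optional precomputed cell-body mask (skips recomputation).
#' @return A tibble with one row per section where the cell is present:
#'   `z_index`, `z_nm`, `x_nm`, `y_nm` (smoothed centroid), `n_voxels`.
#' @export
dynamic_centre_line <- function(lv, smooth_window = 5L, mask = NULL) {
  mask <- mask %||% (if (inherits(lv, "label_volume")) cell_body_mask(lv) else lv)
  vs <- if (inherits(lv, "label_volume")) lv$voxel_size else c(x = 1, y = 1, z = 1)
  d <- dim(mask)
  nzs <- d[1L]
  n <- integer(nzs)
  xc <- yc <- numeric(nzs)
  x_nm <- vox_centre_nm(seq_len(d[3L]), vs[["x"]])
  y_nm <- vox_centre_nm(seq_len(d[2L]), vs[["y"]])
  for (iz in seq_len(nzs)) {
    m <- mask[iz, , ]
    n[iz] <- sum(m)
    if (n[iz] > 0L) {
      xc[iz] <- sum(colSums(m) * x_nm) / n[iz]
      yc[iz] <- sum(rowSums(m) * y_nm) / n[iz]
    }
  }
  present <- which(n > 0L)
  if (!length(present)) abort("Cell mask is empty.")
  inside <- min(present):max(present)
  gap <- setdiff(inside, present)
  if (length(gap)) {
    abort(paste0(
      "Cell mask is empty on section ", gap[1L],
      " although the cell spans sections ", min(present), "-", max(present), "."
    ))
  }
  tibble(
    z_index = inside,
    z_nm = vox_centre_nm(inside, vs[["z"]]),
    x_nm = moving_average(xc[inside], smooth_window),
    y_nm = moving_average(yc[inside], smooth_window),
    n_voxels = n[inside]
  )
}

# all labels that are spatially part of the cell body (everything except
# terminals, which are external boutons)
organelle_mask <- function(lv) {
  class_mask(lv, c("nucleus", "membrane", "mitochondrion", "ribbon", "vesicle", "tether"))
}

cell_body_mask <- function(lv) {
  class_mask(lv, c(
    "cell", "nucleus", "membrane", "mitochondrion", "ribbon",
    "vesicle", "tether"
  ))
}

#' Partition a cell mask into hemispheres
#'
#' `flat_round` (and its anatomical relabelling `mod_pillar`) splits the
#' cell along the y-z plane through the dynamic centre line: a voxel is in
#' the positive-x hemisphere when its x coordinate exceeds the centre line's
#' x at that section. `ant_post` splits along the x-y plane at the cell's
#' mid-section: the anterior hemisphere runs from the section where the
#' cell first appears up to the centre section, the posterior hemisphere
#' starts at the next section. The two masks always partition the cell mask
#' exactly (disjoint and exhaustive).
#'
#' @param lv A [label_volume()] or logical cell mask array.
#' @param centre_line Result of [dynamic_centre_line()]; computed if `NULL`.
#' @param axis One of `"flat_round"`, `"mod_pillar"`, `"ant_post"`.
#' @param flattened_side Which x side is the flattened one: `"x_high"` or
#'   `"x_low"` (decide with [flatness_profile()]).
#' @param flat_faces For `mod_pillar`: the anatomical side the flattened
#'   hemisphere faces (`"pillar"` or `"modiolar"`); supplied by the user, as
#'   orientation in the organ cannot be derived from a single cell.
#' @param anterior_low_z If `TRUE` the anterior hemisphere is the low-z half.
#' @return A named list of two logical arrays (e.g. `flattened`, `rounded`).
#' @export
partition_hemispheres <- function(lv, centre_line = NULL,
                                  axis = c("flat_round", "mod_pillar", "ant_post"),
                                  flattened_side = c("x_high", "x_low"),
                                  flat_faces = c("pillar", "modiolar"),
                                  anterior_low_z = TRUE) {
  if (is.character(axis) && length(axis) == 1L &&
    !axis %in% c("flat_round", "mod_pillar", "ant_post")) {
    abort(paste0("Unknown axis_choice '", axis, "'."))
  }
  axis <- match.arg(axis)
  flattened_side <- match.arg(flattened_side)
  flat_faces <- match.arg(flat_faces)
  mask <- if (inherits(lv, "label_volume")) cell_body_mask(lv) else lv
  vs <- if (inherits(lv, "label_volume")) lv$voxel_size else c(x = 1, y = 1, z = 1)
  d <- dim(mask)
  if (axis %in% c("flat_round", "mod_pillar")) {
    if (is.null(centre_line)) centre_line <- dynamic_centre_line(lv)
    xc <- rep(NA_real_, d[1L])
    xc[centre_line$z_index] <- centre_line$x_nm
    x_nm <- vox_centre_nm(seq_len(d[3L]), vs[["x"]])
    hi <- array(FALSE, dim = d)
    for (iz in which(!is.na(xc))) {
      hi[iz, , ] <- mask[iz, , ] & rep(x_nm > xc[iz], each = d[2L])
    }
    lo <- mask & !hi
    sides <- if (flattened_side == "x_high") {
      list(flattened = hi, rounded = lo)
    } else {
      list(flattened = lo, rounded = hi)
    }
    if (axis == "mod_pillar") {
      names(sides) <- if (flat_faces == "pillar") {
        c("pillar", "modiolar")
      } else {
        c("modiolar", "pillar")
      }
      sides <- sides[c("modiolar", "pillar")]
    }
    sides
  } else {
    zs <- which(rowSums(mask, dims = 1L) > 0)
    z_mid <- floor((min(zs) + max(zs)) / 2)
    ant <- array(FALSE, dim = d)
    ant[seq_len(z_mid), , ] <- mask[seq_len(z_mid), , ]
    post <- mask & !ant
    if (anterior_low_z) list(anterior = ant, posterior = post)
    else list(anterior = post, posterior = ant)
  }
}

#' Flatness profile of a cell
#'
#' Quantifies the side asymmetry of the cell the way it is done on section
#' images: on the widest z-section, a line parallel to the cell's long axis
#' is placed tangent to the maximal lateral extent of each side, and the
#' mean distance from the line to the cell boundary is computed in depth
#' bands below the neck. The side with the smaller mean deviation is the
#' flattened side.
#'
#' @param lv A [label_volume()] (needs `cell`, and `nucleus` for automatic
#'   neck detection) or logical cell mask (then supply `neck_y_nm`).
#' @param bands_um List of `c(lo, hi)` depth bands in µm below the neck.
#' @param neck_y_nm Longitudinal position of the neck; if `NULL` it is
#'   detected as the section of minimal cross-sectional area above the
#'   nucleus.
#' @param z_sections Sections to measure on; default the single widest one.
#' @param mask Optional precomputed cell-body mask (skips recomputation).
#' @return A tibble of class `flatness_profile`: `side`, `band_lo_um`,
#'   `band_hi_um`, `mean_dev_nm`, `n_rows`, with attributes
#'   `flatter_side` (`"x_high"`/`"x_low"`), `tie` flag and `neck_y_nm`.
#' @export
flatness_profile <- function(lv, bands_um = list(c(1, 4), c(5, 7), c(7, 11)),
                             neck_y_nm = NULL, z_sections = NULL, mask = NULL) {
  mask <- mask %||% (if (inherits(lv, "label_volume")) cell_body_mask(lv) else lv)
  vs <- if (inherits(lv, "label_volume")) lv$voxel_size else c(x = 1, y = 1, z = 1)
  d <- dim(mask)
  if (is.null(neck_y_nm)) {
    if (!inherits(lv, "label_volume") || !any(lv$label_table$class == "nucleus")) {
      abort("Supply `neck_y_nm` or a volume with a nucleus for neck detection.")
    }
    nuc <- class_mask(lv, "nucleus")
    nuc_y_max <- max(which(rowSums(colSums(nuc, dims = 1L)) > 0))
    area_y <- rowSums(colSums(mask, dims = 1L))
    above <- which(seq_len(d[2L]) > nuc_y_max & area_y > 0)
    if (!length(above)) abort("No cell sections above the nucleus; cannot find the neck.")
    neck_idx <- above[which.min(area_y[above])]
    neck_y_nm <- vox_centre_nm(neck_idx, vs[["y"]])
  }
  band_rows <- lapply(bands_um, function(b) {
    lo_nm <- neck_y_nm - b[2L] * 1000
    hi_nm <- neck_y_nm - b[1L] * 1000
    rows <- which(vox_centre_nm(seq_len(d[2L]), vs[["y"]]) >= lo_nm &
      vox_centre_nm(seq_len(d[2L]), vs[["y"]]) <= hi_nm)
    rows
  })
  all_rows <- sort(unique(unlist(band_rows)))
  cell_rows <- which(rowSums(colSums(mask, dims = 1L)) > 0)
  if (!length(all_rows) || min(all_rows) < min(cell_rows) - 1L) {
    if (!all(unlist(band_rows) %in% cell_rows)) {
      abort("A depth band exceeds the cell's longitudinal extent.")
    }
  }
  if (is.null(z_sections)) {
    per_z <- rowSums(mask, dims = 1L)
    z_sections <- which.max(per_z)
  }
  x_nm <- vox_centre_nm(seq_len(d[3L]), vs[["x"]])
  out <- list()
  for (iz in z_sections) {
    m <- mask[iz, , ] # (y, x)
    xhi <- apply(m, 1L, function(r) if (any(r)) max(x_nm[r]) else NA_real_)
    xlo <- apply(m, 1L, function(r) if (any(r)) min(x_nm[r]) else NA_real_)
    rows_ok <- all_rows[!is.na(xhi[all_rows])]
    if (!length(rows_ok)) next
    tan_hi <- max(xhi[rows_ok])
    tan_lo <- min(xlo[rows_ok])
    for (bi in seq_along(bands_um)) {
      rows <- intersect(band_rows[[bi]], rows_ok)
      if (!length(rows)) next
      out[[length(out) + 1L]] <- tibble(
        z_index = iz,
        side = c("x_high", "x_low"),
        band_lo_um = bands_um[[bi]][1L],
        band_hi_um = bands_um[[bi]][2L],
        mean_dev_nm = c(mean(tan_hi - xhi[rows]), mean(xlo[rows] - tan_lo)),
        n_rows = length(rows)
      )
    }
  }
  if (!length(out)) abort("No usable boundary rows inside the requested bands.")
  prof <- bind_rows(out) |>
    group_by(.data$side, .data$band_lo_um, .data$band_hi_um) |>
    summarise(
      mean_dev_nm = stats::weighted.mean(.data$mean_dev_nm, .data$n_rows),
      n_rows = sum(.data$n_rows), .groups = "drop"
    )
  side_means <- prof |>
    group_by(.data$side) |>
    summarise(m = mean(.data$mean_dev_nm), .groups = "drop")
  tie <- abs(diff(side_means$m)) < 1e-9
  flatter <- side_means$side[which.min(side_means$m)]
  structure(
    prof,
    class = c("flatness_profile", class(prof)),
    flatter_side = flatter, tie = tie, neck_y_nm = neck_y_nm,
    z_sections = z_sections
  )
}

#' Infranuclear region of a cell
#'
#' The infranuclear mask contains every cell voxel basal (lower y) to the
#' nucleus' basal-most extent. Also reports the 3-µm peri-nuclear window of
#' sections (1.5 µm either side of the nucleus' z midline) used for
#' partial-volume stereology.
#'
#' @param lv A [label_volume()] with a nucleus.
#' @param mask Optional precomputed cell-body mask (skips recomputation).
#' @return A list: `mask` (logical array), `y_max_index`, `y_boundary_nm`,
#'   `window_z_range` (section index range), `window_half_um`.
#' @export
infranuclear_mask <- function(lv, mask = NULL) {
  if (!any(lv$label_table$class == "nucleus")) {
    abort("No nucleus present: the infranuclear region is undefined.")
  }
  nuc <- class_mask(lv, "nucleus")
  if (!any(nuc)) abort("No nucleus present: the infranuclear region is undefined.")
  mask <- mask %||% cell_body_mask(lv)
  d <- dim(mask)
  nuc_rows <- which(rowSums(colSums(nuc, dims = 1L)) > 0)
  y_min_nuc <- min(nuc_rows)
  out <- array(FALSE, dim = d)
  if (y_min_nuc > 1L) {
    rows <- seq_len(y_min_nuc - 1L)
    out[, rows, ] <- mask[, rows, ]
  }
  nuc_z <- which(rowSums(nuc, dims = 1L) > 0)
  zmid_nm <- mean(vox_centre_nm(nuc_z, lv$voxel_size[["z"]]))
  half <- 1500
  wz <- c(
    nm_to_vox(zmid_nm - half + lv$voxel_size[["z"]] / 2, lv$voxel_size[["z"]], d[1L]),
    nm_to_vox(zmid_nm + half - lv$voxel_size[["z"]] / 2, lv$voxel_size[["z"]], d[1L])
  )
  list(
    mask = out,
    y_max_index = y_min_nuc - 1L,
    y_boundary_nm = (y_min_nuc - 1L) * lv$voxel_size[["y"]],
    window_z_range = wz,
    window_half_um = 1.5
  )
}

#' Establish the full cell frame
#'
#' Convenience orchestration: dynamic centre line, flatness profile (the
#' flatter side names the `flattened` hemisphere), mid-section for the
#' anterior/posterior split, and the infranuclear extent. Depth bands are
#' scaled to the available cell length when the default 1-11 µm pattern does
#' not fit.
#'
#' @inheritParams partition_hemispheres
#' @param bands_um Depth bands for the flatness profile, or `NULL` to scale
#'   the default pattern to the cell's length below the neck.
#' @return An object of class `cell_frame`.
#' @export
cell_frame <- function(lv, flat_faces = c("pillar", "modiolar"),
                       anterior_low_z = TRUE, bands_um = NULL) {
  flat_faces <- match.arg(flat_faces)
  mask <- cell_body_mask(lv)
  cl <- dynamic_centre_line(lv, mask = mask)
  infra <- infranuclear_mask(lv, mask = mask)
  d <- dim(mask)
  # neck detection as in flatness_profile
  nuc <- class_mask(lv, "nucleus")
  nuc_y_max <- max(which(rowSums(colSums(nuc, dims = 1L)) > 0))
  area_y <- rowSums(colSums(mask, dims = 1L))
  above <- which(seq_len(d[2L]) > nuc_y_max & area_y > 0)
  neck_idx <- if (length(above)) above[which.min(area_y[above])] else nuc_y_max
  neck_y_nm <- vox_centre_nm(neck_idx, lv$voxel_size[["y"]])
  if (is.null(bands_um)) {
    cell_rows <- which(area_y > 0)
    depth_um <- (neck_y_nm - vox_centre_nm(min(cell_rows), lv$voxel_size[["y"]])) / 1000
    f <- min(1, depth_um / 11.5)
    bands_um <- lapply(list(c(1, 4), c(5, 7), c(7, 11)), function(b) b * f)
  }
  prof <- flatness_profile(lv, bands_um = bands_um, neck_y_nm = neck_y_nm, mask = mask)
  zs <- which(rowSums(mask, dims = 1L) > 0)
  structure(
    list(
      centre_line = cl,
      flatness = prof,
      flattened_side = attr(prof, "flatter_side"),
      flat_faces = flat_faces,
      anterior_low_z = anterior_low_z,
      z_mid_index = floor((min(zs) + max(zs)) / 2),
      neck_y_nm = neck_y_nm,
      infranuclear = infra[c("y_max_index", "y_boundary_nm", "window_z_range")],
      voxel_size = lv$voxel_size,
      dims = d
    ),
    class = "cell_frame"
  )
}

#' @export
print.cell_frame <- function(x, ...) {
  cat("<cell_frame>\n")
  cat(sprintf("  flattened side: %s (faces %s)\n", x$flattened_side, x$flat_faces))
  cat(sprintf(
    "  infranuclear: y < %.2f um; peri-nuclear window: sections %d-%d\n",
    x$infranuclear$y_boundary_nm / 1000,
    x$infranuclear$window_z_range[1L], x$infranuclear$window_z_range[2L]
  ))
  cat(sprintf("  neck at y = %.2f um; mid-section z = %d\n", x$neck_y_nm / 1000, x$z_mid_index))
  invisible(x)
}

# hemisphere tags of nm points under a cell_frame (used by stereology and
# terminal statistics)
frame_side_of <- function(frame, x_nm, z_nm) {
  zi <- nm_to_vox(z_nm, frame$voxel_size[["z"]], frame$dims[1L])
  xc <- rep(NA_real_, frame$dims[1L])
  xc[frame$centre_line$z_index] <- frame$centre_line$x_nm
  # sections beyond the cell keep the nearest defined centre value
  xc <- fill_nearest(xc)
  hi <- x_nm > xc[zi]
  flat_hi <- frame$flattened_side == "x_high"
  side <- ifelse(hi == flat_hi, "flattened", "rounded")
  ap_low <- zi <= frame$z_mid_index
  ap <- ifelse(ap_low == frame$anterior_low_z, "anterior", "posterior")
  radial <- ifelse(
    side == "flattened",
    ifelse(frame$flat_faces == "pillar", "pillar", "modiolar"),
    ifelse(frame$flat_faces == "pillar", "modiolar", "pillar")
  )
  tibble(hemi_fr = side, hemi_ap = ap, hemi_mp = radial)
}

fill_nearest <- function(x) {
  ok <- which(!is.na(x))
  if (!length(ok)) return(x)
  idx <- findInterval(seq_along(x), ok)
  idx[idx == 0L] <- 1L
  lower <- ok[idx]
  upper <- ok[pmin(idx + 1L, length(ok))]
  pick <- ifelse(
    abs(seq_along(x) - lower) <= abs(upper - seq_along(x)), lower, upper
  )
  x[pick]
}
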