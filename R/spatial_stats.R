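# Association, density, distance and distribution statistics linking
# mitochondria, sheets, ribbons and terminals. All distances are
# anisotropy-aware: voxel indices are scaled by the per-axis voxel size, and
# surface-to-surface gaps use the voxel-box convention (adjacent voxels have
# gap 0, one empty voxel between two objects is one pitch). Ribbon
# measurements use the ribbon's approximate centre, everything else uses
# voxel surfaces.

# expanding local search for the minimal box gap between an object and a
# target voxel set; a result is only trusted when it lies inside the search
# radius (otherwise a closer target could still hide beyond the box)
expanding_gap <- function(idx, target, voxel_size,
                          margins_nm = c(50, 150, 500, 2000)) {
  for (m in margins_nm) {
    g <- local_box_gap_nm(idx, target, voxel_size, margin_nm = m)
    if (is.na(g)) return(NA_real_)
    if (is.finite(g) && g <= m) return(g)
  }
  min_box_gap_nm(idx, target, voxel_size)
}

#' Mitochondrion-membrane association
#'
#' For every mitochondrion, the minimal surface-to-surface gap (nm) to any
#' membrane strand, whether it is "in close association" (gap at most
#' `gap_threshold_nm`; the default, one in-plane voxel, operationalises
#' "no visible gap" on section images), the sheets it touches at that
#' criterion, and - when a sheet classification is supplied - how many
#' sheet types it is associated with.
#'
#' @param lv A [label_volume()] with mitochondria and membranes.
#' @param gap_threshold_nm Association gap threshold, nm; reported in the
#'   output attributes.
#' @param sheet_map Optional integer array from membrane voxel to sheet id
#'   (internal result of sheet assembly, see [link_strands()]); enables
#'   `sheet_ids` and `n_types_touched_count`.
#' @param sheet_classes Optional tibble `sheet_id` -> `class`.
#' @return A tibble, one row per mitochondrion: `mito_id`, `label`,
#'   `min_gap_nm`, `associated`, `n_sheets_count`, `n_types_touched_count`,
#'   `sheet_ids` (list). Attribute `gap_threshold_nm` records the
#'   criterion. Summarise with [association_summary()].
#' @export
mito_membrane_association <- function(lv, gap_threshold_nm = NULL,
                                      sheet_map = NULL, sheet_classes = NULL) {
  gap_threshold_nm <- gap_threshold_nm %||% lv$voxel_size[["x"]]
  mito_labels <- labels_of_class(lv, "mitochondrion")
  if (!length(mito_labels)) abort("No mitochondria in the volume.")
  memb <- label_idx(lv, labels_of_class(lv, "membrane"))
  if (nrow(memb) == 0L) abort("No membrane strands in the volume.")
  vs <- lv$voxel_size
  all_idx <- label_idx(lv, mito_labels)
  all_lab <- lv$voxels[all_idx]
  d <- dim(lv$voxels)
  res <- vector("list", length(mito_labels))
  for (i in seq_along(mito_labels)) {
    idx <- surface_of_idx(
      all_idx[all_lab == mito_labels[i], , drop = FALSE], d
    )
    g <- expanding_gap(idx, memb, vs)
    sheet_ids <- integer(0)
    if (!is.null(sheet_map) && is.finite(g) && g <= gap_threshold_nm) {
      # membrane voxels within the threshold of this mitochondrion
      marg <- ceiling(gap_threshold_nm / min(vs)) + 2L
      lo <- c(min(idx[, 1L]), min(idx[, 2L]), min(idx[, 3L])) - marg
      hi <- c(max(idx[, 1L]), max(idx[, 2L]), max(idx[, 3L])) + marg
      keep <- memb[, 1L] >= lo[1L] & memb[, 1L] <= hi[1L] &
        memb[, 2L] >= lo[2L] & memb[, 2L] <= hi[2L] &
        memb[, 3L] >= lo[3L] & memb[, 3L] <= hi[3L]
      near <- memb[keep, , drop = FALSE]
      if (nrow(near)) {
        gv <- vapply(seq_len(nrow(near)), function(k) {
          min_box_gap_nm(near[k, , drop = FALSE], idx, vs)
        }, numeric(1))
        hit <- near[gv <= gap_threshold_nm, , drop = FALSE]
        if (nrow(hit)) sheet_ids <- sort(unique(sheet_map[hit]))
      }
    }
    res[[i]] <- tibble(
      mito_id = i, label = mito_labels[i],
      min_gap_nm = g,
      associated = is.finite(g) & g <= gap_threshold_nm,
      n_sheets_count = length(sheet_ids),
      sheet_ids = list(sheet_ids)
    )
  }
  out <- bind_rows(res)
  if (!is.null(sheet_classes)) {
    out$n_types_touched_count <- vapply(out$sheet_ids, function(s) {
      length(unique(sheet_classes$class[match(s, sheet_classes$sheet_id)]))
    }, integer(1))
  }
  structure(out, gap_threshold_nm = gap_threshold_nm)
}

#' Summarise an association table
#'
#' @param assoc Result of [mito_membrane_association()].
#' @return One-row tibble: number of mitochondria, associated fraction, and
#'   (when types were resolved) the fraction of associated mitochondria
#'   touching exactly one sheet type.
#' @export
association_summary <- function(assoc) {
  out <- tibble(
    n_mito_count = nrow(assoc),
    associated_frac = mean(assoc$associated),
    se_frac = sqrt(mean(assoc$associated) * (1 - mean(assoc$associated)) / nrow(assoc))
  )
  if ("n_types_touched_count" %in% names(assoc)) {
    ass <- assoc[assoc$associated, ]
    out$single_type_frac <- mean(ass$n_types_touched_count == 1L)
  }
  out
}

#' Mitochondrial density per sheet type
#'
#' Only mitochondria associated with exactly one sheet type are counted
#' (mitochondria touching several types cannot be attributed). Density is
#' count divided by the total area of that type.
#'
#' @param assoc Result of [mito_membrane_association()] with types resolved.
#' @param type_areas Tibble `class` -> `total_area_um2` (e.g. from
#'   [tidy()] of a [classify_sheets()] result).
#' @param sheet_classes Tibble `sheet_id` -> `class`.
#' @return Tibble: `class`, `n_mito_count`, `total_area_um2`,
#'   `density_per_um2`.
#' @export
mito_density_per_type <- function(assoc, type_areas, sheet_classes) {
  if (!"n_types_touched_count" %in% names(assoc)) {
    abort("Association table lacks sheet types; rerun with `sheet_map`/`sheet_classes`.")
  }
  if (any(type_areas$total_area_um2 <= 0)) abort("Zero type area.")
  single <- assoc[assoc$associated & assoc$n_types_touched_count == 1L, ]
  cls <- vapply(single$sheet_ids, function(s) {
    unique(sheet_classes$class[match(s, sheet_classes$sheet_id)])[1L]
  }, character(1))
  counts <- table(factor(cls, levels = type_areas$class))
  type_areas |>
    mutate(
      n_mito_count = as.integer(counts[.data$class]),
      density_per_um2 = .data$n_mito_count / .data$total_area_um2
    ) |>
    select("class", "n_mito_count", "total_area_um2", "density_per_um2")
}

#' Ribbon-to-sheet distances per sheet type
#'
#' Distance from the approximate centre of each ribbon (centroid of its
#' voxels) to the closest voxel surface of the nearest sheet of each type.
#' A type with no sheets yields a missing distance, never an infinite one.
#'
#' @param lv A [label_volume()] with ribbons and membranes.
#' @param sheet_map Membrane-voxel -> sheet-id array (see [link_strands()]).
#' @param sheet_classes Tibble `sheet_id` -> `class`.
#' @return A tibble in long form: `ribbon_id`, `label`, `class`,
#'   `distance_nm`, plus `nearest_class` repeated per ribbon.
#' @export
ribbon_to_sheet_distances <- function(lv, sheet_map, sheet_classes) {
  rib_labels <- labels_of_class(lv, "ribbon")
  if (!length(rib_labels)) abort("No ribbons in the volume.")
  vs <- lv$voxel_size
  types <- sort(unique(sheet_classes$class))
  # per-type voxel index sets
  memb_idx <- which(sheet_map > 0L)
  sheet_of <- sheet_map[memb_idx]
  cls_of <- sheet_classes$class[match(sheet_of, sheet_classes$sheet_id)]
  d <- dim(lv$voxels)
  zyx <- cbind(
    z = as.integer((memb_idx - 1) %% d[1L] + 1),
    y = as.integer(((memb_idx - 1) %/% d[1L]) %% d[2L] + 1),
    x = as.integer((memb_idx - 1) %/% (as.double(d[1L]) * d[2L]) + 1)
  )
  cents <- label_centroids_nm(lv, rib_labels)
  out <- list()
  for (i in seq_along(rib_labels)) {
    cen <- c(x = cents$x_nm[i], y = cents$y_nm[i], z = cents$z_nm[i])
    dists <- vapply(types, function(tp) {
      sel <- zyx[cls_of == tp, , drop = FALSE]
      if (nrow(sel) == 0L) return(NA_real_)
      point_box_dist_nm(c(cen[["x"]], cen[["y"]], cen[["z"]]), sel, vs)$dist
    }, numeric(1), USE.NAMES = FALSE)
    nearest <- if (all(is.na(dists))) NA_character_ else types[which.min(dists)]
    out[[i]] <- tibble(
      ribbon_id = i, label = rib_labels[i], class = types,
      distance_nm = dists, nearest_class = nearest
    )
  }
  bind_rows(out)
}

#' Terminal distribution across hemispheres
#'
#' Terminal positions (sphere centres = label centroids) are assigned to
#' hemispheres through the cell frame; reports per-pair counts and the
#' terminal with the maximal longitudinal distance from the basal pole,
#' with the anatomical (modiolar/pillar) side it sits on. Longitudinal
#' position is measured along the straight y axis.
#'
#' @param lv A [label_volume()] with terminals.
#' @param frame A [cell_frame()].
#' @return A tibble of per-terminal records (`terminal_id`, `label`,
#'   hemisphere tags, `y_from_base_nm`) with attributes `counts` (tibble)
#'   and `extremum` (one-row tibble).
#' @export
terminal_distribution <- function(lv, frame) {
  t_labels <- labels_of_class(lv, "terminal")
  if (!length(t_labels)) abort("No terminals in the volume.")
  cell_rows <- which(apply(cell_body_mask(lv), 2L, any))
  y_base_nm <- vox_centre_nm(min(cell_rows), lv$voxel_size[["y"]])
  cent <- label_centroids_nm(lv, t_labels)
  tags <- frame_side_of(frame, cent$x_nm, cent$z_nm)
  rec <- bind_cols(
    tibble(
      terminal_id = seq_along(t_labels), label = t_labels,
      x_nm = cent$x_nm, y_nm = cent$y_nm, z_nm = cent$z_nm,
      y_from_base_nm = cent$y_nm - y_base_nm
    ),
    tags
  )
  counts <- bind_rows(
    rec |> dplyr::count(.data$hemi_fr) |> dplyr::rename(hemisphere = "hemi_fr"),
    rec |> dplyr::count(.data$hemi_mp) |> dplyr::rename(hemisphere = "hemi_mp")
  )
  extremum <- rec[which.max(rec$y_from_base_nm), ]
  structure(rec, counts = counts, extremum = extremum)
}

#' Volume and membrane-area share of a sub-region
#'
#' For a region of interest (e.g. the envelope of the large flattened-side
#' sheet), returns the region's share of the cytoplasm volume and of the
#' total membrane sheet area. Sheet area is attributed by the fraction of
#' each sheet's membrane voxels lying inside the region.
#'
#' @param region_mask Logical array, subset of `cytoplasm_mask`.
#' @param cytoplasm_mask Logical array of the analysis cytoplasm (e.g. the
#'   infranuclear cell mask).
#' @param sheets [sheet_area()] result (needs `area_um2`).
#' @param sheet_map Membrane-voxel -> sheet-id array.
#' @return One-row tibble: `volume_share_frac`, `area_share_frac`.
#' @export
region_membrane_share <- function(region_mask, cytoplasm_mask, sheets, sheet_map) {
  if (!any(region_mask)) abort("Empty region.")
  if (any(region_mask & !cytoplasm_mask)) {
    abort("Region must be a subset of the cytoplasm mask.")
  }
  vol_share <- sum(region_mask) / sum(cytoplasm_mask)
  memb_idx <- which(sheet_map > 0L)
  sheet_of <- sheet_map[memb_idx]
  inreg <- region_mask[memb_idx]
  frac_in <- tapply(inreg, sheet_of, mean)
  f <- rep(0, nrow(sheets))
  f[match(as.integer(names(frac_in)), sheets$sheet_id)] <- as.numeric(frac_in)
  area_share <- sum(sheets$area_um2 * f) / sum(sheets$area_um2)
  tibble(volume_share_frac = vol_share, area_share_frac = area_share)
}
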