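# Tomogram-scale morphometry: tether (link) lengths by context, vesicle
# equivalent-sphere diameters, and between-context comparisons.

#' Measure one tether
#'
#' The tether's voxel skeleton is ordered along its principal axis and
#' measured surface-to-surface: the gap between the endpoint structures,
#' excluding any travel inside them (tether voxels only exist in the gap).
#' Two conventions are emitted: `length_nm` - the extent of the ordered
#' skeleton along its principal direction plus one voxel (half a voxel per
#' end, compensating the clipping of endpoint voxels at the structure
#' surfaces) - and `length_arc_nm`, the raw arc length of the ordered
#' voxel-centre polyline (upper bound; zig-zag inflation for oblique
#' lines). Endpoints are resolved to the structures touching the tether
#' (gap 0); context is classified from the endpoint kinds, with
#' vesicle-vesicle links within 100 nm of a ribbon surface assigned to the
#' ribbon context.
#'
#' @param lv A [label_volume()].
#' @param tether_label Label of the tether to measure.
#' @param ribbon_context_nm Cutoff for "at the ribbon", nm.
#' @return One-row tibble: `label`, `length_nm`, `length_arc_nm`,
#'   `end1_label`, `end2_label`, `end1_kind`, `end2_kind`, `context`,
#'   `attached_both_ends`.
#' @export
measure_link <- function(lv, tether_label, ribbon_context_nm = 100) {
  idx <- label_idx(lv, tether_label)
  if (nrow(idx) == 0L) abort(paste0("Tether label ", tether_label, " is empty."))
  rib_idx <- surface_of_mask(class_mask(lv, "ribbon"))
  measure_link_core(lv, idx, tether_label, rib_idx, ribbon_context_nm)
}

measure_link_core <- function(lv, idx, tether_label, rib_idx, ribbon_context_nm) {
  vs <- lv$voxel_size
  d <- dim(lv$voxels)
  nm <- idx_to_nm(idx, vs)
  # principal direction
  ctr <- colMeans(nm)
  dirv <- if (nrow(nm) > 1L) {
    pc <- stats::prcomp(nm, center = TRUE, scale. = FALSE)
    pc$rotation[, 1L]
  } else {
    c(1, 0, 0)
  }
  proj <- as.numeric((nm - matrix(ctr, nrow(nm), 3L, byrow = TRUE)) %*% dirv)
  ord <- order(proj)
  span <- max(proj) - min(proj)
  length_nm <- span + mean(vs)
  arc <- if (nrow(nm) > 1L) {
    dd <- diff(nm[ord, , drop = FALSE])
    sum(sqrt(rowSums(dd * dd))) + mean(vs)
  } else {
    mean(vs)
  }
  # structures touching the tether
  nb <- dilate_lin_1(idx, d)
  touched <- setdiff(unique(lv$voxels[nb]), c(0L, tether_label))
  touched <- touched[lv$label_table$class[match(touched, lv$label_table$label)] != "tether"]
  kinds <- lv$label_table$class[match(touched, lv$label_table$label)]
  # assign touching structures to the two ends by the projection of their
  # contact voxels (the structure voxels adjacent to the tether)
  end1 <- end2 <- NA_integer_
  if (length(touched)) {
    nb_lab <- lv$voxels[nb]
    nb_zyx <- cbind(
      z = as.integer((nb - 1) %% d[1L] + 1),
      y = as.integer(((nb - 1) %/% d[1L]) %% d[2L] + 1),
      x = as.integer((nb - 1) %/% (as.double(d[1L]) * d[2L]) + 1)
    )
    nb_nm <- idx_to_nm(nb_zyx, vs)
    nb_proj <- as.numeric((nb_nm - matrix(ctr, nrow(nb_nm), 3L, byrow = TRUE)) %*% dirv)
    pos <- vapply(touched, function(l) mean(nb_proj[nb_lab == l]), numeric(1))
    end1 <- touched[which.min(pos)]
    if (length(touched) > 1L) end2 <- touched[which.max(pos)]
  }
  kind_of <- function(l) {
    if (is.na(l)) return(NA_character_)
    lv$label_table$class[match(l, lv$label_table$label)]
  }
  k1 <- kind_of(end1); k2 <- kind_of(end2)
  ks <- sort(c(k1, k2))
  context <- NA_character_
  if (!any(is.na(c(k1, k2)))) {
    if (setequal(ks, c("membrane", "mitochondrion"))) {
      context <- "mito-RER"
    } else if (setequal(ks, c("membrane", "vesicle"))) {
      context <- "vesicle-RER"
    } else if (identical(ks, c("vesicle", "vesicle"))) {
      g <- if (nrow(rib_idx)) {
        gg <- local_box_gap_nm(idx, rib_idx, vs,
          margin_nm = ribbon_context_nm + 2 * min(vs)
        )
        if (is.na(gg)) Inf else gg
      } else {
        Inf
      }
      context <- if (is.finite(g) && g <= ribbon_context_nm) {
        "vesicle-vesicle@ribbon"
      } else {
        "vesicle-vesicle@RER"
      }
    } else if (setequal(ks, c("ribbon", "vesicle"))) {
      context <- "vesicle-ribbon"
    }
  }
  tibble(
    label = tether_label,
    length_nm = length_nm, length_arc_nm = arc,
    end1_label = end1, end2_label = end2,
    end1_kind = k1, end2_kind = k2,
    context = context,
    attached_both_ends = !is.na(end1) && !is.na(end2)
  )
}

#' Measure every tether in a volume
#'
#' @param lv A [label_volume()].
#' @param ribbon_context_nm Cutoff for the ribbon context, nm.
#' @return A tibble with one row per tether ([measure_link()] columns plus
#'   `link_id`).
#' @export
measure_links <- function(lv, ribbon_context_nm = 100) {
  tl <- labels_of_class(lv, "tether")
  if (!length(tl)) {
    return(tibble(
      link_id = integer(), label = integer(), length_nm = numeric(),
      length_arc_nm = numeric(), end1_label = integer(), end2_label = integer(),
      end1_kind = character(), end2_kind = character(), context = character(),
      attached_both_ends = logical()
    ))
  }
  # one pass over the volume for all tether voxels
  all_idx <- label_idx(lv, tl)
  labs <- lv$voxels[all_idx]
  rib_idx <- surface_of_mask(class_mask(lv, "ribbon"))
  out <- bind_rows(lapply(tl, function(l) {
    measure_link_core(lv, all_idx[labs == l, , drop = FALSE], l, rib_idx,
      ribbon_context_nm
    )
  }))
  mutate(out, link_id = dplyr::row_number(), .before = 1L)
}

#' Equivalent-sphere diameters of vesicles
#'
#' Diameter from the voxel volume `V` of each vesicle label:
#' `d = 2 (3V / 4 pi)^(1/3)`. Vesicles narrower than 2 voxels along any
#' axis are flagged unreliable. The location class is `at_RER` /
#' `at_ribbon` when the vesicle lies within `location_nm` of the membrane /
#' ribbon surface (the nearer one wins), otherwise `free`.
#'
#' @param lv A [label_volume()].
#' @param location_nm Location cutoff, nm.
#' @return Tibble: `vesicle_id`, `label`, `diameter_nm`, `n_voxels_count`,
#'   `location`, `reliable`.
#' @export
vesicle_diameters <- function(lv, location_nm = 100) {
  vlabs <- labels_of_class(lv, "vesicle")
  if (!length(vlabs)) abort("No vesicles in the volume.")
  vs <- lv$voxel_size
  vox_vol <- prod(vs)
  memb <- surface_of_mask(class_mask(lv, "membrane"))
  rib <- surface_of_mask(class_mask(lv, "ribbon"))
  all_idx <- label_idx(lv, vlabs)
  all_lab <- lv$voxels[all_idx]
  # vesicles are near-spherical: the surface gap to a structure is the
  # centre-to-structure distance minus the equivalent-sphere radius (exact
  # to within voxelisation)
  memb_nm <- if (nrow(memb)) idx_to_nm(memb, vs) else NULL
  rib_nm <- if (nrow(rib)) idx_to_nm(rib, vs) else NULL
  centre_gap <- function(cen, radius, target, t_nm) {
    if (is.null(t_nm)) return(Inf)
    marg_nm <- location_nm + radius + 3 * max(vs)
    lo <- cen - marg_nm; hi <- cen + marg_nm
    keep <- t_nm[, "x"] >= lo[1L] & t_nm[, "x"] <= hi[1L] &
      t_nm[, "y"] >= lo[2L] & t_nm[, "y"] <= hi[2L] &
      t_nm[, "z"] >= lo[3L] & t_nm[, "z"] <= hi[3L]
    if (!any(keep)) return(Inf)
    d <- point_box_dist_nm(cen, target[keep, , drop = FALSE], vs)$dist
    max(0, d - radius)
  }
  out <- lapply(seq_along(vlabs), function(i) {
    idx <- all_idx[all_lab == vlabs[i], , drop = FALSE]
    nvox <- nrow(idx)
    dnm <- 2 * (3 * nvox * vox_vol / (4 * pi))^(1 / 3)
    ext <- c(
      diff(range(idx[, 1L])) + 1L, diff(range(idx[, 2L])) + 1L,
      diff(range(idx[, 3L])) + 1L
    )
    cen <- colMeans(idx_to_nm(idx, vs))[c("x", "y", "z")]
    gm <- centre_gap(cen, dnm / 2, memb, memb_nm)
    gr <- centre_gap(cen, dnm / 2, rib, rib_nm)
    loc <- if (min(gm, gr) > location_nm) {
      "free"
    } else if (gr <= gm) "at_ribbon" else "at_RER"
    tibble(
      vesicle_id = i, label = vlabs[i], diameter_nm = dnm,
      n_voxels_count = nvox, location = loc,
      reliable = all(ext >= 2L)
    )
  })
  bind_rows(out)
}

#' Compare tether lengths between contexts
#'
#' Per-context mean +/- SE plus pairwise Games-Howell comparisons (when at
#' least two contexts have n >= 3), and an ordering summary naming the
#' shortest context and whether it is significantly shorter than every
#' other context.
#'
#' @param links A [measure_links()] table.
#' @param alpha Significance level for the ordering summary.
#' @param min_n Minimal per-context n to enter the tests.
#' @return An object of class `link_context_report`: list with
#'   `by_context`, `report` (a [run_group_tests()] result or `NULL`),
#'   `shortest_context`, `shortest_significant`.
#' @export
compare_contexts <- function(links, alpha = 0.05, min_n = 3L) {
  lk <- dplyr::filter(links, !is.na(.data$context))
  by_context <- lk |>
    group_by(.data$context) |>
    summarise(
      n_count = n(),
      mean_length_nm = mean(.data$length_nm),
      se_length_nm = stats::sd(.data$length_nm) / sqrt(n()),
      .groups = "drop"
    )
  eligible <- by_context$context[by_context$n_count >= min_n]
  report <- NULL
  shortest <- by_context$context[which.min(by_context$mean_length_nm)]
  shortest_sig <- NA
  if (length(eligible) >= 2L) {
    sub <- dplyr::filter(lk, .data$context %in% eligible)
    report <- run_group_tests(sub, "length_nm", "context",
      tests = c("anova", "games_howell", "kruskal")
    )
    if (!is.null(report$pairwise)) {
      pw <- report$pairwise
      inv <- pw$group1 == shortest | pw$group2 == shortest
      shortest_sig <- all(pw$p_value_p[inv] < alpha)
    }
  }
  structure(
    list(
      by_context = by_context, report = report,
      shortest_context = shortest, shortest_significant = shortest_sig,
      alpha = alpha
    ),
    class = "link_context_report"
  )
}

#' @export
print.link_context_report <- function(x, ...) {
  cat("<link_context_report>\n")
  print(x$by_context)
  cat(sprintf(
    "  shortest context: %s (significantly shorter than all others: %s)\n",
    x$shortest_context, format(x$shortest_significant)
  ))
  invisible(x)
}

#' @rdname compare_contexts
#' @param x A `link_context_report`.
#' @param ... Unused.
#' @export
tidy.link_context_report <- function(x, ...) {
  if (is.null(x$report)) return(tibble())
  generics::tidy(x$report)
}

#' @rdname compare_contexts
#' @export
glance.link_context_report <- function(x, ...) {
  x$by_context
}
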