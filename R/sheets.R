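# Membrane sheet assembly: per-section strands (in-plane 8-connected
# components of the membrane class), linkage of strands that lie directly
# above each other in adjacent sections, tube-model surface areas, and the
# Type 1/2/3 size classification.

#' Extract per-section membrane strands
#'
#' One strand per in-plane 8-connected component of the membrane class on
#' each section. Strand length is the geodesic diameter of the pixel set:
#' the longest shortest path through 8-neighbour steps weighted by their
#' physical nm length, which for a one-pixel-wide line equals the polyline
#' arc length (99 steps of 19 nm for a straight 100-pixel line).
#'
#' @param lv A [label_volume()].
#' @param z Optional integer vector of sections; default all.
#' @return A tibble: `strand_id`, `z_index`, `n_px_count`, `length_nm`,
#'   `centroid_x_nm`, `centroid_y_nm`, and `pixels` (list of (y,x) index
#'   matrices).
#' @export
extract_strands <- function(lv, z = NULL) {
  d <- dim(lv$voxels)
  z <- z %||% seq_len(d[1L])
  memb <- labels_of_class(lv, "membrane")
  vs <- lv$voxel_size
  out <- list()
  sid <- 0L
  for (iz in z) {
    sec <- lv$voxels[iz, , ]
    bin <- matrix(0L, nrow = nrow(sec), ncol = ncol(sec))
    bin[sec %in% memb] <- 1L
    if (!any(bin == 1L)) next
    cc <- bwlabel8(bin)
    ncc <- max(cc)
    for (k in seq_len(ncc)) {
      px <- which(cc == k, arr.ind = TRUE) # (y, x) since rows are y
      sid <- sid + 1L
      out[[sid]] <- tibble(
        strand_id = sid, z_index = iz, n_px_count = nrow(px),
        length_nm = strand_length_nm(px, vs),
        centroid_x_nm = mean(vox_centre_nm(px[, 2L], vs[["x"]])),
        centroid_y_nm = mean(vox_centre_nm(px[, 1L], vs[["y"]])),
        pixels = list(unname(px))
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      strand_id = integer(), z_index = integer(), n_px_count = integer(),
      length_nm = numeric(), centroid_x_nm = numeric(),
      centroid_y_nm = numeric(), pixels = list()
    ))
  }
  bind_rows(out)
}

# 8-connected 2D labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged afterwards.
bwlabel8 <- function(bin) {
  cc <- EBImage::bwlabel(bin)
  n <- max(cc)
  if (n <= 1L) return(cc)
  nr <- nrow(cc); ncl <- ncol(cc)
  pairs <- rbind(
    cbind(as.vector(cc[-nr, -ncl]), as.vector(cc[-1L, -1L])), # down-right
    cbind(as.vector(cc[-1L, -ncl]), as.vector(cc[-nr, -1L]))  # up-right
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], ,
    drop = FALSE
  ]
  if (nrow(pairs) == 0L) return(cc)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1L], to = pairs[, 2L]),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  memb <- igraph::components(g)$membership[as.character(seq_len(n))]
  remap <- c(0L, as.integer(memb))
  matrix(remap[cc + 1L], nrow = nr)
}

# geodesic diameter of a 2D pixel set (double-sweep Dijkstra over the
# 8-neighbour graph with physical step weights)
strand_length_nm <- function(px, vs) {
  n <- nrow(px)
  if (n == 1L) return(0)
  ny <- max(px[, 1L]) + 1L
  lin <- px[, 1L] + (px[, 2L] - 1L) * ny
  pos <- stats::setNames(seq_len(n), lin)
  shifts <- cbind(
    dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  wts <- sqrt((shifts[, 1L] * vs[["y"]])^2 + (shifts[, 2L] * vs[["x"]])^2)
  ef <- et <- integer(0)
  ew <- numeric(0)
  for (s in seq_len(8L)) {
    nl <- (px[, 1L] + shifts[s, 1L]) + (px[, 2L] + shifts[s, 2L] - 1L) * ny
    m <- pos[as.character(nl)]
    ok <- !is.na(m)
    ef <- c(ef, which(ok))
    et <- c(et, m[ok])
    ew <- c(ew, rep(wts[s], sum(ok)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  d1 <- igraph::distances(g, v = 1L)[1L, ]
  d1[!is.finite(d1)] <- -1
  u <- which.max(d1)
  d2 <- igraph::distances(g, v = u)[1L, ]
  d2[!is.finite(d2)] <- -1
  max(d2)
}

#' Link strands across adjacent sections into putative sheets
#'
#' Two strands belong to the same putative sheet when they lie directly
#' above each other in adjacent sections: their in-plane pixel sets overlap
#' by at least `overlap_min` pixels (default 1). Sheets are the connected
#' components of this strand-adjacency graph. A strand missing on one
#' section and resuming on the next does NOT bridge the gap. A
#' centroid-distance alternative rule (`method = "centroid"`, linking
#' strands whose in-plane centroids lie within `centroid_max_nm`) is
#' provided for sensitivity analysis.
#'
#' @param strands Result of [extract_strands()].
#' @param overlap_min Minimum in-plane pixel overlap (>= 0).
#' @param method `"overlap"` (default) or `"centroid"`.
#' @param centroid_max_nm Centroid distance cutoff for `method = "centroid"`.
#' @return A tibble of class `sheet_set`: `sheet_id`, `n_strands_count`,
#'   `z_first_index`, `z_last_index`, `total_length_nm`, `strand_ids`
#'   (list). Sheet ids are deterministic: sorted by total strand length
#'   (desc), then first section, then centroid x.
#' @export
link_strands <- function(strands, overlap_min = 1L,
                         method = c("overlap", "centroid"),
                         centroid_max_nm = 100) {
  method <- match.arg(method)
  if (overlap_min < 0) abort("`overlap_min` must be >= 0.")
  if (nrow(strands) == 0L) {
    return(structure(
      tibble(
        sheet_id = integer(), n_strands_count = integer(),
        z_first_index = integer(), z_last_index = integer(),
        total_length_nm = numeric(), strand_ids = list()
      ),
      class = c("sheet_set", class(tibble()))
    ))
  }
  edges <- strand_adjacency(strands, overlap_min, method, centroid_max_nm)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = strands$strand_id)
  )
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(strands$strand_id)]
  agg <- strands |>
    mutate(component = as.integer(comp)) |>
    group_by(.data$component) |>
    summarise(
      n_strands_count = n(),
      z_first_index = min(.data$z_index),
      z_last_index = max(.data$z_index),
      total_length_nm = sum(.data$length_nm),
      centroid_x_nm = mean(.data$centroid_x_nm),
      strand_ids = list(.data$strand_id),
      .groups = "drop"
    ) |>
    arrange(
      dplyr::desc(.data$total_length_nm), .data$z_first_index,
      .data$centroid_x_nm
    ) |>
    mutate(sheet_id = dplyr::row_number()) |>
    select(
      "sheet_id", "n_strands_count", "z_first_index", "z_last_index",
      "total_length_nm", "strand_ids"
    )
  structure(agg, class = c("sheet_set", class(agg)))
}

# adjacency edges between strands (by strand_id)
strand_adjacency <- function(strands, overlap_min = 1L,
                             method = c("overlap", "centroid"),
                             centroid_max_nm = 100) {
  method <- match.arg(method)
  zs <- sort(unique(strands$z_index))
  ef <- et <- integer(0)
  for (z1 in zs) {
    a <- strands[strands$z_index == z1, ]
    b <- strands[strands$z_index == z1 + 1L, ]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    if (method == "overlap") {
      ny <- 1L + max(
        vapply(a$pixels, function(p) max(p[, 1L]), integer(1)),
        vapply(b$pixels, function(p) max(p[, 1L]), integer(1))
      )
      alin <- lapply(a$pixels, function(p) p[, 1L] + (p[, 2L] - 1L) * ny)
      blin <- lapply(b$pixels, function(p) p[, 1L] + (p[, 2L] - 1L) * ny)
      need <- max(1L, overlap_min)
      for (i in seq_len(nrow(a))) {
        for (j in seq_len(nrow(b))) {
          ov <- sum(alin[[i]] %in% blin[[j]])
          if (ov >= need) {
            ef <- c(ef, a$strand_id[i]); et <- c(et, b$strand_id[j])
          }
        }
      }
    } else {
      for (i in seq_len(nrow(a))) {
        dx <- b$centroid_x_nm - a$centroid_x_nm[i]
        dy <- b$centroid_y_nm - a$centroid_y_nm[i]
        hit <- which(sqrt(dx^2 + dy^2) <= centroid_max_nm)
        ef <- c(ef, rep(a$strand_id[i], length(hit)))
        et <- c(et, b$strand_id[hit])
      }
    }
  }
  data.frame(from = ef, to = et)
}

#' Surface area of sheets under the 50-nm tube model
#'
#' Strands are modelled as representative tubes of radius `tube_radius_nm`
#' (default 50 nm, the half-gap between consecutive sections). Two
#' conventions are emitted: `"sheet_face"` (default) takes the area of the
#' implied sheet face, strand length x section gap, summed over member
#' strands; `"tube_surface"` takes the full tube lateral surface
#' `2 pi r x length`. The mode is carried in the output so no area leaves
#' the package without its convention.
#'
#' @param sheets A [link_strands()] result.
#' @param strands The matching [extract_strands()] tibble.
#' @param lv The source [label_volume()] (for the section gap).
#' @param tube_radius_nm Tube radius, nm.
#' @param mode `"sheet_face"` or `"tube_surface"`.
#' @return `sheets` with columns `area_um2` and `area_mode` added.
#' @export
sheet_area <- function(sheets, strands, lv, tube_radius_nm = 50,
                       mode = c("sheet_face", "tube_surface")) {
  if (is.character(mode) && length(mode) == 1L &&
    !mode %in% c("sheet_face", "tube_surface")) {
    abort(paste0("Unknown area mode '", mode, "'."))
  }
  mode <- match.arg(mode)
  dz <- lv$voxel_size[["z"]]
  len <- sheets$total_length_nm
  area_nm2 <- switch(mode,
    sheet_face = len * dz,
    tube_surface = 2 * pi * tube_radius_nm * len
  )
  mutate(sheets, area_um2 = area_nm2 / 1e6, area_mode = mode)
}

#' Classify sheets into Type 1 / 2 / 3 size classes
#'
#' The size distribution of membrane sheets splits into a handful of very
#' large sheets (Type 1), a small population of intermediate sheets forming
#' the flat portion of the sorted-area curve (Type 2), and a large
#' population of very small sheets forming its steep portion (Type 3).
#' `method = "largest_gap"` finds the Type 1 boundary as the largest gap in
#' log-area among the top order statistics (at most `max_type1` sheets),
#' and the Type 2/3 boundary as the elbow between the flat and steep
#' regions: the split of the remaining sorted log-areas that minimises the
#' total squared error of two independent straight-line fits.
#' `method = "manual"` applies two supplied thresholds.
#'
#' @param areas_um2 Numeric vector of sheet areas (µm^2); or a tibble with
#'   an `area_um2` column.
#' @param boundaries For `method = "manual"`: list or named vector with
#'   `t1` and `t2` (µm^2), `t1 > t2 > 0`.
#' @param method `"largest_gap"` or `"manual"`.
#' @param max_type1 Largest admissible Type 1 count for the gap search.
#' @param min_gap_log Minimal log-area gap accepted as the Type 1 boundary.
#' @return An object of class `sheet_classification`: the per-sheet
#'   assignment tibble plus thresholds; [tidy()] gives per-type statistics
#'   (count, mean area +/- SE, total-area fraction).
#' @export
classify_sheets <- function(areas_um2, boundaries = NULL,
                            method = c("largest_gap", "manual"),
                            max_type1 = 6L, min_gap_log = 1) {
  method <- match.arg(method)
  tbl <- NULL
  if (is.data.frame(areas_um2)) {
    tbl <- areas_um2
    areas_um2 <- tbl$area_um2
  }
  if (length(areas_um2) < 3L) abort("Need at least 3 sheets to classify.")
  if (any(areas_um2 <= 0)) abort("Sheet areas must be > 0.")
  degenerate <- diff(range(log(areas_um2))) < 1e-9
  if (method == "manual") {
    b <- unlist(boundaries)
    t1 <- b[["t1"]]; t2 <- b[["t2"]]
    if (!(t1 > t2 && t2 > 0)) abort("Thresholds out of order: need t1 > t2 > 0.")
  } else if (degenerate) {
    t1 <- Inf
    t2 <- Inf
  } else {
    y <- sort(log(areas_um2), decreasing = TRUE)
    n <- length(y)
    ktop <- min(max_type1, n - 1L)
    gaps <- y[seq_len(ktop)] - y[seq_len(ktop) + 1L]
    k1 <- if (max(gaps) >= min_gap_log) which.max(gaps) else 0L
    t1 <- if (k1 > 0L) exp((y[k1] + y[k1 + 1L]) / 2) else Inf
    rest <- y[(k1 + 1L):n]
    # Type 2/3 boundary between the flat and steep regions: when the two
    # populations are separated in log-area the transition shows up as the
    # dominant gap among the top order statistics of the remainder (the
    # flat portion is small by definition); otherwise fall back to the
    # elbow of a two-segment piecewise-linear fit to the sorted log-areas.
    k2max <- min(length(rest) - 1L, max(12L, ceiling(0.02 * length(rest))))
    gaps2 <- rest[seq_len(k2max)] - rest[seq_len(k2max) + 1L]
    j <- if (max(gaps2) >= min_gap_log / 2) {
      which.max(gaps2)
    } else {
      two_piece_split(rest)
    }
    t2 <- exp((rest[j] + rest[j + 1L]) / 2)
  }
  cls <- dplyr::case_when(
    degenerate & method != "manual" ~ "Type3",
    areas_um2 >= t1 ~ "Type1",
    areas_um2 >= t2 ~ "Type2",
    .default = "Type3"
  )
  assignments <- if (is.null(tbl)) {
    tibble(area_um2 = areas_um2, class = cls)
  } else {
    mutate(tbl, class = cls)
  }
  structure(
    list(
      assignments = assignments,
      t1_um2 = t1, t2_um2 = t2,
      method = method, degenerate = degenerate
    ),
    class = "sheet_classification"
  )
}

# split index (within 1..n-1) minimising SSE of two independent line fits to
# (rank, value); O(n) via prefix sums
two_piece_split <- function(y) {
  n <- length(y)
  if (n < 4L) return(max(1L, n - 1L))
  x <- as.numeric(seq_len(n))
  cx <- cumsum(x); cy <- cumsum(y); cxx <- cumsum(x * x)
  cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg_sse <- function(i, j) {
    # SSE of least-squares line on indices i..j (j > i)
    m <- j - i + 1
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
    syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
    vxx <- sxx - sx * sx / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy * sy / m
    if (vxx <= 0) return(vyy)
    vyy - vxy * vxy / vxx
  }
  ks <- 2:(n - 2)
  sse <- vapply(ks, function(k) seg_sse(1L, k) + seg_sse(k + 1L, n), numeric(1))
  ks[which.min(sse)]
}

#' @export
print.sheet_classification <- function(x, ...) {
  cat("<sheet_classification> method:", x$method, "\n")
  if (x$degenerate) cat("  DEGENERATE: all areas equal; single class, no Type 1\n")
  cat(sprintf("  thresholds: t1 = %.4g, t2 = %.4g um^2\n", x$t1_um2, x$t2_um2))
  print(generics::tidy(x))
  invisible(x)
}

#' @rdname classify_sheets
#' @param x A `sheet_classification`.
#' @param ... Unused.
#' @export
tidy.sheet_classification <- function(x, ...) {
  tot <- sum(x$assignments$area_um2)
  x$assignments |>
    group_by(.data$class) |>
    summarise(
      n_sheets_count = n(),
      mean_area_um2 = mean(.data$area_um2),
      se_area_um2 = stats::sd(.data$area_um2) / sqrt(n()),
      total_area_um2 = sum(.data$area_um2),
      .groups = "drop"
    ) |>
    mutate(area_fraction_frac = .data$total_area_um2 / tot)
}

#' @rdname classify_sheets
#' @export
glance.sheet_classification <- function(x, ...) {
  tibble(
    n_sheets_count = nrow(x$assignments),
    t1_um2 = x$t1_um2, t2_um2 = x$t2_um2,
    method = x$method, degenerate = x$degenerate
  )
}

# Integer array mapping every membrane voxel to its sheet id (0 elsewhere);
# the workhorse lookup for per-type distances and associations.
sheet_voxel_map <- function(lv, strands, sheets) {
  d <- dim(lv$voxels)
  map <- array(0L, dim = d)
  strand_sheet <- integer(max(strands$strand_id))
  for (i in seq_len(nrow(sheets))) {
    strand_sheet[sheets$strand_ids[[i]]] <- sheets$sheet_id[i]
  }
  for (i in seq_len(nrow(strands))) {
    px <- strands$pixels[[i]]
    map[cbind(strands$z_index[i], px[, 1L], px[, 2L])] <-
      strand_sheet[strands$strand_id[i]]
  }
  map
}
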