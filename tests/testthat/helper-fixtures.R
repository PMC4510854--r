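# Shared fixtures (generated once per session) and independent oracles.
# All synthetic inputs are scaled-down study conditions: same voxel
# geometry, probabilities and planted targets as the full-size defaults,
# smaller cells so the whole suite stays fast. The methods vignette states
# the sizes used.

fixture_env <- new.env(parent = emptyenv())

small_cell_params <- function(seed = 1L) {
  cell_gen_params(
    cell_width_um = 5, cell_depth_um = 4, infranuclear_um = 4,
    nucleus_um = 2.5, neck_um = 1.5,
    n_terminals = 8, n_ribbons = 4,
    ribbon_type3_distance_sd_nm = 250,
    terminal_radius_nm = 400,
    sheet_area_mixture = list(
      counts = c(3L, 8L, 60L),
      mean_area_um2 = c(4, 0.8, 0.08),
      sdlog = c(0.2, 0.2, 0.4)
    ),
    seed = seed
  )
}

# a cell whose only purpose is terminal placement: minimal internal content
terminal_cell_params <- function(seed) {
  cell_gen_params(
    cell_width_um = 3.2, cell_depth_um = 2.6, infranuclear_um = 2.4,
    nucleus_um = 1.5, neck_um = 1, bulge_amplitude_nm = 450,
    n_terminals = 16, p_flat_terminal = 0.63,
    n_ribbons = 0, terminal_radius_nm = 250,
    membrane_fraction_flat = 0.04, membrane_fraction_round = 0.03,
    membrane_fraction_ant = 0.036, membrane_fraction_post = 0.034,
    sheet_area_mixture = list(
      counts = c(1L, 2L, 6L),
      mean_area_um2 = c(0.5, 0.15, 0.04),
      sdlog = c(0.2, 0.2, 0.3)
    ),
    seed = seed
  )
}

tiny_cell_params <- function(seed = 1L) {
  cell_gen_params(
    cell_width_um = 3, cell_depth_um = 2.4, infranuclear_um = 2.2,
    nucleus_um = 1.4, neck_um = 1, bulge_amplitude_nm = 450,
    n_terminals = 5, n_ribbons = 2,
    ribbon_type3_distance_nm = 350, ribbon_type3_distance_sd_nm = 120,
    terminal_radius_nm = 300,
    membrane_fraction_flat = 0.12, membrane_fraction_round = 0.08,
    membrane_fraction_ant = 0.11, membrane_fraction_post = 0.09,
    sheet_area_mixture = list(
      counts = c(2L, 3L, 12L),
      mean_area_um2 = c(0.9, 0.25, 0.05),
      sdlog = c(0.2, 0.2, 0.3)
    ),
    seed = seed
  )
}

small_tomo_params <- function(seed = 1L, n = 10L) {
  tomo_gen_params(
    link_counts = c(
      "mito-RER" = n, "vesicle-RER" = n, "vesicle-vesicle@RER" = n,
      "vesicle-vesicle@ribbon" = n, "vesicle-ribbon" = n
    ),
    n_free_vesicles = 4L, n_unattached_tethers = 2L, seed = seed
  )
}

# cached small cell plus every derived stage result used across test files
cached_cell <- function() {
  if (is.null(fixture_env$cell)) {
    gen <- generate_cell_volume(small_cell_params(seed = 1L))
    frame <- cell_frame(gen$volume)
    strands <- extract_strands(gen$volume)
    sheets <- sheet_area(link_strands(strands), strands, gen$volume)
    classification <- classify_sheets(sheets)
    smap <- cytoarch3d:::sheet_voxel_map(gen$volume, strands, classification$assignments)
    scl <- dplyr::select(classification$assignments, sheet_id, class)
    fixture_env$cell <- list(
      gen = gen, volume = gen$volume, truth = gen$truth, frame = frame,
      strands = strands, sheets = sheets, classification = classification,
      smap = smap, scl = scl
    )
  }
  fixture_env$cell
}

cached_tomo <- function() {
  if (is.null(fixture_env$tomo)) {
    gen <- generate_tomogram_volume(small_tomo_params(seed = 1L))
    links <- measure_links(gen$volume)
    fixture_env$tomo <- list(gen = gen, volume = gen$volume, truth = gen$truth, links = links)
  }
  fixture_env$tomo
}

# terminal placements from terminal-only cells, one entry per seed:
# data frame of per-terminal hemisphere assignments from the real pipeline
cached_terminal_counts <- function(n_cells = 24L) {
  if (is.null(fixture_env$terminal_counts) ||
    nrow(fixture_env$terminal_counts) < n_cells) {
    rows <- lapply(seq_len(n_cells), function(s) {
      g <- generate_cell_volume(terminal_cell_params(seed = 1000L + s))
      fr <- cell_frame(g$volume)
      td <- terminal_distribution(g$volume, fr)
      data.frame(
        seed = 1000L + s,
        n_flat = sum(td$hemi_fr == "flattened"),
        n_round = sum(td$hemi_fr == "rounded"),
        n_flat_true = sum(g$truth$terminals$side == "flattened"),
        n_total = nrow(td)
      )
    })
    fixture_env$terminal_counts <- do.call(rbind, rows)
  }
  fixture_env$terminal_counts
}

# ---- independent oracles ----------------------------------------------------

# brute-force voxel-box gap between two index sets (direct double loop over
# the definition; no pruning, no early exit)
bf_box_gap <- function(a, b, vs) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      gz <- max(0, abs(a[i, 1] - b[j, 1]) - 1) * vs[["z"]]
      gy <- max(0, abs(a[i, 2] - b[j, 2]) - 1) * vs[["y"]]
      gx <- max(0, abs(a[i, 3] - b[j, 3]) - 1) * vs[["x"]]
      d <- sqrt(gx^2 + gy^2 + gz^2)
      if (d < best) best <- d
    }
  }
  best
}

bf_point_box_dist <- function(p, idx, vs) {
  best <- Inf
  for (j in seq_len(nrow(idx))) {
    gx <- max(0, abs((idx[j, 3] - 0.5) * vs[["x"]] - p[1]) - vs[["x"]] / 2)
    gy <- max(0, abs((idx[j, 2] - 0.5) * vs[["y"]] - p[2]) - vs[["y"]] / 2)
    gz <- max(0, abs((idx[j, 1] - 0.5) * vs[["z"]] - p[3]) - vs[["z"]] / 2)
    d <- sqrt(gx^2 + gy^2 + gz^2)
    if (d < best) best <- d
  }
  best
}

# brute-force sheet partition: reflexive-transitive closure (Warshall) of
# the pairwise adjacent-section overlap relation
bf_sheet_partition <- function(strands, overlap_min = 1L) {
  n <- nrow(strands)
  A <- diag(TRUE, n)
  lin <- lapply(strands$pixels, function(p) p[, 1] * 100000 + p[, 2])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(strands$z_index[i] - strands$z_index[j]) == 1L) {
        ov <- length(intersect(lin[[i]], lin[[j]]))
        if (ov >= max(1L, overlap_min)) A[i, j] <- TRUE
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (A[i, k]) A[i, ] <- A[i, ] | A[k, ]
    }
  }
  # partition as canonical membership: smallest reachable strand id
  comp <- apply(A | t(A), 1L, function(r) min(strands$strand_id[r]))
  split(strands$strand_id, comp)
}

# random strand instance (no volume needed): short random walks on a grid
rand_strand_instance <- function(n_strands, n_z = 5L, grid = 14L) {
  rows <- lapply(seq_len(n_strands), function(i) {
    z <- sample.int(n_z, 1L)
    len <- sample(2:8, 1L)
    y <- sample.int(grid - 9L, 1L) + 1L
    x <- sample.int(grid - 9L, 1L) + 1L
    px <- matrix(c(y, x), ncol = 2L)
    for (s in seq_len(len)) {
      stp <- px[nrow(px), ] + sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
      stp <- pmin(pmax(stp, 1L), grid)
      px <- rbind(px, stp)
    }
    px <- px[!duplicated(px), , drop = FALSE]
    tibble::tibble(
      strand_id = i, z_index = z, n_px_count = nrow(px),
      length_nm = nrow(px) * 19, centroid_x_nm = mean(px[, 2]) * 19,
      centroid_y_nm = mean(px[, 1]) * 19, pixels = list(px)
    )
  })
  dplyr::bind_rows(rows)
}

# sheet partition of link_strands output as a canonical list
partition_of_sheets <- function(sheets) {
  out <- lapply(sheets$strand_ids, sort)
  out[order(vapply(out, min, numeric(1)))]
}

partition_of_bf <- function(bf) {
  out <- lapply(unname(bf), sort)
  out[order(vapply(out, min, numeric(1)))]
}

# simple geometric label volumes ---------------------------------------------

# cube cell of side `side_nm` with a centred organelle sphere of radius r_nm
cube_sphere_volume <- function(side_nm = 4000, r_nm = 1000, voxel_nm = 20) {
  n <- round(side_nm / voxel_nm)
  vox <- array(1L, dim = c(n, n, n))
  ctr <- side_nm / 2
  cc <- (seq_len(n) - 0.5) * voxel_nm
  for (iz in seq_len(n)) {
    d2 <- outer((cc - ctr)^2, (cc - ctr)^2, "+") + (cc[iz] - ctr)^2
    m <- d2 <= r_nm^2
    sec <- vox[iz, , ]
    sec[m] <- 3L
    vox[iz, , ] <- sec
  }
  label_volume(
    vox, c(x = voxel_nm, y = voxel_nm, z = voxel_nm),
    tibble::tibble(label = c(1L, 3L), class = c("cell", "mitochondrion"))
  )
}

# half-disc prism: flat face at low x, circular arc at high x, extruded in z
hemicylinder_mask <- function(r_px = 60L, nz = 20L, pad = 4L) {
  ny <- 2L * r_px + 2L * pad
  nx <- r_px + 2L * pad
  m <- array(FALSE, dim = c(nz, ny, nx))
  yc <- pad + r_px + 0.5
  for (iy in seq_len(ny)) {
    dy <- iy - yc
    if (abs(dy) <= r_px) {
      w <- floor(sqrt(r_px^2 - dy^2))
      if (w >= 0) m[, iy, pad + (0:w)] <- TRUE
    }
  }
  m
}
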