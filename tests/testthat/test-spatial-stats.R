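tiny_assoc_lv <- function() {
  # a 12^3 volume with one membrane strand and two mitochondria: one sharing
  # a face with the strand, one three voxels away
  vox <- array(0L, dim = c(12, 12, 12))
  vox[vox == 0L] <- 1L
  vox[6, 6, 3:8] <- 3L # strand
  vox[6, 7, 4:5] <- 9L # face-adjacent mitochondrion
  vox[6, 11, 4:5] <- 10L # |dy| = 5 voxels: four empty voxels between
  label_volume(
    vox, c(x = 19, y = 19, z = 50),
    tibble::tibble(
      label = c(1L, 3L, 9L, 10L),
      class = c("cell", "membrane", "mitochondrion", "mitochondrion")
    )
  )
}

test_that("association gap follows the voxel-surface convention", {
  lv <- tiny_assoc_lv()
  assoc <- mito_membrane_association(lv)
  expect_equal(assoc$min_gap_nm[assoc$label == 9L], 0)
  expect_true(assoc$associated[assoc$label == 9L])
  # |dy| = 5 voxels -> gap = 4 * 19 nm
  expect_equal(assoc$min_gap_nm[assoc$label == 10L], 4 * 19)
  expect_false(assoc$associated[assoc$label == 10L])
  expect_equal(attr(assoc, "gap_threshold_nm"), 19)

  # association is monotone non-decreasing in the gap threshold
  a1 <- mito_membrane_association(lv, gap_threshold_nm = 19)
  a2 <- mito_membrane_association(lv, gap_threshold_nm = 60)
  expect_gte(mean(a2$associated), mean(a1$associated))

  expect_error(
    mito_membrane_association(label_volume(
      array(1L, dim = c(2, 2, 2)), c(x = 19, y = 19, z = 50),
      tibble::tibble(label = 1L, class = "cell")
    )),
    "No mitochondria"
  )
})

test_that("gaps equal brute-force all-pair search on small random volumes", {
  for (s in 1:6) {
    set.seed(100 + s)
    vox <- array(0L, dim = c(14, 14, 14))
    vox[vox == 0L] <- 1L
    # random membrane voxels and two compact random mitochondria
    memb <- cbind(
      sample(14, 25, TRUE), sample(14, 25, TRUE), sample(14, 25, TRUE)
    )
    vox[memb] <- 3L
    for (lab in c(9L, 10L)) {
      ctr <- sample(3:12, 3)
      blob <- as.matrix(expand.grid(
        ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)
      ))
      blob <- blob[rowSums((t(t(blob) - ctr))^2) <= 2, , drop = FALSE]
      blob <- blob[vox[blob] == 1L, , drop = FALSE]
      if (nrow(blob)) vox[blob] <- lab
    }
    tab <- tibble::tibble(
      label = c(1L, 3L, 9L, 10L),
      class = c("cell", "membrane", "mitochondrion", "mitochondrion")
    )
    present <- intersect(tab$label, unique(as.vector(vox)))
    lv <- label_volume(vox, c(x = 19, y = 19, z = 50), tab[tab$label %in% present, ])
    if (!any(present %in% c(9L, 10L))) next
    assoc <- mito_membrane_association(lv)
    for (k in seq_len(nrow(assoc))) {
      idx <- which(vox == assoc$label[k], arr.ind = TRUE)
      expect_equal(
        assoc$min_gap_nm[k],
        bf_box_gap(idx, which(vox == 3L, arr.ind = TRUE), lv$voxel_size),
        info = paste("volume", s, "mito", assoc$label[k])
      )
    }
  }
})

test_that("association fraction recovers the planted probability exactly", {
  cell <- cached_cell()
  assoc <- mito_membrane_association(cell$volume,
    sheet_map = cell$smap, sheet_classes = cell$scl
  )
  expect_equal(mean(assoc$associated), mean(cell$truth$mitochondria$attached))
  s <- association_summary(assoc)
  expect_equal(s$n_mito_count, nrow(cell$truth$mitochondria))
  expect_true(s$single_type_frac > 0 && s$single_type_frac <= 1)
})

test_that("per-type densities compose and handle edge cases", {
  # 10 mitochondria on 4000 um^2 of one type -> 2.5e-3 per um^2
  assoc <- tibble::tibble(
    mito_id = 1:12, label = 100 + 1:12,
    min_gap_nm = 0, associated = c(rep(TRUE, 11), FALSE),
    n_sheets_count = 1L,
    sheet_ids = c(as.list(rep(1L, 10)), list(2L), list(integer(0))),
    n_types_touched_count = c(rep(1L, 11), 0L)
  )
  classes <- tibble::tibble(sheet_id = 1:2, class = c("Type2", "Type3"))
  areas <- tibble::tibble(class = c("Type2", "Type3"), total_area_um2 = c(4000, 500))
  dens <- mito_density_per_type(assoc, areas, classes)
  expect_equal(dens$density_per_um2[dens$class == "Type2"], 2.5e-3)
  expect_equal(dens$n_mito_count[dens$class == "Type3"], 1L)
  # zero mitochondria of a type -> density 0
  dens0 <- mito_density_per_type(assoc[11:12, ], areas, classes)
  expect_equal(dens0$density_per_um2[dens0$class == "Type2"], 0)
  expect_error(
    mito_density_per_type(assoc, dplyr::mutate(areas, total_area_um2 = 0), classes),
    "Zero type area"
  )

  # recomposition on the cached cell: sum(density * area) = single-type count
  cell <- cached_cell()
  assoc_c <- mito_membrane_association(cell$volume,
    sheet_map = cell$smap, sheet_classes = cell$scl
  )
  ta <- generics::tidy(cell$classification) |>
    dplyr::select(class, total_area_um2)
  dens_c <- mito_density_per_type(assoc_c, ta, cell$scl)
  expect_equal(
    sum(dens_c$density_per_um2 * dens_c$total_area_um2),
    sum(assoc_c$associated & assoc_c$n_types_touched_count == 1L)
  )
})

test_that("ribbon distances use centres, voxel surfaces and report missing types", {
  # ribbon centred on a sheet voxel -> distance 0
  vox <- array(1L, dim = c(9, 9, 9))
  vox[5, 5, 5] <- 3L
  vox[5, 5, 4] <- 7L # two-voxel ribbon straddling the sheet voxel:
  vox[5, 5, 6] <- 7L # its centre falls ON the sheet -> distance 0
  lv <- label_volume(
    vox, c(x = 19, y = 19, z = 50),
    tibble::tibble(label = c(1L, 3L, 7L), class = c("cell", "membrane", "ribbon"))
  )
  smap <- array(0L, dim(vox))
  smap[5, 5, 5] <- 1L
  rd <- ribbon_to_sheet_distances(lv, smap, tibble::tibble(sheet_id = 1L, class = "Type3"))
  expect_equal(rd$distance_nm, 0)
  expect_equal(rd$nearest_class, "Type3")

  # absent type -> NA (missing), not infinite
  rd2 <- ribbon_to_sheet_distances(
    lv, smap,
    tibble::tibble(sheet_id = c(1L, 99L), class = c("Type3", "Type1"))
  )
  expect_true(is.na(rd2$distance_nm[rd2$class == "Type1"]))
  expect_false(any(is.infinite(rd2$distance_nm), na.rm = TRUE))

  # cached cell: measured Type-3 distances equal the generator's truth
  cell <- cached_cell()
  rdc <- ribbon_to_sheet_distances(cell$volume, cell$smap, cell$scl)
  t3 <- rdc[rdc$class == "Type3", ]
  expect_equal(t3$distance_nm, cell$truth$ribbons$d_type3_nm, tolerance = 5 / 400)

  # brute-force oracle on one cached ribbon
  rb <- cell$truth$ribbons[1, ]
  t3vox <- which(
    array(cell$smap > 0, dim(cell$volume$voxels)) &
      array(cell$scl$class[match(cell$smap, cell$scl$sheet_id)] == "Type3",
        dim(cell$volume$voxels)
      ),
    arr.ind = TRUE
  )
  # restrict brute force to a neighbourhood to keep it brute but bounded
  near <- t3vox[abs((t3vox[, 3] - 0.5) * 19 - rb$x_nm) < 2000 &
    abs((t3vox[, 2] - 0.5) * 19 - rb$y_nm) < 2000, , drop = FALSE]
  cen <- c(
    mean((which(cell$volume$voxels == rb$label, arr.ind = TRUE)[, 3] - 0.5) * 19),
    mean((which(cell$volume$voxels == rb$label, arr.ind = TRUE)[, 2] - 0.5) * 19),
    mean((which(cell$volume$voxels == rb$label, arr.ind = TRUE)[, 1] - 0.5) * 50)
  )
  expect_equal(
    t3$distance_nm[1],
    bf_point_box_dist(cen, near, cell$volume$voxel_size),
    tolerance = 1e-6
  )
})

test_that("terminal distribution matches the plant and basic invariants", {
  cell <- cached_cell()
  td <- terminal_distribution(cell$volume, cell$frame)
  counts <- attr(td, "counts")
  truth <- table(cell$truth$terminals$side)
  expect_equal(
    counts$n[counts$hemisphere == "flattened"],
    as.integer(truth[["flattened"]])
  )
  expect_equal(sum(counts$n[counts$hemisphere %in% c("flattened", "rounded")]), nrow(td))
  # counts equal exhaustive per-terminal lookup against the truth table
  mm <- merge(
    as.data.frame(td[, c("label", "hemi_fr")]),
    as.data.frame(cell$truth$terminals[, c("label", "side")]),
    by = "label"
  )
  expect_equal(mm$hemi_fr, mm$side)
  # the extremum terminal is the apical-most one
  ex <- attr(td, "extremum")
  expect_equal(ex$y_from_base_nm, max(td$y_from_base_nm))
  expect_true(ex$hemi_mp %in% c("modiolar", "pillar"))

  expect_error(
    terminal_distribution(
      label_volume(
        array(1L, dim = c(2, 2, 2)), c(x = 19, y = 19, z = 50),
        tibble::tibble(label = 1L, class = "cell")
      ),
      cell$frame
    ),
    "No terminals"
  )
})

test_that("region shares behave at the identity and recover the plant", {
  cell <- cached_cell()
  infra <- infranuclear_mask(cell$volume)
  rs_id <- region_membrane_share(infra$mask, infra$mask, cell$sheets, cell$smap)
  expect_equal(rs_id$volume_share_frac, 1)
  expect_equal(rs_id$area_share_frac, 1)

  expect_error(
    region_membrane_share(array(FALSE, dim(infra$mask)), infra$mask, cell$sheets, cell$smap),
    "Empty region"
  )

  region <- array(FALSE, dim(cell$volume$voxels))
  region[, , cell$truth$region$x_min_index:dim(cell$volume$voxels)[3]] <- TRUE
  region <- region & infra$mask
  rs <- region_membrane_share(region, infra$mask, cell$sheets, cell$smap)
  expect_equal(rs$volume_share_frac, cell$truth$region$volume_share_true, tolerance = 1e-6)
  expect_equal(rs$area_share_frac, cell$truth$region$area_share_true, tolerance = 0.05)
})

test_that("group tests match base distributions and a reference Games-Howell", {
  # identical groups: statistic ~ 0, p ~ 1
  d0 <- data.frame(v = rep(c(1, 2, 3, 4), 2), g = rep(c("a", "b"), each = 4))
  r0 <- run_group_tests(d0, "v", "g")
  t0 <- r0$tests[r0$tests$test == "welch_t", ]
  expect_lt(abs(t0$statistic_stat), 1e-9)
  expect_gt(t0$p_value_p, 0.99)

  # two groups drawn 4 SE apart: p < 0.05 in >= 95% of seeds
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    n <- 20
    delta <- 4 * sqrt(2 / n) # 4 standard errors of the difference at sd = 1
    d <- data.frame(
      v = c(rnorm(n, 0), rnorm(n, delta)),
      g = rep(c("a", "b"), each = n)
    )
    r <- run_group_tests(d, "v", "g", tests = "t")
    r$tests$p_value_p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # Games-Howell on a frozen fixture: expected values computed independently
  # with pingouin.pairwise_gameshowell and frozen here
  g1 <- c(23, 25, 21, 26, 28, 24, 22, 25)
  g2 <- c(30, 33, 29, 35, 32, 31, 34, 33)
  g3 <- c(24, 26, 27, 23, 25, 28, 26, 27)
  gh <- games_howell(
    c(g1, g2, g3),
    rep(c("a", "b", "c"), each = 8)
  )
  expect_equal(gh$diff_stat, c(-7.875, -1.5, 6.375))
  expect_equal(gh$se_stat, c(1.07217236, 0.99103121, 0.92942955), tolerance = 1e-7)
  expect_equal(gh$df_stat, c(13.85327981, 12.90765011, 13.49322368), tolerance = 1e-7)
  expect_equal(
    gh$statistic_stat,
    abs(c(-7.34490114, -1.51357494, 6.85904597)) * sqrt(2),
    tolerance = 1e-7
  )
  expect_equal(
    gh$p_value_p, c(0.00001092, 0.31703627, 0.00002655),
    tolerance = 1e-3
  )

  # error contracts
  expect_error(run_group_tests(d0[d0$g == "a", ], "v", "g"), "at least 2 groups")
  expect_error(
    run_group_tests(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")), "v", "g"),
    "Group size"
  )
})
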