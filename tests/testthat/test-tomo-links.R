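test_that("a straight tether between two structures measures its gap", {
  # two slabs 30 nm apart, connected by a straight 1-voxel tether
  v <- 2
  vox <- array(0L, dim = c(60, 40, 40))
  vox[1:10, , ] <- 1L # membrane slab, top surface at z = 20 nm
  vox[26:35, , ] <- 2L # mitochondrion slab, bottom surface at z = 50 nm
  zt <- 11:25 # 15 voxels of tether spanning the 30 nm gap
  vox[cbind(zt, 20L, 20L)] <- 5000L
  lv <- label_volume(
    vox, c(x = v, y = v, z = v),
    tibble::tibble(
      label = c(1L, 2L, 5000L),
      class = c("membrane", "mitochondrion", "tether")
    )
  )
  m <- measure_link(lv, 5000L)
  expect_lt(abs(m$length_nm - 30), 2 * v) # within a voxel of the true gap
  expect_equal(sort(c(m$end1_kind, m$end2_kind)), c("membrane", "mitochondrion"))
  expect_equal(m$context, "mito-RER")
  expect_true(m$attached_both_ends)
  # skeleton arc length >= straight extent (path inequality)
  expect_gte(m$length_arc_nm, m$length_nm - 1e-9)
})

test_that("one-ended tethers are measured and flagged unattached", {
  tomo <- cached_tomo()
  one_ended <- tomo$links[!tomo$links$attached_both_ends, ]
  expect_equal(nrow(one_ended), 2L)
  expect_true(all(is.na(one_ended$context)))
  expect_true(all(one_ended$length_nm > 0))
})

test_that("measured link lengths and contexts recover the planted truth", {
  tomo <- cached_tomo()
  m <- dplyr::inner_join(
    tomo$links, tomo$truth$links,
    by = "label", suffix = c("_meas", "_true")
  )
  both <- m[m$attached_both_ends_true, ]
  expect_equal(both$context_meas, both$context_true)
  expect_lt(max(abs(both$length_nm_meas - both$length_nm_true)), 4)
  expect_lt(abs(mean(both$length_nm_meas - both$length_nm_true)), 1)
})

test_that("link lengths are invariant under rigid rotation of the tomogram", {
  tomo <- cached_tomo()
  lv <- tomo$volume
  # 90-degree rotation about z: swap the two in-plane axes
  vox_rot <- aperm(lv$voxels, c(1, 3, 2))
  lv_rot <- label_volume(vox_rot, lv$voxel_size, lv$label_table)
  lk_rot <- measure_links(lv_rot)
  mm <- dplyr::inner_join(tomo$links, lk_rot, by = "label", suffix = c("_a", "_b"))
  expect_lt(max(abs(mm$length_nm_a - mm$length_nm_b)), 2 * lv$voxel_size[["x"]])
  expect_equal(mm$context_a, mm$context_b)
})

test_that("vesicle diameters follow voxel counting and flag unreliable objects", {
  # rasterised sphere of the printed diameter at 2 nm voxels
  v <- 2
  vox <- array(0L, dim = c(40, 40, 40))
  idx <- cytoarch3d:::raster_sphere(c(40, 40, 40), 37.3 / 2, dim(vox), c(x = v, y = v, z = v))
  vox[idx] <- 100L
  vox[2, 2, 2] <- 101L # single-voxel object
  lv <- label_volume(
    vox, c(x = v, y = v, z = v),
    tibble::tibble(label = c(100L, 101L), class = "vesicle")
  )
  vd <- vesicle_diameters(lv)
  big <- vd[vd$label == 100L, ]
  expect_lt(abs(big$diameter_nm - 37.3), v)
  expect_true(big$reliable)
  expect_false(vd$reliable[vd$label == 101L])
  expect_equal(vd$location, c("free", "free"))
  # diameters equal brute-force voxel counting
  expect_equal(
    big$diameter_nm,
    2 * (3 * sum(vox == 100L) * v^3 / (4 * pi))^(1 / 3)
  )
})

test_that("vesicle locations recover the planted pools", {
  tomo <- cached_tomo()
  vd <- vesicle_diameters(tomo$volume)
  vm <- dplyr::inner_join(vd, tomo$truth$vesicles, by = "label")
  expect_gte(mean(vm$location.x == vm$location.y), 0.9)
})

test_that("context comparison reports means, tests and the shortest context", {
  tomo <- cached_tomo()
  cc <- compare_contexts(tomo$links)
  expect_equal(nrow(cc$by_context), 5L)
  expect_true(all(cc$by_context$n_count == 10L))
  expect_false(is.null(cc$report))
  expect_s3_class(generics::tidy(cc), "tbl_df")

  # single context: means only, no tests
  one <- dplyr::filter(tomo$links, context == "mito-RER")
  cc1 <- compare_contexts(one)
  expect_null(cc1$report)
  expect_equal(cc1$shortest_context, "mito-RER")

  # under a common distribution the significant-pair rate stays near alpha
  rates <- vapply(1:40, function(s) {
    set.seed(200 + s)
    fake <- tibble::tibble(
      length_nm = rnorm(45, 30, 6),
      context = rep(c("a", "b", "c"), each = 15)
    )
    cc0 <- compare_contexts(fake)
    mean(cc0$report$pairwise$p_value_p < 0.05)
  }, numeric(1))
  expect_lt(mean(rates), 0.10)
})
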