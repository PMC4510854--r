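test_that("grid construction follows the spacing arithmetic", {
  # 2x2x2 um cube volume, 200 nm spacing, fixed (half-spacing) offsets:
  # a 10x10x10 interior lattice of 1000 points
  vox <- array(1L, dim = c(100, 100, 100))
  lv <- label_volume(
    vox, c(x = 20, y = 20, z = 20),
    tibble::tibble(label = 1L, class = "cell")
  )
  grid <- make_point_grid(lv, spacing_nm = c(x = 200, y = 200, z = 200), offset = "fixed")
  expect_equal(nrow(grid), 1000L)

  expect_error(
    make_point_grid(lv, spacing_nm = c(x = 10, y = 200, z = 200), offset = "fixed"),
    "sub-voxel"
  )
  expect_error(make_point_grid(lv, offset = "sur"), "seed")
  expect_error(
    make_point_grid(lv, mode = "partial", offset = "fixed"),
    "frame"
  )
})

test_that("points are classified by their containing voxel (brute-force oracle)", {
  # all-background volume -> everything not_in_cell
  vox0 <- array(0L, dim = c(10, 10, 10))
  vox0[1, 1, 1] <- 1L # constructor requires the label to occur
  lv0 <- label_volume(
    vox0, c(x = 50, y = 50, z = 50),
    tibble::tibble(label = 1L, class = "cell")
  )
  g0 <- make_point_grid(lv0, spacing_nm = c(x = 120, y = 120, z = 120), offset = "fixed")
  p0 <- classify_points(g0, lv0)
  expect_true(all(p0$class[p0$x_nm > 60] == "not_in_cell"))

  # a point centred in a mitochondrion takes that class
  vox0[5, 5, 5] <- 9L
  lv1 <- label_volume(
    vox0, c(x = 50, y = 50, z = 50),
    tibble::tibble(label = c(1L, 9L), class = c("cell", "mitochondrion"))
  )
  pt <- tibble::tibble(point_id = 1L, x_nm = 225, y_nm = 225, z_nm = 225)
  expect_equal(classify_points(pt, lv1)$class, "mitochondrion")

  # out-of-volume points are an error
  expect_error(
    classify_points(tibble::tibble(point_id = 1, x_nm = 1e6, y_nm = 1, z_nm = 1), lv1),
    "outside the volume"
  )

  # full grid on the cached cell equals an independent per-point lookup
  cell <- cached_cell()
  lv <- cell$volume
  grid <- make_point_grid(lv, offset = "sur", seed = 42)
  pts <- classify_points(grid, lv)
  iz <- pmin(pmax(floor(pts$z_nm / lv$voxel_size[["z"]]) + 1, 1), dim(lv$voxels)[1])
  iy <- pmin(pmax(floor(pts$y_nm / lv$voxel_size[["y"]]) + 1, 1), dim(lv$voxels)[2])
  ix <- pmin(pmax(floor(pts$x_nm / lv$voxel_size[["x"]]) + 1, 1), dim(lv$voxels)[3])
  labs <- lv$voxels[cbind(iz, iy, ix)]
  cls <- lv$label_table$class[match(labs, lv$label_table$label)]
  expected <- dplyr::case_when(
    is.na(cls) ~ "not_in_cell",
    cls == "cell" ~ "cytoplasm",
    cls == "terminal" ~ "not_in_cell",
    TRUE ~ cls
  )
  expect_equal(pts$class, expected)
})

test_that("the estimator is unbiased on an analytic solid", {
  lv <- cube_sphere_volume(side_nm = 4000, r_nm = 1000, voxel_nm = 20)
  grid <- make_point_grid(lv, spacing_nm = c(x = 100, y = 100, z = 100),
    offset = "sur", seed = 7
  )
  vf <- volume_fraction(classify_points(grid, lv), classes = "mitochondrion")
  truth <- (4 / 3) * pi / 64 # sphere of radius r in a cube of side 4r
  expect_lt(abs(vf$fraction_frac - truth), 2 * vf$se_frac + 0.002)
  # error shrinks with spacing (systematic uniform sampling)
  grid2 <- make_point_grid(lv, spacing_nm = c(x = 50, y = 50, z = 50),
    offset = "sur", seed = 7
  )
  vf2 <- volume_fraction(classify_points(grid2, lv), classes = "mitochondrion")
  expect_lt(abs(vf2$fraction_frac - truth), abs(vf$fraction_frac - truth) + 0.002)
})

test_that("class fractions sum to one and per-class counts are consistent", {
  cell <- cached_cell()
  pts <- classify_points(
    make_point_grid(cell$volume, offset = "fixed"),
    cell$volume, cell$frame
  )
  infra <- dplyr::filter(pts, infranuclear)
  cf <- class_fractions(infra)
  expect_equal(sum(cf$fraction_frac), 1)
  vf <- volume_fraction(infra)
  expect_equal(
    vf$n_hits_count,
    sum(cf$n_hits_count[cf$class %in% c("membrane", "mitochondrion")])
  )
})

test_that("a generated cell yields the paper-scale sampling depth and stable estimates", {
  cell <- cached_cell()
  lv <- cell$volume
  grid <- make_point_grid(lv, offset = "sur", seed = 3)
  pts <- classify_points(grid, lv, cell$frame)
  expect_gt(sum(pts$class != "not_in_cell"), 5000)

  # shifting the grid origin changes hemisphere estimates by < 2 SE
  infra1 <- dplyr::filter(pts, infranuclear)
  v1 <- volume_fraction(infra1, by = "hemi_fr")
  pts2 <- classify_points(
    make_point_grid(lv, offset = "sur", seed = 103),
    lv, cell$frame
  )
  v2 <- volume_fraction(dplyr::filter(pts2, infranuclear), by = "hemi_fr")
  for (h in c("flattened", "rounded")) {
    d <- abs(
      v1$fraction_frac[v1$hemi_fr == h] - v2$fraction_frac[v2$hemi_fr == h]
    )
    se <- sqrt(v1$se_frac[v1$hemi_fr == h]^2 + v2$se_frac[v2$hemi_fr == h]^2)
    expect_lt(d, 2 * se)
  }
})

test_that("partial mode samples every section of the peri-nuclear window", {
  cell <- cached_cell()
  grid <- make_point_grid(cell$volume,
    mode = "partial", frame = cell$frame,
    offset = "sur", seed = 5
  )
  vz <- cell$volume$voxel_size[["z"]]
  zs <- sort(unique(grid$z_nm))
  wz <- cell$frame$infranuclear$window_z_range
  expect_equal(length(zs), diff(wz) + 1L)
  expect_equal(diff(zs), rep(vz, length(zs) - 1L))
})
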