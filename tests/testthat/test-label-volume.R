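test_that("label_volume validates its invariants", {
  vox <- array(0L, dim = c(2, 3, 4))
  vox[1, 1, 1] <- 1L
  tab <- tibble::tibble(label = 1L, class = "cell")
  lv <- label_volume(vox, c(x = 19, y = 19, z = 50), tab)
  expect_s3_class(lv, "label_volume")
  expect_equal(unname(volume_extent_nm(lv)), c(4 * 19, 3 * 19, 2 * 50))

  expect_error(
    label_volume(vox, c(x = 0, y = 19, z = 50), tab),
    "strictly positive"
  )
  expect_error(
    label_volume(vox, c(x = 19, y = 19), tab),
    "voxel_size"
  )
  vox2 <- vox
  vox2[2, 2, 2] <- 7L # label absent from the table
  expect_error(
    label_volume(vox2, c(x = 19, y = 19, z = 50), tab),
    "absent from label_table"
  )
  expect_error(
    label_volume(vox, c(x = 19, y = 19, z = 50),
      tibble::tibble(label = 1L, class = "golgi")
    ),
    "Unknown label class"
  )
})

test_that("class masks and object summaries agree with direct counting", {
  set.seed(7)
  vox <- array(sample(c(0L, 1L, 5L, 9L), 4 * 5 * 6, replace = TRUE), dim = c(4, 5, 6))
  tab <- tibble::tibble(
    label = c(1L, 5L, 9L),
    class = c("cell", "membrane", "mitochondrion")
  )
  lv <- label_volume(vox, c(x = 10, y = 10, z = 25), tab)
  expect_equal(class_mask(lv, "membrane"), array(vox == 5L, dim(vox)))
  expect_equal(
    class_mask(lv, c("cell", "mitochondrion")),
    array(vox %in% c(1L, 9L), dim(vox))
  )
  os <- object_summary(lv)
  expect_equal(os$n_voxels, c(sum(vox == 1L), sum(vox == 5L), sum(vox == 9L)))
  # centroid oracle for one label
  idx <- which(vox == 9L, arr.ind = TRUE)
  expect_equal(
    os$centroid_x_nm[os$label == 9L],
    mean((idx[, 3] - 0.5) * 10)
  )
})

test_that("estimates are invariant under relabeling with the same semantics", {
  cell <- cached_cell()
  lv <- cell$volume
  # permute all labels by a fixed offset
  off <- 1000L
  vox2 <- lv$voxels
  vox2[vox2 > 0L] <- vox2[vox2 > 0L] + off
  tab2 <- dplyr::mutate(lv$label_table, label = label + off)
  lv2 <- label_volume(vox2, lv$voxel_size, tab2)
  grid <- make_point_grid(lv, offset = "fixed")
  f1 <- volume_fraction(classify_points(grid, lv))
  f2 <- volume_fraction(classify_points(grid, lv2))
  expect_equal(f1, f2)
})
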