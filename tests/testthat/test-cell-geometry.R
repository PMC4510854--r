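test_that("centre line of a symmetric prism is its axis and translates with it", {
  # rectangular prism, symmetric in x and y
  m <- array(FALSE, dim = c(10, 40, 30))
  m[2:9, 6:35, 6:25] <- TRUE
  cl <- dynamic_centre_line(m)
  expect_equal(cl$z_index, 2:9)
  # voxel-centre coordinates: mean of columns 6..25 at unit pitch is 15.0
  expect_equal(cl$x_nm, rep(mean(6:25) - 0.5, 8), tolerance = 1e-9)
  expect_equal(cl$y_nm, rep(mean(6:35) - 0.5, 8), tolerance = 1e-9)

  # translation equivariance
  m2 <- array(FALSE, dim = c(10, 40, 30))
  m2[2:9, 8:37, 9:28] <- TRUE
  cl2 <- dynamic_centre_line(m2)
  expect_equal(cl2$x_nm - cl$x_nm, rep(3, 8))
  expect_equal(cl2$y_nm - cl$y_nm, rep(2, 8))
})

test_that("an empty section inside the cell range is an error naming the section", {
  m <- array(FALSE, dim = c(8, 10, 10))
  m[2:7, 3:8, 3:8] <- TRUE
  m[4, , ] <- FALSE
  expect_error(dynamic_centre_line(m), "section 4")
})

test_that("hemisphere partitions are exact set partitions", {
  # symmetric cylinder: the flat/round split gives two equal halves
  m <- array(FALSE, dim = c(12, 30, 31)) # odd x so one column sits on the line
  m[2:11, 4:27, 4:28] <- TRUE
  pm <- partition_hemispheres(m)
  expect_identical(pm$flattened | pm$rounded, m)
  expect_false(any(pm$flattened & pm$rounded))
  # equal within one section row (the centre column goes to one side)
  expect_lt(abs(sum(pm$flattened) - sum(pm$rounded)), 10 * 24 + 1)

  ap <- partition_hemispheres(m, axis = "ant_post")
  expect_identical(ap$anterior | ap$posterior, m)
  expect_false(any(ap$anterior & ap$posterior))

  expect_error(partition_hemispheres(m, axis = "sideways"), "axis_choice")

  # generated cell: >= 98% of voxels on the generator's true side
  cell <- cached_cell()
  fr <- cell$frame
  pm <- partition_hemispheres(cell$volume, fr$centre_line,
    flattened_side = fr$flattened_side
  )
  mask <- cytoarch3d:::cell_body_mask(cell$volume)
  expect_identical(pm$flattened | pm$rounded, mask)
  d <- dim(mask)
  truth_flat <- array(FALSE, d)
  x_nm <- (seq_len(d[3]) - 0.5) * cell$volume$voxel_size[["x"]]
  for (iz in seq_len(d[1])) {
    mx <- cell$truth$midline$x_nm[iz]
    if (!is.na(mx) && cell$truth$midline$n_cell_voxels[iz] > 0) {
      truth_flat[iz, , ] <- rep(x_nm > mx, each = d[2])
    }
  }
  agree <- sum((pm$flattened & truth_flat) | (pm$rounded & !truth_flat & mask)) / sum(mask)
  expect_gte(agree, 0.98)
})

test_that("centre line recovers the generator's planted midline", {
  cell <- cached_cell()
  cl <- cell$frame$centre_line
  tm <- cell$truth$midline[cell$truth$midline$n_cell_voxels > 0, ]
  mm <- merge(cl, tm, by = "z_index")
  vx <- cell$volume$voxel_size[["x"]]
  expect_lt(max(abs(mm$x_nm.x - mm$x_nm.y)), vx) # within 1 in-plane voxel
})

test_that("flatness is zero for a prism and matches arc geometry for a hemicylinder", {
  # rectangular prism: both sides are planes -> zero deviation
  m <- array(FALSE, dim = c(6, 60, 30))
  m[2:5, 5:56, 5:26] <- TRUE
  prof <- flatness_profile(m,
    bands_um = list(c(0.002, 0.01), c(0.012, 0.02)),
    neck_y_nm = 56
  )
  expect_equal(prof$mean_dev_nm, rep(0, 4))

  # hemicylinder: flat side zero, curved side the mean sagitta of the arc
  r <- 60L
  hc <- hemicylinder_mask(r_px = r, nz = 10L, pad = 4L)
  neck <- 4 + 2 * r # top of the disc
  prof <- flatness_profile(hc,
    bands_um = list(c(0.005, 0.04)),
    neck_y_nm = neck
  )
  flat <- prof$mean_dev_nm[prof$side == "x_low"]
  curved <- prof$mean_dev_nm[prof$side == "x_high"]
  expect_lt(flat, 1e-9)
  # closed-form oracle on the same discrete rows: sagitta r - sqrt(r^2 - dy^2)
  yc <- 4 + r + 0.5
  rows <- which((seq_len(dim(hc)[2]) - 0.5) >= neck - 40 &
    (seq_len(dim(hc)[2]) - 0.5) <= neck - 5)
  dy <- abs(rows - yc)
  dy <- dy[dy <= r]
  w <- floor(sqrt(r^2 - dy^2))
  sag <- max(w) - w
  expect_equal(curved, mean(sag), tolerance = 0.05)
})

test_that("the flatter side is identified across seeds and bands must fit", {
  cell <- cached_cell()
  expect_equal(cell$frame$flattened_side, "x_high") # generator bulges -x
  for (s in 11:14) {
    g <- generate_cell_volume(tiny_cell_params(seed = s))
    fr <- cell_frame(g$volume)
    expect_equal(fr$flattened_side, "x_high")
  }
  expect_error(
    flatness_profile(cell$volume, bands_um = list(c(1, 400))),
    "exceeds the cell"
  )
})

test_that("flatness and centre line are equivariant under 180-degree rotation", {
  g <- generate_cell_volume(tiny_cell_params(seed = 21L))
  lv <- g$volume
  d <- dim(lv$voxels)
  # rotate 180 degrees in-plane about the y axis: reverse x and z
  vox_rot <- lv$voxels[d[1]:1, , d[3]:1]
  lv_rot <- label_volume(vox_rot, lv$voxel_size, lv$label_table)
  fr <- cell_frame(lv)
  fr_rot <- cell_frame(lv_rot)
  # sides swap labels consistently
  expect_equal(fr$flattened_side, "x_high")
  expect_equal(fr_rot$flattened_side, "x_low")
  # the centre line mirrors: x + x_mirrored = extent
  ext_x <- volume_extent_nm(lv)[["x"]]
  cl <- fr$centre_line
  clr <- fr_rot$centre_line
  mirrored <- ext_x - rev(clr$x_nm)
  expect_equal(cl$x_nm, mirrored, tolerance = 1e-6)
})

test_that("the infranuclear region and peri-nuclear window match the plant", {
  cell <- cached_cell()
  infra <- infranuclear_mask(cell$volume)
  expect_equal(infra$y_max_index, cell$truth$infranuclear$y_max_index)
  expect_equal(infra$window_z_range, cell$truth$infranuclear$window_z_range)
  # 3 um window = 1.5 um either side = 60 sections at 50 nm
  expect_equal(diff(infra$window_z_range) + 1L, 60L)
  # mask equals the planted region exactly: all cell voxels below the nucleus
  mask <- cytoarch3d:::cell_body_mask(cell$volume)
  expected <- array(FALSE, dim(mask))
  expected[, seq_len(infra$y_max_index), ] <- mask[, seq_len(infra$y_max_index), ]
  expect_identical(infra$mask, expected)

  # nucleus absent -> error
  m <- array(1L, dim = c(3, 3, 3))
  lv0 <- label_volume(m, c(x = 19, y = 19, z = 50), tibble::tibble(label = 1L, class = "cell"))
  expect_error(infranuclear_mask(lv0), "nucleus")
})
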