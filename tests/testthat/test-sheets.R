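line_lv <- function(px_list_by_z, nx = 120L, ny = 30L, nz = 6L) {
  # build a label volume with membrane pixels at given (y,x) per section
  vox <- array(0L, dim = c(nz, ny, nx))
  vox[1, 1, 1] <- 1L
  for (z in seq_along(px_list_by_z)) {
    px <- px_list_by_z[[z]]
    if (!is.null(px) && nrow(px)) vox[cbind(z, px[, 1], px[, 2])] <- 3L
  }
  label_volume(
    vox, c(x = 19, y = 19, z = 50),
    tibble::tibble(label = c(1L, 3L), class = c("cell", "membrane"))
  )
}

test_that("strand extraction: components, lengths, and 8-connectivity", {
  # straight 100-pixel line: 99 steps of 19 nm
  line <- cbind(rep(10L, 100L), 5:104)
  lv <- line_lv(list(line))
  s <- extract_strands(lv)
  expect_equal(nrow(s), 1L)
  expect_equal(s$length_nm, 99 * 19)

  # two disjoint curves on one section -> two strands
  lv2 <- line_lv(list(rbind(line, cbind(rep(20L, 50L), 5:54))))
  expect_equal(nrow(extract_strands(lv2)), 2L)

  # diagonal line is one 8-connected strand with diagonal step lengths
  diagl <- cbind(5:24, 5:24)
  s3 <- extract_strands(line_lv(list(diagl)))
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$length_nm, 19 * sqrt(2) * 19, tolerance = 1e-9)

  # empty volume -> empty table, not an error
  expect_equal(nrow(extract_strands(line_lv(list(NULL)))), 0L)

  # generated cell: one strand per planted sheet per covered section
  cell <- cached_cell()
  per_z_true <- table(unlist(Map(
    seq, cell$truth$sheets$z_first, cell$truth$sheets$z_last
  )))
  per_z_meas <- table(cell$strands$z_index)
  expect_equal(
    as.integer(per_z_meas[names(per_z_true)]),
    as.integer(per_z_true)
  )
})

test_that("the adjacent-section rule links strands as specified", {
  line <- cbind(rep(10L, 40L), 11:50)
  # identical strand on 5 sections -> one sheet spanning 5 sections
  lv <- line_lv(rep(list(line), 5))
  s <- extract_strands(lv)
  sh <- link_strands(s)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$n_strands_count, 5L)
  expect_equal(c(sh$z_first_index, sh$z_last_index), c(1L, 5L))

  # two stacks offset beyond overlap -> two sheets
  line_far <- cbind(rep(20L, 40L), 11:50)
  lv2 <- line_lv(list(line, line_far, line, line_far))
  expect_equal(nrow(link_strands(extract_strands(lv2))), 4L)

  # a gap in z does NOT join the stacks
  lv3 <- line_lv(list(line, NULL, line))
  expect_equal(nrow(link_strands(extract_strands(lv3))), 2L)

  expect_error(link_strands(s, overlap_min = -1), "overlap_min")

  # overlap_min above the actual overlap separates the stacks
  shifted <- cbind(rep(10L, 40L), 13:52) # overlaps line by 38 px
  lv4 <- line_lv(list(line, shifted))
  expect_equal(nrow(link_strands(extract_strands(lv4), overlap_min = 39L)), 2L)
  expect_equal(nrow(link_strands(extract_strands(lv4), overlap_min = 38L)), 1L)

  # centroid-distance alternative rule
  expect_equal(
    nrow(link_strands(extract_strands(lv4), method = "centroid", centroid_max_nm = 100)),
    1L
  )
})

test_that("linkage equals brute-force transitive closure and survives z-flip", {
  for (s in 1:30) {
    set.seed(s)
    strands <- rand_strand_instance(sample(5:18, 1L))
    sheets <- link_strands(strands)
    expect_equal(
      partition_of_sheets(sheets),
      partition_of_bf(bf_sheet_partition(strands)),
      info = paste("instance seed", s)
    )
    # section order reversal: same membership
    flipped <- strands
    flipped$z_index <- max(strands$z_index) + 1L - strands$z_index
    expect_equal(
      partition_of_sheets(link_strands(flipped)),
      partition_of_sheets(sheets)
    )
  }
})

test_that("tube-model areas follow the stated conventions", {
  line <- cbind(rep(10L, 54L), 11:64) # 53 steps * 19 nm = 1007 nm... use exact
  lv <- line_lv(list(line))
  s <- extract_strands(lv)
  sh <- link_strands(s)
  face <- sheet_area(sh, s, lv, mode = "sheet_face")
  tube <- sheet_area(sh, s, lv, mode = "tube_surface")
  L <- s$length_nm
  expect_equal(face$area_um2, L * 50 / 1e6)
  expect_equal(tube$area_um2, 2 * pi * 50 * L / 1e6)
  expect_equal(face$area_mode, "sheet_face")
  expect_error(sheet_area(sh, s, lv, mode = "banana"), "Unknown area mode")

  # planted sheets: measured face areas within 10% of the generator's truth
  cell <- cached_cell()
  expect_lt(
    abs(sum(cell$sheets$area_um2) - sum(cell$truth$sheets$area_um2)) /
      sum(cell$truth$sheets$area_um2),
    0.1
  )
})

test_that("size classification recovers planted populations", {
  # the cached cell's 3 + 8 + 60 mixture is recovered exactly
  cell <- cached_cell()
  td <- generics::tidy(cell$classification)
  expect_equal(td$n_sheets_count[td$class == "Type1"], 3L)
  expect_equal(td$n_sheets_count[td$class == "Type2"], 8L)
  expect_equal(td$n_sheets_count[td$class == "Type3"], 60L)

  # total area is conserved across types
  expect_equal(
    sum(td$total_area_um2),
    sum(cell$classification$assignments$area_um2)
  )

  # classification is monotone: sorted areas give sorted classes
  a <- cell$classification$assignments
  ord <- order(a$area_um2, decreasing = TRUE)
  cls_ord <- a$class[ord]
  expect_true(all(diff(match(cls_ord, c("Type1", "Type2", "Type3"))) >= 0))

  # abstract mixture at the printed Type-3 scale: mean recovered within 2 SE
  set.seed(8)
  areas <- c(
    rlnorm(3, log(36700) - 0.3^2 / 2, 0.3),
    rlnorm(8, log(2383) - 0.36^2 / 2, 0.36),
    rlnorm(2073, log(85) - 0.5^2 / 2, 0.5)
  )
  cl <- classify_sheets(areas)
  td2 <- generics::tidy(cl)
  t3 <- td2[td2$class == "Type3", ]
  expect_lt(abs(t3$mean_area_um2 - 85), 2 * 2) # printed 85 +/- 2 (SE)
})

test_that("manual thresholds and degenerate inputs follow their contracts", {
  areas <- c(100, 90, 10, 9, 1, 0.9, 0.8)
  cl <- classify_sheets(areas, boundaries = list(t1 = 50, t2 = 5), method = "manual")
  expect_equal(
    cl$assignments$class,
    c("Type1", "Type1", "Type2", "Type2", "Type3", "Type3", "Type3")
  )
  expect_error(
    classify_sheets(areas, boundaries = list(t1 = 5, t2 = 50), method = "manual"),
    "out of order"
  )
  expect_error(classify_sheets(c(1, 2)), "at least 3")

  # all-equal areas: degenerate, flagged, no Type 1
  cl0 <- classify_sheets(rep(2, 10))
  expect_true(cl0$degenerate)
  expect_true(all(cl0$assignments$class == "Type3"))
})
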