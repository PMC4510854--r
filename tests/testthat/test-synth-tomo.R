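test_that("tomogram parameters are validated", {
  expect_error(tomo_gen_params(link_counts = c("vesicle-golgi" = 3L)), "Unknown link context")
  expect_error(tomo_gen_params(voxel_size_nm = -1), "voxel_size")
  expect_error(
    tomo_gen_params(link_length_means = c(
      "mito-RER" = -5, "vesicle-RER" = 52.9, "vesicle-vesicle@RER" = 45.4,
      "vesicle-vesicle@ribbon" = 22.3, "vesicle-ribbon" = 26.8
    )),
    "must be > 0"
  )
})

test_that("zero link counts give a membranes-only volume with empty truth", {
  g <- generate_tomogram_volume(tomo_gen_params(
    link_counts = c("mito-RER" = 0L),
    n_free_vesicles = 0L, n_unattached_tethers = 0L, seed = 1L
  ))
  expect_equal(nrow(g$truth$links), 0L)
  expect_equal(nrow(g$truth$vesicles), 0L)
  expect_setequal(
    g$volume$label_table$class,
    c("membrane", "mitochondrion", "ribbon")
  )
})

test_that("a fixed seed reproduces the tomogram bit for bit", {
  p <- small_tomo_params(seed = 9L, n = 4L)
  g1 <- generate_tomogram_volume(p)
  g2 <- generate_tomogram_volume(p)
  expect_identical(g1$volume$voxels, g2$volume$voxels)
  expect_identical(g1$truth$links, g2$truth$links)
})

test_that("planted lengths and diameters follow their target distributions", {
  tomo <- cached_tomo()
  tr <- tomo$truth
  means <- c(
    "mito-RER" = 30.9, "vesicle-RER" = 52.9, "vesicle-vesicle@RER" = 45.4,
    "vesicle-vesicle@ribbon" = 22.3, "vesicle-ribbon" = 26.8
  )
  sds <- c(
    "mito-RER" = 8.6, "vesicle-RER" = 26.2, "vesicle-vesicle@RER" = 23.4,
    "vesicle-vesicle@ribbon" = 6.2, "vesicle-ribbon" = 10.8
  )
  agg <- tr$links |>
    dplyr::filter(!is.na(context)) |>
    dplyr::group_by(context) |>
    dplyr::summarise(n = dplyr::n(), m = mean(length_nm))
  expect_equal(agg$n, rep(10L, 5))
  for (ct in agg$context) {
    se <- sds[[ct]] / sqrt(10)
    expect_lt(abs(agg$m[agg$context == ct] - means[[ct]]), 3.5 * se)
  }
  # voxelised vesicles reproduce their drawn diameters within one voxel
  vd <- vesicle_diameters(tomo$volume)
  vm <- dplyr::inner_join(vd, tr$vesicles, by = "label")
  expect_lt(mean(abs(vm$diameter_nm.x - vm$diameter_nm.y)), 2)
})

test_that("tomogram truth traces every label and separates objects", {
  tomo <- cached_tomo()
  lv <- tomo$volume
  truth_labels <- sort(c(1L, 2L, 3L, tomo$truth$vesicles$label, tomo$truth$links$label))
  expect_equal(sort(lv$label_table$label), truth_labels)
  expect_equal(anyDuplicated(truth_labels), 0L)
  # unattached tethers are flagged in the truth
  expect_equal(sum(!tomo$truth$links$attached_both_ends), 2L)
})
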