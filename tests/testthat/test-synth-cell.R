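test_that("parameter validation names the violated constraint", {
  expect_error(cell_gen_params(p_flat_terminal = 1.4), "p_flat_terminal")
  expect_error(cell_gen_params(membrane_fraction_flat = -0.1), "membrane_fraction_flat")
  expect_error(
    cell_gen_params(voxel_size = c(x = 0, y = 19, z = 50)),
    "voxel_size"
  )
  expect_error(
    cell_gen_params(
      membrane_fraction_ant = 0.4, membrane_fraction_post = 0.38
    ),
    "Inconsistent hemisphere fractions"
  )
  # geometry infeasibility is reported, not silently mangled
  expect_error(
    generate_cell_volume(cell_gen_params(
      cell_width_um = 2, bulge_amplitude_nm = 800
    )),
    "bulge_amplitude"
  )
  # every ribbon needs a dedicated Type-3 sheet
  p <- tiny_cell_params()
  p$sheet_area_mixture$counts[3] <- 1L
  expect_error(generate_cell_volume(p), "Type-3")
})

test_that("a fixed seed reproduces the volume bit for bit", {
  p <- tiny_cell_params(seed = 5L)
  g1 <- generate_cell_volume(p)
  g2 <- generate_cell_volume(p)
  expect_identical(g1$volume$voxels, g2$volume$voxels)
  expect_identical(g1$truth$fractions, g2$truth$fractions)
  expect_identical(g1$truth$sheets, g2$truth$sheets)
  # a different seed gives a different volume
  g3 <- generate_cell_volume(tiny_cell_params(seed = 6L))
  expect_false(identical(g1$volume$voxels, g3$volume$voxels))
})

test_that("ground truth is complete and labels are mutually exclusive", {
  cell <- cached_cell()
  lv <- cell$volume
  tr <- cell$truth
  # every non-zero label maps to exactly one truth object
  truth_labels <- sort(c(
    1L, 2L, tr$sheets$label, tr$mitochondria$label,
    tr$ribbons$label, tr$terminals$label
  ))
  expect_equal(sort(lv$label_table$label), truth_labels)
  present <- setdiff(unique(as.vector(lv$voxels)), 0L)
  expect_true(all(present %in% truth_labels))
  # labels are unique per object by construction: no duplicates
  expect_equal(anyDuplicated(truth_labels), 0L)
  # sum of per-class sheet counts equals total sheets
  expect_equal(sum(table(tr$sheets$type)), nrow(tr$sheets))
})

test_that("planted hemisphere fractions hit their targets within 0.01", {
  tr <- cached_cell()$truth
  # flattened/rounded are honoured exactly; anterior/posterior absorb the
  # (inconsistent) printed pair additively around the flat/round mean
  expect_lt(
    max(abs(tr$fractions$planted_frac - tr$fractions$target_frac)),
    0.01
  )
  expect_gt(
    tr$fractions$planted_frac[1] - tr$fractions$planted_frac[2],
    0.05
  ) # the flat > round contrast is present
})

test_that("terminal placement is binomial with the configured bias", {
  counts <- cached_terminal_counts(24L)
  n <- 16L
  p <- 0.63
  # binomial oracle: mean flattened-terminal count within 3 SE of n*p
  se <- sqrt(n * p * (1 - p) / nrow(counts))
  expect_lt(abs(mean(counts$n_flat_true) - n * p), 3 * se)
  expect_true(all(counts$n_total == n))
})

test_that("planted ribbon-to-sheet distances land near their draws", {
  tr <- cached_cell()$truth
  # the realised nearest-Type-3 distance tracks the per-ribbon draw
  expect_lt(max(abs(tr$ribbons$d_type3_nm - tr$ribbons$d3_target_nm)), 120)
})
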