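# Unit tests for table round-trips, NIfTI ROI extraction, and result bundles.

small_cohort <- function(seed = 4) {
  generate_cohort(cohort_spec(n_group_a = 10, n_group_b = 10, n_regions = 12,
                              module_assignment = rep(1:2, each = 6),
                              seed = seed))
}

test_that("volume tables round-trip losslessly through CSV", {
  coh <- small_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_volume_table(coh, f)
  back <- read_volume_table(f, attr(coh, "atlas"))
  for (nm in names(coh)) {
    if (is.numeric(coh[[nm]])) {
      expect_equal(back[[nm]], coh[[nm]], tolerance = 1e-12)
    } else {
      expect_identical(back[[nm]], coh[[nm]])
    }
  }
})

test_that("region columns are matched by label regardless of order", {
  coh <- small_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  atlas <- attr(coh, "atlas")
  shuffled <- coh[, c("subject_id", "group", "tiv", rev(as.character(atlas)))]
  utils::write.csv(shuffled, f, row.names = FALSE, quote = FALSE)
  back <- read_volume_table(f, atlas)
  expect_identical(names(back)[4:15], as.character(atlas))
  expect_equal(back[[as.character(atlas)[1]]], coh[[as.character(atlas)[1]]],
               tolerance = 1e-12)
})

test_that("malformed volume tables produce named errors", {
  coh <- small_cohort()
  atlas <- attr(coh, "atlas")
  f <- withr::local_tempfile(fileext = ".csv")

  # missing region column
  drop1 <- coh[, setdiff(names(coh), as.character(atlas)[3])]
  utils::write.csv(drop1, f, row.names = FALSE, quote = FALSE)
  expect_error(read_volume_table(f, atlas), as.character(atlas)[3], fixed = TRUE)

  # duplicated subject id
  dup <- coh; dup$subject_id[2] <- dup$subject_id[1]
  utils::write.csv(dup, f, row.names = FALSE, quote = FALSE)
  expect_error(read_volume_table(f, atlas), "duplicate")

  # three group levels
  tri <- coh; tri$group[1] <- "C"
  utils::write.csv(tri, f, row.names = FALSE, quote = FALSE)
  expect_error(read_volume_table(f, atlas), "two levels")

  # non-numeric volume cell names row and column
  bad <- coh; bad[[as.character(atlas)[2]]] <- as.character(bad[[as.character(atlas)[2]]])
  bad[3, as.character(atlas)[2]] <- "oops"
  utils::write.csv(bad, f, row.names = FALSE, quote = FALSE)
  err <- tryCatch(read_volume_table(f, atlas), error = conditionMessage)
  expect_match(err, as.character(atlas)[2], fixed = TRUE)
  expect_match(err, "row 3")

  expect_error(read_volume_table("/nonexistent/file.csv", atlas), "not found")
})

test_that("ROI extraction sums voxels and converts with the voxel volume", {
  atlas <- region_atlas(c("left", "right"))
  dims <- c(4, 4, 2)
  lab <- array(0L, dims); lab[1:2, , ] <- 1L; lab[3:4, 1:2, ] <- 2L
  gm <- array(0.5, dims)
  gm[1, 1, 1] <- 1.5   # perturb one voxel of region 1
  f_gm <- withr::local_tempfile(fileext = ".nii.gz")
  f_lab <- withr::local_tempfile(fileext = ".nii.gz")
  # 2 x 2 x 2.5 mm voxels -> 10 mm^3 each
  attr(gm, "pixdim") <- c(2, 2, 2.5)
  attr(lab, "pixdim") <- c(2, 2, 2.5)
  RNifti::writeNifti(RNifti::asNifti(gm, datatype = "double"), f_gm)
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"), f_lab)
  vols <- extract_roi_volumes(f_gm, f_lab, atlas)
  expect_equal(unname(vols["left"]), (16 * 0.5 + 1) * 10 / 1000, tolerance = 1e-9)
  expect_equal(unname(vols["right"]), 8 * 0.5 * 10 / 1000, tolerance = 1e-9)

  # mismatched grids are refused with both shapes in the message
  f_bad <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0.5, c(3, 4, 2)), datatype = "double"), f_bad)
  expect_error(extract_roi_volumes(f_bad, f_lab, atlas), "3x4x2")
})

test_that("result bundles round-trip and incomplete bundles are refused", {
  grid <- density_grid(0.35, 0.5, 0.075)
  cfg <- pipeline_config(
    synthetic = cohort_spec(n_group_a = 30, n_group_b = 30, n_regions = 20,
                            module_assignment = rep(1:4, each = 5),
                            r_within = 0.6, r_between = 0.2, seed = 31),
    perm = perm_config(n_perm = 19, seed = 2, grid = grid, n_null = 3),
    out_dir = withr::local_tempdir(), resilience_modes = "targeted",
    resilience_n_iter = 5, verbose = FALSE)
  res <- suppressMessages(run_pipeline(cfg))
  bundle <- read_results(cfg$out_dir)
  expect_identical(bundle$manifest$seed, 2L)
  expect_equal(nrow(bundle$global_a), 3)
  expect_equal(nrow(bundle$nodal), 20)
  expect_true(all(c("metric", "auc_a", "auc_b", "auc_diff", "p") %in%
                  names(bundle$auc_tests)))

  file.remove(file.path(cfg$out_dir, "nodal_bc.csv"))
  expect_error(read_results(cfg$out_dir), "nodal_bc.csv")
})
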