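test_that("extract_label_mask takes unions and rejects empty results", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:5, 1:5, 1:4] <- 8L
  lab[6:10, 1:5, 1:4] <- 47L
  lv <- label_volume(lab, grid_affine())
  m8 <- extract_label_mask(lv, 8L)
  m47 <- extract_label_mask(lv, 47L)
  m_both <- extract_label_mask(lv, c(8L, 47L))
  expect_equal(sum(m_both$voxels), 200L)
  expect_equal(m_both$voxels, m8$voxels | m47$voxels)
  expect_error(extract_label_mask(lv, integer(0)), "empty")
  expect_error(extract_label_mask(lv, 99L), "no voxel")
})

test_that("erosion peels a cube as expected and always shrinks", {
  cube <- cube_mask(c(9, 9, 9), c(3, 3, 3), c(7, 7, 7))  # 5x5x5 solid
  e1 <- anat_correct_erode(cube, 1)
  expect_equal(sum(e1$voxels), 27L)
  e2 <- anat_correct_erode(cube, 2)
  expect_equal(sum(e2$voxels), 1L)
  expect_true(all(e1$voxels[cube$voxels] | !e1$voxels[cube$voxels]))
  expect_true(all(which(e1$voxels) %in% which(cube$voxels)))
  expect_error(anat_correct_erode(cube, 3), "smaller depth")
})

test_that("lateral cut removes voxels strictly lateral to the ventricles", {
  d <- c(41, 11, 11)
  aff <- grid_affine(2)
  aff[1:3, 4] <- -c(40, 10, 10)  # world x spans [-40, 40] mm
  vent <- array(FALSE, d)
  occ <- array(FALSE, d)
  xw <- seq(-40, 40, by = 2)
  vent[abs(xw) <= 20, 4:8, 4:8] <- TRUE
  occ[, 2:10, 2:10] <- TRUE
  cut <- anat_correct_lateral_cut(voxel_mask(occ, aff), voxel_mask(vent, aff))
  # brute-force coordinate oracle: surviving voxels must satisfy |x| <= 20
  surv <- which(cut$voxels, arr.ind = TRUE)
  x_surv <- (surv[, 1] - 1) * 2 - 40
  expect_true(all(abs(x_surv) <= 20))
  # every medial voxel survives
  keep_expected <- occ & array(rep(abs(xw) <= 20, prod(d[2:3])), d)
  expect_equal(cut$voxels, keep_expected)

  # mask entirely medial -> unchanged
  med <- array(FALSE, d); med[abs(xw) <= 10, 4:8, 4:8] <- TRUE
  out <- anat_correct_lateral_cut(voxel_mask(med, aff), voxel_mask(vent, aff))
  expect_equal(out$voxels, med)

  # mask entirely lateral -> error
  lat <- array(FALSE, d); lat[abs(xw) > 30, 4:8, 4:8] <- TRUE
  expect_error(anat_correct_lateral_cut(voxel_mask(lat, aff),
                                        voxel_mask(vent, aff)), "every")

  # one-hemisphere ventricles fall back to the global limit with a warning
  vhalf <- vent; vhalf[xw < 0, , ] <- FALSE
  expect_warning(anat_correct_lateral_cut(voxel_mask(occ, aff),
                                          voxel_mask(vhalf, aff)),
                 "left hemisphere")
})

test_that("tail exclusion reproduces Gaussian FWHM bounds and kills outliers", {
  set.seed(21)
  d <- c(30, 30, 30)
  n <- 10000
  img <- array(0, d)
  mask <- array(FALSE, d)
  idx <- sample(prod(d), n + 20)
  mask[idx] <- TRUE
  img[idx[1:n]] <- rnorm(n, 2, 0.3)
  img[idx[(n + 1):(n + 20)]] <- 2 + 10 * 0.3  # simulated spill-in
  te <- tail_exclusion(voxel_mask(mask, grid_affine()), img)
  lo_true <- 2 - 1.1774 * 0.3
  hi_true <- 2 + 1.1774 * 0.3
  expect_lt(abs(te$bounds[1] - lo_true) / lo_true, 0.05)
  expect_lt(abs(te$bounds[2] - hi_true) / hi_true, 0.05)
  # brute-force oracle: exactly the voxels outside [lo, hi] are excluded
  vals <- img[mask]
  expect_equal(sum(te$mask$voxels), sum(vals >= te$bounds[1] & vals <= te$bounds[2]))
  # all 20 injected outliers excluded
  expect_false(any(te$mask$voxels[idx[(n + 1):(n + 20)]]))
  expect_gte(te$n_excluded_high, 20L)
})

test_that("tail exclusion degenerates gracefully", {
  d <- c(10, 10, 10)
  m <- voxel_mask(array(TRUE, d), grid_affine())
  img <- array(4.2, d)
  te <- tail_exclusion(m, img)  # constant intensities: nothing to exclude
  expect_equal(te$bounds, c(4.2, 4.2))
  expect_equal(sum(te$mask$voxels), 1000L)
  # small masks skip with a warning
  small <- cube_mask(d, c(1, 1, 1), c(3, 3, 3))
  expect_warning(te2 <- tail_exclusion(small, img), "skipping")
  expect_equal(te2$mask$voxels, small$voxels)
})

test_that("generate_reference_region chains stages with monotone shrinkage", {
  ph <- fx_phantom()
  cfg <- default_tracer_config("raclopride")
  tr <- generate_reference_region(ph$labels, ph$image, cfg)
  expect_true(all(which(tr$mask_final$voxels) %in% which(tr$mask_anat$voxels)))
  expect_true(all(which(tr$mask_anat$voxels) %in% which(tr$mask_raw$voxels)))
  expect_true(tr$volumes_ml["final"] <= tr$volumes_ml["anat"])
  expect_true(tr$volumes_ml["anat"] <= tr$volumes_ml["raw"])
  # volumes consistent with voxel count x voxel volume (2 mm isotropic)
  expect_equal(unname(tr$volumes_ml["raw"]),
               sum(tr$mask_raw$voxels) * 8 / 1000)

  # tail_exclusion off -> mask_final == mask_anat
  cfg_off <- cfg; cfg_off$tail_exclusion <- FALSE
  tr_off <- generate_reference_region(ph$labels, ph$image, cfg_off)
  expect_equal(tr_off$mask_final$voxels, tr_off$mask_anat$voxels)

  # errors carry the stage name
  cfg_bad <- cfg; cfg_bad$label_codes <- 999L
  expect_error(generate_reference_region(ph$labels, ph$image, cfg_bad),
               "label_extraction")
})

test_that("noiseless homogeneous phantom: final-mask TAC equals generator TAC", {
  ph <- fx_phantom0()
  cfg <- default_tracer_config("raclopride")
  tr <- generate_reference_region(ph$labels, ph$image, cfg)
  tc <- extract_tac(ph$image, tr$mask_final)
  expect_lt(max(abs(tc$value - ph$truth[["8"]]$tac$value)), 1e-10)
})

test_that("hot rim adjacent to the reference is excluded by the tail step", {
  # homogeneous reference sphere plus a hot rim simulating occipital
  # spill-in: rim voxels carry 3x the reference activity
  ph <- fx_phantom0()
  img <- ph$image
  cfg <- default_tracer_config("raclopride")
  cfg$erosion_depth <- 1L
  raw <- extract_label_mask(ph$labels, 8L)
  anat <- anat_correct_erode(raw, 1L)
  # paint a hot shell: the peeled-off voxels, at 3x activity
  shell <- raw$voxels & !anat$voxels
  vox <- img$voxels
  nf <- dim(vox)[4]
  nvox <- prod(dim(vox)[1:3])
  sh_idx <- which(shell)
  for (f in seq_len(nf)) vox[sh_idx + (f - 1) * nvox] <-
    3 * vox[sh_idx + (f - 1) * nvox]
  hot_img <- dynamic_image(vox, img$affine, img$schedule)
  # without anatomical correction the tail exclusion must drop the rim
  cfg_none <- cfg; cfg_none$anatomical_correction <- "none"
  # the rim makes the intensity distribution bimodal; the half-max search
  # is expected to warn and fall back on one side
  suppressWarnings(tr <- generate_reference_region(ph$labels, hot_img, cfg_none))
  expect_false(any(tr$mask_final$voxels[shell]))
})
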