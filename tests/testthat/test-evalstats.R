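test_that("spatial_overlap is the manual-denominated asymmetric ratio", {
  a <- cube_mask(c(10, 10, 10), c(1, 1, 1), c(5, 5, 5))
  expect_equal(spatial_overlap(a, a), 100)
  b <- cube_mask(c(10, 10, 10), c(6, 6, 6), c(10, 10, 10))
  expect_equal(spatial_overlap(a, b), 0)
  # auto strictly containing manual scores 100 regardless of auto size
  big <- cube_mask(c(10, 10, 10), c(1, 1, 1), c(9, 9, 9))
  expect_equal(spatial_overlap(big, a), 100)
  expect_lt(spatial_overlap(a, big), 100)
  # shared-intersection identity
  expect_equal(spatial_overlap(a, big) * sum(big$voxels),
               spatial_overlap(big, a) * sum(a$voxels))
  expect_error(spatial_overlap(a, cube_mask(c(10, 10, 10), c(1, 1, 1),
                                            c(1, 1, 1))), NA)
  empty <- voxel_mask(array(FALSE, c(10, 10, 10)), grid_affine())
  expect_error(spatial_overlap(a, empty), "empty")
})

test_that("pairwise_overlap_summary averages ordered pairs", {
  d <- c(6, 6, 6)
  a <- cube_mask(d, c(1, 1, 1), c(1, 1, 10 %% 6))  # placeholder replaced below
  A <- voxel_mask(array(rep(c(TRUE, FALSE), length.out = 216), d), grid_affine())
  expect_equal(pairwise_overlap_summary(list(A, A, A)), 100)
  # |A|=|B|=10, |A and B|=5 -> mean(50, 50) = 50
  m1 <- array(FALSE, d); m1[1:10] <- TRUE
  m2 <- array(FALSE, d); m2[6:15] <- TRUE
  expect_equal(pairwise_overlap_summary(list(voxel_mask(m1, grid_affine()),
                                             voxel_mask(m2, grid_affine()))), 50)
  disj <- list(voxel_mask(m1, grid_affine()),
               voxel_mask(array(c(rep(FALSE, 100), rep(TRUE, 10),
                                  rep(FALSE, 106)), d), grid_affine()))
  expect_equal(pairwise_overlap_summary(disj), 0)
  expect_error(pairwise_overlap_summary(list(A)), ">= 2")
})

test_that("icc_components: deterministic edge cases", {
  # values depend only on study -> icc_study = 1
  d <- expand.grid(study = 1:10, operator = 1:4)
  d$value <- d$study * 2.5
  vc <- icc_components(rater_table(d$study, d$operator, d$value))
  expect_equal(vc$icc_study, 1, tolerance = 1e-6)
  expect_equal(vc$icc_operator, 0, tolerance = 1e-6)
  # share sum is 1 after clipping
  expect_equal(vc$icc_study + vc$icc_operator +
                 vc$sigma2_residual / (vc$sigma2_study + vc$sigma2_operator +
                                         vc$sigma2_residual), 1,
               tolerance = 1e-10)
  # pure noise -> icc_study ~ 0
  set.seed(5)
  d$value <- rnorm(nrow(d))
  vc0 <- icc_components(rater_table(d$study, d$operator, d$value))
  expect_lt(vc0$icc_study, 0.2)
  expect_error(rater_table(c(1, 1), c(1, 1), c(1, 2)), "duplicated")
})

test_that("icc is invariant under affine transformation of the values", {
  set.seed(6)
  d <- expand.grid(study = 1:15, operator = 1:4)
  d$value <- rnorm(15)[d$study] + rnorm(4, 0, 0.4)[d$operator] +
    rnorm(nrow(d), 0, 0.3)
  v1 <- icc_components(rater_table(d$study, d$operator, d$value))
  v2 <- icc_components(rater_table(d$study, d$operator, 3.7 * d$value - 11))
  expect_equal(v1$icc_study, v2$icc_study, tolerance = 1e-6)
  expect_equal(v1$icc_operator, v2$icc_operator, tolerance = 1e-6)
})

test_that("standardize_auc divides by per-study union means and cancels in ICC", {
  t0 <- rater_table(rep(1:2, each = 2), rep(1:2, 2), c(100, 110, 50, 55))
  st <- standardize_auc(t0, c(`1` = 50, `2` = 25))
  expect_equal(st$value, c(2, 2.2, 2, 2.2))
  expect_error(standardize_auc(t0, c(`1` = 50, `2` = 0)), "> 0")
  # a per-study scale factor cancels after standardization
  set.seed(8)
  d <- expand.grid(study = 1:12, operator = 1:4)
  base <- 2 + rnorm(12, 0, 0.5)[d$study] + rnorm(4, 0, 0.2)[d$operator] +
    rnorm(nrow(d), 0, 0.1)
  scale_per_study <- runif(12, 0.5, 2)
  scaled <- base * scale_per_study[d$study]
  um <- setNames(scale_per_study, 1:12)
  v_ref <- icc_components(rater_table(d$study, d$operator, base))
  v_std <- icc_components(standardize_auc(
    rater_table(d$study, d$operator, scaled), um))
  expect_equal(v_std$icc_study, v_ref$icc_study, tolerance = 1e-6)
})

test_that("distribution_summary matches known-distribution oracles", {
  set.seed(9)
  x <- rnorm(1e5, 1.5, 0.2)
  ds <- distribution_summary(x)
  expect_lt(abs(ds$mode - 1.5), 0.02)
  expect_lt(abs(ds$skewness), 0.05)
  expect_equal(ds$mean, mean(x))
  expect_equal(ds$sd, sd(x))
  # exponential: skewness 2
  e <- rexp(1e5)
  expect_lt(abs(distribution_summary(e)$skewness - 2) / 2, 0.10)
  # degenerate constant sample
  dc <- distribution_summary(rep(3, 200))
  expect_equal(dc$sd, 0)
  expect_equal(dc$fwhm_bounds, c(3, 3))
  expect_error(distribution_summary(rnorm(50)), ">= 100")
})

test_that("distribution_overlap: identity, disjoint, analytic Gaussian case", {
  set.seed(10)
  x <- rnorm(1e5)
  expect_gt(distribution_overlap(x, x), 99)
  expect_lt(distribution_overlap(x, rnorm(1e5, 10)), 1)
  # two unit Gaussians one sd apart: overlap 2*pnorm(-1/2) = 61.7%
  ov <- distribution_overlap(x, rnorm(1e5, 1))
  expect_lt(abs(ov - 100 * 2 * pnorm(-0.5)), 2)
  # symmetry within KDE grid tolerance
  y <- rnorm(1e4, 0.4)
  expect_equal(distribution_overlap(x[1:1e4], y),
               distribution_overlap(y, x[1:1e4]), tolerance = 1e-6)
})

test_that("relative_bias handles equality, scaling, and zero denominators", {
  expect_equal(relative_bias(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(relative_bias(1.05 * c(2, 4, 8), c(2, 4, 8)), rep(5, 3),
               tolerance = 1e-12)
  expect_warning(b <- relative_bias(c(1, 1), c(1, 0)), "zero denominator")
  expect_true(is.nan(b[2]))
  expect_error(relative_bias(1:3, 1:2), "shape")
})

test_that("pearson_r matches expectations on exact and null cases", {
  x <- 1:50
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(12)
  expect_lt(abs(pearson_r(rnorm(1e5), rnorm(1e5))), 0.01)
  expect_error(pearson_r(x, rep(1, 50)), "zero variance")
})
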