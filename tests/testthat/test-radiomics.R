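# Radiomics primitives: discretization, first-order, shape, texture edge
# cases, filter banks, and the assembled 1,132-feature bank.

test_that("discretization follows the right-closed equal-width convention", {
  v <- array(c(0, 5, 10), dim = c(3, 1, 1))
  m <- array(TRUE, dim = c(3, 1, 1))
  d <- discretize(v, m, n_bins = 2)
  expect_equal(as.vector(d$levels), c(1L, 1L, 2L))
  # identity mapping when values already hit every bin
  v2 <- array(0:31, dim = c(32, 1, 1))
  d2 <- discretize(v2, array(TRUE, dim = c(32, 1, 1)), n_bins = 32)
  expect_equal(as.vector(d2$levels), 1:32)
  # constant region occupies level 1 only
  d3 <- discretize(array(7, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), n_bins = 32)
  expect_equal(unique(as.vector(d3$levels)), 1L)
  expect_error(discretize(v, array(FALSE, dim = c(3, 1, 1))), "empty mask")
})

test_that("first-order features hit the closed-form histogram values", {
  d <- const_dvol()
  f <- first_order(d)
  expect_length(f, 18)
  expect_equal(f[["firstorder__Uniformity"]], 1.0)
  expect_equal(f[["firstorder__Entropy"]], 0.0)
  # two equally frequent levels
  d2 <- make_dvol(array(rep(c(1L, 2L), 8), c(4, 2, 2)), 2)
  expect_equal(first_order(d2)[["firstorder__Uniformity"]], 0.5)
  # histogram (0.5, 0.25, 0.25): sum of squares = 0.375
  lev <- array(c(rep(1L, 4), rep(2L, 2), rep(3L, 2)), c(8, 1, 1))
  d3 <- make_dvol(lev, 3)
  expect_equal(first_order(d3)[["firstorder__Uniformity"]], 0.375)
  # the 19th feature is only present on request
  expect_length(first_order(d, include_sd = TRUE), 19)
})

test_that("shape features match analytic geometry", {
  ball <- test_ellipsoid(c(8, 8, 8))
  f <- shape3d(ball, c(1, 1, 1))
  expect_length(f, 14)
  expect_lt(abs(f[["shape__Flatness"]] - 1), 0.05)
  expect_lt(abs(f[["shape__Elongation"]] - 1), 0.05)
  ell <- test_ellipsoid(c(8, 4, 2))
  expect_lt(abs(shape3d(ell, c(1, 1, 1))[["shape__Flatness"]] - 0.25), 0.05)
  # single voxel at unit spacing
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  fs <- shape3d(single, c(1, 1, 1))
  expect_equal(fs[["shape__VoxelVolume"]], 1)
  expect_equal(fs[["shape__SurfaceArea"]], 6)
  # degenerate coplanar mask flagged by zero flatness
  plane <- array(FALSE, c(4, 4, 4)); plane[, , 2] <- TRUE
  expect_equal(shape3d(plane, c(1, 1, 1))[["shape__Flatness"]], 0)
})

test_that("shape features are invariant to axis permutation with permuted spacing", {
  ell <- test_ellipsoid(c(7, 5, 3), spacing = c(1, 1, 2))
  f1 <- shape3d(ell, c(1, 1, 2))
  f2 <- shape3d(aperm(ell, c(3, 1, 2)), c(2, 1, 1))
  keep <- setdiff(names(f1), paste0("shape__", c("Maximum2DDiameterSlice",
                                                 "Maximum2DDiameterColumn",
                                                 "Maximum2DDiameterRow")))
  expect_equal(f1[keep], f2[keep], tolerance = 1e-10)
})

test_that("co-occurrence features on constructed volumes match hand enumeration", {
  expect_equal(glcm_features(const_dvol())[["glcm__MaximumProbability"]], 1.0)
  expect_equal(glcm_features(const_dvol())[["glcm__JointEntropy"]], 0.0)
  # 1x1x4 levels (1,1,2,2) along the only informative direction:
  # symmetric pairs {(1,1),(2,2),(1,2),(2,1)} with masses 1/3,1/3,1/6,1/6
  d <- make_dvol(array(c(1L, 1L, 2L, 2L), c(1, 1, 4)), 2)
  f <- glcm_features(d, directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(f[["glcm__MaximumProbability"]], 1 / 3)
  # single voxel: no pairs in any direction -> missing
  d1 <- make_dvol(array(1L, c(1, 1, 1)), 2)
  expect_true(all(is.na(glcm_features(d1))))
})

test_that("run-length features on constructed volumes match hand enumeration", {
  d1 <- make_dvol(array(1L, c(1, 1, 1)), 2)
  expect_equal(glrlm_features(d1)[["glrlm__LongRunLowGrayLevelEmphasis"]], 1.0)
  # 1x1x4 all level 1 along the axis: single run of length 4 -> 16/1
  d <- make_dvol(array(1L, c(1, 1, 4)), 2)
  f <- glrlm_features(d, directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(f[["glrlm__LongRunLowGrayLevelEmphasis"]], 16.0)
  expect_equal(f[["glrlm__RunPercentage"]], 1 / 4)
})

test_that("size-zone features on constructed volumes match hand enumeration", {
  # constant 2x2x2: one zone of level 1, size 8 -> SALGLE = 1/64
  d <- make_dvol(array(1L, c(2, 2, 2)), 2)
  expect_equal(glszm_features(d)[["glszm__SmallAreaLowGrayLevelEmphasis"]], 1 / 64)
  d1 <- make_dvol(array(1L, c(1, 1, 1)), 2)
  expect_equal(glszm_features(d1)[["glszm__SmallAreaLowGrayLevelEmphasis"]], 1.0)
})

test_that("dependence features on constructed volumes match hand enumeration", {
  # single voxel: zero dependents -> dependence size 1 -> SDE = 1
  d1 <- make_dvol(array(1L, c(1, 1, 1)), 2)
  expect_equal(gldm_features(d1)[["gldm__SmallDependenceEmphasis"]], 1.0)
  # constant 3x3x3: centre voxel has 26 dependents (size 27), corners 7 (size 8)
  d <- make_dvol(array(1L, c(3, 3, 3)), 2)
  deps <- radpath:::cpp_gldm_deps(as.integer(d$levels), d$dims, 0L)
  expect_equal(sort(unique(deps[, 2])), c(7L, 11L, 17L, 26L))
  expect_equal(sum(deps[, 2] == 26), 1)   # only the centre
  expect_equal(gldm_features(d)[["gldm__LargeDependenceEmphasis"]],
               mean((deps[, 2] + 1)^2))
})

test_that("wavelet bank is an orthogonal 8-band decomposition", {
  set.seed(3)
  v <- array(rnorm(12 * 10 * 8), c(12, 10, 8))
  wb <- wavelet_bank(v)
  expect_length(wb, 8)
  expect_true(all(vapply(wb, function(x) identical(dim(x), dim(v)), TRUE)))
  # constant volume: every band with an H letter is (numerically) zero
  wc <- wavelet_bank(array(4, c(8, 8, 8)))
  expect_lt(max(abs(wc$`wavelet-HHH`)), 1e-8)
  expect_lt(max(abs(wc$`wavelet-LHL`)), 1e-8)
  # energy conservation (orthogonal wavelet, even dims)
  energy <- sum(vapply(wb, function(x) sum(x^2), 0))
  expect_equal(energy / sum(v^2), 1, tolerance = 0.01)
  # the sub-bands are projections: they sum back to the input
  expect_equal(Reduce(`+`, wb), v, tolerance = 1e-10)
  expect_error(wavelet_bank(array(0, c(4, 8, 8))), "too small")
})

test_that("LoG bank responds at the blob's characteristic scale", {
  lb <- log_bank(array(rnorm(8^3), c(8, 8, 8)), c(1, 1, 1), c(1, 2, 3, 4))
  expect_length(lb, 4)
  expect_lt(max(abs(log_bank(array(2, c(10, 10, 10)), c(1, 1, 1), 2)[[1]])), 1e-10)
  expect_error(log_bank(array(0, c(8, 8, 8)), sigmas_mm = c(-1)), "sigmas")
  # bright ball of radius 4 mm: |normalized response| at the centre peaks
  # near sigma = r / sqrt(3) ~ 2.3 on the 1..4 grid
  m <- test_ellipsoid(c(4, 4, 4))
  vol <- array(0, dim(m)); vol[m] <- 1
  cen <- (dim(m) + 1) %/% 2
  resp <- vapply(log_bank(vol, c(1, 1, 1), c(1, 2, 3, 4)),
                 function(x) abs(x[cen[1], cen[2], cen[3]]), 0)
  expect_equal(unname(which.max(resp)), 2)
})

test_that("the assembled bank reproduces the published feature counts", {
  ph <- make_phantom(phantom_spec(shape_voxels = c(24, 24, 18),
                                  semi_axes_mm = list(edema = c(9, 7, 6),
                                                      enhancing = c(6, 4.5, 4),
                                                      necrosis = c(3, 2.2, 2)),
                                  seed = 8), "wildtype")
  v <- extract_all(ph$volumes$t1ce, ph$masks$edema, spacing = ph$spacing_mm)
  expect_length(v, 1132)
  reg <- mri_bank_registry()
  expect_identical(names(v), reg$name)
  counts <- table(reg$class)
  expect_equal(unname(counts[["firstorder"]]), 234)
  expect_equal(unname(counts[["shape"]]), 14)
  expect_equal(unname(counts[["glcm"]]), 286)
  expect_equal(unname(counts[["glrlm"]]), 208)
  expect_equal(unname(counts[["glszm"]]), 208)
  expect_equal(unname(counts[["gldm"]]), 182)
  expect_false(any(duplicated(reg$name)))
  # optional NGTDM class adds 5 per image type
  expect_equal(nrow(mri_bank_registry(include_ngtdm = TRUE)), 1132 + 13 * 5)
  expect_error(extract_all(ph$volumes$t1ce, array(FALSE, dim(ph$volumes$t1ce))),
               "empty mask")
})

test_that("texture features ignore a constant intensity shift", {
  ph <- make_phantom(phantom_spec(shape_voxels = c(20, 20, 16),
                                  semi_axes_mm = list(edema = c(7, 6, 5),
                                                      enhancing = c(4.5, 4, 3.5),
                                                      necrosis = c(2, 1.8, 1.6)),
                                  seed = 3), "wildtype")
  v <- ph$volumes$t1ce
  m <- ph$masks$edema
  d1 <- discretize(v, m, 16)
  d2 <- discretize(v + 11.5, m, 16)
  expect_identical(d1$levels, d2$levels)
  expect_equal(glcm_features(d1), glcm_features(d2))
  expect_equal(glszm_features(d1), glszm_features(d2))
  f1 <- first_order(d1); f2 <- first_order(d2)
  expect_equal(f1[["firstorder__Entropy"]], f2[["firstorder__Entropy"]])
  expect_equal(f2[["firstorder__Mean"]] - f1[["firstorder__Mean"]], 11.5)
})

test_that("registry hash is stable and order-sensitive", {
  reg <- mri_bank_registry()
  expect_identical(bank_hash(reg), bank_hash(reg))
  expect_false(identical(bank_hash(reg), bank_hash(reg[rev(seq_len(nrow(reg))), ])))
})
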