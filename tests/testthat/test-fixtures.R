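# Synthetic tile, phantom and cohort generators.

test_that("blank tile has no nuclei and a pure background", {
  r <- make_tile(tile_spec(width_px = 64, height_px = 64, n_nuclei = 0, seed = 3))
  expect_equal(nrow(r$nuclei), 0)
  expect_equal(dim(r$tile$pixels), c(64, 64, 3))
  # all pixels identical to the background colour
  bg <- c(0.95, 0.87, 0.92)
  for (ch in 1:3) {
    expect_equal(unique(as.vector(r$tile$pixels[, , ch])), bg[ch],
                 tolerance = 1e-10)
  }
})

test_that("identical seeds give bit-identical tiles; different seeds differ", {
  a <- make_tile(tile_spec(n_nuclei = 50, seed = 1))
  b <- make_tile(tile_spec(n_nuclei = 50, seed = 1))
  c <- make_tile(tile_spec(n_nuclei = 50, seed = 2))
  expect_identical(a$tile$pixels, b$tile$pixels)
  expect_identical(a$nuclei, b$nuclei)
  expect_false(identical(a$tile$pixels, c$tile$pixels))
})

test_that("zero radius spread yields identical disks matching the pixel-count oracle", {
  r <- make_tile(tile_spec(width_px = 512, height_px = 512, n_nuclei = 50,
                           radius_mean = 8, radius_sd = 0, seed = 2))
  expect_equal(nrow(r$nuclei), 50)
  expect_equal(sd(r$nuclei$area_px), 0)
  expect_equal(mean(r$nuclei$area_px), disk_pixel_count(8))
})

test_that("infeasible packing is an explicit error", {
  expect_error(make_tile(tile_spec(width_px = 48, height_px = 48,
                                   n_nuclei = 200, radius_mean = 6,
                                   radius_sd = 0, overlap_fraction = 0,
                                   seed = 1)),
               "infeasible packing")
})

test_that("noiseless phantom compartments equal their means exactly", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, seed = 1), "wildtype")
  expect_equal(unique(ph$volumes$t1ce[ph$masks$enhancing]), 0.75)
  expect_equal(unique(ph$volumes$t1ce[ph$masks$necrosis]), 0.25)
  expect_equal(unique(ph$volumes$flair[ph$masks$edema]), 0.80)
})

test_that("phantom seeds change the noise but never the masks", {
  a <- make_phantom(phantom_spec(seed = 1), "wildtype")
  b <- make_phantom(phantom_spec(seed = 2), "wildtype")
  expect_identical(a$masks, b$masks)
  expect_false(identical(a$volumes$t1ce, b$volumes$t1ce))
  # and the same seed is bit-identical
  a2 <- make_phantom(phantom_spec(seed = 1), "wildtype")
  expect_identical(a$volumes, a2$volumes)
})

test_that("phantom masks nest, are disjoint, and match analytic volumes", {
  sp <- phantom_spec(shape_voxels = c(44, 44, 44),
                     semi_axes_mm = list(edema = c(16, 14, 12),
                                         enhancing = c(11, 9, 8),
                                         necrosis = c(6, 5, 4)))
  ph <- make_phantom(sp, "wildtype")
  m <- ph$masks
  expect_equal(sum(m$enhancing & m$necrosis), 0)
  expect_equal(sum(m$enhancing & m$edema), 0)
  expect_equal(sum(m$necrosis & m$edema), 0)
  # voxel counts within 10% of analytic ellipsoid(-shell) volumes
  vol_ell <- function(ax) 4 / 3 * pi * prod(ax)
  expect_equal(sum(m$necrosis), vol_ell(c(6, 5, 4)), tolerance = 0.1)
  expect_equal(sum(m$necrosis) + sum(m$enhancing), vol_ell(c(11, 9, 8)),
               tolerance = 0.1)
})

test_that("ellipsoid (8,4,2) mask flatness is near the analytic axis ratio", {
  sp <- phantom_spec(semi_axes_mm = list(edema = c(8, 4, 2),
                                         enhancing = c(5, 2.6, 1.4),
                                         necrosis = c(2, 1.2, 0.7)),
                     shape_voxels = c(26, 16, 12))
  ph <- make_phantom(sp, "wildtype")
  full_ell <- ph$masks$edema | ph$masks$enhancing | ph$masks$necrosis
  fl <- shape3d(full_ell, c(1, 1, 1))[["shape__Flatness"]]
  expect_lt(abs(fl - 0.25), 0.05)
})

test_that("compartments exceeding the volume bounds are rejected", {
  expect_error(phantom_spec(shape_voxels = c(16, 16, 16),
                            semi_axes_mm = list(edema = c(20, 9, 8),
                                                enhancing = c(9, 7, 6),
                                                necrosis = c(4, 3, 2))),
               "bounds")
  expect_error(phantom_spec(semi_axes_mm = list(edema = c(14, 11, 9),
                                                enhancing = c(15, 7, 6),
                                                necrosis = c(4, 3, 2))),
               "nest")
})

test_that("cohort manifest has exact class balance and existing files", {
  dir <- tempfile("coh_")
  man <- make_cohort(10, class_balance = 0.5, effect_size = 1, seed = 4,
                     dir = dir, n_tiles = 1, tile_px = 64,
                     phantom_shape = c(16, 16, 12))
  expect_equal(sum(man$label == "mutant"), 5)
  expect_equal(sum(man$label == "wildtype"), 5)
  expect_equal(nrow(man), 10)
  expect_true(all(file.exists(man$t1ce)))
  expect_true(all(file.exists(man$mask)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # NIfTI round trip preserves masks and spacing
  v <- read_volume_nifti(man$t1ce[1], man$mask[1])
  expect_equal(sort(unique(as.vector(v$label_array))), 0:3)
  expect_equal(unname(v$spacing_mm), c(1, 1, 1))
  unlink(dir, recursive = TRUE)
})

test_that("zero effect size gives label-independent feature distributions", {
  tb <- make_feature_table(400, p_informative = 2, p_noise = 5,
                           effect_size = 0, seed = 9)
  d1 <- abs(diff(tapply(tb$inf_1, tb$label, mean)))
  da <- abs(diff(tapply(tb$age, tb$label, mean)))
  expect_lt(d1, 0.3)
  expect_lt(da, 3)
})

test_that("feature table has the requested composition and is seed-stable", {
  tb <- make_feature_table(20, p_informative = 3, p_noise = 7, effect_size = 2,
                           seed = 5)
  expect_equal(ncol(tb), 1 + 3 + 7 + 2 + 1)  # id, inf, noise, age+sex, label
  expect_identical(tb, make_feature_table(20, 3, 7, effect_size = 2, seed = 5))
  d <- abs(diff(tapply(tb$inf_1, tb$label, mean)))
  expect_gt(d, 1)
})
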