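# Histology ROI selection: tissue masking, watershed nuclei detection, the
# density tile and HSV-representative tiles.

make_origin_tile <- function(n, seed, ox, oy, px = 96) {
  r <- make_tile(tile_spec(px, px, n, radius_mean = 4, radius_sd = 0.5,
                           seed = seed))
  tl <- r$tile
  tl$origin <- c(ox, oy)
  tl
}

test_that("tissue mask separates stained tissue from glass background", {
  white <- tile_image(array(1, c(32, 32, 3)))
  expect_equal(sum(tissue_mask(white)), 0)
  tissue <- make_tile(tile_spec(32, 32, 0, seed = 1))$tile  # saturated background
  expect_equal(sum(tissue_mask(tissue)), 32 * 32)
  # composite: left half white, right half tissue
  comp <- tissue$pixels
  comp[, 1:16, ] <- 1
  half <- tissue_mask(tile_image(comp))
  expect_equal(sum(half[, 1:16]), 0)
  expect_equal(sum(half[, 17:32]), 32 * 16)
})

test_that("watershed detection recovers non-overlapping disks and their centroids", {
  r <- make_tile(tile_spec(256, 256, 30, radius_mean = 7, radius_sd = 0, seed = 6))
  ns <- detect_nuclei(r$tile)
  expect_s3_class(ns, "nucleus_set")
  expect_equal(nrow(ns$measurements), 30)
  # labels contiguous 1..K and areas equal label-image pixel counts
  expect_equal(sort(unique(as.vector(ns$labels[ns$labels > 0]))), 1:30)
  expect_equal(ns$measurements$area_px,
               as.vector(table(ns$labels[ns$labels > 0])[as.character(1:30)]))
  # every truth centroid matched within 2 px
  for (i in seq_len(30)) {
    dmin <- min(sqrt((ns$measurements$cx - r$nuclei$cx[i])^2 +
                       (ns$measurements$cy - r$nuclei$cy[i])^2))
    expect_lt(dmin, 2)
  }
  # blank tile: zero nuclei
  expect_equal(nrow(detect_nuclei(make_tile(tile_spec(64, 64, 0, seed = 1))$tile)$measurements), 0)
})

test_that("watershed splits two moderately overlapping nuclei", {
  tl <- tile_from_disks(96, 96, rbind(c(40, 48), c(52, 48)), radius = 8)
  ns <- detect_nuclei(tl)
  expect_equal(nrow(ns$measurements), 2)
})

test_that("nucleus count is stable under 90-degree tile rotation", {
  r <- make_tile(tile_spec(192, 192, 40, radius_mean = 5, radius_sd = 0.8, seed = 9))
  n0 <- nrow(detect_nuclei(r$tile)$measurements)
  rot <- tile_image(aperm(r$tile$pixels, c(2, 1, 3)))
  n90 <- nrow(detect_nuclei(rot)$measurements)
  expect_lte(abs(n0 - n90), 1)
})

test_that("the density tile maximizes nuclei per tissue area with a stable tie-break", {
  tiles <- list(make_origin_tile(40, 1, 0, 0), make_origin_tile(20, 2, 96, 0),
                make_origin_tile(20, 3, 0, 96), make_origin_tile(20, 4, 96, 96))
  sel <- select_density_tile(tiles, min_area = 20)
  expect_equal(sel$origin, c(0L, 0L))
  # permutation invariance
  sel2 <- select_density_tile(rev(tiles), min_area = 20)
  expect_equal(sel2$origin, sel$origin)
  # single tile: identity
  one <- select_density_tile(tiles[2], min_area = 20)
  expect_equal(one$origin, c(96L, 0L))
  # exact tie (identical tiles at different origins): lowest (y, x) wins
  t1 <- make_origin_tile(15, 5, 96, 96); t2 <- t1; t2$origin <- c(0L, 0L)
  expect_equal(select_density_tile(list(t1, t2), min_area = 20)$origin, c(0L, 0L))
  # all-background slide errors
  white <- tile_image(array(1, c(32, 32, 3)))
  expect_error(select_density_tile(list(white)), "no tissue")
})

test_that("representative tiles come from the dominant tissue type", {
  # 9 dense-type tiles (spaced, so adjacency never binds) + 1 blank-type tile:
  # all k selected tiles come from the majority type
  tiles <- c(lapply(1:9, function(i) make_origin_tile(30, i + 10, 2 * (i - 1) * 96, 0)),
             list(make_origin_tile(0, 99, 2 * 9 * 96, 0)))
  sel <- select_representative_tiles(tiles, k = 5)
  expect_length(sel, 5)
  expect_true(all(vapply(sel, function(t) t$origin[1] < 2 * 9 * 96, TRUE)))
  for (i in seq_along(sel)) for (j in seq_along(sel)) {
    if (i < j) expect_false(radpath:::tiles_adjacent(sel[[i]], sel[[j]]))
  }
})

test_that("adjacent equally scored tiles are skipped in favour of the next candidate", {
  base <- make_origin_tile(12, 77, 0, 0)
  t2 <- base; t2$origin <- c(96L, 0L)
  t3 <- base; t3$origin <- c(192L, 0L)
  sel <- select_representative_tiles(list(base, t2, t3), k = 2)
  expect_equal(lapply(sel, `[[`, "origin"), list(c(0L, 0L), c(192L, 0L)))
})

test_that("homogeneous slides give near-equal distances and k = n returns all", {
  tiles <- lapply(1:4, function(i) make_origin_tile(0, i, (i - 1) * 96, 0))
  sel <- select_representative_tiles(tiles, k = 4)
  expect_length(sel, 4)
  d <- attr(sel, "distances")
  expect_lt(max(d) - min(d), 1e-6)
  # fewer tissue tiles than k: all returned with a warning flag
  white <- tile_image(array(1, c(96, 96, 3)))
  few <- select_representative_tiles(c(tiles[1:2], list(white)), k = 5)
  expect_length(few, 2)
  expect_true(attr(few, "warning_flag"))
})

test_that("selected tiles represent the slide better than random subsets", {
  set.seed(21)
  tiles <- c(lapply(1:8, function(i) make_origin_tile(35, i, (i - 1) * 96, 0)),
             lapply(1:4, function(i) make_origin_tile(5, 50 + i, (i - 1) * 96, 96)))
  slide <- hsv_profile(tiles)
  sel <- select_representative_tiles(tiles, k = 5)
  d_sel <- chisq_distance(hsv_profile(sel), slide)
  d_rand <- replicate(100, {
    chisq_distance(hsv_profile(sample(tiles, 5)), slide)
  })
  expect_lt(d_sel, mean(d_rand))
})
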