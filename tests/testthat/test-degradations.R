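test_that("Gaussian noise is zero-mean, clipped, and sd = 0 is the identity", {
  img <- flat_image(60, 60, value = 1000, n_channels = 2)
  expect_identical(add_gaussian_noise(img, 0), img)
  noisy <- add_gaussian_noise(img, 10, seed = 3)
  added <- noisy$planes[[1]] - img$planes[[1]]
  expect_lt(abs(mean(added)), 3 * 10 / sqrt(length(added)))
  expect_gte(min(noisy$planes[[1]]), 0)
  low <- add_gaussian_noise(flat_image(40, 40, value = 1), 50, seed = 1)
  expect_gte(min(low$planes[[1]]), 0)  # clipping engaged
})

test_that("downsampling resizes planes bilinearly and masks without label blending", {
  tis <- small_tissue(seed = 2)
  d <- downsample(tis$image, list(tis$seg$cell, tis$seg$nucleus), scale = 0.5)
  expect_equal(dim(d$image), round(0.5 * dim(tis$image)))
  expect_equal(d$image$pixel_size_um, tis$image$pixel_size_um / 0.5)
  for (m in d$masks) {
    expect_true(all(unique(as.vector(m)) %in% c(0L, mask_ids(tis$seg$cell))))
  }
  # identity at scale 1; error when a dimension would vanish
  same <- downsample(tis$image, list(tis$seg$cell), scale = 1)
  expect_identical(same$image, tis$image)
  expect_equal(dim(downsample(flat_image(100, 100), scale = 0.5)$image), c(50, 50))
  expect_error(downsample(flat_image(2, 2), scale = 0.1), "smaller than 1")
})

test_that("label sets only shrink under downsampling (50 random masks)", {
  for (seed in 1:50) {
    set.seed(seed)
    m <- matrix(0L, 24, 24)
    for (id in 1:6) {
      r <- sample(1:20, 1); c <- sample(1:20, 1)
      m[r:(r + 3), c:(c + 3)] <- id
    }
    d <- downsample(flat_image(24, 24), list(m), scale = runif(1, 0.3, 0.9))
    expect_true(all(mask_ids(d$masks[[1]]) %in% mask_ids(m)))
  }
})

test_that("undersegmentation accounting: counts, unions, and no double merges", {
  tis <- small_tissue(seed = 3)           # 20 cells
  n <- n_cells(tis$seg)
  expect_identical(simulate_undersegmentation(tis$seg, 1)$cell, tis$seg$cell)

  u <- simulate_undersegmentation(tis$seg, 0.9, seed = 5)
  expect_equal(n_cells(u), ceiling(0.9 * n))
  merged <- attr(u, "merged_ids")
  expect_length(merged, 2 * (n - ceiling(0.9 * n)))
  expect_false(anyDuplicated(merged) > 0)   # participation registry

  # merged pixel sets are exact unions of the original cells
  for (id in intersect(merged, mask_ids(u$cell))) {
    donors <- mask_ids(tis$seg$cell)[vapply(mask_ids(tis$seg$cell), function(o) {
      any(u$cell[tis$seg$cell == o] == id) && o %in% merged
    }, logical(1))]
    expect_identical(u$cell == id,
                     matrix(tis$seg$cell %in% donors, nrow(u$cell)))
  }

  u6 <- simulate_undersegmentation(tis$seg, 0.6, seed = 5)
  expect_equal(n_cells(u6), ceiling(0.6 * n))
  expect_length(attr(u6, "merged_ids"), 2 * (n - ceiling(0.6 * n)))

  # nuclear fusion closes the gap wherever the merged cell permits it: the
  # fused nucleus is connected whenever the merged cell region is (the
  # nucleus must stay inside its cell, so a background slit splitting the
  # merged cell also splits its nucleus)
  for (id in intersect(attr(u6, "merged_ids"), mask_ids(u6$cell))) {
    expect_lte(max(label_components(u6$nucleus == id, connectivity = 8)),
               max(label_components(u6$cell == id, connectivity = 8)))
  }
})

test_that("mask shifting uses the stated offset rounding and preserves in-bounds objects", {
  tis <- small_tissue(seed = 4)
  expect_identical(shift_masks(tis$seg, 0)$cell, tis$seg$cell)

  # 200x100 grid, fraction 0.01: mean dim 150, offset round-half-up(1.5) = 2
  m <- box_mask(200, 100, rbind(c(1, 50, 60, 50, 60)))
  seg <- apply_repair(m, m, match_cells_to_nuclei(m, m))
  sh <- shift_masks(seg, 0.01)
  expect_identical(which(sh$cell == 1, arr.ind = TRUE),
                   which(m == 1, arr.ind = TRUE) + 2L, ignore_attr = TRUE)
  expect_equal(sum(sh$cell == 1), sum(m == 1))

  # large shifts drop cells but keep the one-to-one invariants
  big <- shift_masks(tis$seg, 0.5)
  expect_lt(n_cells(big), n_cells(tis$seg))
  expect_identical(mask_ids(big$cell), mask_ids(big$nucleus))
  expect_true(all(big$cell[big$nucleus > 0] == big$nucleus[big$nucleus > 0]))
})

test_that("Voronoi baseline partitions the image by nearest nucleus centroid", {
  # single nucleus: the whole image is one cell
  p <- matrix(10, 30, 30); p[14:17, 14:17] <- 1000
  img1 <- multichannel_image(list(nuc = p), 1)
  v1 <- voronoi_baseline(img1, "nuc")
  expect_equal(n_cells(v1), 1)
  expect_true(all(v1$cell == 1))

  # two nuclei separated vertically: the half-way row splits the cells
  p2 <- matrix(10, 21, 21); p2[2:4, 10:12] <- 1000; p2[18:20, 10:12] <- 1000
  img2 <- multichannel_image(list(nuc = p2), 1)
  v2 <- voronoi_baseline(img2, "nuc")
  expect_equal(n_cells(v2), 2)
  top_id <- v2$cell[1, 11]; bottom_id <- v2$cell[21, 11]
  expect_true(all(v2$cell[1:10, ] == top_id))
  expect_true(all(v2$cell[13:21, ] == bottom_id))

  # assignment agrees with a brute-force nearest-centroid scan
  tis <- generate_tissue(synthetic_tissue_spec(grid = c(3, 3)), seed = 5)
  v <- voronoi_baseline(tis$image, "nuc")
  nuc <- v$nucleus
  pos <- which(nuc > 0, arr.ind = TRUE)
  ids <- mask_ids(nuc)
  cent <- t(vapply(ids, function(i) colMeans(pos[nuc[pos] == i, , drop = FALSE]),
                   numeric(2)))
  oracle <- oracle_nearest_centroid(nrow(nuc), ncol(nuc), cent, ids)
  mismatch <- mean(v$cell != oracle)
  expect_lt(mismatch, 0.005)   # only equidistant/containment-forced pixels differ
  # full coverage: no background pixel remains
  expect_true(all(v$cell > 0))
})
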