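test_that("cell feature table equals brute-force per-pixel accumulation", {
  tis <- small_tissue(seed = 2)
  feats <- compute_cell_features(tis$image, tis$seg$cell)
  oracle <- oracle_cell_features(tis$image, tis$seg$cell)
  expect_equal(feats, oracle, ignore_attr = TRUE)
  expect_identical(rownames(feats), rownames(oracle))

  # uniform intensity: every cell's feature equals the constant
  img <- flat_image(20, 20, value = 7)
  mask <- box_mask(20, 20, rbind(c(1, 2, 5, 2, 5), c(2, 10, 15, 10, 15)))
  expect_true(all(compute_cell_features(img, mask) == 7))

  # a 4-pixel cell with values 1, 2, 3, 6 has mean 3
  p <- matrix(0, 4, 4); p[1, 1:4] <- c(1, 2, 3, 6)
  img2 <- multichannel_image(list(a = p), 1)
  mask2 <- matrix(0L, 4, 4); mask2[1, 1:4] <- 1L
  expect_equal(as.numeric(compute_cell_features(img2, mask2)), 3)

  # channel restriction
  expect_identical(colnames(compute_cell_features(tis$image, tis$seg$cell,
                                                  channels = c("marker1", "marker2"))),
                   c("marker1", "marker2"))
  expect_error(compute_cell_features(tis$image, tis$seg$cell, channels = "nope"),
               "unknown")
})

test_that("ACVC/FPCC degenerate and single-dimension cases follow the conventions", {
  # identical feature vectors: CV of constants is 0 -> 1/(ACVC+1) = 1
  same <- matrix(5, 20, 3, dimnames = list(1:20, c("a", "b", "c")))
  r <- compute_acvc_fpcc(same, seed = 1)
  expect_equal(r$ACVC, 0)
  # single channel: one dimension holds all variance for every k
  one_ch <- matrix(runif(30, 1, 2), 30, 1, dimnames = list(1:30, "a"))
  expect_equal(compute_acvc_fpcc(one_ch, seed = 1)$FPCC, 1)
  # fewer than 2 cells
  expect_message(r1 <- compute_acvc_fpcc(same[1, , drop = FALSE]), "degenerate")
  expect_equal(r1$ACVC, 0)
  expect_equal(r1$FPCC, 1)
})

test_that("k = 1 clustering reduces to the global CV and PC1 fraction", {
  set.seed(42)
  feats <- matrix(rexp(40 * 3, 1 / 100), 40, 3,
                  dimnames = list(1:40, c("a", "b", "c")))
  r <- compute_acvc_fpcc(feats, k_max = 1, seed = 1)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(r$ACVC, mean(apply(feats, 2, psd) / colMeans(feats)))
  fs <- sweep(feats, 2, colMeans(feats), "/")
  ev <- eigen(stats::cov(sweep(fs, 2, colMeans(fs))), only.values = TRUE)$values
  expect_equal(r$FPCC, max(ev) / sum(ev))
})

test_that("silhouette conventions: separated clouds near 1, identical points 0", {
  # two tight, far-separated clouds
  set.seed(7)
  a <- matrix(rnorm(20, 0, 0.01), 10, 2)
  b <- matrix(rnorm(20, 100, 0.01), 10, 2) + 100
  feats <- rbind(a + 50, b)  # keep all entries positive
  colnames(feats) <- c("x", "y"); rownames(feats) <- 1:20
  expect_gt(compute_avg_silhouette(feats, k_max = 2, seed = 1), 0.95)

  same <- matrix(3, 10, 2, dimnames = list(1:10, c("x", "y")))
  expect_equal(compute_avg_silhouette(same, seed = 1), 0)
  expect_message(s <- compute_avg_silhouette(same[1:2, ], seed = 1), "degenerate")
  expect_equal(s, 0)
})

test_that("well-separated cell types score better than shuffled features", {
  wins_acvc <- 0; wins_as <- 0
  for (seed in 1:8) {
    tis <- small_tissue(seed = seed)
    feats <- compute_cell_features(tis$image, tis$seg$cell,
                                   channels = paste0("marker", 1:3))
    r_true <- compute_acvc_fpcc(feats, seed = seed)
    as_true <- compute_avg_silhouette(feats, seed = seed)
    shuffled <- feats
    set.seed(seed + 1000)
    for (j in seq_len(ncol(shuffled))) shuffled[, j] <- sample(shuffled[, j])
    r_shuf <- compute_acvc_fpcc(shuffled, seed = seed)
    as_shuf <- compute_avg_silhouette(shuffled, seed = seed)
    wins_acvc <- wins_acvc + (1 / (r_true$ACVC + 1) > 1 / (r_shuf$ACVC + 1))
    wins_as <- wins_as + (as_true > as_shuf)
  }
  expect_gte(wins_acvc, 6)
  expect_gte(wins_as, 6)
})

test_that("outside-cell uniformity uses the stated empty-set and constancy conventions", {
  tis <- small_tissue(seed = 1)
  # cells cover everything: best-case values
  all_cells <- matrix(1L, nrow(tis$seg$cell), ncol(tis$seg$cell))
  seg_all <- apply_repair(all_cells, all_cells,
                          match_cells_to_nuclei(all_cells, all_cells))
  expect_message(
    r <- compute_outside_cell_metrics(tis$image, seg_all,
                                      matrix(TRUE, nrow(all_cells), ncol(all_cells))),
    "cover")
  expect_equal(r$ACVF, 0)
  expect_equal(r$FPCF, 1)

  # constant outside-cell intensities: ACVF = 0; single channel: FPCF = 1
  img <- flat_image(16, 16, value = 4, n_channels = 1)
  cellm <- box_mask(16, 16, rbind(c(1, 2, 5, 2, 5)))
  seg <- apply_repair(cellm, cellm, match_cells_to_nuclei(cellm, cellm))
  r2 <- compute_outside_cell_metrics(img, seg, matrix(TRUE, 16, 16))
  expect_equal(r2$ACVF, 0)
  expect_equal(r2$FPCF, 1)
})

test_that("metric vectors have the right shape, range, and are deterministic", {
  tis <- small_tissue(seed = 4)
  cfg <- segqc_config(nuclear_channel = "nuc", seed = 11)
  mv <- compute_metric_vector(tis$image, tis$cell_mask, tis$nuclear_mask, cfg)
  expect_length(mv, 14)
  expect_identical(names(mv), metric_names("full14"))
  expect_true(all(is.finite(mv)))
  transformed <- c("FFC", "1-FBC", "FCF", "FMCN", "1/(ACVF+1)", "FPCF",
                   "1/(ACVC_NUC+1)", "1/(ACVC_CEN+1)", "FPCC_NUC", "FPCC_CEN",
                   "1/(ln(CSSD)+1)")
  expect_true(all(mv[transformed] > 0 & mv[transformed] <= 1))
  expect_true(all(mv[c("AS_NUC", "AS_CEN")] >= -1 & mv[c("AS_NUC", "AS_CEN")] <= 1))

  red <- compute_metric_vector(tis$image, tis$cell_mask, tis$nuclear_mask,
                               segqc_config(variant = "reduced10",
                                            nuclear_channel = "nuc", seed = 11))
  expect_length(red, 10)
  expect_false("FMCN" %in% names(red))

  mv2 <- compute_metric_vector(tis$image, tis$cell_mask, tis$nuclear_mask, cfg)
  expect_identical(as.numeric(mv), as.numeric(mv2))
})
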