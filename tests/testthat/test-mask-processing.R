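test_that("matching pairs each cell with its best-fitting nucleus", {
  # cell 1 fully contains nucleus 1; nucleus 2 overlaps cell 1 with half its
  # pixels outside; nucleus 3 overlaps no cell
  cell <- box_mask(10, 10, rbind(c(1, 2, 7, 2, 7)))
  nuc <- box_mask(10, 10, rbind(c(1, 3, 5, 3, 5),
                                c(2, 6, 7, 6, 9),
                                c(3, 9, 10, 1, 2)))
  m <- match_cells_to_nuclei(cell, nuc)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$cell_id, 1)
  expect_equal(m$pairs$nucleus_id, 1)
  expect_equal(m$pairs$mismatch_fraction, 0)
  expect_setequal(m$unmatched_nuclei, c(2, 3))
  expect_equal(m$n_cells_pre, 1)
  expect_equal(m$n_nuclei_pre, 3)
  # brute-force pixel-scan oracle agrees on the candidate table
  expect_equal(oracle_overlaps(cell, nuc)$mismatch_fraction, c(0, 0.5))
})

test_that("matching errors on shape mismatch and handles empty masks", {
  expect_error(match_cells_to_nuclei(matrix(0L, 3, 3), matrix(0L, 4, 4)), "shape")
  m <- match_cells_to_nuclei(matrix(0L, 5, 5), matrix(0L, 5, 5))
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$n_cells_pre + m$n_nuclei_pre, 0)
})

test_that("repair trims protruding nuclei; strict removes the pair", {
  # nucleus 2 of cell 2 protrudes: 4 of its 10 pixels lie outside (rows 9:10,
  # cols 5:6), so its mismatch fraction is 0.4
  cell <- box_mask(12, 12, rbind(c(1, 1, 4, 1, 4), c(2, 7, 10, 1, 4)))
  nuc <- box_mask(12, 12, rbind(c(1, 2, 3, 2, 3), c(2, 9, 10, 2, 6)))
  m <- match_cells_to_nuclei(cell, nuc)
  expect_equal(m$pairs$mismatch_fraction[m$pairs$cell_id == 2], 0.4)

  rep_seg <- apply_repair(cell, nuc, m, mode = "repair")
  expect_equal(n_cells(rep_seg), 2)
  # trimmed nucleus is exactly the overlap region (rows 9:10, cols 2:4)
  new2 <- which(rep_seg$id_map == 2)
  expect_equal(sum(rep_seg$nucleus == new2), 6)
  expect_true(all(rep_seg$cell[rep_seg$nucleus == new2] == new2))

  strict_seg <- apply_repair(cell, nuc, m, mode = "strict")
  expect_equal(n_cells(strict_seg), 1)
  expect_equal(unname(strict_seg$id_map), 1)
})

test_that("repair output satisfies the one-to-one invariants and is idempotent", {
  for (seed in 1:5) {
    tis <- small_tissue(seed = seed, orphan_cell_frac = 0.1,
                        orphan_nucleus_frac = 0.1, protrude_frac = 0.3)
    m <- match_cells_to_nuclei(tis$cell_mask, tis$nuclear_mask)
    seg <- apply_repair(tis$cell_mask, tis$nuclear_mask, m)
    ids <- mask_ids(seg$cell)
    expect_identical(ids, mask_ids(seg$nucleus))
    expect_true(all(seg$cell[seg$nucleus > 0] == seg$nucleus[seg$nucleus > 0]))
    expect_identical(seg$cell_excluding_nucleus > 0L,
                     seg$cell > 0L & seg$nucleus == 0L)
    # repair never adds nucleus pixels
    expect_lte(sum(seg$nucleus > 0), sum(tis$nuclear_mask > 0))
    # idempotence: repairing the repaired segmentation changes nothing
    m2 <- match_cells_to_nuclei(seg$cell, seg$nucleus)
    seg2 <- apply_repair(seg$cell, seg$nucleus, m2)
    expect_identical(seg2$cell, seg$cell)
    expect_identical(seg2$nucleus, seg$nucleus)
  }
})

test_that("matching agrees with the brute-force overlap oracle", {
  for (seed in 1:3) {
    tis <- small_tissue(seed = seed, protrude_frac = 0.25,
                        orphan_cell_frac = 0.1)
    m <- match_cells_to_nuclei(tis$cell_mask, tis$nuclear_mask)
    oracle <- oracle_overlaps(tis$cell_mask, tis$nuclear_mask)
    # every reported pair must be a candidate with the oracle's mismatch
    for (i in seq_len(nrow(m$pairs))) {
      row <- oracle[oracle$cell_id == m$pairs$cell_id[i] &
                    oracle$nucleus_id == m$pairs$nucleus_id[i], ]
      expect_equal(nrow(row), 1)
      expect_equal(m$pairs$mismatch_fraction[i], row$mismatch_fraction)
    }
    # accounting: every pre-processing id appears exactly once
    expect_setequal(c(m$pairs$cell_id, m$unmatched_cells),
                    sort(unique(tis$cell_mask[tis$cell_mask > 0])))
    expect_setequal(c(m$pairs$nucleus_id, m$unmatched_nuclei),
                    sort(unique(tis$nuclear_mask[tis$nuclear_mask > 0])))
  }
})

test_that("cell-excluding-nucleus mask is the exact per-id set difference", {
  cell <- box_mask(9, 9, rbind(c(1, 2, 6, 2, 6)))   # 5x5 cell
  nuc <- box_mask(9, 9, rbind(c(1, 3, 5, 3, 5)))    # central 3x3 nucleus
  seg <- apply_repair(cell, nuc, match_cells_to_nuclei(cell, nuc))
  cen <- derive_cell_excluding_nucleus(seg)
  expect_equal(sum(cen == 1), 16)  # 25 - 9
  expect_true(all(cen[seg$nucleus > 0] == 0))

  # nucleus fills the cell: empty CEN, id retained and flagged
  nuc2 <- cell
  seg2 <- apply_repair(cell, nuc2, match_cells_to_nuclei(cell, nuc2))
  expect_message(cen2 <- derive_cell_excluding_nucleus(seg2), "empty CEN")
  expect_equal(attr(cen2, "empty_cen_ids"), 1L)
  expect_equal(n_cells(seg2), 1)
})
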