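# Small toy builders used across test files.

# Place rectangular objects on an empty grid: each row of `boxes` is
# (id, r0, r1, c0, c1).
box_mask <- function(h, w, boxes) {
  m <- matrix(0L, h, w)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    m[b[2]:b[3], b[4]:b[5]] <- as.integer(b[1])
  }
  m
}

# A flat image (all channels constant) to drive mask-only code paths.
flat_image <- function(h, w, value = 10, n_channels = 2, pixel_size_um = 1) {
  planes <- replicate(n_channels, matrix(value, h, w), simplify = FALSE)
  names(planes) <- paste0("ch", seq_len(n_channels))
  multichannel_image(planes, pixel_size_um)
}

# A small, fast tissue fixture (20 cells, 64 x 80 px).
small_tissue <- function(seed = 1, ...) {
  generate_tissue(synthetic_tissue_spec(grid = c(4, 5), ...), seed = seed)
}

# Random blob label-mask pair for benchmark property tests: the true mask of
# a small tissue plus a degraded copy of it.
random_mask_pair <- function(seed) {
  tis <- small_tissue(seed = seed)
  deg <- if (seed %% 2 == 0) {
    simulate_undersegmentation(tis$seg, 0.8, seed = seed)$cell
  } else {
    shift_masks(tis$seg, 0.01 * (seed %% 5))$cell
  }
  list(ref = tis$seg$cell, query = deg)
}
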