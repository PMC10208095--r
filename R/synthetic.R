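#' Specification for a synthetic multichannel tissue fixture
#'
#' Describes an artificial tissue emulating the key assumption behind
#' reference-free evaluation: the image contains several cell types that
#' differ in their per-channel marker expression. Cells are ellipses on a
#' jittered grid (one cell per grid tile, clipped to its tile so cells never
#' overlap, with neighbouring cells close enough to be in contact), nuclei
#' are concentric ellipses scaled by `nucleus_ratio`, and each cell type has
#' its own mean intensity in the marker channels. A dedicated nuclear-stain
#' channel is bright inside nuclei for every type. Per-cell multiplicative
#' brightness variation (`brightness_sd`) emulates staining variability,
#' giving realistically correlated per-cell channel means.
#'
#' Optional defect fractions plant the pathologies the mask-processing step
#' must handle: `orphan_cell_frac` (cells without a nucleus),
#' `orphan_nucleus_frac` (nuclei without a cell), and `protrude_frac`
#' (nuclei shifted so they poke through their cell boundary).
#'
#' @param grid Cells as (rows, cols) of grid tiles; default `c(8, 10)`
#'   (rectangular, like typical acquisition tiles).
#' @param spacing Tile edge in pixels (default 16).
#' @param pixel_size_um Pixel size in micrometres (default 0.5).
#' @param n_types Number of planted cell types (default 3).
#' @param n_marker_channels Marker channels beside the nuclear one.
#' @param type_means Types x marker-channels matrix of mean intensities;
#'   default: each type bright (1000) in its own marker, dim (200) elsewhere.
#' @param nuclear_level Nuclear-channel intensity inside nuclei.
#' @param background Background intensity level (default 100).
#' @param noise_sd Per-pixel Gaussian intensity noise (default 50).
#' @param radius_range Cell semi-axis range in pixels (default 6.5..8,
#'   nearly filling the tile: confluent tissue).
#' @param nucleus_ratio Nucleus/cell semi-axis ratio in (0, 1).
#' @param jitter Maximum centre jitter in pixels.
#' @param brightness_sd SD of the per-cell brightness factor around 1.
#' @param orphan_cell_frac,orphan_nucleus_frac,protrude_frac Defect
#'   fractions in \[0, 1\] (defaults 0: a clean tissue).
#' @return A list of class `synthetic_tissue_spec`.
#' @export
synthetic_tissue_spec <- function(grid = c(8, 10), spacing = 16,
                                  pixel_size_um = 0.5, n_types = 3,
                                  n_marker_channels = 3, type_means = NULL,
                                  nuclear_level = 1200, background = 100,
                                  noise_sd = 50, radius_range = c(6.5, 8),
                                  nucleus_ratio = 0.55, jitter = 1,
                                  brightness_sd = 0.1,
                                  orphan_cell_frac = 0,
                                  orphan_nucleus_frac = 0,
                                  protrude_frac = 0) {
  stopifnot(length(grid) == 2, all(grid >= 1), spacing >= 8,
            n_types >= 1, nucleus_ratio > 0, nucleus_ratio < 1,
            radius_range[1] > 1, radius_range[2] <= spacing / 2,
            orphan_cell_frac >= 0, orphan_nucleus_frac >= 0, protrude_frac >= 0,
            orphan_cell_frac + orphan_nucleus_frac <= 1)
  if (is.null(type_means)) {
    type_means <- matrix(200, n_types, n_marker_channels)
    for (t in seq_len(n_types)) {
      type_means[t, ((t - 1) %% n_marker_channels) + 1] <- 1000
    }
  }
  type_means <- as.matrix(type_means)
  if (nrow(type_means) != n_types || ncol(type_means) != n_marker_channels)
    stop("type_means must be n_types x n_marker_channels")
  if (anyDuplicated(apply(type_means, 1, paste, collapse = ",")) > 0)
    stop("type mean vectors must be distinct")
  structure(list(grid = as.integer(grid), spacing = spacing,
                 pixel_size_um = pixel_size_um, n_types = as.integer(n_types),
                 n_marker_channels = as.integer(n_marker_channels),
                 type_means = type_means, nuclear_level = nuclear_level,
                 background = background, noise_sd = noise_sd,
                 radius_range = radius_range, nucleus_ratio = nucleus_ratio,
                 jitter = jitter, brightness_sd = brightness_sd,
                 orphan_cell_frac = orphan_cell_frac,
                 orphan_nucleus_frac = orphan_nucleus_frac,
                 protrude_frac = protrude_frac),
            class = "synthetic_tissue_spec")
}

# Fill an ellipse (integer pixels) clipped to the window [r0,r1]x[c0,c1].
ellipse_pixels <- function(cy, cx, ay, ax, r0, r1, c0, c1) {
  rr <- max(r0, floor(cy - ay)):min(r1, ceiling(cy + ay))
  cc <- max(c0, floor(cx - ax)):min(c1, ceiling(cx + ax))
  d <- outer(((rr - cy) / ay)^2, ((cc - cx) / ax)^2, "+")
  sel <- which(d <= 1, arr.ind = TRUE)
  cbind(rr[sel[, 1]], cc[sel[, 2]])
}

#' Generate a synthetic tissue image with ground-truth masks
#'
#' Deterministic given `seed`. Returns both the raw drawn masks (which
#' contain any planted defects) and the matched segmentation obtained by
#' running the matching/repair step on them; for a defect-free spec the two
#' are identical up to relabelling.
#'
#' @param spec A [synthetic_tissue_spec()].
#' @param seed RNG seed.
#' @return List with `image` (a `multichannel_image`), `cell_mask` and
#'   `nuclear_mask` (raw label masks), `seg` (a `matched_segmentation`),
#'   `types` (named vector: planted type per cell id), and `seed`.
#' @export
generate_tissue <- function(spec = synthetic_tissue_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_tissue_spec"))
  with_seed_(seed, {
    s <- spec$spacing
    H <- spec$grid[1] * s; W <- spec$grid[2] * s
    n <- spec$grid[1] * spec$grid[2]
    cell <- matrix(0L, H, W); nuc <- matrix(0L, H, W)

    roles <- rep("normal", n)
    n_oc <- round(spec$orphan_cell_frac * n)
    n_on <- round(spec$orphan_nucleus_frac * n)
    n_pr <- round(spec$protrude_frac * n)
    pool <- sample(n)
    if (n_oc > 0) roles[pool[seq_len(n_oc)]] <- "orphan_cell"
    if (n_on > 0) roles[pool[n_oc + seq_len(n_on)]] <- "orphan_nucleus"
    normal_idx <- which(roles == "normal")
    if (n_pr > 0) roles[sample(normal_idx, min(n_pr, length(normal_idx)))] <- "protrude"

    types <- (sample(n) %% spec$n_types) + 1L
    bright <- pmax(0.2, stats::rnorm(n, 1, spec$brightness_sd))

    id <- 0L
    for (gi in seq_len(spec$grid[1])) for (gj in seq_len(spec$grid[2])) {
      id <- id + 1L
      r0 <- (gi - 1L) * s + 1L; r1 <- gi * s
      c0 <- (gj - 1L) * s + 1L; c1 <- gj * s
      cy <- (r0 + r1) / 2 + stats::runif(1, -spec$jitter, spec$jitter)
      cx <- (c0 + c1) / 2 + stats::runif(1, -spec$jitter, spec$jitter)
      ay <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      ax <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      role <- roles[id]
      if (role != "orphan_nucleus") {
        px <- ellipse_pixels(cy, cx, ay, ax, r0, r1, c0, c1)
        cell[px] <- id
      }
      if (role != "orphan_cell") {
        ncy <- cy; ncx <- cx
        if (role == "protrude") ncx <- cx + (1 - spec$nucleus_ratio) * ax + 2
        px <- ellipse_pixels(ncy, ncx, ay * spec$nucleus_ratio,
                             ax * spec$nucleus_ratio, r0, r1, c0, c1)
        nuc[px] <- id
      }
    }

    planes <- vector("list", 1L + spec$n_marker_channels)
    names(planes) <- c("nuc", paste0("marker", seq_len(spec$n_marker_channels)))
    noise <- function() matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    nuc_plane <- matrix(spec$background, H, W)
    nuc_pos <- nuc > 0L
    nuc_plane[nuc_pos] <- spec$nuclear_level * bright[nuc[nuc_pos]]
    planes[["nuc"]] <- pmax(nuc_plane + noise(), 0)
    cell_pos <- cell > 0L
    for (m in seq_len(spec$n_marker_channels)) {
      p <- matrix(spec$background, H, W)
      p[cell_pos] <- spec$type_means[types[cell[cell_pos]], m] * bright[cell[cell_pos]]
      planes[[paste0("marker", m)]] <- pmax(p + noise(), 0)
    }
    image <- multichannel_image(planes, spec$pixel_size_um)

    matching <- match_cells_to_nuclei(cell, nuc)
    seg <- apply_repair(cell, nuc, matching, mode = "repair",
                        pixel_size_um = spec$pixel_size_um)
    list(image = image, cell_mask = cell, nuclear_mask = nuc, seg = seg,
         types = stats::setNames(types, seq_len(n)), roles = roles, seed = seed)
  })
}

#' Generate a synthetic rank-1-plus-noise metric matrix
#'
#' Emulates a metric matrix driven by one latent quality factor: row i is
#' `quality_i * loadings + noise`, with `quality_i ~ Uniform(0, 1)`. Used to
#' validate the PCA quality model's conventions (all-positive PC1 loadings).
#'
#' @param n_rows Number of rows (segmentations).
#' @param latent_loadings Positive loading vector (one entry per metric).
#' @param noise_sd Elementwise Gaussian noise SD.
#' @param seed RNG seed.
#' @return Numeric matrix with columns named `m1..mp`.
#' @export
generate_metric_matrix <- function(n_rows, latent_loadings, noise_sd = 0.05,
                                   seed = 1) {
  stopifnot(n_rows >= 3, all(latent_loadings > 0), noise_sd >= 0)
  with_seed_(seed, {
    q <- stats::runif(n_rows)
    x <- q %o% latent_loadings +
      matrix(stats::rnorm(n_rows * length(latent_loadings), 0, noise_sd),
             n_rows, length(latent_loadings))
    colnames(x) <- paste0("m", seq_along(latent_loadings))
    x
  })
}
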