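#' Add zero-mean Gaussian noise to every pixel of every channel
#'
#' Used to probe the robustness of segmentation and of the quality metrics.
#' Noise is drawn independently per pixel and channel; results are clipped
#' at 0 because negative fluorescence intensities are unphysical (and some
#' downstream methods reject them). In a robustness study the perturbed copy
#' is what is fed to segmentation; metric evaluation normally uses the
#' original image.
#'
#' @param image A `multichannel_image`.
#' @param sd Noise standard deviation in intensity units (0 = identity).
#' @param seed Optional RNG seed; when given, the caller's RNG state is
#'   untouched.
#' @return A perturbed `multichannel_image`.
#' @export
add_gaussian_noise <- function(image, sd, seed = NULL) {
  stopifnot(inherits(image, "multichannel_image"), sd >= 0)
  if (sd == 0) return(image)
  draw <- function() {
    planes <- lapply(image$planes, function(p) {
      pmax(p + matrix(stats::rnorm(length(p), 0, sd), nrow(p)), 0)
    })
    multichannel_image(planes, image$pixel_size_um)
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

#' Downsample an image and its label masks
#'
#' Intensity planes are resized by bilinear interpolation; label masks by
#' nearest neighbour, the only choice that never blends labels. Both
#' dimensions become `round(scale * dim)` and the physical pixel size grows
#' accordingly (`pixel_size_um / scale`).
#'
#' @param image A `multichannel_image`.
#' @param masks A list of label masks (possibly empty) resized alongside.
#' @param scale Fraction in (0, 1\].
#' @return List with elements `image` and `masks`.
#' @export
downsample <- function(image, masks = list(), scale) {
  stopifnot(inherits(image, "multichannel_image"), scale > 0, scale <= 1)
  d <- dim(image)
  nh <- round(scale * d[1]); nw <- round(scale * d[2])
  if (nh < 1 || nw < 1) stop("downsampled dimension smaller than 1 pixel")
  if (scale == 1) return(list(image = image, masks = masks))
  planes <- lapply(image$planes, function(p) {
    m <- EBImage::resize(p, w = nh, h = nw, filter = "bilinear")
    pmax(matrix(as.numeric(m), nh, nw), 0)
  })
  new_img <- multichannel_image(planes, image$pixel_size_um / scale)
  new_masks <- lapply(masks, function(m) {
    r <- EBImage::resize(as_label_mask(m), w = nh, h = nw, filter = "none")
    as_label_mask(matrix(as.integer(round(r)), nh, nw))
  })
  list(image = new_img, masks = new_masks)
}

# Unordered pairs of contacting cell ids: objects that are 8-adjacent after
# each is dilated by one pixel, i.e. whose pixel sets lie within a Chebyshev
# distance of 3 of each other. Returned as a 2-column matrix (smaller id
# first).
contact_pairs <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- list()
  for (dr in 0:3) for (dc in -3:3) {
    if (dr == 0 && dc <= 0) next
    offs[[length(offs) + 1L]] <- c(dr, dc)
  }
  acc <- new.env()
  for (d in offs) {
    dr <- d[1]; dc <- d[2]
    r1 <- seq_len(H - dr); r2 <- r1 + dr
    if (dc >= 0) { c1 <- seq_len(W - dc); c2 <- c1 + dc }
    else { c1 <- seq(1 - dc, W); c2 <- c1 + dc }
    a <- mask[r1, c1, drop = FALSE]; b <- mask[r2, c2, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      lo <- pmin(a[sel], b[sel]); hi <- pmax(a[sel], b[sel])
      for (k in unique(as.numeric(lo) * (max(mask) + 1) + hi)) {
        assign(as.character(k), TRUE, envir = acc)
      }
    }
  }
  keys <- as.numeric(ls(acc))
  if (length(keys) == 0L) return(matrix(integer(0), 0, 2))
  m <- max(mask) + 1
  cbind(as.integer(keys %/% m), as.integer(keys %% m))
}

#' Simulate undersegmentation by merging contacting cells
#'
#' Sequentially merges randomly chosen pairs of contacting cells until the
#' cell count reaches `ceil(target_fraction * n)`. Cells that have already
#' been merged are not allowed to merge again, reflecting how
#' undersegmentation typically manifests; merging to 90% of the original
#' count therefore means 20% of the original cells participated in a merge.
#' The two nuclei of a merged pair are fused by morphological opening of the
#' inverted nuclear mask around the pair (structuring element: disc of
#' radius half the inter-nucleus gap, at least 1), closing the gap between
#' them.
#'
#' @param seg A `matched_segmentation`.
#' @param target_fraction Target cell count as a fraction of the original.
#' @param seed RNG seed for the random pair order.
#' @return A degraded `matched_segmentation`; the original ids that took
#'   part in a merge are in `attr(, "merged_ids")`.
#' @export
simulate_undersegmentation <- function(seg, target_fraction, seed = 1) {
  stopifnot(inherits(seg, "matched_segmentation"),
            target_fraction > 0, target_fraction <= 1)
  n <- n_cells(seg)
  if (n == 0L) stop("segmentation has no cells")
  n_target <- ceiling(target_fraction * n)
  cell <- seg$cell; nucleus <- seg$nucleus
  merged <- integer(0)
  if (n_target < n) {
    pairs <- contact_pairs(cell)
    participated <- rep(FALSE, max(cell))
    with_seed_(seed, {
      remaining <- n - n_target
      while (remaining > 0L) {
        ok <- !participated[pairs[, 1]] & !participated[pairs[, 2]]
        idx <- which(ok)
        if (length(idx) == 0L) {
          warning(sprintf("ran out of mergeable contacting pairs: %d merge(s) short of the target", remaining))
          break
        }
        pick <- pairs[if (length(idx) == 1L) idx else sample(idx, 1L), ]
        a <- pick[1]; b <- pick[2]
        cell[cell == b] <- a
        nucleus <- fuse_nuclei(nucleus, cell, a, b)
        participated[c(a, b)] <- TRUE
        merged <- c(merged, a, b)
        remaining <- remaining - 1L
      }
    })
  }
  cen <- cell
  cen[nucleus > 0L] <- 0L
  out <- matched_segmentation(cell, nucleus, cen, matching = seg$matching,
                              pixel_size_um = seg$pixel_size_um)
  attr(out, "merged_ids") <- sort(merged)
  out
}

# Fuse nuclei a and b (already sharing cell id a in `cell`): open the
# inverted nuclear mask in the pair's neighbourhood with a disc sized from
# the inter-nucleus gap, then claim the filled gap for nucleus a, restricted
# to the merged cell so containment is preserved.
fuse_nuclei <- function(nucleus, cell, a, b) {
  nucleus[nucleus == b] <- a
  pos <- which(nucleus == a, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(nucleus)
  bin_a <- nucleus == a
  pad <- 6L
  r0 <- max(1L, min(pos[, 1]) - pad); r1 <- min(nrow(nucleus), max(pos[, 1]) + pad)
  c0 <- max(1L, min(pos[, 2]) - pad); c1 <- min(ncol(nucleus), max(pos[, 2]) + pad)
  sub_bin <- bin_a[r0:r1, c0:c1, drop = FALSE]
  comp <- label_components(sub_bin, connectivity = 8)
  if (max(comp) < 2L) return(nucleus)   # already connected
  # gap distance between the two largest components
  areas <- mask_areas(comp)
  big2 <- as.integer(names(sort(areas, decreasing = TRUE))[1:2])
  dmb <- EBImage::distmap(matrix(as.numeric(comp != big2[1]), nrow(comp)))
  gap <- min(dmb[comp == big2[2]])
  radius <- max(1L, as.integer(ceiling(gap / 2)))
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  inv <- matrix(as.numeric(!sub_bin), nrow(sub_bin))
  opened <- EBImage::opening(inv, brush)
  fused <- matrix(as.vector(opened) < 0.5, nrow(sub_bin))
  claim <- fused & cell[r0:r1, c0:c1, drop = FALSE] == a
  sub_nuc <- nucleus[r0:r1, c0:c1, drop = FALSE]
  sub_nuc[claim] <- a
  nucleus[r0:r1, c0:c1] <- sub_nuc
  nucleus
}

#' Shift all masks of a segmentation right and down
#'
#' The offset is `fraction` of the mean of the two image dimensions, rounded
#' to the nearest pixel (ties up); for a 1000 x 1000 mask a fraction of
#' 0.001 is a (1, 1) pixel offset. Vacated area becomes background, shifted-
#' out content is cropped, and any object losing all its pixels is removed
#' together with its partner so the one-to-one relationship survives.
#'
#' @param seg A `matched_segmentation`.
#' @param fraction Shift as a fraction of the mean dimension (>= 0).
#' @return The shifted `matched_segmentation`.
#' @export
shift_masks <- function(seg, fraction) {
  stopifnot(inherits(seg, "matched_segmentation"), fraction >= 0)
  H <- nrow(seg$cell); W <- ncol(seg$cell)
  off <- floor(fraction * (H + W) / 2 + 0.5)   # ties round up
  if (off == 0) return(seg)
  shift1 <- function(m) {
    out <- matrix(0L, H, W)
    if (off < H && off < W)
      out[(off + 1):H, (off + 1):W] <- m[1:(H - off), 1:(W - off)]
    out
  }
  cell <- shift1(seg$cell); nucleus <- shift1(seg$nucleus)
  keep <- intersect(mask_ids(cell), mask_ids(nucleus))
  cell[!(cell %in% keep)] <- 0L
  nucleus[!(nucleus %in% keep)] <- 0L
  cen <- cell
  cen[nucleus > 0L] <- 0L
  matched_segmentation(cell, nucleus, cen, matching = seg$matching,
                       pixel_size_um = seg$pixel_size_um)
}

#' Voronoi baseline segmentation
#'
#' A deliberately simple reference method: Otsu thresholding of the nuclear
#' channel yields nuclei (8-connected components; specks under
#' `min_nucleus_px` pixels are discarded), and every image pixel is assigned
#' to the cell of the nucleus with the nearest centroid (Euclidean distance,
#' ties to the lower nucleus id). The resulting cells tile the whole image.
#' Methods scoring below this baseline are considered unacceptable.
#'
#' @param image A `multichannel_image`.
#' @param nuclear_channel Name of the nuclear channel.
#' @param min_nucleus_px Minimum nucleus component size in pixels.
#' @return A `matched_segmentation` (cells, nuclei and CEN share ids).
#' @export
voronoi_baseline <- function(image, nuclear_channel, min_nucleus_px = 4L) {
  stopifnot(inherits(image, "multichannel_image"))
  nuc <- otsu_nuclear_mask(image, nuclear_channel, min_size = min_nucleus_px)
  ids <- mask_ids(nuc)
  if (length(ids) == 0L) stop("no nuclei detected by Otsu thresholding")
  H <- nrow(nuc); W <- ncol(nuc)
  pos <- which(nuc > 0L, arr.ind = TRUE)
  lab <- nuc[nuc > 0L]
  cy <- as.vector(rowsum(as.numeric(pos[, 1]), lab)) / as.vector(rowsum(rep(1, length(lab)), lab))
  cx <- as.vector(rowsum(as.numeric(pos[, 2]), lab)) / as.vector(rowsum(rep(1, length(lab)), lab))
  best_d <- matrix(Inf, H, W); cell <- matrix(0L, H, W)
  rows <- seq_len(H); cols <- seq_len(W)
  for (i in seq_along(ids)) {
    d <- outer((rows - cy[i])^2, (cols - cx[i])^2, "+")
    upd <- d < best_d          # strict: earlier (lower) id wins ties
    best_d[upd] <- d[upd]
    cell[upd] <- ids[i]
  }
  cell[nuc > 0L] <- nuc[nuc > 0L]   # defensive: containment for stray pixels
  cen <- cell
  cen[nuc > 0L] <- 0L
  matched_segmentation(cell, nuc, cen,
                       matching = match_cells_to_nuclei(cell, nuc),
                       pixel_size_um = image$pixel_size_um)
}
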