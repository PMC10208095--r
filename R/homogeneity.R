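# Population standard deviation (divisor n, not n-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Fraction of total variance carried by the first principal component of an
# observations x channels matrix. Degenerate inputs (fewer than 2 rows, or no
# variance at all) carry all their "variance" in one direction: returns 1.
pc1_fraction <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) return(1)
  xc <- sweep(x, 2, colMeans(x))
  total <- sum(xc^2)
  if (total <= 0) return(1)
  ev <- eigen(crossprod(xc), symmetric = TRUE, only.values = TRUE)$values
  max(ev) / sum(ev)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-channel mean-standardised features (bright channels must not dominate
# clustering); all-zero channels are left untouched.
standardise_features <- function(features) {
  mu <- colMeans(features)
  mu[mu == 0] <- 1
  sweep(features, 2, mu, "/")
}

# k-means partition robust to degenerate inputs: k is capped by the number
# of distinct rows, and when it reaches that cap the optimal partition is
# simply one cluster per distinct row (kmeans itself rejects k = nrow).
kmeans_partition <- function(fs, k) {
  keys <- apply(fs, 1, paste, collapse = "\r")
  nd <- length(unique(keys))
  if (k <= 1L || nd < 2L) return(rep(1L, nrow(fs)))
  if (k >= nd) return(match(keys, unique(keys)))
  stats::kmeans(fs, centers = k, nstart = 10, iter.max = 50)$cluster
}

#' Per-cell mean channel intensities over a compartment mask
#'
#' Builds the cell-by-channel feature table used by the cell-level
#' homogeneity metrics: for every object in `mask` (a nuclear,
#' cell-excluding-nucleus, or whole-cell compartment), the mean intensity of
#' each requested channel over that object's pixels. Cells whose compartment
#' is empty are simply absent from the table.
#'
#' @param image A `multichannel_image`.
#' @param mask Compartment label mask (same shape as the image planes).
#' @param channels Channel names to use; default all. Restricting channels
#'   supports panels where only a subset is comparable across datasets.
#' @return Numeric matrix, one row per cell (rownames are ids), one column
#'   per channel, with `attr(, "compartment")` carried from `mask` if set.
#' @export
compute_cell_features <- function(image, mask, channels = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  mask <- as_label_mask(mask)
  if (!identical(dim(image), dim(mask))) stop("image and mask differ in shape")
  if (is.null(channels)) channels <- channel_names(image)
  if (!all(channels %in% channel_names(image))) stop("unknown channel name(s)")
  ids <- mask_ids(mask)
  if (length(ids) == 0L) stop("mask contains no objects")
  pos <- mask > 0L
  grp <- mask[pos]
  counts <- as.vector(rowsum(rep(1, sum(pos)), grp))
  out <- vapply(channels, function(ch) {
    as.vector(rowsum(image$planes[[ch]][pos], grp)) / counts
  }, numeric(length(ids)))
  out <- matrix(out, nrow = length(ids),
                dimnames = list(ids, channels))
  out
}

#' Cluster-averaged cell-intensity uniformity (ACVC) and PC1 fraction (FPCC)
#'
#' A good segmentation produces cells whose channel compositions are
#' homogeneous within a cell type. Cells are partitioned into k clusters for
#' every k in 1..`k_max` (k-means on per-channel mean-standardised features;
#' k = 1 is the trivial single cluster). For each cluster, (a) the
#' coefficient of variation of each channel's per-cell means, averaged over
#' channels, and (b) the fraction of the cluster's variance carried by its
#' first principal component are computed and weighted by the cluster's size
#' fraction. ACVC and FPCC are the means of the weighted sums over k.
#' Clusters of size 1 are variance-free: CV contribution 0, PC1 fraction 1.
#'
#' @param features Cell-by-channel matrix from [compute_cell_features()].
#' @param k_max Largest number of clusters (default 10; truncated when fewer
#'   cells or fewer distinct feature rows are available).
#' @param seed RNG seed controlling the k-means restarts.
#' @return List with raw `ACVC` and `FPCC`; report `1/(ACVC+1)` and `FPCC`.
#' @export
compute_acvc_fpcc <- function(features, k_max = 10, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) {
    message("fewer than 2 cells: ACVC = 0, FPCC = 1 (degenerate)")
    return(list(ACVC = 0, FPCC = 1))
  }
  fs <- standardise_features(features)
  ks <- seq_len(min(k_max, n))
  with_seed_(seed, {
    per_k <- vapply(ks, function(k) {
      cl <- kmeans_partition(fs, k)
      acv <- 0; fpc <- 0
      for (c_id in unique(cl)) {
        idx <- which(cl == c_id)
        w <- length(idx) / n
        if (length(idx) < 2L) {
          cv <- 0; p1 <- 1
        } else {
          sub <- features[idx, , drop = FALSE]
          mu <- colMeans(sub)
          cvs <- ifelse(mu > 0, apply(sub, 2, pop_sd) / ifelse(mu > 0, mu, 1), 0)
          cv <- mean(cvs)
          p1 <- pc1_fraction(fs[idx, , drop = FALSE])
        }
        acv <- acv + w * cv
        fpc <- fpc + w * p1
      }
      c(acv, fpc)
    }, numeric(2))
    list(ACVC = mean(per_k[1, ]), FPCC = mean(per_k[2, ]))
  })
}

#' Average silhouette of cell-intensity clusterings (AS)
#'
#' Mean silhouette coefficient of k-means partitions of the cell feature
#' table for k = 2..min(10, n-1), averaged over k. Well-separated, compact
#' cell-type clusters give values near 1; structureless features give values
#' near 0. Identical features (zero distances) are reported as 0 by
#' convention.
#'
#' @inheritParams compute_acvc_fpcc
#' @param k_max Largest number of clusters (default 10).
#' @return AS in \[-1, 1\].
#' @export
compute_avg_silhouette <- function(features, k_max = 10, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3L) {
    message("fewer than 3 cells: AS = 0 (degenerate)")
    return(0)
  }
  fs <- standardise_features(features)
  d <- stats::dist(fs)
  if (max(d) == 0) return(0)
  nd <- nrow(unique(fs))
  ks <- 2:min(k_max, n - 1L, nd)
  if (length(ks) == 0L || ks[1] > min(n - 1L, nd)) return(0)
  with_seed_(seed, {
    mean(vapply(ks, function(k) {
      cl <- kmeans_partition(fs, k)
      if (length(unique(cl)) < 2L) return(0)
      sil <- cluster::silhouette(cl, d)
      mean(sil[, "sil_width"])
    }, numeric(1)))
  })
}

#' Uniformity of foreground pixels outside the cell mask (ACVF, FPCF)
#'
#' Foreground pixels not claimed by any cell should be uninteresting: if the
#' leftover pixels are heterogeneous, cells were probably missed. Over the
#' pixels in foreground minus cell mask, ACVF is the mean over channels of
#' the per-pixel coefficient of variation (reported as `1/(ACVF+1)`), and
#' FPCF is the fraction of variance in the first principal component of the
#' pixel-by-channel matrix. When the cells cover the whole foreground there
#' are no such pixels and both metrics take their best value 1.
#'
#' @param image A `multichannel_image`.
#' @param seg A `matched_segmentation`.
#' @param fg Logical foreground mask.
#' @return List with raw `ACVF` and `FPCF`.
#' @export
compute_outside_cell_metrics <- function(image, seg, fg) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(seg, "matched_segmentation"),
            identical(dim(image), dim(fg)))
  sel <- fg & seg$cell == 0L
  if (!any(sel)) {
    message("cells cover the whole foreground: ACVF = 0, FPCF = 1")
    return(list(ACVF = 0, FPCF = 1))
  }
  x <- vapply(image$planes, function(p) p[sel], numeric(sum(sel)))
  x <- matrix(x, ncol = length(image$planes))
  mu <- colMeans(x)
  cvs <- rep(0, ncol(x))
  nz <- mu > 0
  cvs[nz] <- apply(x[, nz, drop = FALSE], 2, pop_sd) / mu[nz]
  list(ACVF = mean(cvs), FPCF = pc1_fraction(x))
}
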