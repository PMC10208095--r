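#' Validate and coerce a label mask
#'
#' A label mask is a 2D integer matrix in which 0 marks background and each
#' positive integer identifies one object (a cell or a nucleus). Object ids
#' need not be consecutive; two objects never share a pixel because the mask
#' itself is single-valued.
#'
#' @param x A numeric or integer matrix with non-negative whole values.
#' @return An integer matrix of the same shape.
#' @export
as_label_mask <- function(x) {
  if (!is.matrix(x)) stop("a label mask must be a 2D matrix")
  if (anyNA(x)) stop("label mask contains NA")
  if (any(x < 0)) stop("label mask values must be >= 0")
  if (any(x != round(x))) stop("label mask values must be whole numbers")
  storage.mode(x) <- "integer"
  x
}

#' Object ids present in a label mask
#'
#' @param mask A label mask.
#' @return Sorted integer vector of positive ids (background excluded).
#' @export
mask_ids <- function(mask) {
  ids <- sort(unique(as.vector(mask)))
  ids[ids > 0L]
}

#' Per-object pixel areas
#'
#' @param mask A label mask.
#' @param ids Ids to report; defaults to all ids present.
#' @return Named integer vector of pixel counts, one entry per id.
#' @export
mask_areas <- function(mask, ids = mask_ids(mask)) {
  if (length(ids) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- tabulate(mask, nbins = max(ids))
  stats::setNames(counts[ids], ids)
}

#' Relabel objects consecutively from 1
#'
#' @param mask A label mask.
#' @return A label mask with ids 1..n (order of old ids preserved), carrying
#'   the old ids as `attr(, "id_map")` (named vector new -> old).
#' @export
relabel_mask <- function(mask) {
  ids <- mask_ids(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(ids) > 0L) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    pos <- mask > 0L
    out[pos] <- lut[mask[pos]]
  }
  attr(out, "id_map") <- stats::setNames(ids, seq_along(ids))
  out
}

#' Label connected components of a binary mask
#'
#' Components are found at 4- or 8-connectivity. EBImage's labelling is
#' 4-connective; for 8-connectivity, components touching diagonally are
#' merged by union-find over the 4-connected pieces.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return A label mask of components.
#' @export
label_components <- function(binary, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(matrix(as.numeric(binary != 0), nrow(binary)))
  lab <- matrix(as.integer(round(lab)), nrow(binary))
  n <- max(lab)
  if (connectivity == 4 || n < 2L) return(as_label_mask(lab))
  # merge labels that are diagonally adjacent
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  for (d in list(c(1, 1), c(1, -1))) {
    ar <- 1:(H - 1); ac <- if (d[2] > 0) 1:(W - 1) else 2:W
    a <- lab[ar, ac]; b <- lab[ar + 1, ac + d[2]]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      for (p in unique(a[sel] + (n + 1L) * b[sel])) {
        i <- p %% (n + 1L); j <- p %/% (n + 1L)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lut <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- lut[lab[pos]]
  as_label_mask(lab)
}

#' Read a label mask from TIFF or NPY
#'
#' TIFF masks must be single-plane unsigned-integer images with background 0.
#' NPY files (NumPy array format, version 1.0, C order, integer dtypes) are
#' also supported since several segmentation tools emit them.
#'
#' @param path File path (`.tif`, `.tiff`, or `.npy`).
#' @return A label mask.
#' @export
read_mask <- function(path) {
  if (grepl("\\.npy$", path, ignore.case = TRUE)) return(as_label_mask(read_npy_matrix(path)))
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) != 2L) stop("mask TIFF must be single-plane")
  as_label_mask(matrix(as.integer(round(x)), nrow(x)))
}

#' Write a label mask as 16- or 32-bit TIFF
#'
#' @param mask A label mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_label_mask(mask)
  mx <- max(mask)
  bits <- if (mx < 2^16) 16L else 32L
  tiff::writeTIFF(mask / (2^bits - 1), path, bits.per.sample = bits)
  invisible(path)
}

# Minimal NPY (v1.0, C-order, little-endian integer) reader for 2D arrays.
read_npy_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(rawToChar(magic[2:6]), "NUMPY")) stop("not an NPY file")
  readBin(con, "raw", 2)                       # version
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  if (length(dims) != 2L) stop("NPY mask must be 2D")
  size <- as.integer(sub(".*[iuf]", "", descr))
  what <- if (grepl("f", descr)) "double" else "integer"
  v <- readBin(con, what, n = prod(dims), size = size, endian = "little")
  matrix(as.integer(round(v)), nrow = dims[1], byrow = TRUE)  # C order
}
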