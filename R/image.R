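#' Construct a multichannel fluorescence image
#'
#' Bundles one 2D non-negative intensity plane per named channel together
#' with the physical pixel size. All planes must share one shape. Typical
#' multiplexed modalities (CODEX, Cell DIVE, MIBI, IMC) have pixel sizes
#' between roughly 0.3 and 1 micrometre.
#'
#' @param planes Named list of numeric matrices (intensities, >= 0).
#' @param pixel_size_um Physical edge length of one pixel in micrometres.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(planes, pixel_size_um) {
  if (!is.list(planes) || length(planes) < 1L) stop("need at least one channel plane")
  if (is.null(names(planes)) || any(!nzchar(names(planes))) || anyDuplicated(names(planes)))
    stop("planes must have unique non-empty names")
  dims <- lapply(planes, dim)
  if (!all(vapply(planes, is.matrix, logical(1))) ||
      !all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop("all planes must be matrices of one shape")
  for (p in planes) {
    if (anyNA(p) || any(p < 0)) stop("intensities must be finite and >= 0")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(planes = lapply(planes, function(p) { storage.mode(p) <- "double"; p }),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("multichannel_image: %d x %d px, %.4g um/px, %d channel(s): %s\n",
              d[1], d[2], x$pixel_size_um, length(x$planes),
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$planes[[1]])

#' Channel names of a multichannel image
#' @param image A `multichannel_image`.
#' @return Character vector of channel names.
#' @export
channel_names <- function(image) names(image$planes)

#' Read a multichannel image from a (multi-plane) TIFF
#'
#' Each TIFF directory becomes one channel. Channel names default to
#' `ch1..chn` when not supplied.
#'
#' @param path TIFF path.
#' @param pixel_size_um Pixel size in micrometres.
#' @param channel_names Optional character vector naming the planes.
#' @return A `multichannel_image`.
#' @export
read_multichannel_image <- function(path, pixel_size_um, channel_names = NULL) {
  x <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  planes <- lapply(x, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p))
  })
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_along(planes))
  names(planes) <- channel_names
  multichannel_image(planes, pixel_size_um)
}

#' Write a multichannel image as a multi-plane 16-bit TIFF
#'
#' Intensities are stored as-is when they fit 16-bit, otherwise scaled by the
#' global maximum (the scale factor is returned as an attribute).
#'
#' @param image A `multichannel_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multichannel_image <- function(image, path) {
  mx <- max(1, vapply(image$planes, max, numeric(1)))
  scale <- if (mx > 2^16 - 1) (2^16 - 1) / mx else 1
  planes <- lapply(image$planes, function(p) round(p * scale) / (2^16 - 1))
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(structure(path, scale = scale))
}
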