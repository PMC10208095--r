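#' Estimate the tissue foreground of a multichannel image
#'
#' Marks the tissue-occupied part of the image, as opposed to slide
#' background. Each channel is normalised by its mean, the normalised
#' channels are averaged, an Otsu threshold is applied to the average, and
#' the binary mask is cleaned up by morphological closing (disc radius 1)
#' and hole filling. A constant image has no contrast and yields an
#' all-background mask.
#'
#' @param image A `multichannel_image`.
#' @return Logical matrix, `TRUE` on foreground.
#' @export
compute_foreground <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  d <- dim(image)
  acc <- matrix(0, d[1], d[2])
  for (p in image$planes) {
    m <- mean(p)
    if (m > 0) acc <- acc + p / m
  }
  acc <- acc / length(image$planes)
  rng <- range(acc)
  if (diff(rng) == 0) return(matrix(FALSE, d[1], d[2]))
  sc <- (acc - rng[1]) / diff(rng)
  thr <- EBImage::otsu(sc, range = c(0, 1))
  fg <- sc > thr
  kern <- EBImage::makeBrush(3, shape = "disc")
  fg <- EBImage::closing(matrix(as.numeric(fg), d[1]), kern)
  fg <- EBImage::fillHull(fg)
  matrix(as.vector(fg) > 0.5, d[1], d[2])
}

#' Fraction of match between cells and nuclei (FMCN)
#'
#' A Dice-style agreement between the cell and nuclear masks prior to any
#' mask processing: twice the number of matched cell/nucleus pairs divided
#' by the total number of cells plus nuclei. Orphan cells and orphan nuclei
#' are penalised symmetrically; FMCN is 1 exactly when the matching is
#' perfect on both sides.
#'
#' @param matching A `cell_nucleus_matching` computed on raw masks.
#' @return FMCN in \[0, 1\].
#' @export
compute_fmcn <- function(matching) {
  stopifnot(inherits(matching, "cell_nucleus_matching"))
  denom <- matching$n_cells_pre + matching$n_nuclei_pre
  if (denom == 0L) stop("no cells and no nuclei: FMCN undefined")
  2 * nrow(matching$pairs) / denom
}

#' Coverage metrics of a matched cell mask
#'
#' Computes, against a foreground estimate:
#' \describe{
#'   \item{NC}{number of cells per 100 square micrometres of image}
#'   \item{FFC}{fraction of image foreground occupied by cells}
#'   \item{1-FBC}{one minus the fraction of image background occupied by cells}
#'   \item{FCF}{fraction of the cell mask lying in the foreground}
#' }
#'
#' @param seg A `matched_segmentation`.
#' @param fg Logical foreground mask of the same shape.
#' @return Named list `NC`, `FFC`, `one_minus_FBC`, `FCF`.
#' @export
compute_coverage_metrics <- function(seg, fg) {
  stopifnot(inherits(seg, "matched_segmentation"), is.logical(fg),
            identical(dim(seg$cell), dim(fg)))
  cellpix <- seg$cell > 0L
  n_fg <- sum(fg); n_bg <- length(fg) - n_fg
  n_cell <- sum(cellpix)
  area_um2 <- length(fg) * seg$pixel_size_um^2
  NC <- 100 * n_cells(seg) / area_um2
  if (n_fg == 0L) {
    warning("empty foreground: FFC reported as 0")
    FFC <- 0
  } else FFC <- sum(cellpix & fg) / n_fg
  FBC <- if (n_bg == 0L) 0 else sum(cellpix & !fg) / n_bg
  if (n_cell == 0L) {
    warning("empty cell mask: FCF reported as 0")
    FCF <- 0
  } else FCF <- sum(cellpix & fg) / n_cell
  list(NC = NC, FFC = FFC, one_minus_FBC = 1 - FBC, FCF = FCF)
}

#' Cell-size dispersion metric 1/(ln(CSSD)+1)
#'
#' CSSD is the population standard deviation of per-cell areas in square
#' micrometres, so the value is resolution-independent. It is clamped to at
#' least 1 before the logarithm so the published transform stays defined;
#' uniform cell sizes therefore map to the best value 1.
#'
#' @param seg A `matched_segmentation` with at least one cell.
#' @return The transformed metric in (0, 1\].
#' @export
compute_cssd_metric <- function(seg) {
  stopifnot(inherits(seg, "matched_segmentation"))
  areas_px <- mask_areas(seg$cell)
  if (length(areas_px) == 0L) stop("no cells: CSSD undefined")
  areas <- areas_px * seg$pixel_size_um^2
  cssd <- sqrt(mean((areas - mean(areas))^2))
  1 / (log(max(cssd, 1)) + 1)
}
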