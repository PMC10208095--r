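#' Metric names of the two panel variants
#'
#' The full panel has 14 metrics; the reduced panel (for segmentations
#' without nuclear masks, e.g. expert annotations) drops FMCN and computes
#' the cell-level uniformity metrics once on the whole-cell compartment
#' instead of separately on the nuclear (NUC) and cell-excluding-nucleus
#' (CEN) compartments.
#'
#' @param variant `"full14"` or `"reduced10"`.
#' @return Character vector of metric names.
#' @export
metric_names <- function(variant = c("full14", "reduced10")) {
  variant <- match.arg(variant)
  if (variant == "full14") {
    c("NC", "FFC", "1-FBC", "FCF", "FMCN", "1/(ACVF+1)", "FPCF",
      "1/(ACVC_NUC+1)", "1/(ACVC_CEN+1)", "FPCC_NUC", "FPCC_CEN",
      "AS_NUC", "AS_CEN", "1/(ln(CSSD)+1)")
  } else {
    c("NC", "FFC", "1-FBC", "FCF", "1/(ACVF+1)", "FPCF",
      "1/(ACVC+1)", "FPCC", "AS", "1/(ln(CSSD)+1)")
  }
}

#' Evaluation configuration
#'
#' @param variant Metric panel: `"full14"` (default) or `"reduced10"`.
#' @param repair_mode How to enforce one-to-one masks: `"repair"` (trim
#'   protruding nuclei, default) or `"strict"` (drop misshaped pairs).
#' @param nuclear_channel Channel used to synthesise a nuclear mask by Otsu
#'   thresholding when no nuclear mask is supplied.
#' @param channels Channel subset for the homogeneity metrics; default all.
#' @param k_max Largest cluster count for the cell-level metrics.
#' @param seed RNG seed for clustering restarts.
#' @return A list of class `segqc_config`.
#' @export
segqc_config <- function(variant = c("full14", "reduced10"),
                         repair_mode = c("repair", "strict"),
                         nuclear_channel = NULL, channels = NULL,
                         k_max = 10, seed = 1) {
  structure(list(variant = match.arg(variant),
                 repair_mode = match.arg(repair_mode),
                 nuclear_channel = nuclear_channel,
                 channels = channels, k_max = k_max, seed = seed),
            class = "segqc_config")
}

# Otsu-thresholded nuclear mask used when a method provides no nuclei:
# threshold the nuclear channel, label 8-connected components, drop specks.
otsu_nuclear_mask <- function(image, nuclear_channel, min_size = 4L) {
  p <- image$planes[[nuclear_channel]]
  if (is.null(p)) stop(sprintf("nuclear channel '%s' not found", nuclear_channel))
  rng <- range(p)
  if (diff(rng) == 0) stop("constant nuclear channel: cannot threshold")
  sc <- (p - rng[1]) / diff(rng)
  thr <- EBImage::otsu(sc, range = c(0, 1))
  lab <- label_components(sc > thr, connectivity = 8)
  areas <- mask_areas(lab)
  small <- as.integer(names(areas)[areas < min_size])
  if (length(small) > 0L) {
    lab[lab %in% small] <- 0L
    lab <- relabel_mask(lab)
    attr(lab, "id_map") <- NULL
  }
  lab
}

#' Compute the full quality-metric vector for one segmentation
#'
#' Runs the whole single-method evaluation: cell/nucleus matching, strict or
#' repair enforcement of the one-to-one relationship, foreground estimation,
#' and all coverage and homogeneity metrics. When no nuclear mask is given,
#' one is synthesised by Otsu thresholding of `config$nuclear_channel`.
#'
#' @param image A `multichannel_image`.
#' @param cell_mask Cell label mask.
#' @param nuclear_mask Nuclear label mask, or `NULL` to synthesise one.
#' @param config A [segqc_config()].
#' @return A named numeric vector of class `metric_vector` with attributes
#'   `variant` and `n_cells`.
#' @export
compute_metric_vector <- function(image, cell_mask, nuclear_mask = NULL,
                                  config = segqc_config()) {
  stopifnot(inherits(image, "multichannel_image"), inherits(config, "segqc_config"))
  cell_mask <- as_label_mask(cell_mask)
  if (!identical(dim(image), dim(cell_mask))) stop("image and cell mask differ in shape")
  if (is.null(nuclear_mask)) {
    if (is.null(config$nuclear_channel))
      stop("no nuclear mask supplied and no nuclear_channel configured")
    nuclear_mask <- otsu_nuclear_mask(image, config$nuclear_channel)
  }
  nuclear_mask <- as_label_mask(nuclear_mask)

  matching <- match_cells_to_nuclei(cell_mask, nuclear_mask)
  seg <- apply_repair(cell_mask, nuclear_mask, matching,
                      mode = config$repair_mode,
                      pixel_size_um = image$pixel_size_um)
  if (n_cells(seg) == 0L) stop("no matched cells survive mask processing")

  fg <- compute_foreground(image)
  cov <- compute_coverage_metrics(seg, fg)
  out_px <- compute_outside_cell_metrics(image, seg, fg)
  cssd <- compute_cssd_metric(seg)

  homog <- function(mask) {
    feats <- compute_cell_features(image, mask, config$channels)
    af <- compute_acvc_fpcc(feats, k_max = config$k_max, seed = config$seed)
    as_ <- compute_avg_silhouette(feats, k_max = config$k_max, seed = config$seed)
    c(acvc = 1 / (af$ACVC + 1), fpcc = af$FPCC, as = as_)
  }

  if (config$variant == "full14") {
    h_nuc <- homog(seg$nucleus)
    cen <- seg$cell_excluding_nucleus
    h_cen <- if (length(mask_ids(cen)) > 0L) homog(cen) else {
      message("all CEN regions empty; CEN homogeneity metrics degenerate")
      c(acvc = 1, fpcc = 1, as = 0)
    }
    v <- c(cov$NC, cov$FFC, cov$one_minus_FBC, cov$FCF,
           compute_fmcn(matching),
           1 / (out_px$ACVF + 1), out_px$FPCF,
           h_nuc[["acvc"]], h_cen[["acvc"]],
           h_nuc[["fpcc"]], h_cen[["fpcc"]],
           h_nuc[["as"]], h_cen[["as"]], cssd)
  } else {
    h_cell <- homog(seg$cell)
    v <- c(cov$NC, cov$FFC, cov$one_minus_FBC, cov$FCF,
           1 / (out_px$ACVF + 1), out_px$FPCF,
           h_cell[["acvc"]], h_cell[["fpcc"]], h_cell[["as"]], cssd)
  }
  names(v) <- metric_names(config$variant)
  structure(v, variant = config$variant, n_cells = n_cells(seg),
            class = c("metric_vector", "numeric"))
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("metric_vector (%s, %d cells):\n", attr(x, "variant"), attr(x, "n_cells")))
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Convert metric vectors to a one-row-per-segmentation data frame
#'
#' @param x A `metric_vector`.
#' @param image_id,method_id Optional identifiers recorded in the row.
#' @param ... Unused.
#' @return A data frame with identifier columns, the variant, and one column
#'   per metric (named exactly as in [metric_names()]).
#' @export
as.data.frame.metric_vector <- function(x, image_id = NA_character_,
                                        method_id = NA_character_, ...) {
  df <- as.data.frame(as.list(stats::setNames(as.numeric(x), names(x))),
                      check.names = FALSE)
  cbind(data.frame(image_id = image_id, method_id = method_id,
                   variant = attr(x, "variant"), stringsAsFactors = FALSE), df)
}
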