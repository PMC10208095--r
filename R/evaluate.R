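#' Evaluate one segmentation of one image
#'
#' End-to-end single-pair evaluation: reads the image and masks when paths
#' are given, computes the metric vector (see [compute_metric_vector()]),
#' and optionally scores it with a fitted quality model.
#'
#' @param image A `multichannel_image` or a TIFF path.
#' @param cell_mask Label mask or TIFF/NPY path.
#' @param nuclear_mask Label mask, TIFF/NPY path, or `NULL` to synthesise a
#'   nuclear mask by Otsu thresholding of `config$nuclear_channel`.
#' @param config A [segqc_config()].
#' @param model Optional `quality_model` used to append `pc1`, `pc2`,
#'   `score`.
#' @param pixel_size_um Required when `image` is a path.
#' @param channel_names Optional channel names when `image` is a path.
#' @param image_id,method_id Identifiers recorded in the output row.
#' @return One-row data frame: identifiers, variant, the metrics, `n_cells`,
#'   and (with a model) `pc1`, `pc2`, `score`.
#' @export
evaluate_image <- function(image, cell_mask, nuclear_mask = NULL,
                           config = segqc_config(), model = NULL,
                           pixel_size_um = NULL, channel_names = NULL,
                           image_id = NA_character_, method_id = NA_character_) {
  if (is.character(image)) {
    if (is.null(pixel_size_um)) stop("pixel_size_um is required when reading an image from file")
    image <- read_multichannel_image(image, pixel_size_um, channel_names)
  }
  if (is.character(cell_mask)) cell_mask <- read_mask(cell_mask)
  if (is.character(nuclear_mask)) nuclear_mask <- read_mask(nuclear_mask)
  mv <- compute_metric_vector(image, cell_mask, nuclear_mask, config)
  row <- as.data.frame(mv, image_id = image_id, method_id = method_id)
  row$n_cells <- attr(mv, "n_cells")
  if (!is.null(model)) row <- cbind(row, score_segmentation(model, mv))
  row
}

#' Evaluate a batch of (image, cell mask, nuclear mask) triplets
#'
#' Rows are processed sequentially in the order given and the output is
#' merged deterministically by `image_id`/`method_id`, so results do not
#' depend on scheduling.
#'
#' @param table Data frame with columns `image`, `cell_mask`, optionally
#'   `nuclear_mask`, `image_id`, `method_id`, `pixel_size_um`.
#' @inheritParams evaluate_image
#' @return Data frame, one metric row per input row.
#' @export
evaluate_batch <- function(table, config = segqc_config(), model = NULL) {
  table <- as.data.frame(table)
  stopifnot(nrow(table) >= 1, all(c("image", "cell_mask") %in% names(table)))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    evaluate_image(table$image[i], table$cell_mask[i],
                   if (!is.null(table$nuclear_mask)) table$nuclear_mask[i],
                   config = config, model = model,
                   pixel_size_um = table$pixel_size_um[i],
                   image_id = if (!is.null(table$image_id)) table$image_id[i] else basename(table$image[i]),
                   method_id = if (!is.null(table$method_id)) table$method_id[i] else NA_character_)
  })
  out <- do.call(rbind, rows)
  out[order(out$image_id, out$method_id), , drop = FALSE]
}

#' Plot a method ranking
#'
#' Horizontal bar chart of overall quality scores from [rank_methods()],
#' with the baseline (when flagged) drawn as a reference line.
#'
#' @param ranking Data frame from [rank_methods()].
#' @return A ggplot object.
#' @export
plot_quality_ranking <- function(ranking) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ranking$method <- factor(ranking$method, levels = rev(ranking$method))
  p <- ggplot2::ggplot(ranking, ggplot2::aes(x = score, y = method)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "overall quality score", y = NULL)
  if (!is.null(ranking$acceptable) && any(ranking$acceptable)) {
    thr <- min(ranking$score[ranking$acceptable], na.rm = TRUE)
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed")
  }
  p
}

#' Plot metric loadings of a fitted quality model
#'
#' @param model A `quality_model`.
#' @return A ggplot object with PC1/PC2 loadings per metric.
#' @export
plot_model_loadings <- function(model) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  td <- tidy(model)
  long <- rbind(data.frame(metric = td$metric, component = "PC1", loading = td$loading_pc1),
                data.frame(metric = td$metric, component = "PC2", loading = td$loading_pc2))
  long$metric <- factor(long$metric, levels = td$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = metric, y = loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "loading")
}

utils::globalVariables(c("score", "method", "metric", "loading", "pc1", "pc2", "component"))
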