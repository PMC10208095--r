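#' Fit the PCA-based segmentation quality model
#'
#' The metric matrix (one row per evaluated segmentation, one column per
#' metric) is z-scored column-wise and decomposed by principal component
#' analysis. The first component summarises overall quality and its loadings
#' are expected to be all positive: the sign of PC1 is flipped when its
#' loading sum is negative. PC2 indicates the overall coverage of a mask
#' (high NC and FFC loadings): its sign is flipped when the NC+FFC loading
#' sum is negative (falling back to the total loading sum when those columns
#' are absent). Zero-variance columns are kept, with their z-scale set to 1,
#' so the vector length is stable across model versions.
#'
#' @param x Numeric matrix or data frame of metric rows; at least 3 rows, no
#'   missing entries, all rows the same panel variant.
#' @param variant Panel variant recorded on the model.
#' @return An object of class `quality_model` with fields `metric_names`,
#'   `mean`, `sd`, `L1`, `L2`, `v1`, `v2`, `variant`.
#' @export
fit_quality_model <- function(x, variant = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 metric rows to fit the model")
  if (anyNA(x)) stop("metric matrix contains missing entries")
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) {
    message(sprintf("%d zero-variance metric column(s); z-scale set to 1", sum(sdv == 0)))
    sdv[sdv == 0] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  lambda <- pca$sdev^2
  if (sum(lambda > max(lambda) * 1e-10) < 2L)
    stop("metric matrix is rank-deficient: fewer than 2 non-degenerate components")
  L1 <- pca$rotation[, 1]
  L2 <- pca$rotation[, 2]
  if (sum(L1) < 0) L1 <- -L1
  cov_cols <- intersect(c("NC", "FFC"), colnames(x))
  s2 <- if (length(cov_cols) > 0L) sum(L2[cov_cols]) else sum(L2)
  if (s2 < 0) L2 <- -L2
  structure(list(metric_names = colnames(x), mean = mu, sd = sdv,
                 L1 = L1, L2 = L2,
                 v1 = lambda[1] / sum(lambda), v2 = lambda[2] / sum(lambda),
                 variant = variant),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("quality_model on %d metrics%s: v1 = %.3f, v2 = %.3f\n",
              length(x$metric_names),
              if (is.null(x$variant)) "" else paste0(" (", x$variant, ")"),
              x$v1, x$v2))
  invisible(x)
}

#' Loadings and z-score parameters of a quality model
#' @param x A `quality_model`.
#' @param ... Unused.
#' @return Data frame with one row per metric: mean, sd, PC1/PC2 loadings.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.quality_model <- function(x, ...) {
  data.frame(metric = x$metric_names, mean = unname(x$mean), sd = unname(x$sd),
             loading_pc1 = unname(x$L1), loading_pc2 = unname(x$L2),
             row.names = NULL)
}

#' One-row summary of a quality model
#' @param x A `quality_model`.
#' @param ... Unused.
#' @return One-row data frame with explained-variance fractions.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.quality_model <- function(x, ...) {
  data.frame(n_metrics = length(x$metric_names), v1 = x$v1, v2 = x$v2,
             variant = if (is.null(x$variant)) NA_character_ else x$variant)
}

# z-score rows of m against the model's stored parameters, after checking
# and aligning metric names.
model_z <- function(model, m) {
  m <- if (is.null(dim(m))) matrix(m, nrow = 1, dimnames = list(NULL, names(m))) else as.matrix(m)
  if (is.null(colnames(m)) || !setequal(colnames(m), model$metric_names))
    stop("metric names do not match the model")
  m <- m[, model$metric_names, drop = FALSE]
  sweep(sweep(m, 2, model$mean), 2, model$sd, "/")
}

#' Score one or more segmentations with a fitted quality model
#'
#' Projects z-scored metric vectors on the model's first two components;
#' the overall quality score is the variance-weighted sum
#' `score = v1 * pc1 + v2 * pc2`.
#'
#' @param model A `quality_model`.
#' @param m A `metric_vector`, named numeric vector, or matrix/data frame of
#'   rows whose (column) names match the model's metrics.
#' @return Data frame with columns `pc1`, `pc2`, `score`, one row per input
#'   row.
#' @export
score_segmentation <- function(model, m) {
  stopifnot(inherits(model, "quality_model"))
  if (inherits(m, "metric_vector") && !is.null(model$variant) &&
      !identical(attr(m, "variant"), model$variant))
    stop("metric vector variant does not match the model")
  z <- model_z(model, m)
  pc1 <- as.vector(z %*% model$L1)
  pc2 <- as.vector(z %*% model$L2)
  data.frame(pc1 = pc1, pc2 = pc2, score = model$v1 * pc1 + model$v2 * pc2)
}

#' Rank segmentation methods with modality balancing
#'
#' Averages the top-2 PC values per method within each imaging modality,
#' then (unweighted) across modalities, so that modalities with unequal
#' image counts contribute equally; the final score is computed from the
#' balanced PC means. A baseline method (typically the Voronoi segmenter)
#' can be named: methods scoring above it are flagged acceptable.
#'
#' @param scores Data frame with columns `method`, `pc1`, `pc2` and
#'   optionally `modality` (a single modality is assumed when absent).
#' @param model The `quality_model` providing the variance weights.
#' @param baseline Optional method name used as the acceptability threshold.
#' @return Data frame ordered by descending score with columns `method`,
#'   `pc1`, `pc2`, `score`, `rank`, and `acceptable` when a baseline is
#'   given.
#' @export
rank_methods <- function(scores, model, baseline = NULL) {
  stopifnot(inherits(model, "quality_model"))
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0L) stop("empty score table")
  if (!all(c("method", "pc1", "pc2") %in% names(scores)))
    stop("scores must have columns method, pc1, pc2")
  if (is.null(scores$modality)) scores$modality <- "all"
  per_mod <- stats::aggregate(cbind(pc1, pc2) ~ method + modality, scores, mean)
  per_meth <- stats::aggregate(cbind(pc1, pc2) ~ method, per_mod, mean)
  per_meth$score <- model$v1 * per_meth$pc1 + model$v2 * per_meth$pc2
  per_meth <- per_meth[order(-per_meth$score), ]
  per_meth$rank <- seq_len(nrow(per_meth))
  if (!is.null(baseline)) {
    if (!baseline %in% per_meth$method) stop("baseline method not present")
    per_meth$acceptable <- per_meth$score > per_meth$score[per_meth$method == baseline]
  }
  rownames(per_meth) <- NULL
  per_meth
}

#' Normalised metric-vector difference score between two methods
#'
#' Quantifies how differently two methods segment the same images from
#' their single-method metric vectors alone. Metric columns are z-scored
#' over the pooled rows of both methods; per image the element-wise absolute
#' difference of the two z-scored vectors is taken; PCA (PC1 sign fixed to a
#' positive loading sum) is applied across the difference rows of all method
#' pairs including the self-comparisons, whose difference rows are all-zero;
#' and the score is the mean PC1 of the pair's rows minus the PC1 of the
#' all-zero self-comparison row. A score of zero means no difference.
#'
#' @param mA,mB Metric matrices (rows aligned by image, same metric columns).
#' @return Non-negative difference score; symmetric in its arguments.
#' @export
pairwise_difference_score <- function(mA, mB) {
  mA <- as.matrix(mA); mB <- as.matrix(mB)
  if (!identical(dim(mA), dim(mB))) stop("metric matrices are misaligned")
  if (!is.null(colnames(mA)) && !is.null(colnames(mB))) {
    if (!setequal(colnames(mA), colnames(mB))) stop("metric columns differ")
    mB <- mB[, colnames(mA), drop = FALSE]
  }
  pooled <- rbind(mA, mB)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  sdv[sdv == 0] <- 1
  zA <- sweep(sweep(mA, 2, mu), 2, sdv, "/")
  zB <- sweep(sweep(mB, 2, mu), 2, sdv, "/")
  dAB <- abs(zA - zB)
  zero <- matrix(0, nrow(mA), ncol(mA))
  D <- rbind(zero, dAB, zero)          # pairs (A,A), (A,B), (B,B)
  ctr <- colMeans(D)
  Dc <- sweep(D, 2, ctr)
  if (sum(Dc^2) == 0) return(0)        # identical methods: no difference
  L1 <- stats::prcomp(D, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (sum(L1) < 0) L1 <- -L1
  pc1_pair <- mean((dAB %*% L1) - sum(ctr * L1))
  pc1_self <- -sum(ctr * L1)
  pc1_pair - pc1_self
}

#' Serialise a quality model to JSON
#'
#' @param model A `quality_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality_model <- function(model, path) {
  stopifnot(inherits(model, "quality_model"))
  obj <- list(metric_names = model$metric_names,
              mean = unname(model$mean), sd = unname(model$sd),
              L1 = unname(model$L1), L2 = unname(model$L2),
              v1 = model$v1, v2 = model$v2, variant = model$variant,
              generator = paste0("segqc ", as.character(utils::packageVersion("segqc"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quality model from JSON
#'
#' @param path Path written by [write_quality_model()].
#' @return A `quality_model`.
#' @export
read_quality_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- obj$metric_names
  structure(list(metric_names = nm,
                 mean = stats::setNames(as.numeric(obj$mean), nm),
                 sd = stats::setNames(as.numeric(obj$sd), nm),
                 L1 = stats::setNames(as.numeric(obj$L1), nm),
                 L2 = stats::setNames(as.numeric(obj$L2), nm),
                 v1 = as.numeric(obj$v1), v2 = as.numeric(obj$v2),
                 variant = obj$variant),
            class = "quality_model")
}
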