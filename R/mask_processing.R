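# Overlap accounting between two label masks: one row per (a_id, b_id) pair
# of objects sharing at least one pixel.
overlap_pairs <- function(a, b) {
  sel <- a > 0L & b > 0L
  if (!any(sel)) {
    return(data.frame(a_id = integer(0), b_id = integer(0), overlap = integer(0)))
  }
  ka <- as.numeric(a[sel]); kb <- as.numeric(b[sel])
  mb <- max(kb) + 1
  key <- ka * mb + kb
  u <- sort(unique(key))
  counts <- tabulate(match(key, u), nbins = length(u))
  data.frame(a_id = as.integer(u %/% mb), b_id = as.integer(u %% mb),
             overlap = counts)
}

#' Match cells to nuclei
#'
#' Pairs each cell with at most one nucleus. A nucleus is a candidate for a
#' cell when the two overlap by at least one pixel; the mismatch fraction of
#' a candidate pair is the fraction of the nucleus' pixels lying outside the
#' cell. Pairing is resolved globally and greedily by ascending mismatch
#' fraction (ties: larger overlap, then smaller cell id, then smaller nucleus
#' id), enforcing a one-to-one relationship. Cells without a candidate
#' nucleus and nuclei without a candidate cell are reported unmatched.
#'
#' @param cell,nucleus Label masks of identical shape.
#' @return An object of class `cell_nucleus_matching`: a list with `pairs`
#'   (data.frame `cell_id`, `nucleus_id`, `mismatch_fraction`, `overlap`),
#'   `unmatched_cells`, `unmatched_nuclei`, and the pre-processing object
#'   counts `n_cells_pre`, `n_nuclei_pre`.
#' @export
match_cells_to_nuclei <- function(cell, nucleus) {
  cell <- as_label_mask(cell); nucleus <- as_label_mask(nucleus)
  if (!identical(dim(cell), dim(nucleus))) stop("cell and nucleus masks differ in shape")
  cell_ids <- mask_ids(cell); nuc_ids <- mask_ids(nucleus)
  ov <- overlap_pairs(cell, nucleus)
  pairs <- data.frame(cell_id = integer(0), nucleus_id = integer(0),
                      mismatch_fraction = numeric(0), overlap = integer(0))
  if (nrow(ov) > 0L) {
    nuc_area <- mask_areas(nucleus)
    ov$mismatch_fraction <- 1 - ov$overlap / nuc_area[as.character(ov$b_id)]
    ov <- ov[order(ov$mismatch_fraction, -ov$overlap, ov$a_id, ov$b_id), ]
    used_c <- logical(max(cell_ids)); used_n <- logical(max(nuc_ids))
    keep <- logical(nrow(ov))
    for (i in seq_len(nrow(ov))) {
      ci <- ov$a_id[i]; ni <- ov$b_id[i]
      if (!used_c[ci] && !used_n[ni]) {
        keep[i] <- TRUE; used_c[ci] <- TRUE; used_n[ni] <- TRUE
      }
    }
    kept <- ov[keep, ]
    pairs <- data.frame(cell_id = kept$a_id, nucleus_id = kept$b_id,
                        mismatch_fraction = kept$mismatch_fraction,
                        overlap = kept$overlap)
    pairs <- pairs[order(pairs$cell_id), ]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs,
                 unmatched_cells = setdiff(cell_ids, pairs$cell_id),
                 unmatched_nuclei = setdiff(nuc_ids, pairs$nucleus_id),
                 n_cells_pre = length(cell_ids),
                 n_nuclei_pre = length(nuc_ids)),
            class = "cell_nucleus_matching")
}

#' @export
print.cell_nucleus_matching <- function(x, ...) {
  cat(sprintf("cell_nucleus_matching: %d pair(s) of %d cells / %d nuclei; %d orphan cell(s), %d orphan nucleus(ei)\n",
              nrow(x$pairs), x$n_cells_pre, x$n_nuclei_pre,
              length(x$unmatched_cells), length(x$unmatched_nuclei)))
  invisible(x)
}

#' Construct a matched segmentation
#'
#' Internal constructor validating the one-to-one invariants: identical id
#' sets across the cell, nucleus and cell-excluding-nucleus (CEN) masks, and
#' per id nucleus contained in cell with CEN equal to cell minus nucleus.
#'
#' @param cell,nucleus,cell_excluding_nucleus Label masks sharing shape.
#' @param matching The pre-repair `cell_nucleus_matching` (match statistics).
#' @param pixel_size_um Pixel size in micrometres.
#' @param id_map Optional named vector mapping new ids to original cell ids.
#' @return An object of class `matched_segmentation`.
#' @export
matched_segmentation <- function(cell, nucleus, cell_excluding_nucleus,
                                 matching = NULL, pixel_size_um = 1,
                                 id_map = NULL) {
  cell <- as_label_mask(cell); nucleus <- as_label_mask(nucleus)
  cen <- as_label_mask(cell_excluding_nucleus)
  stopifnot(identical(dim(cell), dim(nucleus)), identical(dim(cell), dim(cen)))
  ids <- mask_ids(cell)
  if (!identical(ids, mask_ids(nucleus))) stop("cell and nucleus id sets differ")
  if (any(nucleus > 0L & cell != nucleus)) stop("nucleus pixels must lie inside their cell")
  if (any((cen != 0L) != (cell > 0L & nucleus == 0L)) ||
      any(cen[cen > 0L] != cell[cen > 0L])) stop("CEN must equal cell minus nucleus")
  structure(list(cell = cell, nucleus = nucleus, cell_excluding_nucleus = cen,
                 matching = matching, pixel_size_um = as.numeric(pixel_size_um),
                 id_map = id_map),
            class = "matched_segmentation")
}

#' @export
print.matched_segmentation <- function(x, ...) {
  d <- dim(x$cell)
  cat(sprintf("matched_segmentation: %d cell(s), %d x %d px, %.4g um/px\n",
              length(mask_ids(x$cell)), d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' Number of cells in a matched segmentation
#' @param seg A `matched_segmentation`.
#' @return Integer count.
#' @export
n_cells <- function(seg) length(mask_ids(seg$cell))

#' Enforce one-to-one cell/nucleus masks by strict removal or repair
#'
#' Misshaped nuclei protrude beyond their cell boundary (positive mismatch
#' fraction). Two policies are offered. `"strict"` treats every misshaped
#' nucleus and its cell as mismatched and removes both. `"repair"` trims each
#' paired nucleus to its cell's extent and keeps the pair (pairs whose
#' trimmed nucleus would be empty are dropped; this cannot occur for
#' overlap-based candidates but is guarded). In both modes all unmatched
#' cells and nuclei are erased, the cell-excluding-nucleus mask is derived,
#' and ids are relabelled 1..n consistently across the three masks.
#'
#' @param cell,nucleus Label masks the matching was computed from.
#' @param matching Result of [match_cells_to_nuclei()] on the same masks.
#' @param mode `"repair"` (default) or `"strict"`.
#' @param pixel_size_um Pixel size in micrometres, stored on the result.
#' @return A `matched_segmentation`. The mapping from new ids to original
#'   cell ids is in `$id_map`.
#' @export
apply_repair <- function(cell, nucleus, matching, mode = c("repair", "strict"),
                         pixel_size_um = 1) {
  mode <- match.arg(mode)
  cell <- as_label_mask(cell); nucleus <- as_label_mask(nucleus)
  if (!identical(dim(cell), dim(nucleus))) stop("cell and nucleus masks differ in shape")
  if (!inherits(matching, "cell_nucleus_matching")) stop("matching must come from match_cells_to_nuclei()")
  pairs <- matching$pairs
  if (mode == "strict" && nrow(pairs) > 0L) {
    pairs <- pairs[pairs$mismatch_fraction == 0, , drop = FALSE]
  }
  n <- nrow(pairs)
  new_cell <- matrix(0L, nrow(cell), ncol(cell))
  new_nuc <- matrix(0L, nrow(cell), ncol(cell))
  if (n > 0L) {
    # relabel by ascending original cell id
    pairs <- pairs[order(pairs$cell_id), , drop = FALSE]
    lut_c <- integer(max(cell)); lut_c[pairs$cell_id] <- seq_len(n)
    lut_n <- integer(max(nucleus)); lut_n[pairs$nucleus_id] <- seq_len(n)
    pc <- cell > 0L
    new_cell[pc] <- lut_c[cell[pc]]
    pn <- nucleus > 0L
    new_nuc[pn] <- lut_n[nucleus[pn]]
    # trim: nucleus pixels only survive inside the matching cell
    new_nuc[new_nuc != new_cell] <- 0L
    surv <- tabulate(new_nuc, nbins = n) > 0L
    if (!all(surv)) {  # defensive: trimmed-to-empty pairs are dropped
      drop_new <- which(!surv)
      new_cell[new_cell %in% drop_new] <- 0L
      new_nuc[new_nuc %in% drop_new] <- 0L
      pairs <- pairs[surv, , drop = FALSE]
      new_cell <- relabel_mask(new_cell)
      new_nuc <- relabel_mask(new_nuc)
      attr(new_cell, "id_map") <- NULL; attr(new_nuc, "id_map") <- NULL
      n <- nrow(pairs)
    }
  }
  cen <- new_cell
  cen[new_nuc > 0L] <- 0L
  matched_segmentation(new_cell, new_nuc, cen,
                       matching = matching, pixel_size_um = pixel_size_um,
                       id_map = stats::setNames(pairs$cell_id, seq_len(n)))
}

#' Derive the cell-excluding-nucleus mask
#'
#' Removes every nucleus pixel from the cell mask, per id. Ids whose nucleus
#' fills the whole cell have an empty CEN region; they are retained in the
#' segmentation (removing them would silently change the cell count) and
#' their ids are reported in `attr(, "empty_cen_ids")`.
#'
#' @param seg A `matched_segmentation`.
#' @return The CEN label mask.
#' @export
derive_cell_excluding_nucleus <- function(seg) {
  stopifnot(inherits(seg, "matched_segmentation"))
  cen <- seg$cell
  cen[seg$nucleus > 0L] <- 0L
  ids <- mask_ids(seg$cell)
  empty <- setdiff(ids, mask_ids(cen))
  if (length(empty) > 0L) {
    message(sprintf("%d cell(s) fully occupied by their nucleus (empty CEN): ids %s",
                    length(empty), paste(utils::head(empty, 10), collapse = ", ")))
  }
  attr(cen, "empty_cen_ids") <- empty
  cen
}
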