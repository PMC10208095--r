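#' Jaccard index of two pixel sets
#'
#' @param a,b Logical matrices (or coercible) on the same grid.
#' @return `|a & b| / |a | b|`.
#' @export
jaccard_index <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (!identical(dim(a), dim(b))) stop("pixel sets are on different grids")
  u <- sum(a | b)
  if (u == 0L) stop("both pixel sets are empty: Jaccard index undefined")
  sum(a & b) / u
}

# All overlapping (ref, query) object pairs with their Jaccard indices,
# plus the object counts. Shared by every benchmark.
ji_pairs <- function(ref, query) {
  ref <- as_label_mask(ref); query <- as_label_mask(query)
  if (!identical(dim(ref), dim(query))) stop("masks differ in shape")
  ov <- overlap_pairs(ref, query)
  ref_area <- mask_areas(ref); q_area <- mask_areas(query)
  ji <- if (nrow(ov) > 0L) {
    ov$overlap / (ref_area[as.character(ov$a_id)] +
                  q_area[as.character(ov$b_id)] - ov$overlap)
  } else numeric(0)
  list(pairs = data.frame(ref_id = ov$a_id, query_id = ov$b_id,
                          overlap = ov$overlap, ji = as.numeric(ji)),
       n_ref = length(ref_area), n_query = length(q_area),
       ref_area = ref_area)
}

# Greedy one-to-one assignment of pairs with ji > threshold, by descending
# JI; deterministic tie-break by (ref_id, query_id).
greedy_match <- function(pairs, n_ref, n_query, threshold) {
  cand <- pairs[pairs$ji > threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(matched = cand, tp = 0L, fp = n_query, fn = n_ref))
  }
  cand <- cand[order(-cand$ji, cand$ref_id, cand$query_id), ]
  used_r <- integer(0); used_q <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$ref_id[i] %in% used_r) && !(cand$query_id[i] %in% used_q)) {
      keep[i] <- TRUE
      used_r <- c(used_r, cand$ref_id[i]); used_q <- c(used_q, cand$query_id[i])
    }
  }
  m <- cand[keep, , drop = FALSE]
  rownames(m) <- NULL
  list(matched = m, tp = nrow(m), fp = n_query - nrow(m), fn = n_ref - nrow(m))
}

#' Match objects of two label masks by Jaccard index
#'
#' Candidate pairs are overlapping objects with JI strictly above the
#' threshold; they are assigned one-to-one greedily by descending JI.
#' Unassigned query objects are false positives, unassigned reference
#' objects false negatives.
#'
#' @param ref,query Label masks of identical shape.
#' @param threshold JI threshold (default 0.3, the conventional value for
#'   cell matching).
#' @return List of class `match_table`: `matched` (data.frame `ref_id`,
#'   `query_id`, `overlap`, `ji`), and counts `tp`, `fp`, `fn`.
#' @export
match_by_ji <- function(ref, query, threshold = 0.3) {
  jp <- ji_pairs(ref, query)
  res <- greedy_match(jp$pairs, jp$n_ref, jp$n_query, threshold)
  structure(res, class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("match_table: TP = %d, FP = %d, FN = %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

f1_from_counts <- function(tp, fp, fn) {
  if (tp == 0L) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' F1 score between two segmentations at a Jaccard threshold
#'
#' Symmetric in its arguments: swapping reference and query swaps FP and FN,
#' which leaves F1 unchanged.
#'
#' @inheritParams match_by_ji
#' @return F1 in \[0, 1\]; 0 when no objects match.
#' @export
f1_score <- function(ref, query, threshold = 0.3) {
  jp <- ji_pairs(ref, query)
  if (jp$n_ref + jp$n_query == 0L) stop("both masks are empty")
  m <- greedy_match(jp$pairs, jp$n_ref, jp$n_query, threshold)
  f1_from_counts(m$tp, m$fp, m$fn)
}

#' Threshold-averaged F1 score
#'
#' Removes the arbitrariness of a single JI threshold by averaging the F1
#' score over thresholds 0.00, 0.01, ..., 1.00 (101 values), each with the
#' strict `JI > t` matching rule (so identical masks score 100/101: the
#' t = 1 threshold admits no match).
#'
#' @inheritParams match_by_ji
#' @return Mean F1 over the 101 thresholds.
#' @export
avg_f1_score <- function(ref, query) {
  jp <- ji_pairs(ref, query)
  if (jp$n_ref + jp$n_query == 0L) stop("both masks are empty")
  thresholds <- seq(0, 1, by = 0.01)
  mean(vapply(thresholds, function(t) {
    m <- greedy_match(jp$pairs, jp$n_ref, jp$n_query, t)
    f1_from_counts(m$tp, m$fp, m$fn)
  }, numeric(1)))
}

#' Directional SEG score
#'
#' For every reference object R, a query object S is its match when the
#' overlap exceeds half of R's area (`|R & S| > 0.5 |R|`; at most one S can
#' satisfy this for disjoint label masks, but the largest overlap is kept
#' defensively). Matched objects contribute their Jaccard index, unmatched
#' ones contribute 0; the score is the mean over reference objects.
#'
#' @param ref,query Label masks of identical shape; `ref` non-empty.
#' @return Mean JI over reference objects.
#' @export
seg_score_directional <- function(ref, query) {
  jp <- ji_pairs(ref, query)
  if (jp$n_ref == 0L) stop("reference mask is empty")
  contrib <- stats::setNames(rep(0, jp$n_ref), names(jp$ref_area))
  p <- jp$pairs
  if (nrow(p) > 0L) {
    p <- p[p$overlap > 0.5 * jp$ref_area[as.character(p$ref_id)], , drop = FALSE]
    if (nrow(p) > 0L) {
      p <- p[order(-p$overlap), ]
      p <- p[!duplicated(p$ref_id), ]
      contrib[as.character(p$ref_id)] <- p$ji
    }
  }
  mean(contrib)
}

#' Symmetrised SEG score (SEG′)
#'
#' The directional SEG score ignores extra unmatched query objects; SEG′
#' fixes this by averaging the two directional scores, once with each mask
#' as reference.
#'
#' @param a,b Non-empty label masks of identical shape.
#' @return SEG′ in \[0, 1\], symmetric in `a` and `b`.
#' @export
seg_prime <- function(a, b) {
  (seg_score_directional(a, b) + seg_score_directional(b, a)) / 2
}

#' All symmetric benchmarks of a mask pair
#'
#' @inheritParams match_by_ji
#' @return Named list `f1`, `avg_f1`, `seg_prime`, `tp`, `fp`, `fn` (counts
#'   at the given threshold).
#' @export
benchmark_masks <- function(ref, query, threshold = 0.3) {
  m <- match_by_ji(ref, query, threshold)
  list(f1 = f1_from_counts(m$tp, m$fp, m$fn),
       avg_f1 = avg_f1_score(ref, query),
       seg_prime = seg_prime(ref, query),
       tp = m$tp, fp = m$fp, fn = m$fn)
}
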