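# Independent brute-force oracles. These deliberately use plain pixel loops
# and enumeration, never the package's vectorised internals.

# All (cell, nucleus) overlap pairs with mismatch fractions, by scanning
# every pixel.
oracle_overlaps <- function(cell, nucleus) {
  acc <- list()
  for (r in seq_len(nrow(cell))) for (c in seq_len(ncol(cell))) {
    ci <- cell[r, c]; ni <- nucleus[r, c]
    if (ci > 0 && ni > 0) {
      key <- paste(ci, ni)
      acc[[key]] <- (acc[[key]] %||% 0) + 1
    }
  }
  if (length(acc) == 0) {
    return(data.frame(cell_id = integer(0), nucleus_id = integer(0),
                      overlap = integer(0), mismatch_fraction = numeric(0)))
  }
  ids <- do.call(rbind, strsplit(names(acc), " "))
  nuc_sizes <- table(nucleus[nucleus > 0])
  out <- data.frame(cell_id = as.integer(ids[, 1]),
                    nucleus_id = as.integer(ids[, 2]),
                    overlap = as.integer(unlist(acc)))
  out$mismatch_fraction <- 1 - out$overlap / as.integer(nuc_sizes[as.character(out$nucleus_id)])
  out[order(out$cell_id, out$nucleus_id), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Maximum achievable number of one-to-one matches among candidate pairs,
# by exhaustive recursion (masks kept small).
oracle_max_matching <- function(pairs) {
  if (nrow(pairs) == 0) return(0L)
  best <- 0L
  recurse <- function(i, used_r, used_q, count) {
    if (count + (nrow(pairs) - i + 1) <= best) return()
    if (i > nrow(pairs)) { best <<- max(best, count); return() }
    r <- pairs$ref_id[i]; q <- pairs$query_id[i]
    if (!(r %in% used_r) && !(q %in% used_q)) {
      recurse(i + 1, c(used_r, r), c(used_q, q), count + 1L)
    }
    recurse(i + 1, used_r, used_q, count)
  }
  recurse(1L, integer(0), integer(0), 0L)
  best
}

# Per-threshold F1 computed independently from a fresh match at each t.
oracle_avg_f1 <- function(ref, query) {
  ts <- seq(0, 1, by = 0.01)
  vals <- numeric(length(ts))
  for (i in seq_along(ts)) {
    m <- match_by_ji(ref, query, threshold = ts[i])
    vals[i] <- if (m$tp == 0) 0 else {
      p <- m$tp / (m$tp + m$fp); r <- m$tp / (m$tp + m$fn)
      2 * p * r / (p + r)
    }
  }
  mean(vals)
}

# Nearest-centroid assignment by scanning each pixel against each centroid.
oracle_nearest_centroid <- function(h, w, centroids_rc, ids) {
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    d <- (centroids_rc[, 1] - r)^2 + (centroids_rc[, 2] - c)^2
    out[r, c] <- ids[which.min(d)]
  }
  out
}

# Per-cell per-channel mean intensities by pixel accumulation.
oracle_cell_features <- function(image, mask) {
  ids <- sort(unique(mask[mask > 0]))
  chs <- names(image$planes)
  out <- matrix(0, length(ids), length(chs), dimnames = list(ids, chs))
  for (k in seq_along(ids)) {
    sel <- mask == ids[k]
    for (j in seq_along(chs)) out[k, j] <- mean(image$planes[[j]][sel])
  }
  out
}
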