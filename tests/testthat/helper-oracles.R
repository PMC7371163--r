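# Independent brute-force oracles. Deliberately naive implementations kept
# separate from the package code paths they check.

# Minimum-image distance as the explicit minimum over the 27 translated
# images of b in an orthorhombic box.
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    bb <- b + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((a - bb)^2)))
  }
  best
}

# O(N^2) contact detection between coordinate sets A and B (strict <).
oracle_all_pairs <- function(A, B, box, threshold, use_pbc = TRUE) {
  out <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- if (use_pbc) {
        oracle_min_image(A[i, ], B[j, ], box)
      } else {
        sqrt(sum((A[i, ] - B[j, ])^2))
      }
      if (d < threshold) out[[length(out) + 1]] <- c(i, j, d)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), d = m[, 3])
}

# Connected components by breadth-first search over an undirected edge list.
# Returns a named membership vector over `nodes`.
oracle_bfs_components <- function(nodes, from, to) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  memb <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  comp <- 0L
  for (n in nodes) {
    if (!is.na(memb[[n]])) next
    comp <- comp + 1L
    queue <- n
    memb[[n]] <- comp
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(memb[[w]])) {
          memb[[w]] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  memb
}

# Canonical string form of a contact pair set, for set equality tests.
pair_key <- function(df) {
  sort(paste(df$protein_atom, df$lipid_atom, df$frame, sep = "/"))
}
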