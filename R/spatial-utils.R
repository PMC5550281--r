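# Exact spatial primitives: single-linkage components at a radius via
# grid-bucketed union-find, and chunked brute-force nearest-neighbour
# queries. Both are exact (closed-ball comparisons, ties count as
# within), so they match all-pairs oracles bit for bit.

# connected components of the graph joining points at distance <= radius
radius_components <- function(xyz, radius) {
  n <- nrow(xyz)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  cell <- floor(xyz / radius)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  cell_of <- do.call(rbind, strsplit(names(buckets), ",", fixed = TRUE))
  cell_of <- matrix(as.numeric(cell_of), ncol = 3)
  keymap <- seq_along(buckets)
  names(keymap) <- names(buckets)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  r2 <- radius^2
  for (b in seq_along(buckets)) {
    idx_b <- buckets[[b]]
    # within-bucket pairs
    if (length(idx_b) > 1L) {
      d2 <- as.matrix(stats::dist(xyz[idx_b, , drop = FALSE]))^2
      hit <- which(d2 <= r2 & upper.tri(d2), arr.ind = TRUE)
      for (h in seq_len(nrow(hit)))
        union_(idx_b[hit[h, 1]], idx_b[hit[h, 2]])
    }
    # pairs with lexicographically-later neighbour buckets
    for (o in seq_len(nrow(offs))) {
      if (all(offs[o, ] == 0)) next
      nb_key <- paste(cell_of[b, 1] + offs[o, 1],
                      cell_of[b, 2] + offs[o, 2],
                      cell_of[b, 3] + offs[o, 3], sep = ",")
      nb <- keymap[nb_key]
      if (is.na(nb) || nb <= b) next
      idx_n <- buckets[[nb]]
      a <- xyz[idx_b, , drop = FALSE]
      c_ <- xyz[idx_n, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(c_^2), "+") - 2 * tcrossprod(a, c_)
      hit <- which(d2 <= r2, arr.ind = TRUE)
      for (h in seq_len(nrow(hit)))
        union_(idx_b[hit[h, 1]], idx_n[hit[h, 2]])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# for each query row, index and distance of the nearest reference row;
# exact, chunked to bound memory
nn_nearest <- function(query, ref, chunk = 512L) {
  nq <- nrow(query)
  if (nq == 0L)
    return(list(index = integer(0), dist = numeric(0)))
  if (is.null(ref) || nrow(ref) == 0L)
    return(list(index = rep.int(NA_integer_, nq),
                dist = rep.int(Inf, nq)))
  ref2 <- rowSums(ref^2)
  idx <- integer(nq); dd <- numeric(nq)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dd[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), j)], 0))
  }
  list(index = idx, dist = dd)
}

# for each query row, the number of reference rows strictly closer than
# the paired threshold distance; a small squared-distance epsilon guards
# against BLAS rounding so points exactly at the threshold (e.g. the
# nearest reference itself) never count as strictly closer
nn_count_within <- function(query, ref, thresholds, strict = TRUE,
                            chunk = 512L) {
  nq <- nrow(query)
  if (nq == 0L) return(integer(0))
  if (is.null(ref) || nrow(ref) == 0L) return(rep.int(0L, nq))
  ref2 <- rowSums(ref^2)
  out <- integer(nq)
  eps <- 1e-6
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, ref)
    d2 <- pmax(d2, 0)
    th2 <- thresholds[s:e]^2
    cmp <- if (strict) sweep(d2, 1, th2 - eps, "<") else
      sweep(d2, 1, th2 + eps, "<=")
    out[s:e] <- rowSums(cmp)
  }
  out
}

site_xyz <- function(sites) {
  as.matrix(sites[, c("x", "y", "z"), drop = FALSE])
}
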