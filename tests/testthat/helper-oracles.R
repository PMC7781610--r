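# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: explicit loops,
# permutation tests, dense rank computations.

rand_digraph <- function(n, p = 0.3, seed = 1, weighted = TRUE) {
  set.seed(seed)
  w <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  if (weighted) w <- w * matrix(stats::runif(n * n, 0.05, 1), n, n)
  diag(w) <- 0
  connectome_graph(w)
}

# --- reciprocity: direct double sum ---------------------------------------
oracle_reciprocity <- function(w) {
  n <- nrow(w)
  vals <- c()
  for (i in 1:n) for (j in 1:n) if (i != j) vals <- c(vals, w[i, j])
  wbar <- mean(vals)
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) {
    num <- num + (w[i, j] - wbar) * (w[j, i] - wbar)
    den <- den + (w[i, j] - wbar)^2
  }
  num / den
}

# --- assortativity: explicit edge-list correlation ------------------------
oracle_assortativity <- function(w, mode = "strength") {
  n <- nrow(w)
  if (mode == "strength") {
    outv <- sapply(1:n, function(i) sum(w[i, ]))
    inv <- sapply(1:n, function(j) sum(w[, j]))
  } else {
    outv <- sapply(1:n, function(i) sum(w[i, ] > 0))
    inv <- sapply(1:n, function(j) sum(w[, j] > 0))
  }
  xs <- c(); ys <- c()
  for (i in 1:n) for (j in 1:n) if (w[i, j] > 0) {
    xs <- c(xs, outv[i]); ys <- c(ys, inv[j])
  }
  stats::cor(xs, ys)
}

# --- Fagiolo clustering: explicit sum over ordered triples ----------------
oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1/3)
  s <- wh + t(wh)
  a <- (w > 0) + 0
  out <- numeric(n)
  for (i in 1:n) {
    tri <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h) tri <- tri + s[i, j] * s[j, h] * s[h, i]
    }
    dtot <- sum(a[i, ]) + sum(a[, i])
    dbi <- sum(a[i, ] * a[, i])
    den <- dtot * (dtot - 1) - 2 * dbi
    out[i] <- if (den > 0) tri / (2 * den) else NA_real_
  }
  out
}

# --- rich club: filter-and-count ------------------------------------------
oracle_phi <- function(w, k, keep_geq = FALSE) {
  a <- w > 0
  deg <- sapply(seq_len(nrow(w)), function(i) sum(a[i, ]) + sum(a[, i]))
  keep <- if (keep_geq) which(deg >= k) else which(deg > k)
  if (length(keep) < 2) return(NA_real_)
  cnt <- 0
  for (i in keep) for (j in keep) if (i != j && a[i, j]) cnt <- cnt + 1
  cnt / (length(keep) * (length(keep) - 1))
}

# --- motifs: classification by trying all 6 vertex permutations -----------
# Reference 3-node motif adjacencies, frozen in the canonical (BCT) order:
# 1 divergence, 2 chain, 3 reciprocal pair + out-edge, 4 convergence,
# 5 feedforward triangle, 6 reciprocal pair receiving from both,
# 7 reciprocal pair + in-edge, 8 directed cycle, 9 reciprocal two-chain,
# 10 reciprocal pair on a cycle, 11 reciprocal pair sending to both,
# 12 reciprocal pair + reciprocal pair + edge, 13 fully reciprocal.
reference_motifs3 <- function() {
  e <- function(...) {
    m <- matrix(0, 3, 3)
    for (p in list(...)) m[p[1], p[2]] <- 1
    m
  }
  list(
    e(c(1, 2), c(1, 3)),                                  # M1  divergence
    e(c(1, 2), c(2, 3)),                                  # M2  chain
    e(c(1, 2), c(2, 1), c(1, 3)),                         # M3  recip + out
    e(c(2, 1), c(3, 1)),                                  # M4  convergence
    e(c(1, 2), c(1, 3), c(2, 3)),                         # M5  feedforward
    e(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),                # M6  recip -> both
    e(c(1, 2), c(2, 1), c(3, 1)),                         # M7  recip + in
    e(c(1, 2), c(2, 3), c(3, 1)),                         # M8  cycle
    e(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),                # M9  recip chain
    e(c(1, 2), c(2, 1), c(3, 1), c(2, 3)),                # M10 recip on cycle
    e(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),                # M11 both -> recip
    e(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3)),       # M12
    e(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1)) # M13 complete
  )
}

perms3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))

oracle_motif_class <- function(a, refs = reference_motifs3()) {
  for (cl in seq_along(refs)) {
    ref <- refs[[cl]]
    for (r in seq_len(nrow(perms3))) {
      p <- perms3[r, ]
      if (all(a[p, p] == ref)) return(cl)
    }
  }
  0L
}

oracle_motif_census <- function(w) {
  a <- (w > 0) + 0
  n <- nrow(a)
  refs <- reference_motifs3()
  counts <- integer(13)
  connected3 <- function(sub) {
    u <- (sub + t(sub)) > 0
    all(colSums(u) + rowSums(u) > 0) # n = 3: no isolated node <=> connected
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    sub <- a[c(i, j, k), c(i, j, k)]
    if (!connected3(sub)) next
    cl <- oracle_motif_class(sub, refs)
    counts[cl] <- counts[cl] + 1L
  }
  counts
}

# count weakly connected triples only (connectivity-only counter)
oracle_connected_triples <- function(w) {
  a <- (w > 0) + 0
  n <- nrow(a)
  cnt <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    sub <- a[c(i, j, k), c(i, j, k)]
    u <- (sub + t(sub)) > 0
    if (all(colSums(u) + rowSums(u) > 0)) cnt <- cnt + 1
  }
  cnt
}

# --- homology oracles -----------------------------------------------------
# GF(2) rank by Gaussian elimination on a dense 0/1 matrix.
gf2_rank <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0) return(0L)
  m <- m %% 2
  r <- 0L
  for (col in seq_len(ncol(m))) {
    piv <- which(m[, col] == 1)
    piv <- piv[piv > r]
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1] != r) m[c(r, piv[1]), ] <- m[c(piv[1], r), ]
    for (row in which(m[, col] == 1)) {
      if (row != r) m[row, ] <- (m[row, ] + m[r, ]) %% 2
    }
  }
  r
}

# Betti numbers of the sub-complex of a filtration up to filtration rank t,
# via dense boundary matrices and GF(2) ranks (independent of the package's
# column-reduction code).
oracle_betti_at <- function(f, t, max_hdim = 2) {
  keep <- which(f$simplices$rank <= t)
  dims <- f$simplices$dim[keep]
  counts <- sapply(0:(max_hdim + 1), function(d) sum(dims == d))
  ranks <- numeric(max_hdim + 2)
  for (d in 1:(max_hdim + 1)) {
    cols <- keep[dims == d]
    rows <- keep[dims == d - 1]
    if (!length(cols) || !length(rows)) { ranks[d + 1] <- 0; next }
    B <- matrix(0L, length(rows), length(cols))
    for (cj in seq_along(cols)) {
      fc <- f$faces[[cols[cj]]]
      B[match(fc, rows), cj] <- 1L
    }
    ranks[d + 1] <- gf2_rank(B)
  }
  sapply(0:max_hdim, function(d) counts[d + 1] - ranks[d + 1] - ranks[d + 2])
}

# Component count of the graph restricted to edges with rank <= t (union-find).
oracle_components_at <- function(f, t) {
  n <- sum(f$simplices$dim == 0)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in which(f$simplices$dim == 1 & f$simplices$rank <= t)) {
    v <- f$vertices[[i]]
    a <- find(v[1]); b <- find(v[2])
    if (a != b) parent[a] <- b
  }
  length(unique(sapply(seq_len(n), find)))
}

# Interval-based Betti curve from a persistence diagram at rank t.
betti_from_bars <- function(diagram, d, t) {
  sum(diagram$dimension == d & diagram$birth <= t & diagram$death > t)
}
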