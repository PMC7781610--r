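# Three-node motif census. Motif classes are derived at run time by
# exhaustive enumeration of labeled digraphs collapsed under vertex
# permutations (no lookup table). Class IDs 1..13 follow the Brain
# Connectivity Toolbox convention: classes are ordered lexicographically by
# their canonical degree label (the (out, in) degree pairs of the three
# nodes sorted by out- then in-degree), which puts the reciprocal two-chain
# at class 9 and the fully reciprocal triangle at class 13.

# Off-diagonal positions of an n x n matrix in column-major order; a labeled
# digraph on n nodes is encoded as the bit vector of these positions.
offdiag_positions <- function(n) {
  idx <- which(row(diag(n)) != col(diag(n)))
  cbind(row = ((idx - 1) %% n) + 1, col = ((idx - 1) %/% n) + 1)
}

code_to_adj <- function(code, n, pos = offdiag_positions(n)) {
  nb <- nrow(pos)
  a <- matrix(0L, n, n)
  a[pos] <- as.integer(bitwAnd(code, 2^(seq_len(nb) - 1)) > 0)
  a
}

adj_to_code <- function(a, pos = offdiag_positions(nrow(a))) {
  sum(a[pos] * 2^(seq_len(nrow(pos)) - 1))
}

is_weakly_connected <- function(a) {
  n <- nrow(a)
  u <- (a + t(a)) > 0
  reach <- rep(FALSE, n)
  reach[1] <- TRUE
  repeat {
    nxt <- reach | (colSums(u[reach, , drop = FALSE]) > 0)
    if (all(nxt == reach)) break
    reach <- nxt
  }
  all(reach)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Enumerate all weakly connected labeled digraphs on n nodes and collapse
# them into isomorphism classes (canonical code = minimum code over all
# vertex permutations). Returns, per class: the canonical code, one
# representative adjacency, the sorted degree label, and a vector mapping
# every labeled code to its class id (0 = not weakly connected).
enumerate_motif_classes <- function(n) {
  pos <- offdiag_positions(n)
  nb <- nrow(pos)
  perms <- all_permutations(n)
  codes <- 0:(2^nb - 1)
  bits <- matrix(0L, length(codes), nb)
  for (b in seq_len(nb)) bits[, b] <- as.integer(bitwAnd(codes, 2^(b - 1)) > 0)
  # bit position of each off-diagonal entry after relabeling by a permutation
  perm_maps <- apply(perms, 1, function(p) {
    newpos <- cbind(p[pos[, 1]], p[pos[, 2]])
    match(paste(newpos[, 1], newpos[, 2]),
          paste(pos[, 1], pos[, 2]))
  })  # nb x nperm
  canon <- rep(Inf, length(codes))
  pw <- 2^(seq_len(nb) - 1)
  for (k in seq_len(ncol(perm_maps))) {
    permuted <- as.vector(bits[, order(perm_maps[, k]), drop = FALSE] %*% pw)
    canon <- pmin(canon, permuted)
  }
  connected <- vapply(codes, function(cd)
    is_weakly_connected(code_to_adj(cd, n, pos)), logical(1))
  conn_canon <- unique(canon[connected])
  # BCT ordering: lexicographic sorted (k_out, k_in) degree-pair labels
  degree_label <- function(cd) {
    a <- code_to_adj(cd, n, pos)
    u <- cbind(rowSums(a), colSums(a))
    u <- u[order(u[, 1], u[, 2]), , drop = FALSE]
    as.vector(t(u))
  }
  labs <- t(vapply(conn_canon, degree_label, numeric(2 * n)))
  ord <- do.call(order, as.data.frame(labs))
  conn_canon <- conn_canon[ord]
  labs <- labs[ord, , drop = FALSE]
  class_of_code <- integer(length(codes))
  class_of_code[connected] <- match(canon[connected], conn_canon)
  list(n_classes = length(conn_canon),
       canonical_codes = conn_canon,
       representatives = lapply(conn_canon, code_to_adj, n = n, pos = pos),
       degree_labels = labs,
       class_of_code = class_of_code)
}

motif_cache <- new.env(parent = emptyenv())

motif_classes <- function(n) {
  key <- as.character(n)
  if (is.null(motif_cache[[key]])) motif_cache[[key]] <- enumerate_motif_classes(n)
  motif_cache[[key]]
}

#' Number of connected directed motif classes
#'
#' Counts isomorphism classes of weakly connected simple digraphs on n
#' unlabeled nodes by exhaustive enumeration of all labeled digraphs with
#' canonical labeling under vertex permutations: 2 classes for n = 2,
#' 13 for n = 3, 199 for n = 4.
#'
#' @param n motif size (2, 3 or 4).
#' @return integer class count.
#' @export
motif_class_count <- function(n) {
  if (!n %in% 2:4) stop("motif size must be 2, 3 or 4")
  motif_classes(n)$n_classes
}

#' Three-node motif census
#'
#' Counts, for every unordered node triple whose induced (binarized)
#' subgraph is weakly connected, the motif class of that induced subgraph,
#' in the canonical 13-class ordering (see package docs; class 9 is the
#' reciprocal two-chain, class 13 the fully reciprocal triangle).
#' Induced-subgraph counting: each connected triple contributes to exactly
#' one class.
#'
#' @param g a [connectome_graph()] (weights > 0 are binarized).
#' @return a `motif_spectrum`: list with `class_count` (13 integers),
#'   `n_connected_triples`.
#' @export
motif3_census <- function(g) {
  w <- if (inherits(g, "connectome_graph")) g$weights else as.matrix(g)
  n <- nrow(w)
  if (n < 3) stop("need at least 3 nodes")
  a <- (w > 0) + 0L
  mc <- motif_classes(3)
  triples <- utils::combn(n, 3)
  i <- triples[1, ]; j <- triples[2, ]; k <- triples[3, ]
  # bits in column-major off-diagonal order for nodes (1,2,3) = (i,j,k):
  # positions (2,1),(3,1),(1,2),(3,2),(1,3),(2,3)
  code <- a[cbind(j, i)] * 1L + a[cbind(k, i)] * 2L + a[cbind(i, j)] * 4L +
    a[cbind(k, j)] * 8L + a[cbind(i, k)] * 16L + a[cbind(j, k)] * 32L
  cls <- mc$class_of_code[code + 1L]
  counts <- tabulate(cls[cls > 0], nbins = mc$n_classes)
  structure(list(class_count = counts,
                 n_connected_triples = sum(cls > 0)),
            class = "motif_spectrum")
}

#' @export
print.motif_spectrum <- function(x, ...) {
  cat("<motif_spectrum>", x$n_connected_triples, "connected triples\n")
  print(stats::setNames(x$class_count, paste0("M", seq_along(x$class_count))))
  if (!is.null(x$p_two_tailed)) {
    cat("direction:", paste(x$direction, collapse = " "), "\n")
  }
  invisible(x)
}

#' Motif significance spectrum against rewired nulls
#'
#' Runs the census on the graph and on every ensemble member; per class, a
#' two-tailed empirical p-value indexes how unexpectedly frequent or
#' infrequent the motif is, and the direction is `enriched`/`depleted` by
#' the sign of (observed - null median), `ns` where p > alpha.
#'
#' @param g a [connectome_graph()].
#' @param ensemble a [build_ensemble()] result from `g` (100 members in the
#'   reference analysis).
#' @param alpha significance level (default 0.05).
#' @return a `motif_spectrum` with `class_count`, `null_counts`
#'   (members x 13), `p_two_tailed`, `direction`.
#' @export
motif_significance <- function(g, ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$n_nodes != n_nodes(g)) stop("ensemble/graph size mismatch")
  obs <- motif3_census(g)
  nulls <- t(vapply(ensemble$members,
                    function(x) motif3_census(x)$class_count,
                    numeric(length(obs$class_count))))
  p <- vapply(seq_along(obs$class_count), function(i)
    empirical_pvalue(obs$class_count[i], nulls[, i], tail = "two"),
    numeric(1))
  med <- apply(nulls, 2, stats::median)
  dir <- ifelse(p > alpha, "ns",
                ifelse(obs$class_count >= med, "enriched", "depleted"))
  structure(list(class_count = obs$class_count,
                 n_connected_triples = obs$n_connected_triples,
                 null_counts = nulls, p_two_tailed = p, direction = dir,
                 alpha = alpha),
            class = "motif_spectrum")
}
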