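# Persistent homology of the weighted network: the directed graph is
# symmetrized, edges are added one at a time in order of decreasing weight,
# and the clique (flag) complex grows with them. Homology over GF(2) in
# dimensions 0-2 (simplices up to tetrahedra) is computed by standard
# boundary-matrix column reduction, with representative cycles taken from
# the reduced column at pairing time.

#' Build a clique-complex edge filtration
#'
#' Symmetrizes the graph, sorts undirected edges by strictly decreasing
#' weight (ties broken by lexicographic endpoint order so runs are
#' reproducible), and lets each (k+1)-clique enter the complex when its last
#' edge does. The filtration value of a simplex is the rank of its latest
#' edge (1-based; vertices have rank 0); the metric value
#' `-ln(w / w_max)` of that edge is carried alongside.
#'
#' @param g a [connectome_graph()].
#' @param symmetrize_rule `"max"` (default) or `"mean"`.
#' @param max_dim maximal simplex dimension (<= 3; 3 is needed for H2).
#' @return a `filtration`: list with `simplices` (data.frame: dim, rank,
#'   value), `vertices` (list of vertex index sets), `faces` (list of face
#'   row indices), `n_edges`, `labels`.
#' @export
build_filtration <- function(g, symmetrize_rule = c("max", "mean"),
                             max_dim = 3) {
  symmetrize_rule <- match.arg(symmetrize_rule)
  if (max_dim > 3) stop("max_dim must be <= 3")
  if (max_dim < 1) stop("max_dim must be >= 1")
  s <- symmetrize(g, symmetrize_rule)$weights
  n <- nrow(s)
  ut <- which(upper.tri(s) & s > 0, arr.ind = TRUE)
  w <- s[ut]
  ord <- order(-w, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  w <- w[ord]
  m <- length(w)
  if (m == 0) stop("graph has no edges")
  erank <- matrix(NA_integer_, n, n)
  erank[ut] <- seq_len(m)
  erank[ut[, c(2, 1), drop = FALSE]] <- seq_len(m)
  metric <- -log(w / max(w))
  adj <- !is.na(erank)
  verts <- c(lapply(seq_len(n), identity), # vertices
             lapply(seq_len(m), function(e) sort(c(ut[e, 1], ut[e, 2]))))
  dims <- c(rep(0L, n), rep(1L, m))
  ranks <- c(rep(0L, n), seq_len(m))
  if (max_dim >= 2) {
    tri <- list()
    for (i in seq_len(n - 2)) {
      nb <- which(adj[i, ] & seq_len(n) > i)
      if (length(nb) < 2) next
      for (jx in seq_along(nb)[-length(nb)]) {
        j <- nb[jx]
        ks <- nb[adj[j, nb] & nb > j]
        for (k in ks) tri[[length(tri) + 1]] <- c(i, j, k)
      }
    }
    if (length(tri)) {
      tr <- vapply(tri, function(v)
        max(erank[v[1], v[2]], erank[v[1], v[3]], erank[v[2], v[3]]),
        integer(1))
      verts <- c(verts, tri)
      dims <- c(dims, rep(2L, length(tri)))
      ranks <- c(ranks, tr)
    }
    if (max_dim >= 3 && length(tri)) {
      tets <- list()
      trimat <- do.call(rbind, tri)
      for (t_ in seq_along(tri)) {
        v <- tri[[t_]]
        cand <- which(adj[v[1], ] & adj[v[2], ] & adj[v[3], ] &
                        seq_len(n) > v[3])
        for (l in cand) tets[[length(tets) + 1]] <- c(v, l)
      }
      if (length(tets)) {
        tetr <- vapply(tets, function(v) {
          pr <- utils::combn(v, 2)
          max(erank[cbind(pr[1, ], pr[2, ])])
        }, integer(1))
        verts <- c(verts, tets)
        dims <- c(dims, rep(3L, length(tets)))
        ranks <- c(ranks, tetr)
      }
    }
  }
  # sort by (rank, dim, vertex tuple) -- faces always precede cofaces
  key <- vapply(verts, function(v) paste(sprintf("%06d", v), collapse = ","),
                character(1))
  ord2 <- order(ranks, dims, key)
  verts <- verts[ord2]
  dims <- dims[ord2]
  ranks <- ranks[ord2]
  values <- numeric(length(ranks))
  values[ranks > 0] <- metric[ranks[ranks > 0]]
  # face indices
  index_of <- new.env(parent = emptyenv(), size = length(verts))
  for (i in seq_along(verts)) {
    assign(paste(verts[[i]], collapse = ","), i, envir = index_of)
  }
  faces <- lapply(seq_along(verts), function(i) {
    v <- verts[[i]]
    if (length(v) == 1) return(integer(0))
    vapply(seq_along(v), function(drop)
      get(paste(v[-drop], collapse = ","), envir = index_of), integer(1))
  })
  structure(list(simplices = data.frame(dim = dims, rank = ranks,
                                        value = values),
                 vertices = verts, faces = faces, n_edges = m,
                 labels = g$labels),
            class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  tb <- table(factor(x$simplices$dim, levels = 0:3))
  cat(sprintf("<filtration> %d simplices (%s vertices, %s edges, %s triangles, %s tetrahedra)\n",
              nrow(x$simplices), tb[1], tb[2], tb[3], tb[4]))
  invisible(x)
}

# Symmetric difference of two sorted integer vectors (GF(2) addition).
xor_chain <- function(x, y) {
  z <- c(x, y)
  z <- sort(z)
  dup <- z[duplicated(z)]
  z[!(z %in% dup)]
}

#' Persistent homology by boundary-matrix reduction
#'
#' Standard column reduction over the two-element field in increasing
#' filtration order. Finite bars pair a creator simplex (birth) with a
#' destroyer (death); unpaired creators give infinite bars. The
#' representative cycle of a finite bar is the support of the reduced
#' boundary column at pairing time (the cycle that dies); for infinite bars
#' it is the reduced chain of the creator.
#'
#' @param f a [build_filtration()] result.
#' @return a `persistence_diagram`: data.frame with columns `dimension`,
#'   `birth`, `death` (rank scale, `Inf` allowed), `birth_value`,
#'   `death_value` (metric scale), `lifetime` (rank scale), plus attribute
#'   `representatives` (list of simplex vertex lists) and `n_edges`.
#' @export
persistent_homology <- function(f) {
  sx <- f$simplices
  ns <- nrow(sx)
  R <- f$faces           # columns of the boundary matrix, reduced in place
  V <- lapply(seq_len(ns), function(i) i)
  low_owner <- integer(ns)   # low_owner[r] = column with pivot r (0 = none)
  pair_of <- integer(ns)     # creator -> destroyer (0 = essential)
  killed <- logical(ns)      # TRUE if the column died as a pivot
  reps <- vector("list", ns)
  for (j in seq_len(ns)) {
    col <- sort(R[[j]])
    while (length(col) > 0) {
      low <- col[length(col)]
      k <- low_owner[low]
      if (k == 0) break
      col <- xor_chain(col, R[[k]])
      V[[j]] <- xor_chain(V[[j]], V[[k]])
    }
    R[[j]] <- col
    if (length(col) > 0) {
      low <- col[length(col)]
      low_owner[low] <- j
      pair_of[low] <- j
      killed[low] <- TRUE
      reps[[low]] <- col        # the dying cycle, as faces of dim(j) - 1
    }
  }
  dims <- sx$dim
  bars <- list()
  rep_out <- list()
  for (i in seq_len(ns)) {
    creator <- length(R[[i]]) == 0
    if (!creator) next
    j <- pair_of[i]
    if (j == 0) {
      bars[[length(bars) + 1]] <- c(dims[i], sx$rank[i], Inf,
                                    sx$value[i], Inf)
      rep_out[[length(bars)]] <- f$vertices[V[[i]]]
    } else {
      bars[[length(bars) + 1]] <- c(dims[i], sx$rank[i], sx$rank[j],
                                    sx$value[i], sx$value[j])
      rep_out[[length(bars)]] <- f$vertices[reps[[i]]]
    }
  }
  d <- do.call(rbind, bars)
  out <- data.frame(dimension = as.integer(d[, 1]), birth = d[, 2],
                    death = d[, 3], birth_value = d[, 4],
                    death_value = d[, 5])
  out$lifetime <- out$death - out$birth
  ord <- order(out$dimension, out$birth, out$death)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, representatives = rep_out[ord], n_edges = f$n_edges,
            class = c("persistence_diagram", "data.frame"))
}

#' Final Betti numbers of a filtration
#'
#' Counts infinite bars per dimension (features of the complete complex).
#'
#' @param diagram a [persistent_homology()] result.
#' @param max_dim report dimensions 0..max_dim.
#' @return named integer vector `b0`, `b1`, ...
#' @export
betti_numbers <- function(diagram, max_dim = 2) {
  vapply(0:max_dim, function(d)
    sum(diagram$dimension == d & is.infinite(diagram$death)),
    integer(1)) |>
    stats::setNames(paste0("b", 0:max_dim))
}

#' Cavity significance against rewired nulls
#'
#' Computes persistence for the graph and for every ensemble member
#' (edge-rank filtration scale, so curves are comparable across graphs with
#' similar edge counts). Per homology dimension, two defensible summary
#' statistics are tested with empirical p-values (tail = greater): the
#' number of long-lived bars (lifetime at least `lifetime_frac` of the
#' graph's own filtration length) and the longest finite-capped lifetime
#' (infinite deaths are capped at one past the filtration length). The
#' graph's bars are ranked by lifetime and the top `top_m` per dimension are
#' returned with their representative cycles mapped to node labels.
#'
#' @param g a [connectome_graph()].
#' @param ensemble a [build_ensemble()] result from `g` (100 members in the
#'   reference analysis).
#' @param top_m bars to report per dimension.
#' @param dims homology dimensions to summarize (default 1:2).
#' @param lifetime_frac long-lived threshold as a fraction of the
#'   filtration length.
#' @param symmetrize_rule,max_dim passed to [build_filtration()].
#' @return list with `summary` (data.frame per dimension: bar counts,
#'   longest lifetime, long-lived count, p-values), `top_bars` (per
#'   dimension: data.frame of bars with node labels), `diagram`.
#' @export
cavity_significance <- function(g, ensemble, top_m = 5, dims = 1:2,
                                lifetime_frac = 0.25,
                                symmetrize_rule = "max", max_dim = 3) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$n_nodes != n_nodes(g)) stop("ensemble/graph size mismatch")
  ph_stats <- function(graph) {
    dg <- persistent_homology(build_filtration(graph, symmetrize_rule, max_dim))
    m <- attr(dg, "n_edges")
    life <- pmin(dg$death, m + 1) - dg$birth
    out <- lapply(dims, function(d) {
      idx <- dg$dimension == d & life > 0
      c(n_bars = sum(idx),
        longest = if (any(idx)) max(life[idx]) else 0,
        n_long = sum(idx & life >= lifetime_frac * m))
    })
    list(stats = do.call(rbind, out), diagram = dg, life = life, m = m)
  }
  obs <- ph_stats(g)
  null_stats <- lapply(ensemble$members, function(x) ph_stats(x)$stats)
  summary <- do.call(rbind, lapply(seq_along(dims), function(di) {
    ns_long <- vapply(null_stats, function(s) s[di, "n_long"], numeric(1))
    ns_max <- vapply(null_stats, function(s) s[di, "longest"], numeric(1))
    data.frame(dimension = dims[di],
               n_bars = obs$stats[di, "n_bars"],
               longest_lifetime = obs$stats[di, "longest"],
               n_long_lived = obs$stats[di, "n_long"],
               null_mean_n_long = mean(ns_long),
               null_mean_longest = mean(ns_max),
               p_n_long = empirical_pvalue(obs$stats[di, "n_long"], ns_long,
                                           "greater"),
               p_longest = empirical_pvalue(obs$stats[di, "longest"], ns_max,
                                            "greater"))
  }))
  reps <- attr(obs$diagram, "representatives")
  top_bars <- lapply(dims, function(d) {
    idx <- which(obs$diagram$dimension == d & obs$life > 0)
    idx <- idx[order(-obs$life[idx])]
    idx <- utils::head(idx, top_m)
    if (!length(idx)) return(NULL)
    nodes <- vapply(idx, function(i) {
      vs <- sort(unique(unlist(reps[[i]])))
      paste(g$labels[vs], collapse = ",")
    }, character(1))
    cbind(obs$diagram[idx, c("dimension", "birth", "death", "lifetime",
                             "birth_value", "death_value")],
          nodes = nodes)
  })
  names(top_bars) <- paste0("H", dims)
  list(summary = summary, top_bars = top_bars, diagram = obs$diagram,
       lifetime_frac = lifetime_frac)
}
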