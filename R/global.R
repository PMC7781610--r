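# Node- and graph-level statistics: strengths/degrees, weighted reciprocity,
# assortativity, Fagiolo directed-weighted clustering, characteristic path
# length on the -log weight-to-length transform, and null-normalized
# small-world indices.

#' Node strengths and binary degrees
#'
#' Out-strength is the row sum (efferent weight), in-strength the column sum
#' (afferent weight); `k_in`/`k_out` are the binary degrees.
#'
#' @param g a [connectome_graph()].
#' @return list with `s_in`, `s_out`, `k_in`, `k_out`, named by node.
#' @export
strengths <- function(g) {
  w <- g$weights
  a <- w > 0
  list(s_in = colSums(w), s_out = rowSums(w),
       k_in = colSums(a), k_out = rowSums(a))
}

#' Weighted reciprocity
#'
#' Correlation between the weight matrix and its transpose over all ordered
#' off-diagonal pairs, centered on the common off-diagonal mean:
#' `rho = sum((w_ij - wbar)(w_ji - wbar)) / sum((w_ij - wbar)^2)`.
#' Equals 1 for any symmetric matrix; near 0 for rewired nulls.
#'
#' @param g a [connectome_graph()].
#' @return reciprocity in \[-1, 1\], or `NA` (with a warning) when the
#'   off-diagonal entries have zero variance.
#' @export
reciprocity <- function(g) {
  w <- g$weights
  off <- !diag(nrow(w))
  x <- w[off]
  y <- t(w)[off]
  wbar <- mean(x)
  den <- sum((x - wbar)^2)
  if (den == 0) {
    warning("reciprocity undefined: zero off-diagonal variance")
    return(NA_real_)
  }
  sum((x - wbar) * (y - wbar)) / den
}

#' Degree/strength assortativity over directed edges
#'
#' Pearson correlation, across directed edges i -> j, of the source's
#' out-value with the target's in-value (out-in flavor).
#'
#' @param g a [connectome_graph()].
#' @param mode `"degree"` (binary) or `"strength"` (weighted).
#' @return correlation in \[-1, 1\]; `NA` with a warning if either endpoint
#'   value is constant (e.g. a regular graph).
#' @export
assortativity <- function(g, mode = c("degree", "strength")) {
  mode <- match.arg(mode)
  el <- which(g$weights > 0, arr.ind = TRUE)
  if (nrow(el) < 2) stop("need at least 2 edges")
  s <- strengths(g)
  xv <- if (mode == "degree") s$k_out else s$s_out
  yv <- if (mode == "degree") s$k_in else s$s_in
  x <- xv[el[, 1]]
  y <- yv[el[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("assortativity undefined: zero variance of endpoint values")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Fagiolo directed-weighted clustering coefficient
#'
#' With `What = (W / max(W))^(1/3)` elementwise, the per-node coefficient is
#' `c_i = [(What + What^T)^3]_ii / (2 * (d_i (d_i - 1) - 2 d_i^bidir))`,
#' where `d_i = k_in + k_out` and `d_i^bidir` counts reciprocated neighbors.
#' Nodes whose denominator is not positive (fewer than two neighbors) are
#' `NA` and excluded from the mean.
#'
#' @param g a [connectome_graph()].
#' @param normalize divide by the maximum weight before the cube root
#'   (default; the mean is scale-dependent, so the choice is recorded in the
#'   output).
#' @return list with `per_node` (n values, `NA` where undefined), `mean`
#'   (over defined nodes), `n_undefined`, `normalized`.
#' @export
clustering_coefficient <- function(g, normalize = TRUE) {
  w <- g$weights
  if (normalize && max(w) > 0) w <- w / max(w)
  a <- (g$weights > 0) + 0
  wh <- w^(1/3)
  s <- wh + t(wh)
  t_i <- diag(s %*% s %*% s)
  d_tot <- rowSums(a) + colSums(a)
  d_bi <- diag(a %*% a)
  den <- d_tot * (d_tot - 1) - 2 * d_bi
  c_i <- ifelse(den > 0, t_i / (2 * den), NA_real_)
  names(c_i) <- g$labels
  list(per_node = c_i,
       mean = mean(c_i, na.rm = TRUE),
       n_undefined = sum(is.na(c_i)),
       normalized = normalize)
}

# All-pairs shortest path lengths on a length matrix (Floyd-Warshall;
# n is small at mesoscale so the dense O(n^3) sweep is fine).
shortest_path_lengths <- function(L) {
  D <- L
  diag(D) <- 0
  n <- nrow(D)
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

#' Characteristic path length
#'
#' All-pairs shortest paths on a length matrix (typically from
#' [weight_to_length()]), summarized over ordered pairs i != j.
#' The arithmetic rule averages finite distances and reports the number of
#' unreachable pairs; the harmonic rule is n_pairs / sum(1/d), with
#' unreachable pairs contributing zero inverse distance.
#'
#' @param L length matrix (`Inf` = absent edge) or a `connectome_graph`
#'   (transformed internally).
#' @param mean_rule `"arithmetic"` (default; matches the toolbox convention
#'   behind the headline value) or `"harmonic"`.
#' @return list with `value`, `mean_rule`, `n_unreachable`, and the distance
#'   matrix `distances`.
#' @export
characteristic_path_length <- function(L, mean_rule = c("arithmetic", "harmonic")) {
  mean_rule <- match.arg(mean_rule)
  if (inherits(L, "connectome_graph")) L <- weight_to_length(L)
  D <- shortest_path_lengths(L)
  off <- !diag(nrow(D))
  d <- D[off]
  reach <- is.finite(d)
  if (sum(reach) < 2) stop("fewer than 2 reachable pairs")
  value <- if (mean_rule == "arithmetic") mean(d[reach])
           else length(d) / sum(1 / d[reach])
  list(value = value, mean_rule = mean_rule,
       n_unreachable = sum(!reach), distances = D)
}

#' Global metrics bundle
#'
#' @param g a [connectome_graph()].
#' @param mean_rule passed to [characteristic_path_length()].
#' @return list with densities, reciprocity, degree and strength
#'   assortativity, mean clustering, characteristic path length.
#' @export
global_metrics <- function(g, mean_rule = "arithmetic") {
  dens <- density_connectome(g)
  list(density_directed = dens$directed,
       density_undirected = dens$undirected,
       reciprocity = reciprocity(g),
       assortativity_degree = assortativity(g, "degree"),
       assortativity_strength = assortativity(g, "strength"),
       clustering_mean = clustering_coefficient(g)$mean,
       char_path_length = characteristic_path_length(g, mean_rule)$value)
}

#' Null-normalized small-world indices
#'
#' `gamma_norm` is the mean clustering of `g` divided by the ensemble-mean
#' clustering of the rewired nulls; `lambda_norm` the analogous path-length
#' ratio; `sigma = gamma_norm / lambda_norm` (> 1 indicates small-world
#' organization).
#'
#' @param g a [connectome_graph()].
#' @param ensemble a [build_ensemble()] result built from `g`.
#' @param mean_rule passed to [characteristic_path_length()].
#' @return list with `gamma_norm`, `lambda_norm`, `sigma`, plus the raw and
#'   null mean values and the per-member null distributions.
#' @export
small_world <- function(g, ensemble, mean_rule = "arithmetic") {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$n_nodes != n_nodes(g)) stop("ensemble/graph size mismatch")
  c_obs <- clustering_coefficient(g)$mean
  l_obs <- characteristic_path_length(g, mean_rule)$value
  c_null <- vapply(ensemble$members,
                   function(x) clustering_coefficient(x)$mean, numeric(1))
  l_null <- vapply(ensemble$members,
                   function(x) characteristic_path_length(x, mean_rule)$value,
                   numeric(1))
  if (mean(c_null) == 0 || mean(l_null) == 0) stop("null mean is zero")
  gamma_norm <- c_obs / mean(c_null)
  lambda_norm <- l_obs / mean(l_null)
  list(gamma_norm = gamma_norm, lambda_norm = lambda_norm,
       sigma = gamma_norm / lambda_norm,
       clustering = c_obs, path_length = l_obs,
       null_clustering = c_null, null_path_length = l_null)
}
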