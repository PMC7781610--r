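# Hub analysis: participation coefficients against a partition, cross-scale
# participation rank profiles, out/in-strength ratios, and rich-club curves
# normalized against degree-preserving rewired nulls.

#' Participation coefficients
#'
#' Diversity of a node's connections across communities:
#' `p_i^in = 1 - sum_c (s_i(c)^in / s_i^in)^2`, where `s_i(c)^in` is the
#' afferent strength node i receives from community c (analogously for out).
#' 0 means all connections stay within one module; the maximum is
#' `1 - 1/C` for C communities. Nodes with zero strength get participation 0
#' and are flagged.
#'
#' @param g a [connectome_graph()].
#' @param labels community labels, length n.
#' @return list with `p_in`, `p_out` (named), `zero_in`, `zero_out` (logical
#'   flags for zero-strength nodes), `n_communities`.
#' @export
participation <- function(g, labels) {
  w <- g$weights
  n <- nrow(w)
  if (length(labels) != n) stop("labels must have length n")
  labels <- relabel_partition(labels)
  k <- max(labels)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  s_in_c <- t(w) %*% ind        # [i, c] afferent strength of i from community c
  s_out_c <- w %*% ind          # [i, c] efferent strength of i into community c
  s_in <- rowSums(s_in_c)
  s_out <- rowSums(s_out_c)
  p_of <- function(sc, s) {
    p <- 1 - rowSums((sc / ifelse(s > 0, s, 1))^2)
    p[s == 0] <- 0
    stats::setNames(p, g$labels)
  }
  list(p_in = p_of(s_in_c, s_in), p_out = p_of(s_out_c, s_out),
       zero_in = stats::setNames(s_in == 0, g$labels),
       zero_out = stats::setNames(s_out == 0, g$labels),
       n_communities = k)
}

#' Cross-resolution participation rank profile
#'
#' Within each resolution's consensus partition, nodes are ranked by their
#' participation coefficient (ties receive average ranks); ranks are then
#' averaged across resolutions. High mean rank = consistently diverse
#' connection profile across scales.
#'
#' @param g a [connectome_graph()].
#' @param sweep a [resolution_sweep()] result (or a list of label vectors).
#' @return list with `rank_in`, `rank_out` (mean ranks, named), and the
#'   per-resolution rank matrices `ranks_in`, `ranks_out`
#'   (gamma x node).
#' @export
participation_rank_profile <- function(g, sweep) {
  parts <- if (!is.null(sweep$consensus))
    lapply(sweep$consensus, function(x) x$partition$labels)
  else sweep
  if (length(parts) < 1) stop("need at least one partition")
  ri <- t(vapply(parts, function(lab) rank(participation(g, lab)$p_in),
                 numeric(n_nodes(g))))
  ro <- t(vapply(parts, function(lab) rank(participation(g, lab)$p_out),
                 numeric(n_nodes(g))))
  colnames(ri) <- colnames(ro) <- g$labels
  list(rank_in = colMeans(ri), rank_out = colMeans(ro),
       ranks_in = ri, ranks_out = ro)
}

#' Out-strength to in-strength ratio and its relation to total strength
#'
#' `ratio_i = s_i^out / s_i^in`; large values mark sources (disseminators),
#' small values sinks. Nodes with zero in-strength are flagged and excluded
#' from the correlation between total strength and ratio.
#'
#' @param g a [connectome_graph()].
#' @param use_log correlate the log-ratio instead of the raw ratio (skew
#'   robustness); default uses the raw ratio.
#' @return list with `ratio` (named, `NA` where s_in = 0), `total_strength`,
#'   `correlation` (Pearson r of total strength vs ratio over unflagged
#'   nodes; `NA` with warning if degenerate), `flagged`.
#' @export
strength_ratio <- function(g, use_log = FALSE) {
  s <- strengths(g)
  flagged <- s$s_in == 0
  ratio <- ifelse(flagged, NA_real_, s$s_out / s$s_in)
  total <- s$s_in + s$s_out
  x <- total[!flagged]
  y <- ratio[!flagged]
  if (use_log) y <- log(y)
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  corr <- if (length(x) > 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y)
  else {
    warning("strength-ratio correlation undefined (zero variance or too few nodes)")
    NA_real_
  }
  list(ratio = stats::setNames(ratio, g$labels),
       total_strength = stats::setNames(total, g$labels),
       correlation = corr,
       flagged = stats::setNames(flagged, g$labels),
       use_log = use_log)
}

# Rich-club coefficient curve of one weight matrix: for each k, density of
# the subgraph on nodes with total binary degree > k (or >= k).
phi_curve <- function(w, k_levels, keep_geq = FALSE) {
  a <- w > 0
  deg <- rowSums(a) + colSums(a)
  vapply(k_levels, function(k) {
    keep <- if (keep_geq) deg >= k else deg > k
    ns <- sum(keep)
    if (ns < 2) return(NA_real_)
    sum(a[keep, keep]) / (ns * (ns - 1))
  }, numeric(1))
}

#' Rich-club curve with rewired-null normalization
#'
#' At each degree level k, nodes with total binary degree <= k are removed
#' and the directed density of the surviving subgraph is the rich-club
#' coefficient phi(k). The identical procedure on every ensemble member
#' yields the null distribution phi_rand(k); the normalized curve is
#' phi(k) / mean(phi_rand(k)) and the per-k p-value is the empirical
#' proportion of null curves at least as large (add-one estimator).
#' The rich-club regime is the longest contiguous run of k with p <= alpha.
#'
#' @param g a [connectome_graph()].
#' @param ensemble a [build_ensemble()] result built from `g`.
#' @param keep_geq keep nodes with degree >= k instead of > k.
#' @param alpha significance level for the regime (default 0.05).
#' @return a `rich_club_curve`: data.frame-like list with `k_levels`, `phi`,
#'   `phi_rand` (matrix members x k), `phi_norm`, `p_values`, `regime`
#'   (k range or NULL).
#' @export
rich_club <- function(g, ensemble, keep_geq = FALSE, alpha = 0.05) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$n_nodes != n_nodes(g)) stop("ensemble/graph size mismatch")
  a <- g$weights > 0
  deg <- rowSums(a) + colSums(a)
  k_levels <- seq_len(max(deg) - 1L)
  phi <- phi_curve(g$weights, k_levels, keep_geq)
  phi_rand <- t(vapply(ensemble$members,
                       function(x) phi_curve(x$weights, k_levels, keep_geq),
                       numeric(length(k_levels))))
  ok <- !is.na(phi)
  phi_norm <- rep(NA_real_, length(k_levels))
  p <- rep(NA_real_, length(k_levels))
  for (i in which(ok)) {
    nr <- phi_rand[, i]
    if (all(is.na(nr))) next
    phi_norm[i] <- phi[i] / mean(nr, na.rm = TRUE)
    p[i] <- empirical_pvalue(phi[i], nr, tail = "greater")
  }
  sig <- !is.na(p) & p <= alpha
  regime <- NULL
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    best <- which(r$values)[which.max(r$lengths[r$values])]
    regime <- c(k_min = k_levels[starts[best]], k_max = k_levels[ends[best]])
  }
  structure(list(k_levels = k_levels, phi = phi, phi_rand = phi_rand,
                 phi_norm = phi_norm, p_values = p, regime = regime,
                 keep_geq = keep_geq, alpha = alpha),
            class = "rich_club_curve")
}

#' @export
print.rich_club_curve <- function(x, ...) {
  cat(sprintf("<rich_club_curve> %d degree levels", length(x$k_levels)))
  if (is.null(x$regime)) cat("; no significant regime\n")
  else cat(sprintf("; significant regime k in [%d, %d]\n",
                   x$regime["k_min"], x$regime["k_max"]))
  invisible(x)
}
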