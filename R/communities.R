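# Multiscale community detection: directed modularity with a resolution
# parameter, a Louvain-style greedy optimizer, Lancichinetti-Fortunato
# consensus clustering, normalized mutual information, and a resolution
# sweep with plateau-based scale selection.

# Relabel an integer vector to contiguous 1..K in order of first appearance.
relabel_partition <- function(labels) {
  match(labels, unique(labels))
}

#' Directed modularity of a partition
#'
#' `Q = (1/m) * sum_ij [A_ij - gamma * s_i^out * s_j^in / m] * delta(c_i, c_j)`
#' with `m` the total weight; the directed (Leicht-Newman) null term uses
#' out-strength of the source and in-strength of the target.
#'
#' @param g a [connectome_graph()] (or a plain weight matrix).
#' @param labels community labels, length n.
#' @param gamma resolution parameter (> 0; larger favors smaller communities).
#' @return modularity Q.
#' @export
modularity_score <- function(g, labels, gamma = 1) {
  w <- if (inherits(g, "connectome_graph")) g$weights else as.matrix(g)
  n <- nrow(w)
  if (length(labels) != n) stop("labels must have length n")
  m <- sum(w)
  if (m <= 0) stop("total weight must be positive")
  labels <- relabel_partition(labels)
  s_out <- rowSums(w)
  s_in <- colSums(w)
  k <- max(labels)
  q <- 0
  for (c_ in seq_len(k)) {
    idx <- labels == c_
    q <- q + sum(w[idx, idx]) - gamma * sum(s_out[idx]) * sum(s_in[idx]) / m
  }
  q / m
}

# One Louvain level: greedy local moves on weight matrix w (may contain
# self-loops from aggregation). Returns integer labels.
louvain_local_moves <- function(w, gamma) {
  n <- nrow(w)
  m <- sum(w)
  s_out <- rowSums(w)
  s_in <- colSums(w)
  labels <- seq_len(n)
  S_out <- s_out            # community out-strength totals
  S_in <- s_in
  improved <- TRUE
  pass <- 0
  while (improved && pass < 50) {
    improved <- FALSE
    pass <- pass + 1
    for (i in sample.int(n)) {
      ci <- labels[i]
      # strengths of i excluding the self-loop
      w_i_to <- w[i, ]          # i -> j
      w_to_i <- w[, i]          # j -> i
      self <- w[i, i]
      # detach i from its community
      S_out[ci] <- S_out[ci] - s_out[i]
      S_in[ci] <- S_in[ci] - s_in[i]
      # candidate communities: those of i's neighbors (+ its own)
      nb <- which((w_i_to > 0 | w_to_i > 0))
      cand <- unique(c(ci, labels[nb]))
      # links from/to each candidate community (excluding i itself)
      best_gain <- 0
      best_c <- ci
      for (cc in cand) {
        idx <- labels == cc
        idx[i] <- FALSE
        k_ic <- sum(w_i_to[idx]) + sum(w_to_i[idx])
        gain <- k_ic / m -
          gamma * (s_out[i] * S_in[cc] + s_in[i] * S_out[cc]) / m^2
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_c <- cc
        }
      }
      labels[i] <- best_c
      S_out[best_c] <- S_out[best_c] + s_out[i]
      S_in[best_c] <- S_in[best_c] + s_in[i]
      if (best_c != ci) improved <- TRUE
    }
  }
  relabel_partition(labels)
}

# Collapse communities into super-nodes (keeps self-loops).
aggregate_graph <- function(w, labels) {
  k <- max(labels)
  ind <- matrix(0, nrow(w), k)
  ind[cbind(seq_len(nrow(w)), labels)] <- 1
  t(ind) %*% w %*% ind
}

#' Louvain-style partition under directed modularity
#'
#' Greedy local moves followed by community aggregation, repeated until no
#' further modularity gain. The node sweep order is randomized by `seed`, so
#' repeated runs explore different local optima.
#'
#' @param g a [connectome_graph()] (or weight matrix).
#' @param gamma resolution parameter.
#' @param seed integer RNG seed.
#' @return a `resolution_partition`: list with `labels` (contiguous from 1),
#'   `gamma`, `quality` (Q of the returned labels), `n_communities`, `seed`.
#' @export
louvain_partition <- function(g, gamma = 1, seed = 1) {
  w <- if (inherits(g, "connectome_graph")) g$weights else as.matrix(g)
  with_seed(seed, {
    labels <- seq_len(nrow(w))
    cur_w <- w
    repeat {
      lv <- louvain_local_moves(cur_w, gamma)
      if (max(lv) == nrow(cur_w)) break        # no merge happened
      labels <- lv[labels]
      cur_w <- aggregate_graph(cur_w, lv)
    }
    labels <- relabel_partition(labels)
    structure(list(labels = labels, gamma = gamma,
                   quality = modularity_score(w, labels, gamma),
                   n_communities = max(labels), seed = seed),
              class = "resolution_partition")
  })
}

#' @export
print.resolution_partition <- function(x, ...) {
  cat(sprintf("<resolution_partition> gamma = %g: %d communities, Q = %.4f\n",
              x$gamma, x$n_communities, x$quality))
  invisible(x)
}

# Co-assignment (agreement) matrix of a list of label vectors.
coassignment_matrix <- function(runs) {
  n <- length(runs[[1]])
  D <- matrix(0, n, n)
  for (lab in runs) {
    k <- max(lab)
    ind <- matrix(0, n, k)
    ind[cbind(seq_len(n), lab)] <- 1
    D <- D + tcrossprod(ind)
  }
  D / length(runs)
}

#' Consensus partition over repeated Louvain runs
#'
#' Lancichinetti-Fortunato consensus clustering: run the optimizer `n_runs`
#' times, build the co-assignment matrix, zero entries below `tau`, and
#' re-cluster the thresholded matrix with the same procedure, iterating until
#' all runs agree.
#'
#' @param g a [connectome_graph()] (or weight matrix).
#' @param gamma resolution parameter for the initial runs.
#' @param n_runs number of optimizer runs (>= 2; 1000 in the reference
#'   analysis).
#' @param tau co-assignment threshold in \[0, 1).
#' @param seed master seed; run seeds are derived deterministically.
#' @param max_iter maximum consensus iterations before flagging
#'   non-convergence.
#' @return a `consensus_result`: list with `partition`
#'   (`resolution_partition` whose Q is evaluated on the original graph),
#'   `coassignment` (first-level co-assignment matrix), `n_runs`.
#' @export
consensus_partition <- function(g, gamma = 1, n_runs = 100, tau = 0.4,
                                seed = 1, max_iter = 50) {
  w <- if (inherits(g, "connectome_graph")) g$weights else as.matrix(g)
  if (n_runs < 2) stop("n_runs must be >= 2")
  seeds <- derive_seeds(seed, max_iter * n_runs)
  si <- 0
  run_batch <- function(mat, gam) {
    lapply(seq_len(n_runs), function(r) {
      si <<- si + 1
      louvain_partition(mat, gam, seed = seeds[si])$labels
    })
  }
  runs <- run_batch(w, gamma)
  D1 <- coassignment_matrix(runs)
  D <- D1
  for (iter in seq_len(max_iter)) {
    if (all_identical_partitions(runs)) {
      labels <- relabel_partition(runs[[1]])
      part <- structure(list(labels = labels, gamma = gamma,
                             quality = modularity_score(w, labels, gamma),
                             n_communities = max(labels), seed = seed),
                        class = "resolution_partition")
      return(structure(list(partition = part, coassignment = D1,
                            n_runs = n_runs, iterations = iter),
                       class = "consensus_result"))
    }
    Dt <- D
    Dt[Dt < tau] <- 0
    diag(Dt) <- 0
    if (sum(Dt) == 0) Dt <- D  # threshold wiped everything: keep raw agreement
    runs <- run_batch(Dt, 1)
    D <- coassignment_matrix(runs)
  }
  stop("consensus clustering did not converge after ", max_iter, " iterations")
}

all_identical_partitions <- function(runs) {
  ref <- relabel_partition(runs[[1]])
  for (lab in runs[-1]) {
    if (!identical(relabel_partition(lab), ref)) return(FALSE)
  }
  TRUE
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d runs -> %d communities (gamma = %g, %d iterations)\n",
              x$n_runs, x$partition$n_communities, x$partition$gamma,
              x$iterations))
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies: `NMI = 2 I(a; b) / (H(a) + H(b))`. Equals 1 iff the partitions
#' are identical up to relabeling; defined as 0 when both entropies are zero.
#'
#' @param a,b integer label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  tab <- table(a, b)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(0)
  pp <- p[p > 0]
  e <- outer(pa, pb)[p > 0]
  i <- sum(pp * log(pp / e))
  max(0, min(1, 2 * i / (ha + hb)))
}

#' Resolution sweep with consensus and scale selection
#'
#' Runs [consensus_partition()] at every resolution of `gamma_grid`,
#' computes the pairwise NMI matrix between the consensus partitions, and
#' selects well-defined scales as plateau centers: maximal contiguous grid
#' intervals wider than `min_width` whose within-interval mean pairwise NMI
#' exceeds the `quantile`-th quantile of all pairwise NMI values.
#'
#' @param g a [connectome_graph()].
#' @param gamma_grid sorted positive resolutions (default seq(0.5, 2.2, 0.1)).
#' @param n_runs optimizer runs per resolution.
#' @param tau consensus threshold.
#' @param seed master seed.
#' @param min_width minimal plateau width in gamma units.
#' @param quantile NMI quantile a plateau must exceed.
#' @return list with `gamma_grid`, `consensus` (per-gamma
#'   `consensus_result`s), `n_communities`, `nmi_matrix`, and `scales`
#'   (data.frame of plateau center, interval, n_communities at the center).
#' @export
resolution_sweep <- function(g, gamma_grid = seq(0.5, 2.2, by = 0.1),
                             n_runs = 100, tau = 0.4, seed = 1,
                             min_width = 0.2, quantile = 0.9) {
  if (length(gamma_grid) == 0) stop("empty resolution grid")
  if (is.unsorted(gamma_grid) || any(gamma_grid <= 0))
    stop("gamma_grid must be sorted and positive")
  seeds <- derive_seeds(seed, length(gamma_grid))
  cons <- lapply(seq_along(gamma_grid), function(i)
    consensus_partition(g, gamma_grid[i], n_runs = n_runs, tau = tau,
                        seed = seeds[i]))
  ng <- length(gamma_grid)
  nmi <- diag(1, ng)
  if (ng > 1) {
    for (i in 1:(ng - 1)) for (j in (i + 1):ng) {
      v <- partition_nmi(cons[[i]]$partition$labels, cons[[j]]$partition$labels)
      nmi[i, j] <- v
      nmi[j, i] <- v
    }
  }
  ncom <- vapply(cons, function(x) x$partition$n_communities, integer(1))
  scales <- select_scales(gamma_grid, nmi, ncom, min_width, quantile)
  list(gamma_grid = gamma_grid, consensus = cons, n_communities = ncom,
       nmi_matrix = nmi, scales = scales)
}

# Plateau detection on the NMI matrix (see resolution_sweep docs).
select_scales <- function(gamma_grid, nmi, ncom, min_width, quantile) {
  ng <- length(gamma_grid)
  empty <- data.frame(center = numeric(0), gamma_lo = numeric(0),
                      gamma_hi = numeric(0), n_communities = integer(0),
                      mean_nmi = numeric(0))
  if (ng < 2) return(empty)
  off <- nmi[upper.tri(nmi)]
  thr <- stats::quantile(off, quantile, names = FALSE)
  win_mean <- function(i, j) {
    sub <- nmi[i:j, i:j]
    mean(sub[upper.tri(sub)])
  }
  # grid points belonging to some qualifying window
  ok <- rep(FALSE, ng)
  for (i in 1:(ng - 1)) for (j in (i + 1):ng) {
    if (gamma_grid[j] - gamma_grid[i] > min_width && win_mean(i, j) >= thr)
      ok[i:j] <- TRUE
  }
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- lapply(which(r$values), function(k) {
    i <- starts[k]; j <- ends[k]
    ctr <- (i + j) %/% 2
    data.frame(center = gamma_grid[ctr], gamma_lo = gamma_grid[i],
               gamma_hi = gamma_grid[j], n_communities = ncom[ctr],
               mean_nmi = win_mean(i, j))
  })
  do.call(rbind, rows)
}
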