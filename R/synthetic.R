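# Synthetic connectome generators: geometric (distance-decaying weights),
# modular (planted partition), hierarchical (nested planted partitions),
# plus exact small fixtures with known topology.

# Run expr under a local RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds (< 2^31) deterministically from a master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Specification for a synthetic connectome
#'
#' Bundles the generator parameters. Defaults emulate a mesoscale
#' cortico-cortical tracer network: ~55 areas, directed density ~0.62,
#' roughly exponential decay of connection weight with Euclidean distance,
#' high reciprocity, and right-skewed (lognormal-noise) weights.
#'
#' @param n node count.
#' @param target_density directed connection density in (0, 1].
#' @param decay_rate exponential weight-distance decay rate (1/mm).
#' @param reciprocity_bias probability that a drawn edge is accompanied by
#'   its reverse.
#' @param sigma_noise total lognormal sigma of multiplicative weight noise.
#' @param shared_noise_frac fraction of log-noise variance shared by the two
#'   directions of a pair (drives weight reciprocity).
#' @param box_size side (mm) of the cube in which nodes are placed.
#' @param community_sizes optional integer vector summing to `n` (planted
#'   partition for [generate_modular()]).
#' @param within_between_ratio ratio (> 1) of within- to between-community
#'   edge probability and expected weight.
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 55, target_density = 0.626, decay_rate = 0.18,
                           reciprocity_bias = 0.7, sigma_noise = 1,
                           shared_noise_frac = 0.7, box_size = 25,
                           community_sizes = NULL,
                           within_between_ratio = NULL, seed = 42) {
  if (target_density * n * (n - 1) < 1) stop("density infeasible for n")
  if (target_density > 1 || target_density <= 0) stop("target_density must be in (0, 1]")
  if (!is.null(community_sizes) && sum(community_sizes) != n)
    stop("community_sizes must sum to n")
  if (!is.null(within_between_ratio) && within_between_ratio <= 0)
    stop("within_between_ratio must be positive")
  structure(list(n = n, target_density = target_density,
                 decay_rate = decay_rate,
                 reciprocity_bias = reciprocity_bias,
                 sigma_noise = sigma_noise,
                 shared_noise_frac = shared_noise_frac,
                 box_size = box_size, community_sizes = community_sizes,
                 within_between_ratio = within_between_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Shared edge-realization step: given a symmetric per-pair acceptance
# probability matrix P (upper triangle used), draw each direction
# independently, then complete unidirectional pairs with probability
# reciprocity_bias. Returns a logical adjacency matrix.
realize_arcs <- function(P, recip) {
  n <- nrow(P)
  A <- matrix(FALSE, n, n)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  p <- P[ut]
  fwd <- stats::runif(nrow(ut)) < p
  bwd <- stats::runif(nrow(ut)) < p
  one <- xor(fwd, bwd)
  fill <- one & (stats::runif(nrow(ut)) < recip)
  fwd2 <- fwd | (fill & bwd)
  bwd2 <- bwd | (fill & fwd)
  A[ut] <- fwd2
  A[ut[, c(2, 1), drop = FALSE]] <- bwd2
  A
}

# Expected number of arcs per unordered pair under realize_arcs.
expected_arcs_per_pair <- function(p, recip) {
  2 * p^2 + 2 * p * (1 - p) * (1 + recip)
}

# Bisection for a global scale s such that sum over pairs of the expected
# arc count of min(1, s * q) matches the target arc total.
tune_scale <- function(q, recip, target_arcs) {
  f <- function(s) sum(expected_arcs_per_pair(pmin(1, s * q), recip)) - target_arcs
  lo <- 0; hi <- 1
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 2
  if (f(hi) < 0) stop("density infeasible for this geometry")
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Lognormal multiplicative weight noise with a component shared between the
# two directions of each pair (yields high weight reciprocity).
pair_noise <- function(n, sigma, shared_frac) {
  s_sh <- sigma * sqrt(shared_frac)
  s_ind <- sigma * sqrt(1 - shared_frac)
  sh <- matrix(0, n, n)
  sh[upper.tri(sh)] <- stats::rnorm(n * (n - 1) / 2, sd = s_sh)
  sh <- sh + t(sh)
  ind <- matrix(stats::rnorm(n * n, sd = s_ind), n, n)
  exp(sh + ind)
}

#' Generate a geometric synthetic connectome
#'
#' Places nodes uniformly at random in a cube, samples directed edges with
#' probability decaying exponentially in Euclidean distance (a global scale
#' is tuned by bisection so the expected directed density matches
#' `target_density`), adds reverse edges with probability
#' `reciprocity_bias`, and assigns weights
#' `w = exp(-decay_rate * d) * u` with multiplicative lognormal noise `u`,
#' rescaled into (0, 1]. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [connectome_graph()] with coordinates; the spec is stored in
#'   `meta$spec`.
#' @export
generate_geometric <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    coords <- matrix(stats::runif(n * 3, 0, spec$box_size), n, 3)
    d <- as.matrix(stats::dist(coords))
    q <- exp(-spec$decay_rate * d)
    target_arcs <- spec$target_density * n * (n - 1)
    s <- tune_scale(q[upper.tri(q)], spec$reciprocity_bias, target_arcs)
    A <- realize_arcs(pmin(s * q, 1), spec$reciprocity_bias)
    u <- pair_noise(n, spec$sigma_noise, spec$shared_noise_frac)
    w <- exp(-spec$decay_rate * d) * u
    w[!A] <- 0
    diag(w) <- 0
    if (max(w) > 0) w <- w / max(w)
    connectome_graph(w, coords = coords,
                     meta = list(generator = "geometric", spec = unclass(spec)))
  })
}

# Solve within/between edge probabilities for a planted partition with the
# requested overall density and probability ratio.
block_probs <- function(sizes, ratio, target_density) {
  n <- sum(sizes)
  pairs_within <- sum(sizes * (sizes - 1))     # ordered pairs
  pairs_total <- n * (n - 1)
  pairs_between <- pairs_total - pairs_within
  # density = (pw * pairs_within + pb * pairs_between) / pairs_total, pw = ratio * pb
  pb <- target_density * pairs_total / (ratio * pairs_within + pairs_between)
  pw <- ratio * pb
  if (pw > 1) stop("within-block probability exceeds 1: lower ratio or density")
  list(within = pw, between = pb)
}

#' Generate a modular synthetic connectome (planted partition)
#'
#' Block-structured directed edge probabilities: within-community pairs are
#' `within_between_ratio` times more likely to be connected (and carry
#' `within_between_ratio` times larger expected weight) than between-community
#' pairs, with the overall directed density held at `target_density`.
#' The planted labels are recorded in `meta$planted`.
#'
#' @param spec a [synthetic_spec()] with `community_sizes` and
#'   `within_between_ratio` set.
#' @return a [connectome_graph()].
#' @export
generate_modular <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$community_sizes) || is.null(spec$within_between_ratio))
    stop("community_sizes and within_between_ratio are required")
  with_seed(spec$seed, {
    sizes <- spec$community_sizes
    n <- spec$n
    planted <- rep(seq_along(sizes), sizes)
    pr <- block_probs(sizes, spec$within_between_ratio, spec$target_density)
    same <- outer(planted, planted, "==")
    P <- ifelse(same, pr$within, pr$between)
    A <- realize_arcs(P, spec$reciprocity_bias)
    u <- pair_noise(n, spec$sigma_noise, spec$shared_noise_frac)
    base <- ifelse(same, spec$within_between_ratio, 1)
    w <- base * u
    w[!A] <- 0
    diag(w) <- 0
    if (max(w) > 0) w <- w / max(w)
    connectome_graph(w, meta = list(generator = "modular",
                                    planted = planted,
                                    spec = unclass(spec)))
  })
}

#' Generate a two-level hierarchical modular connectome
#'
#' Super-blocks of equal size are each split into `split` sub-blocks.
#' Ordered pairs inside a sub-block connect with probability (and expected
#' weight) `ratio * sub_ratio` times the baseline; pairs sharing only a
#' super-block get `ratio` times the baseline. The coarse contrast `ratio`
#' is kept larger than the extra fine contrast `sub_ratio` so that the
#' super-block level is the optimal description at low resolution while the
#' sub-block level takes over at high resolution. Both planted levels are
#' stored in `meta$planted_coarse` / `meta$planted_fine`.
#'
#' @param n node count (must be divisible by `n_super * split`).
#' @param n_super number of super-blocks.
#' @param split sub-blocks per super-block.
#' @param ratio coarse-level probability/weight contrast (> 1).
#' @param sub_ratio additional within-sub-block contrast (> 1).
#' @param target_density overall directed density.
#' @param reciprocity_bias,sigma_noise,seed as in [synthetic_spec()].
#' @return a [connectome_graph()].
#' @export
generate_hierarchical <- function(n = 48, n_super = 4, split = 2, ratio = 6,
                                  sub_ratio = 3, target_density = 0.15,
                                  reciprocity_bias = 0.7, sigma_noise = 0.5,
                                  seed = 42) {
  if (n %% (n_super * split) != 0) stop("n must be divisible by n_super * split")
  with_seed(seed, {
    coarse <- rep(seq_len(n_super), each = n / n_super)
    fine <- rep(seq_len(n_super * split), each = n / (n_super * split))
    same_f <- outer(fine, fine, "==")
    same_c <- outer(coarse, coarse, "==")
    lvl <- ifelse(same_f, ratio * sub_ratio, ifelse(same_c, ratio, 1))
    diag(lvl) <- 0
    # per-pair acceptance scale tuned so expected directed density (with
    # reciprocity completion) matches the target
    s <- tune_scale(lvl[upper.tri(lvl)], reciprocity_bias,
                    target_density * n * (n - 1))
    if (s * ratio * sub_ratio > 1)
      warning("within-sub-block probability saturated at 1")
    A <- realize_arcs(pmin(s * lvl, 1), reciprocity_bias)
    u <- pair_noise(n, sigma_noise, 0.7)
    w <- lvl * u
    w[!A] <- 0
    diag(w) <- 0
    if (max(w) > 0) w <- w / max(w)
    connectome_graph(w, meta = list(generator = "hierarchical",
                                    planted_coarse = coarse,
                                    planted_fine = fine,
                                    ratio = ratio, seed = seed))
  })
}

#' Exact fixture graphs with known topology
#'
#' Unit-weight graphs used throughout the test suite and documentation:
#' \describe{
#'   \item{complete}{complete digraph on `n` nodes (n(n-1) arcs).}
#'   \item{star}{hub node 1 projecting to `n - 1` leaves.}
#'   \item{directed_cycle}{single directed n-cycle.}
#'   \item{square_c4}{4-node cycle with reciprocal arcs (8 arcs, no chords);
#'     its clique complex is a circle (one immortal H1 class).}
#'   \item{octahedron}{reciprocal version of the octahedron skeleton
#'     (6 nodes, 24 arcs); its clique complex triangulates the 2-sphere.}
#'   \item{two_cliques}{two disconnected complete digraphs on `n/2` nodes
#'     each (`n` even, default 8).}
#' }
#'
#' @param name fixture name.
#' @param n node count where meaningful (ignored for square_c4/octahedron).
#' @return a [connectome_graph()].
#' @export
fixture_graph <- function(name = c("complete", "star", "directed_cycle",
                                   "square_c4", "octahedron", "two_cliques"),
                          n = NULL) {
  name <- match.arg(name)
  w <- switch(name,
    complete = {
      if (is.null(n)) n <- 5
      m <- matrix(1, n, n); diag(m) <- 0; m
    },
    star = {
      if (is.null(n)) n <- 5
      m <- matrix(0, n, n); m[1, -1] <- 1; m
    },
    directed_cycle = {
      if (is.null(n)) n <- 4
      m <- matrix(0, n, n)
      m[cbind(seq_len(n), c(seq_len(n)[-1], 1))] <- 1
      m
    },
    square_c4 = {
      m <- matrix(0, 4, 4)
      for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
        m[e[1], e[2]] <- 1; m[e[2], e[1]] <- 1
      }
      m
    },
    octahedron = {
      m <- matrix(1, 6, 6); diag(m) <- 0
      # opposite poles (1,2), (3,4), (5,6) are not adjacent
      for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
        m[p[1], p[2]] <- 0; m[p[2], p[1]] <- 0
      }
      m
    },
    two_cliques = {
      if (is.null(n)) n <- 8
      if (n %% 2 != 0 || n < 4) stop("two_cliques needs even n >= 4")
      h <- n / 2
      b <- matrix(1, h, h); diag(b) <- 0
      m <- matrix(0, n, n)
      m[1:h, 1:h] <- b
      m[(h + 1):n, (h + 1):n] <- b
      m
    })
  connectome_graph(w, meta = list(fixture = name))
}
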