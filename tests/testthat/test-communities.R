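test_that("modularity closed forms", {
  # two disconnected complete digraphs, true labels, gamma = 1 -> Q = 1/2
  for (n in c(8, 10)) {
    g <- fixture_graph("two_cliques", n)
    labels <- rep(1:2, each = n / 2)
    expect_equal(modularity_score(g, labels, 1), 0.5)
    # general closed form Q = 1 - gamma/2
    expect_equal(modularity_score(g, labels, 1.6), 1 - 1.6 / 2)
  }
  # all-in-one partition: Q = 1 - sum(s_out_i * s_in_j) / m^2
  g <- rand_digraph(12, 0.3, seed = 1)
  s <- strengths(g)
  m <- sum(g$weights)
  expect_equal(modularity_score(g, rep(1, 12), 1),
               1 - sum(outer(s$s_out, s$s_in)) / m^2)
  # singletons at gamma = 0: no within-community mass
  expect_equal(modularity_score(g, 1:12, 0), 0)
  expect_error(modularity_score(connectome_graph(matrix(0, 3, 3)), 1:3),
               "positive")
})

test_that("louvain recovers planted components and never undercuts baselines", {
  g <- fixture_graph("two_cliques", 8)
  p <- louvain_partition(g, 1, seed = 5)
  expect_equal(p$n_communities, 2)
  expect_equal(p$quality, 0.5)
  expect_equal(p$labels[1:4], rep(p$labels[1], 4))
  expect_equal(p$labels[5:8], rep(p$labels[5], 4))
  expect_equal(p$quality, modularity_score(g, p$labels, 1))
  for (s in 1:5) {
    gr <- rand_digraph(20, 0.2, seed = 30 + s)
    pr <- louvain_partition(gr, 1, seed = s)
    q_single <- modularity_score(gr, seq_len(20), 1)
    q_allone <- modularity_score(gr, rep(1, 20), 1)
    expect_gte(pr$quality, q_single)
    expect_gte(pr$quality, min(q_single, q_allone))  # bracketing
    expect_identical(louvain_partition(gr, 1, seed = s)$labels, pr$labels)
  }
})

test_that("NMI: relabeling invariance, symmetry, independence baseline", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(partition_nmi(a, a), 1)
  expect_equal(partition_nmi(a, c(3, 3, 1, 1, 2, 2)), 1)
  set.seed(11)
  vals <- replicate(50, {
    x <- sample(1:4, 400, replace = TRUE)
    y <- sample(1:4, 400, replace = TRUE)
    partition_nmi(x, y)
  })
  expect_lt(mean(vals), 0.05)
  b <- c(1, 2, 1, 2, 1, 2)
  expect_equal(partition_nmi(a, b), partition_nmi(b, a))
  expect_equal(partition_nmi(rep(1, 5), rep(1, 5)), 0)  # degenerate by convention
  expect_error(partition_nmi(1:3, 1:4), "length")
})

test_that("consensus: idempotence, permuted labels, planted recovery", {
  spec <- synthetic_spec(n = 40, target_density = 0.3,
                         community_sizes = rep(10, 4),
                         within_between_ratio = 8, seed = 3)
  g <- generate_modular(spec)
  cons <- consensus_partition(g, 1, n_runs = 30, seed = 2)
  expect_gt(partition_nmi(cons$partition$labels, g$meta$planted), 0.9)
  co <- cons$coassignment
  expect_true(isSymmetric(co))
  expect_equal(unname(diag(co)), rep(1, 40))
  expect_true(all(co >= 0 & co <= 1))
  # deterministic given the seed
  cons2 <- consensus_partition(g, 1, n_runs = 30, seed = 2)
  expect_identical(cons$partition$labels, cons2$partition$labels)
})

test_that("consensus of identical or label-permuted partitions is that partition", {
  base <- rep(1:3, each = 5)
  runs <- list(base, base + 3L, c(2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L,
                                  1L, 1L, 1L, 1L, 1L))
  D <- connectocore:::coassignment_matrix(runs)
  expect_true(all(D %in% c(0, 1)))
  expect_equal(partition_nmi(runs[[1]], runs[[3]]), 1)
  # a graph whose optimizer output is stable: consensus returns it unchanged
  g <- fixture_graph("two_cliques", 10)
  cons <- consensus_partition(g, 1, n_runs = 10, seed = 1)
  expect_equal(cons$iterations, 1)
  expect_equal(partition_nmi(cons$partition$labels, rep(1:2, each = 5)), 1)
  expect_true(all(cons$coassignment %in% c(0, 1)))
})

test_that("resolution sweep resolves a planted hierarchy and handles a unit grid", {
  h <- generate_hierarchical(n = 48, seed = 5)
  sweep <- resolution_sweep(h, gamma_grid = c(0.5, 0.6, 1.6, 1.8, 2.0),
                            n_runs = 15, seed = 4)
  expect_equal(dim(sweep$nmi_matrix), c(5, 5))
  expect_true(isSymmetric(sweep$nmi_matrix))
  nc <- sweep$n_communities
  expect_lt(nc[1], nc[5])   # coarse at low gamma, fine at high gamma
  single <- resolution_sweep(h, gamma_grid = 1, n_runs = 10, seed = 1)
  expect_equal(length(single$consensus), 1)
  expect_equal(nrow(single$scales), 0)
  expect_error(resolution_sweep(h, numeric(0)), "empty")
  expect_error(resolution_sweep(h, c(2, 1)), "sorted")
})
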