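test_that("participation: closed cases and accumulation oracle", {
  # all afferents inside own module -> p_in = 0
  g <- fixture_graph("two_cliques", 8)
  pp <- participation(g, rep(1:2, each = 4))
  expect_equal(unname(pp$p_in), rep(0, 8))
  expect_equal(unname(pp$p_out), rep(0, 8))
  # equal split over C modules -> 1 - 1/C
  for (C in c(2, 4)) {
    n <- 2 * C + 1
    w <- matrix(0, n, n)
    w[2:n, 1] <- 0.3                       # node 1 receives equally from all
    labels <- c(1, rep(1:C, each = 2))
    p1 <- participation(connectome_graph(w), labels)$p_in[1]
    # node 1's own module holds 3 of the 2C afferents (its 2 plus itself none)
    sc <- table(labels[2:n])
    expect_equal(unname(p1), 1 - sum((sc / (2 * C))^2))
  }
  w2 <- matrix(0, 5, 5)
  w2[2:5, 1] <- 1
  lab2 <- c(5, 1, 2, 3, 4)
  expect_equal(unname(participation(connectome_graph(w2), lab2)$p_in[1]),
               1 - 1 / 4)
  # random graph + random partition vs direct per-community accumulation
  set.seed(8)
  g3 <- rand_digraph(12, 0.4, seed = 8)
  lab3 <- sample(1:3, 12, replace = TRUE)
  pr <- participation(g3, lab3)
  for (i in 1:12) {
    s_in_c <- sapply(1:3, function(c_) sum(g3$weights[lab3 == c_, i]))
    s_out_c <- sapply(1:3, function(c_) sum(g3$weights[i, lab3 == c_]))
    expect_equal(unname(pr$p_in[i]),
                 if (sum(s_in_c) > 0) 1 - sum((s_in_c / sum(s_in_c))^2) else 0)
    expect_equal(unname(pr$p_out[i]),
                 if (sum(s_out_c) > 0) 1 - sum((s_out_c / sum(s_out_c))^2) else 0)
  }
  # invariant: p <= 1 - 1/C
  C <- max(lab3 <- connectocore:::relabel_partition(lab3))
  expect_true(all(pr$p_in <= 1 - 1 / C + 1e-12))
  expect_true(all(pr$p_out <= 1 - 1 / C + 1e-12))
})

test_that("participation rank profile: identical partitions and a designed connector", {
  g <- rand_digraph(12, 0.4, seed = 9)
  lab <- rep(1:3, each = 4)
  single <- participation_rank_profile(g, list(lab))
  expect_equal(unname(single$rank_in), unname(rank(participation(g, lab)$p_in)))
  multi <- participation_rank_profile(g, list(lab, lab, lab))
  expect_equal(multi$rank_in, single$rank_in)
  # rank aggregation invariant to monotone transforms: ranks only
  # planted connector: one node wired equally into every block
  spec <- synthetic_spec(n = 40, target_density = 0.25,
                         community_sizes = rep(10, 4),
                         within_between_ratio = 8, seed = 12)
  gm <- generate_modular(spec)
  w <- rbind(cbind(gm$weights, 0.5), 0.5)
  diag(w) <- 0
  gc <- connectome_graph(w)
  labs <- list(c(gm$meta$planted, 1L), c(gm$meta$planted, 2L))
  prof <- participation_rank_profile(gc, labs)
  expect_equal(unname(which.max(prof$rank_in)), 41L)
  expect_equal(unname(which.max(prof$rank_out)), 41L)
})

test_that("strength ratio: symmetric, source nodes, correlation defined", {
  gs <- symmetrize(rand_digraph(10, 0.4, seed = 2), "max")
  expect_warning(sr <- strength_ratio(gs), "undefined")
  expect_equal(unname(sr$ratio), rep(1, 10))
  expect_true(is.na(sr$correlation))
  # pure source flagged and excluded
  w <- matrix(0, 4, 4)
  w[1, 2] <- 1; w[2, 3] <- 0.5; w[3, 2] <- 0.25; w[2, 4] <- 0.3
  w[1, 3] <- 0.2; w[4, 2] <- 0.4
  sr2 <- strength_ratio(connectome_graph(w))
  expect_true(sr2$flagged[1])       # node 1 has no afferents
  expect_true(is.na(sr2$ratio[1]))
  g <- rand_digraph(20, 0.4, seed = 3)
  sr3 <- strength_ratio(g)
  s <- strengths(g)
  keep <- !sr3$flagged
  expect_equal(sr3$correlation,
               cor((s$s_in + s$s_out)[keep], (s$s_out / s$s_in)[keep]))
})

test_that("rich club: closed case and filter-and-count oracle", {
  g <- fixture_graph("complete", 6)
  ens <- build_ensemble(g, 5, 10, seed = 1)
  rc <- rich_club(g, ens)
  expect_true(all(rc$phi[!is.na(rc$phi)] == 1))
  expect_true(all(abs(rc$phi_norm[!is.na(rc$phi_norm)] - 1) < 1e-12))
  expect_null(rc$regime)
  gr <- rand_digraph(40, 0.15, seed = 4)
  ens2 <- build_ensemble(gr, 10, 10, seed = 2)
  rc2 <- rich_club(gr, ens2)
  for (i in seq_along(rc2$k_levels)) {
    expect_equal(rc2$phi[i], oracle_phi(gr$weights, rc2$k_levels[i]))
  }
  # keep_geq flips the filter convention
  rc3 <- rich_club(gr, ens2, keep_geq = TRUE)
  for (i in seq_along(rc3$k_levels)) {
    expect_equal(rc3$phi[i], oracle_phi(gr$weights, rc3$k_levels[i], TRUE))
  }
  # surviving-node count is non-increasing in k
  a <- gr$weights > 0
  deg <- rowSums(a) + colSums(a)
  surv <- sapply(rc2$k_levels, function(k) sum(deg > k))
  expect_true(all(diff(surv) <= 0))
  expect_true(all(rc2$phi[!is.na(rc2$phi)] >= 0 & rc2$phi[!is.na(rc2$phi)] <= 1))
})

test_that("a dense core stands out against rewired nulls", {
  # planted rich club: 8 core nodes fully interconnected, sparse periphery
  set.seed(21)
  n <- 30
  w <- matrix(as.numeric(runif(n * n) < 0.08), n, n)
  w[1:8, 1:8] <- 1
  diag(w) <- 0
  g <- connectome_graph(w * matrix(runif(n * n, 0.5, 1), n, n))
  ens <- build_ensemble(g, 60, 10, seed = 5)
  rc <- rich_club(g, ens)
  expect_false(is.null(rc$regime))
  expect_true(any(rc$phi_norm > 1.1, na.rm = TRUE))
})
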