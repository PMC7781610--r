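test_that("strengths: closed cases and transpose symmetry", {
  s <- strengths(fixture_graph("complete", 4))
  expect_equal(unname(s$s_in), rep(3, 4))
  expect_equal(unname(s$s_out), rep(3, 4))
  w <- matrix(0, 3, 3); w[1, 2] <- 0.5
  s2 <- strengths(connectome_graph(w))
  expect_equal(unname(s2$s_in[3]), 0)   # isolated node
  expect_equal(unname(s2$s_out[3]), 0)
  g <- rand_digraph(10, 0.4, seed = 1)
  gt <- connectome_graph(t(g$weights))
  expect_equal(unname(strengths(g)$s_in), unname(strengths(gt)$s_out))
})

test_that("reciprocity matches the direct double-sum oracle", {
  g <- rand_digraph(8, 0.4, seed = 2)
  expect_equal(reciprocity(symmetrize(g, "max")), 1)
  # asymmetric: positive upper triangle only -> negative reciprocity
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.8; w[1, 4] <- 0.7
  ga <- connectome_graph(w)
  expect_equal(reciprocity(ga), oracle_reciprocity(w))
  expect_lt(reciprocity(ga), 0)
  for (s in 1:5) {
    gr <- rand_digraph(9, 0.35, seed = s)
    expect_equal(reciprocity(gr), oracle_reciprocity(gr$weights))
  }
  expect_warning(val <- reciprocity(connectome_graph(matrix(1, 3, 3) - diag(3))),
                 "variance")
  expect_true(is.na(val))
})

test_that("assortativity matches the edge-list oracle; regular graph undefined", {
  st <- fixture_graph("star", 6)
  expect_equal(suppressWarnings(assortativity(st, "degree")),
               suppressWarnings(oracle_assortativity(st$weights, "degree")))
  for (s in 1:5) {
    g <- rand_digraph(10, 0.3, seed = 10 + s)
    expect_equal(assortativity(g, "strength"),
                 oracle_assortativity(g$weights, "strength"))
    expect_equal(assortativity(g, "degree"),
                 oracle_assortativity(g$weights, "degree"))
  }
  reg <- fixture_graph("directed_cycle", 6)   # 1-regular
  expect_warning(v <- assortativity(reg, "degree"), "variance")
  expect_true(is.na(v))
})

test_that("clustering: closed cases and triangle-enumeration oracle", {
  cc <- clustering_coefficient(fixture_graph("complete", 5))
  expect_equal(unname(cc$per_node), rep(1, 5))
  expect_equal(cc$mean, 1)
  cs <- clustering_coefficient(fixture_graph("star", 6))
  expect_equal(unname(cs$per_node[1]), 0)     # hub: neighbors unconnected
  expect_equal(cs$n_undefined, 5)             # leaves have a single neighbor
  for (s in 1:5) {
    g <- rand_digraph(6, 0.5, seed = 20 + s)
    expect_equal(unname(clustering_coefficient(g)$per_node),
                 oracle_clustering(g$weights))
  }
})

test_that("characteristic path length conventions", {
  cy <- fixture_graph("directed_cycle", 4)
  L <- ifelse(cy$weights > 0, 1, Inf)
  expect_equal(characteristic_path_length(L, "arithmetic")$value, 2)
  # two disconnected reciprocal dyads: 4 reachable pairs of distance 1,
  # 8 unreachable pairs contribute zero inverse distance
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
  Ld <- ifelse(w > 0, 1, Inf)
  res <- characteristic_path_length(Ld, "harmonic")
  expect_equal(res$value, 12 / 4)
  expect_equal(res$n_unreachable, 8)
  ra <- characteristic_path_length(Ld, "arithmetic")
  expect_equal(ra$value, 1)
  expect_equal(ra$n_unreachable, 8)
  # shortest paths actually relay through intermediate nodes
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- 1; w2[2, 3] <- 1; w2[1, 3] <- 0.001
  g2 <- connectome_graph(w2)
  D <- characteristic_path_length(g2)$distances
  expect_equal(unname(D[1, 3]), 0)   # via the two max-weight edges
  expect_error(characteristic_path_length(matrix(Inf, 3, 3)), "reachable")
})

test_that("small-world indices: self-ensemble identity and sigma identity", {
  g <- rand_digraph(15, 0.3, seed = 3)
  self_ens <- build_ensemble(g, 1, swaps_per_edge = 0, seed = 1)
  sw <- small_world(g, self_ens)
  expect_equal(sw$gamma_norm, 1)
  expect_equal(sw$lambda_norm, 1)
  expect_equal(sw$sigma, 1)
  ens <- build_ensemble(g, 10, 10, seed = 2)
  sw2 <- small_world(g, ens)
  expect_equal(sw2$sigma * sw2$lambda_norm, sw2$gamma_norm)
})

test_that("geometric graphs are small-world relative to rewired nulls", {
  hits <- 0
  for (s in 1:20) {
    g <- generate_geometric(synthetic_spec(n = 30, target_density = 0.2,
                                           decay_rate = 0.25, seed = 500 + s))
    ens <- build_ensemble(g, 10, 10, seed = s)
    hits <- hits + (small_world(g, ens)$sigma > 1)
  }
  expect_gte(hits, 19)
})

test_that("null members change topology but not total weight", {
  g <- rand_digraph(20, 0.3, seed = 6)
  r <- maslov_sneppen_rewire(g, 10, seed = 7)
  expect_equal(sum(r$weights), sum(g$weights))
  expect_false(isTRUE(all.equal(clustering_coefficient(r)$mean,
                                clustering_coefficient(g)$mean)))
})
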