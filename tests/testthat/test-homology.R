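test_that("filtration orders edges by decreasing weight with stable ties", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.1
  f <- build_filtration(connectome_graph(w))
  ed <- f$simplices$dim == 1
  expect_equal(f$simplices$rank[ed], 1:3)
  expect_equal(f$vertices[which(ed)[1]][[1]], c(1, 2))
  expect_equal(f$vertices[which(ed)[3]][[1]], c(3, 4))
  # metric value of the first edge is 0 (max weight), increasing afterwards
  expect_equal(f$simplices$value[which(ed)[1]], 0)
  expect_true(all(diff(f$simplices$value[ed]) >= 0))
  # triangle enters with its weakest edge
  wt <- matrix(0, 3, 3)
  wt[1, 2] <- wt[2, 1] <- 0.9; wt[1, 3] <- wt[3, 1] <- 0.8
  wt[2, 3] <- wt[3, 2] <- 0.7
  ft <- build_filtration(connectome_graph(wt))
  tri <- ft$simplices$dim == 2
  expect_equal(sum(tri), 1)
  expect_equal(ft$simplices$rank[tri], 3L)
  # ties: repeated builds identical
  g <- fixture_graph("octahedron")
  f1 <- build_filtration(g)
  f2 <- build_filtration(g)
  expect_identical(f1$vertices, f2$vertices)
  expect_identical(f1$simplices, f2$simplices)
  expect_error(build_filtration(g, max_dim = 4), "max_dim")
})

test_that("closed-form diagrams: circle, sphere, contractible complex", {
  d_sq <- persistent_homology(build_filtration(fixture_graph("square_c4")))
  h1 <- d_sq[d_sq$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 4)
  expect_equal(h1$death, Inf)
  expect_equal(unname(betti_numbers(d_sq)), c(1L, 1L, 0L))
  d_oct <- persistent_homology(build_filtration(fixture_graph("octahedron")))
  expect_equal(unname(betti_numbers(d_oct)), c(1L, 0L, 1L))
  d_k6 <- persistent_homology(build_filtration(fixture_graph("complete", 6)))
  expect_equal(unname(betti_numbers(d_k6)), c(1L, 0L, 0L))
  expect_true(all(d_oct$death >= d_oct$birth))
})

test_that("H0 bars track union-find components at every filtration step", {
  for (s in 1:3) {
    g <- symmetrize(rand_digraph(10, 0.2, seed = 60 + s), "max")
    f <- build_filtration(g)
    dg <- persistent_homology(f)
    for (t in 0:f$n_edges) {
      expect_equal(betti_from_bars(dg, 0, t), oracle_components_at(f, t))
    }
  }
})

test_that("Betti curves match the boundary-rank oracle on small graphs", {
  for (s in 1:3) {
    g <- symmetrize(rand_digraph(8, 0.45, seed = 70 + s), "max")
    f <- build_filtration(g, max_dim = 3)
    dg <- persistent_homology(f)
    for (t in unique(c(0, ceiling(f$n_edges / 2), f$n_edges))) {
      bet <- oracle_betti_at(f, t, max_hdim = 2)
      expect_equal(sapply(0:2, function(d) betti_from_bars(dg, d, t)), bet)
    }
  }
  # octahedron: full Euler characteristic audit across all steps
  f <- build_filtration(fixture_graph("octahedron"), max_dim = 3)
  dg <- persistent_homology(f)
  for (t in 0:f$n_edges) {
    bet <- oracle_betti_at(f, t, max_hdim = 2)
    expect_equal(sapply(0:2, function(d) betti_from_bars(dg, d, t)), bet)
    kept <- f$simplices$rank <= t
    chi_simplices <- sum((-1)^f$simplices$dim[kept])
    expect_equal(chi_simplices, sum(bet * c(1, -1, 1)))
  }
})

test_that("diagram is invariant under node relabeling", {
  g <- symmetrize(rand_digraph(9, 0.35, seed = 80), "max")
  dg <- persistent_homology(build_filtration(g))
  set.seed(80)
  p <- sample(9)
  gp <- connectome_graph(g$weights[p, p])
  dgp <- persistent_homology(build_filtration(gp))
  cols <- c("dimension", "birth", "death")
  expect_equal(dg[cols], dgp[cols], ignore_attr = TRUE)
})

test_that("representative cycles name the nodes of a planted ring", {
  # strong chordless 8-ring among nodes 1..8; weak background elsewhere
  set.seed(91)
  n <- 14
  w <- matrix(as.numeric(runif(n * n) < 0.4) * runif(n * n, 0.01, 0.2), n, n)
  w[1:8, ] <- 0
  w[, 1:8] <- 0
  ring <- cbind(1:8, c(2:8, 1))
  w[ring] <- runif(8, 0.9, 1)
  w[ring[, c(2, 1)]] <- runif(8, 0.9, 1)
  diag(w) <- 0
  g <- connectome_graph(w)
  ens <- build_ensemble(g, 15, 10, seed = 9)
  cav <- cavity_significance(g, ens, top_m = 3)
  top1 <- cav$top_bars$H1[1, ]
  expect_equal(top1$dimension, 1)
  nodes <- strsplit(top1$nodes, ",")[[1]]
  expect_true(all(paste0("n", 1:8) %in% nodes))
  expect_true(all(c("p_n_long", "p_longest") %in% names(cav$summary)))
})

test_that("a null member shows no cavity excess against its own ensemble", {
  base <- rand_digraph(15, 0.25, seed = 95)
  calm <- 0
  for (t in 1:20) {
    g <- maslov_sneppen_rewire(base, 10, seed = 200 + t)
    ens <- build_ensemble(g, 20, 10, seed = 300 + t)
    cav <- cavity_significance(g, ens, dims = 1)
    calm <- calm + (cav$summary$p_n_long[1] > 0.05)
  }
  expect_gte(calm, 18)
})
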