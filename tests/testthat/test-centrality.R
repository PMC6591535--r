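test_that("to_weights applies the compression transform", {
  D <- dm(matrix(c(0, 0, 0, 0), 2, 2), ids = c("a", "b"))
  net0 <- to_weights(D)
  expect_lt(abs(net0$W["a", "b"] - 1), 1e-15)  # w(d = 0) ~ 1
  expect_identical(diag(net0$W), c(a = 0, b = 0))

  D2 <- dm_edges(c("a", "b"), list(), fill = 1e-100)
  net2 <- to_weights(D2, q = 0.01)
  expect_equal(net2$Dt["a", "b"], 0.1)
  expect_equal(net2$W["a", "b"], 1 / 1.1)

  D3 <- dm_edges(c("a", "b"), list(), fill = 1)
  expect_equal(to_weights(D3)$W["a", "b"], 0.5)

  expect_error(to_weights(D, q = 0), "q must be > 0")
  expect_error(to_weights(D, delta = 0), "delta")
})

test_that("weight is strictly decreasing in distance and stays in (0, 1]", {
  d <- sort(10^seq(-150, 1, length.out = 40))
  n <- length(d) + 1L
  m <- matrix(0, n, n)
  m[1, 2:n] <- d
  m[2:n, 1] <- d
  m[2:n, 2:n][upper.tri(matrix(0, n - 1, n - 1))] <- 5
  m <- pmax(m, t(m))
  diag(m) <- 0
  net <- to_weights(dm(m, sprintf("u%02d", 1:n)))
  w <- net$W[1, 2:n]
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_identical(net$W, t(net$W))
})

test_that("weighted degree sums incident weights", {
  # complete 3-graph with all weights 0.5 (d = 1, q = 1)
  Deq <- dm_edges(c("a", "b", "c"), list(), fill = 1)
  expect_equal(unname(weighted_degree(to_weights(Deq, q = 1))), rep(1, 3))

  # star weights 0.9 center-leaf, 0.1 leaf-leaf (invert w = 1/(d+1))
  ids <- c("ctr", "l1", "l2", "l3")
  D <- dm_edges(ids, list(list("ctr", "l1", 1 / 9), list("ctr", "l2", 1 / 9),
                          list("ctr", "l3", 1 / 9)), fill = 9)
  wd <- weighted_degree(to_weights(D, q = 1))
  expect_equal(unname(wd["ctr"]), 2.7, tolerance = 1e-12)
  expect_equal(unname(wd["l1"]), 1.1, tolerance = 1e-12)

  D1 <- dm(matrix(0, 1, 1), "a")
  expect_equal(unname(weighted_degree(to_weights(D1))), 0)
})

test_that("closeness follows shortest paths, not matrix entries", {
  # path a-b-c: absent edge modeled by thresholding
  Dp <- dm_edges(c("a", "b", "c"),
                 list(list("a", "b", 1), list("b", "c", 1)), fill = 5)
  gd <- threshold_graph(Dp, t = 1, q = 1)
  cc <- setNames(gd$nodes$closeness, gd$nodes$id)
  expect_equal(unname(cc["b"]), 1, tolerance = 1e-12)
  expect_equal(unname(cc[c("a", "c")]), c(2 / 3, 2 / 3), tolerance = 1e-12)

  # complete graph with equal transformed distance t -> all closeness 1/t
  Deq <- dm_edges(c("a", "b", "c", "d"), list(), fill = 0.25)
  cc2 <- closeness(to_weights(Deq, q = 1))
  expect_equal(unname(cc2), rep(4, 4), tolerance = 1e-12)

  # triangle where the direct edge is longer than the two-hop route
  Dt <- dm(matrix(c(0, 5, 1, 5, 0, 1, 1, 1, 0), 3, 3), c("a", "b", "c"))
  cc3 <- closeness(to_weights(Dt, q = 1))
  expect_equal(unname(cc3["a"]), 2 / 3, tolerance = 1e-12)
})

test_that("betweenness counts shortest-path pass-throughs", {
  # star: center bridges all 3 leaf pairs
  ids <- c("ctr", "l1", "l2", "l3")
  Ds <- dm_edges(ids, list(list("ctr", "l1", 0.5), list("ctr", "l2", 0.5),
                           list("ctr", "l3", 0.5)), fill = 2)
  gd <- threshold_graph(Ds, t = 1, q = 1)
  bt <- setNames(gd$nodes$betweenness, gd$nodes$id)
  expect_equal(unname(bt["ctr"]), 3)
  expect_equal(unname(bt[c("l1", "l2", "l3")]), c(0, 0, 0))

  # path a-b-c-d: inner nodes 2; edge (b,c) carries 4 pairs
  Dp <- dm_edges(c("a", "b", "c", "d"),
                 list(list("a", "b", 0.5), list("b", "c", 0.5),
                      list("c", "d", 0.5)), fill = 2)
  gp <- threshold_graph(Dp, t = 1, q = 1)
  btp <- setNames(gp$nodes$betweenness, gp$nodes$id)
  expect_equal(unname(btp), c(0, 2, 2, 0))
  e_bc <- gp$edges[gp$edges$source == "b" & gp$edges$target == "c", ]
  expect_equal(e_bc$betweenness, 4)

  # complete equal graph: every direct edge is the unique shortest path
  Deq <- dm_edges(c("a", "b", "c", "d"), list(), fill = 0.7)
  bteq <- betweenness(to_weights(Deq, q = 1))
  expect_equal(unname(bteq$node), rep(0, 4))
})

test_that("eigenvector centrality matches symmetry and the dense solver", {
  Deq <- dm_edges(c("a", "b", "c"), list(), fill = 1)
  net <- to_weights(Deq, q = 1)           # all weights 0.5
  ev <- eigenvector_centrality(net)
  expect_equal(unname(ev$vector), rep(1 / sqrt(3), 3), tolerance = 1e-10)
  expect_equal(ev$lambda, 1, tolerance = 1e-10)

  for (seed in c(2, 7, 19)) {
    D <- symmetrize(random_evalue_table(6, asymmetry = 2, seed = seed))
    net <- to_weights(D)
    got <- eigenvector_centrality(net)
    es <- eigen(net$W, symmetric = TRUE)
    ref <- es$vectors[, 1]
    if (sum(ref) < 0) ref <- -ref
    expect_lt(max(abs(got$vector - ref)), 1e-9)
    expect_lt(abs(got$lambda - es$values[1]), 1e-9)
    expect_gt(got$lambda, 0)
  }
})

test_that("disconnected graphs compute eigenvector per component with warning", {
  D <- dm_edges(c("a", "b", "c", "d"),
                list(list("a", "b", 0.5), list("c", "d", 0.5)), fill = 2)
  expect_warning(threshold_graph(D, t = 1, q = 1), "disconnected")
  gd <- suppressWarnings(threshold_graph(D, t = 1, q = 1))
  evc <- setNames(gd$nodes$eigenvector, gd$nodes$id)
  expect_equal(unname(evc), rep(1 / sqrt(2), 4), tolerance = 1e-10)
  cc <- setNames(gd$nodes$closeness, gd$nodes$id)
  expect_equal(unname(cc), rep(2, 4), tolerance = 1e-12)  # |V|=2 per comp
})

test_that("threshold_graph keeps edges at or below the cutoff", {
  D <- dm_edges(c("a", "b", "c"),
                list(list("a", "b", 1e-150), list("a", "c", 1e-60),
                     list("b", "c", 1e-10)), fill = 0)
  suppressWarnings({
    expect_equal(nrow(threshold_graph(D, 1e-50)$edges), 2L)
    expect_equal(nrow(threshold_graph(D, 0)$edges), 0L)
  })
  expect_equal(nrow(threshold_graph(D, Inf)$edges), 3L)

  # monotone edge count in t
  D2 <- symmetrize(random_evalue_table(7, asymmetry = 2, seed = 3))
  counts <- vapply(c(0, 1e-80, 1e-50, 1e-20, 1, Inf), function(t) {
    suppressWarnings(nrow(threshold_graph(D2, t)$edges))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("centralities on sparse graphs equal the enumeration oracle", {
  for (seed in 1:25) {
    n <- 3L + (seed %% 4L)
    D <- random_connected_dm(n, seed = seed)
    gd <- threshold_graph(D, t = 1, q = 1)
    orc <- oracle_centrality(D$ids, lengths_from_dm(D))
    expect_lt(max(abs(gd$nodes$closeness - orc$closeness)), 1e-9)
    expect_lt(max(abs(gd$nodes$betweenness - orc$node_betweenness)), 1e-9)
    for (i in seq_len(nrow(gd$edges))) {
      key <- paste(gd$edges$source[i], gd$edges$target[i])
      ref <- orc$edge_betweenness[[key]] %||% 0
      expect_lt(abs(gd$edges$betweenness[i] - ref), 1e-9)
    }
  }
})

test_that("zero-distance clique members share closeness and eigenvector", {
  spec <- planted_spec(list(c(6, 4)), list(c(-80, -40), c(-8, -6)),
                       zero_core_fraction = 0.5, seed = 31)
  pl <- planted_cluster_matrix(spec)
  core <- find_core(pl$matrix, pl$truth[[1]]$clusters[[1]])
  expect_gte(length(core), 2L)
  net <- to_weights(pl$matrix)
  cc <- closeness(net)[core]
  ev <- eigenvector_centrality(net)$vector[core]
  expect_lt(diff(range(cc)), 1e-12)
  expect_lt(diff(range(ev)), 1e-12)
})

test_that("MST centrality graph computes measures on the tree", {
  # path tree: leaves have zero betweenness
  Dp <- dm(matrix(c(0, 1, 9, 1, 0, 1, 9, 1, 0), 3, 3), c("a", "b", "c"))
  gp <- mst_centrality_graph(Dp, q = 1)
  btp <- setNames(gp$nodes$betweenness, gp$nodes$id)
  expect_equal(unname(btp[c("a", "c")]), c(0, 0))
  expect_equal(unname(btp["b"]), 1)
  expect_true(all(gp$edges$role == "tree"))

  # star tree: center carries all 3 leaf pairs
  ids <- c("ctr", "l1", "l2", "l3")
  Ds <- dm_edges(ids, list(list("ctr", "l1", 0.1), list("ctr", "l2", 0.1),
                           list("ctr", "l3", 0.1)), fill = 5)
  gs <- mst_centrality_graph(Ds, q = 1)
  expect_equal(gs$nodes$betweenness[gs$nodes$id == "ctr"], 3)

  # seeded random tree equals the oracle on the tree's transformed lengths
  D <- symmetrize(random_evalue_table(6, asymmetry = 1, seed = 17))
  g6 <- mst_centrality_graph(D)
  L <- matrix(Inf, 6, 6)
  ei <- cbind(match(g6$edges$source, D$ids), match(g6$edges$target, D$ids))
  dt <- g6$edges$distance^0.01 + 1e-200
  L[ei] <- dt
  L[ei[, c(2, 1)]] <- dt
  orc <- oracle_centrality(D$ids, L)
  expect_lt(max(abs(g6$nodes$closeness - orc$closeness)), 1e-9)
  expect_lt(max(abs(g6$nodes$betweenness - orc$node_betweenness)), 1e-9)
})
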