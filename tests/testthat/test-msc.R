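test_that("nearest-neighbor linkage recovers separated pairs", {
  D <- dm_edges(c("a", "b", "c", "d"),
                list(list("a", "b", 1e-60), list("c", "d", 1e-60)),
                fill = 1e-3)
  p <- nearest_neighbor_partition(D)
  expect_true(same_partition(p$clusters, list(c("a", "b"), c("c", "d"))))
})

test_that("nearest-neighbor linkage handles singletons and full ties", {
  D1 <- dm(matrix(0, 1, 1), ids = "a")
  expect_identical(nearest_neighbor_partition(D1)$clusters, list("a"))

  # equal distances: every unit links to the lexicographic minimum
  Deq <- dm_edges(c("a", "b", "c"), list(), fill = 0.5)
  p <- nearest_neighbor_partition(Deq)
  expect_identical(p$clusters, list(c("a", "b", "c")))
})

test_that("build_hierarchy nests partitions and stops at one cluster", {
  spec <- planted_spec(list(c(2, 2, 3, 2), c(2, 2)),
                       list(c(-80, -60), c(-25, -15), c(-6, -4)), seed = 4)
  pl <- planted_cluster_matrix(spec)
  h <- build_hierarchy(pl$matrix, max_levels = 5)
  expect_equal(length(h$levels), 3L)
  # nesting: every level-(k+1) cluster is a union of level-k clusters
  for (k in seq_len(length(h$levels) - 1L)) {
    memb <- membership_of(h$levels[[k]]$clusters,
                          sort(pl$matrix$ids, method = "radix"))
    for (cl in h$levels[[k + 1L]]$clusters) {
      sub <- membership_of(h$levels[[k]]$clusters, cl)
      # each fine cluster fully inside or fully outside
      for (g in unique(sub)) {
        fine <- h$levels[[k]]$clusters[[g]]
        expect_true(all(fine %in% cl))
      }
    }
  }
  # recovery of the planted truth at every level
  for (k in seq_along(pl$truth)) {
    expect_true(same_partition(h$levels[[k]]$clusters, pl$truth[[k]]$clusters))
  }
})

test_that("build_hierarchy degenerate inputs", {
  D1 <- dm(matrix(0, 1, 1), ids = "a")
  h1 <- build_hierarchy(D1)
  expect_equal(length(h1$levels), 1L)
  expect_identical(h1$levels[[1]]$clusters, list("a"))

  # already one NN-component at level 1 -> single level regardless of cap
  Deq <- dm_edges(c("a", "b", "c"), list(), fill = 0.5)
  expect_equal(length(build_hierarchy(Deq, max_levels = 3)$levels), 1L)
})

test_that("inter_cluster_distance is the single-linkage minimum", {
  D <- dm_edges(c("a", "b", "c"),
                list(list("a", "c", 1e-5), list("b", "c", 1e-9)),
                fill = 1e-2)
  expect_equal(inter_cluster_distance(D, "a", "b"), 1e-2)
  expect_equal(inter_cluster_distance(D, c("a", "b"), "c"), 1e-9)
  expect_error(inter_cluster_distance(D, c("a", "b"), c("b", "c")), "overlap")
  expect_error(inter_cluster_distance(D, character(0), "c"), "non-empty")
})

test_that("MST weight equals the exhaustive enumeration minimum", {
  for (seed in 1:12) {
    n <- 4L + (seed %% 4L)  # sizes 4..7
    D <- symmetrize(random_evalue_table(n, asymmetry = 2, seed = seed))
    mst <- minimum_spanning_tree(D)
    expect_equal(nrow(mst$edges), n - 1L)
    expect_equal(sum(mst$edges$distance), oracle_min_spanning_weight(D))
  }
})

test_that("MST tie-breaking and small cases are deterministic", {
  D2 <- dm_edges(c("a", "b"), list(), fill = 0.7)
  mst2 <- minimum_spanning_tree(D2)
  expect_equal(nrow(mst2$edges), 1L)
  expect_equal(mst2$edges$distance, 0.7)

  Deq <- dm_edges(c("a", "b", "c"), list(), fill = 0.5)
  msteq <- minimum_spanning_tree(Deq)
  got <- msteq$edges[c("source", "target")]
  expect_identical(got, data.frame(source = c("a", "a"),
                                   target = c("b", "c"),
                                   stringsAsFactors = FALSE))

  expect_equal(nrow(minimum_spanning_tree(dm(matrix(0, 1, 1), "a"))$edges), 0L)
})

test_that("find_core extracts maximal zero-distance cliques", {
  # zero triangle inside a larger cluster
  D <- dm_edges(c("a", "b", "c", "d", "e"),
                list(list("a", "b", 0), list("a", "c", 0), list("b", "c", 0)),
                fill = 1e-4)
  expect_identical(find_core(D, c("a", "b", "c", "d", "e")), c("a", "b", "c"))

  # no zero pairs
  expect_identical(find_core(D, c("d", "e")), character(0))

  # zero chain a-b, b-c with d(a,c) > 0: greedy keeps {a, b}
  Dch <- dm_edges(c("a", "b", "c"),
                  list(list("a", "b", 0), list("b", "c", 0)),
                  fill = 1e-4)
  expect_identical(find_core(Dch, c("a", "b", "c")), c("a", "b"))
  expect_error(find_core(Dch, character(0)), "non-empty")
})

test_that("find_core output always satisfies the all-pairs-zero predicate", {
  for (seed in 1:8) {
    spec <- planted_spec(list(c(4, 3, 5)),
                         list(c(-60, -40), c(-6, -4)),
                         zero_core_fraction = 0.6, seed = seed)
    pl <- planted_cluster_matrix(spec)
    for (cl in pl$truth[[1]]$clusters) {
      core <- find_core(pl$matrix, cl)
      if (length(core) >= 2L) {
        expect_true(all(pl$matrix$d[core, core] == 0))
      }
    }
  }
})

ann_lines <- function(rows) {
  read_annotations(c("id,family,class,prefix,structures", rows))
}

test_that("name_clusters numbers by decreasing size within a prefix", {
  ids <- sprintf("p%02d", 1:10)
  ann <- ann_lines(sprintf("%s,Peptide receptors,ClassA,Pe,", ids))
  p <- structure(list(level = 1L,
                      clusters = list(ids[1:5], ids[6:8], ids[9:10]),
                      unit_kind = "sequence"),
                 class = "partition")
  labs <- name_clusters(p, ann)
  expect_identical(labs, c("Pe001", "Pe002", "Pe003"))

  # unknown members fall back to the Un prefix
  pu <- structure(list(level = 1L, clusters = list(c("x", "y")),
                       unit_kind = "sequence"), class = "partition")
  expect_identical(name_clusters(pu, NULL), "Un001")

  # equal sizes: 001 goes to the cluster holding the smaller id
  pt <- structure(list(level = 1L,
                       clusters = list(c("p03", "p04"), c("p01", "p02"))),
                  class = "partition")
  expect_identical(name_clusters(pt, ann), c("Pe002", "Pe001"))
})

test_that("annotate_partition takes the majority family with lexicographic ties", {
  ann <- ann_lines(c("a,Peptide,ClassA,Pe,", "b,Peptide,ClassA,Pe,",
                     "c,Peptide,ClassA,Pe,", "d,Olfactory,ClassA,Ol,",
                     "e,Amine,ClassA,Am,", "f,Bitter,ClassT,Ta,"))
  p <- structure(list(level = 1L,
                      clusters = list(c("a", "b", "c", "d"), c("e", "f"),
                                      c("zz1", "zz2"))),
                 class = "partition")
  out <- annotate_partition(p, ann)
  expect_identical(out$family, c("Peptide", "Amine", "unknown"))
  expect_identical(out$class[2], "ClassA")  # ClassA < ClassT
})

test_that("cluster structure is invariant under order-preserving relabeling", {
  ev <- random_evalue_table(8, asymmetry = 2, seed = 13)
  D <- symmetrize(ev)
  # order-preserving bijection of ids
  map <- setNames(sprintf("t%03d", seq_along(D$ids)),
                  sort(D$ids, method = "radix"))
  d2 <- D$d
  rownames(d2) <- colnames(d2) <- unname(map[rownames(d2)])
  D2 <- distance_matrix(d2, meta = "synthetic")
  h1 <- build_hierarchy(D, max_levels = 3)
  h2 <- build_hierarchy(D2, max_levels = 3)
  expect_equal(length(h1$levels), length(h2$levels))
  for (k in seq_along(h1$levels)) {
    mapped <- lapply(h1$levels[[k]]$clusters, function(cl) unname(map[cl]))
    expect_true(same_partition(mapped, h2$levels[[k]]$clusters))
  }
})
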