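# Independent oracles: exhaustive enumeration implementations used to check
# the package's graph algorithms on small instances. Deliberately naive.

# distance matrix from an explicit symmetric matrix
dm <- function(m, ids = NULL, meta = "synthetic") {
  m <- as.matrix(m)
  if (is.null(ids)) ids <- letters[seq_len(nrow(m))]
  dimnames(m) <- list(ids, ids)
  distance_matrix(m, meta = meta)
}

# distance matrix with all off-diagonal entries `fill`, then explicit pairs
dm_edges <- function(ids, edges, fill) {
  n <- length(ids)
  m <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  for (e in edges) {
    m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  }
  distance_matrix(m, meta = "synthetic")
}

# ---- exhaustive shortest-path oracle -------------------------------------
# L: symmetric edge-length matrix, Inf = no edge, diag Inf.
# Enumerates ALL simple paths per pair; shortest-path set under relative
# tolerance tol; returns closeness, node betweenness, edge betweenness.
oracle_centrality <- function(ids, L, tol = 1e-12) {
  n <- length(ids)
  paths_between <- function(j, k) {
    res <- list()
    walk <- function(v, visited, len, edges) {
      for (u in seq_len(n)) {
        if (u %in% visited || !is.finite(L[v, u])) next
        len2 <- len + L[v, u]
        e2 <- c(edges, list(sort(c(v, u))))
        if (u == k) {
          res[[length(res) + 1L]] <<- list(len = len2,
                                           interior = setdiff(visited, j),
                                           edges = e2)
        } else {
          walk(u, c(visited, u), len2, e2)
        }
      }
    }
    walk(j, j, 0, list())
    res
  }
  S <- matrix(Inf, n, n)
  diag(S) <- 0
  node_bt <- setNames(numeric(n), ids)
  ekey <- function(e) paste(ids[e[1]], ids[e[2]])
  edge_bt <- list()
  for (j in seq_len(n - 1L)) {
    for (k in seq(j + 1L, n)) {
      ps <- paths_between(j, k)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, 0, "len")
      best <- min(lens)
      S[j, k] <- S[k, j] <- best
      sel <- abs(lens - best) <= tol * pmax(lens, best)
      g <- sum(sel)
      for (p in ps[sel]) {
        for (u in p$interior) node_bt[u] <- node_bt[u] + 1 / g
        for (e in p$edges) {
          key <- ekey(e)
          edge_bt[[key]] <- (edge_bt[[key]] %||% 0) + 1 / g
        }
      }
    }
  }
  cc <- setNames(numeric(n), ids)
  for (u in seq_len(n)) {
    members <- which(is.finite(S[u, ]))
    cc[u] <- if (length(members) < 2L) 0 else
      (length(members) - 1) / sum(S[u, members])
  }
  list(S = S, closeness = cc, node_betweenness = node_bt,
       edge_betweenness = edge_bt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exhaustive spanning-tree oracle -------------------------------------
# all labeled spanning trees of K_n via Pruefer sequences; cached per n
pruefer_trees <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    decode <- function(pr) {
      degree <- rep(1L, n)
      for (x in pr) degree[x] <- degree[x] + 1L
      edges <- matrix(0L, n - 1L, 2L)
      ptr <- 0L
      for (x in pr) {
        leaf <- which(degree == 1L)[1L]
        ptr <- ptr + 1L
        edges[ptr, ] <- c(leaf, x)
        degree[leaf] <- degree[leaf] - 1L
        degree[x] <- degree[x] - 1L
      }
      last <- which(degree == 1L)
      edges[n - 1L, ] <- last
      edges
    }
    trees <- if (n == 2L) {
      list(matrix(c(1L, 2L), 1L, 2L))
    } else {
      seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
      lapply(seq_len(nrow(seqs)), function(i) decode(seqs[i, ]))
    }
    cache[[key]] <<- trees
    trees
  }
})

oracle_min_spanning_weight <- function(D) {
  n <- length(D$ids)
  trees <- pruefer_trees(n)
  min(vapply(trees, function(ed) sum(D$d[ed]), 0))
}

# ---- AUC pair-counting oracle --------------------------------------------
oracle_auc <- function(d_min, labels) {
  pos <- d_min[labels == "positive" | labels == TRUE]
  neg <- d_min[labels == "negative" | labels == FALSE]
  cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}

# ---- partition helpers ----------------------------------------------------
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(x, method = "radix"))
  cl[order(vapply(cl, `[`, "", 1L), method = "radix")]
}

same_partition <- function(a, b) {
  identical(canonical_partition(a), canonical_partition(b))
}

membership_of <- function(clusters, ids) {
  mem <- setNames(rep(seq_along(clusters), lengths(clusters)),
                  unlist(clusters))
  unname(mem[ids])
}

# ---- random connected sparse graph as a thresholded distance matrix ------
# kept edges get d in (0.1, 1), removed pairs d = 2; threshold at t = 1 with
# q = 1 makes edge lengths ~ d. Connectivity via a random spanning tree.
random_connected_dm <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    m <- matrix(2, n, n, dimnames = list(ids, ids))
    diag(m) <- 0
    if (n >= 2L) {
      perm <- sample(n)
      for (k in seq(2L, n)) {
        j <- perm[sample(k - 1L, 1L)]
        m[perm[k], j] <- m[j, perm[k]] <- stats::runif(1, 0.1, 1)
      }
      for (a in seq_len(n - 1L)) {
        for (b in seq(a + 1L, n)) {
          if (m[a, b] == 2 && stats::runif(1) < 0.45) {
            m[a, b] <- m[b, a] <- stats::runif(1, 0.1, 1)
          }
        }
      }
    }
    distance_matrix(m, meta = "synthetic")
  })
}

# edge-length matrix (Inf = absent) of the kept edges of such a matrix
lengths_from_dm <- function(D, t = 1) {
  L <- D$d
  L[D$d > t] <- Inf
  diag(L) <- Inf
  L
}
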