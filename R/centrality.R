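#' Transform a distance matrix into a similarity network
#'
#' E-value-derived distances span more than 150 orders of magnitude, so the
#' raw distances are compressed before graph analysis: the transformed
#' distance is `dt = d^q + delta` off-diagonal (with `0^q` defined as 0) and
#' the edge weight is `w = 1/(dt + 1)`, giving weights in (0, 1] that
#' decrease strictly with distance. The offset `delta` (default `1e-200`)
#' keeps transformed distances positive so zero-distance pairs still carry a
#' well-defined, maximal weight just below 1. Diagonals of both matrices
#' are 0.
#'
#' @param D A [distance_matrix()].
#' @param q Compression exponent, `> 0` (default 0.01: a distance of
#'   `1e-100` maps to `0.1`).
#' @param delta Positive offset (default `1e-200`).
#' @return An object of class `similarity_network`: `ids`, `W`, `Dt`,
#'   `params`.
#' @export
to_weights <- function(D, q = 0.01, delta = 1e-200) {
  stopifnot(inherits(D, "distance_matrix"))
  if (!is.numeric(q) || q <= 0) stop_ssn("exponent q must be > 0")
  if (!is.numeric(delta) || delta <= 0) stop_ssn("delta must be > 0")
  Dt <- D$d^q + delta
  diag(Dt) <- 0
  W <- 1 / (Dt + 1)
  diag(W) <- 0
  structure(list(ids = D$ids, W = W, Dt = Dt,
                 params = list(q = q, delta = delta)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes (q = %g, delta = %g)\n",
              length(x$ids), x$params$q, x$params$delta))
  invisible(x)
}

# edge-length matrix of a similarity network: Inf marks absent edges/self
net_lengths <- function(net) {
  L <- net$Dt
  diag(L) <- Inf
  L
}

# relative tie tolerance for "equal" shortest-path lengths
close_len <- function(a, b, tol) abs(a - b) <= tol * pmax(a, b)

# shortest-path length matrix for an edge-length matrix (Inf = no edge)
splength_matrix <- function(L, ids) {
  fin <- which(is.finite(L) & upper.tri(L), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[fin[, 1]], to = ids[fin[, 2]],
               weight = L[fin], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  S <- igraph::distances(g, weights = igraph::E(g)$weight)
  S[ids, ids, drop = FALSE]
}

# shortest-path counts sigma[j, v] under relative tie tolerance. The
# predecessor DAG prefers strictly smaller source distance; nodes at exactly
# equal distance (possible when delta-scale edge lengths underflow a path
# sum) are ordered by processing position so the count stays well defined
# and acyclic
sigma_matrix <- function(L, S, tol) {
  n <- nrow(L)
  sigma <- matrix(0, n, n)
  for (j in seq_len(n)) {
    sigma[j, j] <- 1
    ord <- order(S[j, ])
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    for (v in ord) {
      if (v == j || !is.finite(S[j, v])) next
      cand <- which(is.finite(L[, v]) &
                      (S[j, ] < S[j, v] |
                         (S[j, ] == S[j, v] & pos < pos[v])))
      ok <- close_len(S[j, cand] + L[cand, v], S[j, v], tol)
      sigma[j, v] <- sum(sigma[j, cand[ok]])
    }
  }
  sigma
}

# all centrality measures for one edge-length matrix
centrality_engine <- function(ids, L, tol = 1e-12, power_tol = 1e-12,
                              power_max_iter = 10000L) {
  n <- length(ids)
  dimnames(L) <- NULL
  W <- 1 / (L + 1)
  W[!is.finite(L)] <- 0
  wd <- setNames(rowSums(W), ids)

  S <- splength_matrix(L, ids)
  dimnames(S) <- NULL
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[is.finite(S[i, ])] <- cid
    }
  }

  cc <- numeric(n)
  for (u in seq_len(n)) {
    members <- which(comp == comp[u])
    m <- length(members)
    cc[u] <- if (m < 2L) 0 else (m - 1) / sum(S[u, members])
  }

  sigma <- sigma_matrix(L, S, tol)
  bt <- numeric(n)
  eidx <- which(is.finite(L) & upper.tri(L), arr.ind = TRUE)
  ebt <- numeric(nrow(eidx))
  el <- L[eidx]
  eu <- eidx[, 1]
  ev <- eidx[, 2]
  for (j in seq_len(n - 1L)) {
    for (k in seq(j + 1L, n)) {
      if (comp[j] != comp[k]) next
      g_jk <- sigma[j, k]
      if (g_jk == 0) next
      sjk <- S[j, k]
      thru <- close_len(S[j, ] + S[, k], sjk, tol) & is.finite(S[j, ]) &
        is.finite(S[, k])
      thru[c(j, k)] <- FALSE
      bt <- bt + ifelse(thru, sigma[j, ] * sigma[k, ], 0) / g_jk
      c1 <- close_len(S[j, eu] + el + S[ev, k], sjk, tol)
      c2 <- close_len(S[j, ev] + el + S[eu, k], sjk, tol)
      ebt <- ebt + (ifelse(c1, sigma[j, eu] * sigma[k, ev], 0) +
                    ifelse(c2, sigma[j, ev] * sigma[k, eu], 0)) / g_jk
    }
  }

  evc <- numeric(n)
  lambda <- 0
  ncomp_big <- 0L
  for (cc_id in seq_len(max(comp))) {
    members <- which(comp == cc_id)
    if (length(members) < 2L) next
    ncomp_big <- ncomp_big + 1L
    Wc <- W[members, members, drop = FALSE]
    x <- rep(1 / sqrt(length(members)), length(members))
    converged <- FALSE
    # iterate on W + I: same leading eigenvector, but the spectral shift
    # breaks the +/-lambda oscillation of bipartite weight patterns
    for (it in seq_len(power_max_iter)) {
      y <- as.vector(Wc %*% x) + x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < power_tol) {
        x <- y
        converged <- TRUE
        break
      }
      x <- y
    }
    if (!converged) {
      stop_ssn("eigenvector centrality did not converge in %d iterations",
               power_max_iter)
    }
    evc[members] <- x
    lambda <- max(lambda, as.vector(x %*% Wc %*% x))
  }
  if (ncomp_big > 1L) {
    warning("graph is disconnected: eigenvector centrality computed per component",
            call. = FALSE)
  }

  edges <- data.frame(source = ids[eu], target = ids[ev], distance = el,
                      weight = 1 / (el + 1), betweenness = ebt,
                      stringsAsFactors = FALSE)
  list(weighted_degree = wd, closeness = setNames(cc, ids),
       betweenness = setNames(bt, ids), eigenvector = setNames(evc, ids),
       lambda = lambda, edges = edges, component = setNames(comp, ids))
}

#' Weighted degree centrality
#'
#' Sum of edge weights incident to each node.
#'
#' @param net A `similarity_network` from [to_weights()].
#' @return Named numeric vector.
#' @export
weighted_degree <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  setNames(rowSums(net$W), net$ids)
}

#' Closeness centrality
#'
#' `(|V| - 1) / sum(shortest distances to all other nodes)`, with shortest
#' distances taken over paths in the transformed-distance graph (transformed
#' E-value distances routinely violate the triangle inequality, so a
#' two-hop route can be shorter than the direct edge). On a disconnected
#' graph the formula applies per connected component with `|V|` the
#' component size; isolated nodes get 0.
#'
#' @param net A `similarity_network`.
#' @return Named numeric vector.
#' @export
closeness <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  eng <- centrality_engine(net$ids, net_lengths(net))
  eng$closeness
}

#' Betweenness centrality of nodes and edges
#'
#' For each unordered node pair j < k, every intermediate node (and every
#' edge) accrues the fraction of shortest j-k paths passing through it;
#' endpoints never count as pass-throughs of their own pair, but an edge
#' does carry the paths of its own endpoints. Path lengths are compared with
#' relative tolerance `tol` so float accumulation over tiny offsets does not
#' split genuinely tied paths.
#'
#' @param net A `similarity_network`.
#' @param tol Relative tie tolerance for shortest-path lengths (default
#'   `1e-12`).
#' @return A list with `node` (named vector) and `edge` (a `data.frame`
#'   `source`, `target`, `betweenness`).
#' @export
betweenness <- function(net, tol = 1e-12) {
  stopifnot(inherits(net, "similarity_network"))
  eng <- centrality_engine(net$ids, net_lengths(net), tol = tol)
  list(node = eng$betweenness,
       edge = eng$edges[c("source", "target", "betweenness")])
}

#' Eigenvector centrality
#'
#' Leading eigenpair of the weight matrix `W` by power iteration from the
#' uniform vector: the centrality of a node is proportional to the
#' weight-summed centralities of its neighbors. The returned vector has unit
#' Euclidean norm and nonnegative entries; the leading eigenvalue of a
#' nonnegative irreducible `W` is real, positive and simple. On a
#' disconnected graph uniqueness fails; the computation then proceeds per
#' component (each component's subvector unit-norm) with a warning, and
#' isolated nodes get 0.
#'
#' @param net A `similarity_network`.
#' @param tol Convergence tolerance on successive iterates (default `1e-12`).
#' @param max_iter Iteration cap (default 10000); non-convergence errors.
#' @return List with `vector` (named, unit norm per component) and `lambda`
#'   (leading eigenvalue).
#' @export
eigenvector_centrality <- function(net, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(net, "similarity_network"))
  eng <- centrality_engine(net$ids, net_lengths(net), power_tol = tol,
                           power_max_iter = max_iter)
  list(vector = eng$eigenvector, lambda = eng$lambda)
}

# assemble a graph document from an engine result
centrality_document <- function(ids, eng, d_raw, role) {
  nodes <- data.frame(
    id = ids,
    weighted_degree = as.numeric(eng$weighted_degree),
    closeness = as.numeric(eng$closeness),
    betweenness = as.numeric(eng$betweenness),
    eigenvector = as.numeric(eng$eigenvector),
    component = as.numeric(eng$component),
    stringsAsFactors = FALSE
  )
  edges <- eng$edges
  edges$distance <- d_raw[cbind(match(edges$source, ids),
                                match(edges$target, ids))]
  edges$role <- rep(role, nrow(edges))
  graph_document(nodes, edges)
}

#' Thresholded centrality graph
#'
#' Keeps only edges whose raw distance is at or below the threshold `t`
#' (all nodes are retained), then recomputes weighted degree, closeness,
#' node and edge betweenness and eigenvector centrality on the thresholded
#' graph, per connected component. With `recompute = FALSE` the centralities
#' of the full network are attached instead and only the edge set is
#' filtered.
#'
#' @param D A [distance_matrix()].
#' @param t Distance threshold, `>= 0`; `t = 0` keeps only exact-zero edges.
#' @param q,delta Transform parameters, see [to_weights()].
#' @param recompute Recompute centralities after edge removal (default
#'   `TRUE`).
#' @param tol Shortest-path tie tolerance.
#' @return A [graph_document()] with centrality attributes on nodes and
#'   edges; surviving edges carry their raw `distance`, `weight` and role
#'   `"plain"`.
#' @export
threshold_graph <- function(D, t, q = 0.01, delta = 1e-200,
                            recompute = TRUE, tol = 1e-12) {
  stopifnot(inherits(D, "distance_matrix"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop_ssn("threshold must be >= 0")
  net <- to_weights(D, q = q, delta = delta)
  L <- net_lengths(net)
  keep <- D$d <= t
  if (recompute) {
    L[!keep] <- Inf
    eng <- centrality_engine(D$ids, L, tol = tol)
  } else {
    eng <- centrality_engine(D$ids, L, tol = tol)
    kept <- keep[cbind(match(eng$edges$source, D$ids),
                       match(eng$edges$target, D$ids))]
    eng$edges <- eng$edges[kept, , drop = FALSE]
  }
  centrality_document(D$ids, eng, D$d, role = "plain")
}

#' MST centrality graph
#'
#' Builds the minimum spanning tree of the distance matrix and computes all
#' centrality measures on the tree itself (tree edges carry transformed
#' distances as lengths), the compact backbone view of a family network.
#'
#' @inheritParams threshold_graph
#' @return A [graph_document()] whose edges are the MST edges (role
#'   `"tree"`) with edge betweenness, and whose nodes carry the four
#'   centrality measures computed on the tree.
#' @export
mst_centrality_graph <- function(D, q = 0.01, delta = 1e-200, tol = 1e-12) {
  stopifnot(inherits(D, "distance_matrix"))
  mst <- minimum_spanning_tree(D)
  L <- matrix(Inf, length(D$ids), length(D$ids),
              dimnames = list(D$ids, D$ids))
  if (nrow(mst$edges)) {
    dt <- mst$edges$distance^q + delta
    L[cbind(mst$edges$source, mst$edges$target)] <- dt
    L[cbind(mst$edges$target, mst$edges$source)] <- dt
  }
  dimnames(L) <- NULL
  eng <- centrality_engine(D$ids, L, tol = tol)
  centrality_document(D$ids, eng, D$d, role = "tree")
}
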