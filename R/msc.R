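#' @importFrom igraph graph_from_edgelist components graph_from_data_frame
#'   make_empty_graph distances V E
NULL

new_partition <- function(clusters, level, unit_kind) {
  clusters <- lapply(clusters, lex_sort)
  clusters <- clusters[lex_order(vapply(clusters, `[`, "", 1L))]
  structure(list(level = level, clusters = clusters, unit_kind = unit_kind),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> level %d: %d cluster(s) of %s units\n",
              x$level, length(x$clusters), x$unit_kind))
  invisible(x)
}

unit_kind_for_level <- function(level) {
  c("sequence", "cluster", "family")[min(level, 3L)]
}

#' Partition units by nearest-neighbor linkage
#'
#' Minimum-span clustering step: every unit is linked to its nearest
#' neighbor (ties resolved to the lexicographically smallest id) and the
#' clusters are the connected components of the resulting undirected link
#' graph. No cluster count or scale parameter is required; each cluster has
#' at least 2 members whenever there are at least 2 units.
#'
#' @param D A [distance_matrix()].
#' @param level Level tag recorded in the partition (default 1).
#' @return A `partition`: list of disjoint id sets covering all units.
#' @export
nearest_neighbor_partition <- function(D, level = 1L) {
  stopifnot(inherits(D, "distance_matrix"))
  n <- length(D$ids)
  if (n == 1L) {
    return(new_partition(list(D$ids), level, unit_kind_for_level(level)))
  }
  nn <- vapply(seq_len(n), function(i) {
    d <- D$d[i, ]
    d[i] <- Inf
    lex_min(D$ids[d == min(d)])
  }, "")
  g <- igraph::graph_from_edgelist(cbind(D$ids, nn), directed = FALSE)
  comp <- igraph::components(g)
  mem <- comp$membership[D$ids]
  clusters <- split(D$ids, mem)
  new_partition(unname(clusters), level, unit_kind_for_level(level))
}

#' Minimum distance between two disjoint unit sets
#'
#' Single-linkage superdistance: the smallest pairwise distance across the
#' two sets, i.e. the length of the shortest edge connecting them.
#'
#' @param D A [distance_matrix()] covering both sets.
#' @param A,B Disjoint non-empty character vectors of unit ids.
#' @return The minimum cross-pair distance.
#' @export
inter_cluster_distance <- function(D, A, B) {
  if (!length(A) || !length(B)) stop_ssn("clusters must be non-empty")
  if (length(intersect(A, B))) stop_ssn("clusters overlap: %s",
                                        paste(intersect(A, B), collapse = ", "))
  min(D$d[A, B, drop = FALSE])
}

# distance matrix over clusters (single linkage); each cluster unit is named
# by its lexicographically smallest member so higher-level tie-breaks are
# deterministic
superdistance_matrix <- function(D, clusters) {
  reps <- vapply(clusters, `[`, "", 1L)  # clusters are lex-sorted
  k <- length(clusters)
  m <- matrix(0, k, k, dimnames = list(reps, reps))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        v <- inter_cluster_distance(D, clusters[[i]], clusters[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  distance_matrix(m, meta = D$meta)
}

#' Build a nested cluster hierarchy by minimum-span clustering
#'
#' Level 1 is [nearest_neighbor_partition()] over the sequence distance
#' matrix. Each subsequent level clusters the previous level's clusters
#' using their single-linkage superdistances (minimum cross-pair distance),
#' so level k+1 clusters are exact unions of level-k clusters. Recursion
#' stops when one cluster remains or `max_levels` is reached. With the
#' default 3 levels the resolutions read: sequences, clusters, families.
#'
#' @param D A [distance_matrix()] over sequences.
#' @param max_levels Maximum number of levels (default 3).
#' @return A list of class `msc_hierarchy` with `levels` (partitions of the
#'   original sequence ids) and `superdistances` (per level, the
#'   [distance_matrix()] over that level's clusters, keyed by representative
#'   member id).
#' @export
build_hierarchy <- function(D, max_levels = 3L) {
  stopifnot(inherits(D, "distance_matrix"), max_levels >= 1L)
  levels <- list()
  superdistances <- list()
  # members maps current-unit id -> underlying sequence ids
  current <- dm_subset(D, lex_sort(D$ids))
  members <- setNames(as.list(current$ids), current$ids)
  k <- 0L
  repeat {
    k <- k + 1L
    p_units <- nearest_neighbor_partition(current, level = k)
    clusters_seq <- lapply(p_units$clusters, function(cl) {
      lex_sort(unlist(members[cl], use.names = FALSE))
    })
    levels[[k]] <- new_partition(clusters_seq, k, unit_kind_for_level(k))
    sup <- superdistance_matrix(current, p_units$clusters)
    superdistances[[k]] <- sup
    if (length(p_units$clusters) == 1L || k == max_levels) break
    members <- setNames(
      lapply(p_units$clusters, function(cl) {
        lex_sort(unlist(members[cl], use.names = FALSE))
      }),
      sup$ids
    )
    current <- sup
  }
  structure(list(levels = levels, superdistances = superdistances),
            class = "msc_hierarchy")
}

#' @export
print.msc_hierarchy <- function(x, ...) {
  cat(sprintf("<msc_hierarchy> %d level(s): %s clusters\n",
              length(x$levels),
              paste(vapply(x$levels, function(p) length(p$clusters), 0L),
                    collapse = " -> ")))
  invisible(x)
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm over all unordered pairs. Equal-distance ties prefer
#' the edge whose (smaller id, larger id) pair sorts lexicographically
#' first, so the tree is deterministic across runs and platforms.
#'
#' @param D A [distance_matrix()].
#' @param role Edge role attribute recorded on tree edges (default "tree").
#' @return A [graph_document()] with `|V| - 1` edges carrying `distance`.
#' @export
minimum_spanning_tree <- function(D, role = "tree") {
  stopifnot(inherits(D, "distance_matrix"))
  ids <- lex_sort(D$ids)
  n <- length(ids)
  nodes <- data.frame(id = D$ids, stringsAsFactors = FALSE)
  if (n < 2L) {
    return(graph_document(nodes))
  }
  pairs <- t(utils::combn(ids, 2L))
  w <- D$d[pairs]
  o <- order(w, pairs[, 1], pairs[, 2], method = "radix")
  parent <- setNames(seq_len(n), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  src <- tgt <- character(n - 1L)
  dist <- numeric(n - 1L)
  taken <- 0L
  for (k in o) {
    ri <- find(match(pairs[k, 1], ids))
    rj <- find(match(pairs[k, 2], ids))
    if (ri != rj) {
      parent[ri] <- rj
      taken <- taken + 1L
      src[taken] <- pairs[k, 1]
      tgt[taken] <- pairs[k, 2]
      dist[taken] <- w[k]
      if (taken == n - 1L) break
    }
  }
  edges <- data.frame(source = src, target = tgt, distance = dist,
                      role = role, stringsAsFactors = FALSE)
  graph_document(nodes, edges)
}

#' Extract the zero-distance core of a cluster
#'
#' The conservative core is the largest subset of the cluster whose members
#' all sit at pairwise distance exactly 0. Computation: connected components
#' of the zero-distance edge graph, each reduced to a fully-zero clique by
#' greedily removing the member with the most nonzero in-component pairs
#' (ties remove the lexicographically largest id); the largest resulting
#' clique wins (ties prefer the clique holding the smallest id). Returns
#' the empty set when no zero-distance pair exists; a core has >= 2 members.
#'
#' @param D A [distance_matrix()].
#' @param cluster Non-empty character vector of member ids.
#' @return Character vector of core member ids (possibly empty), lex-sorted.
#' @export
find_core <- function(D, cluster) {
  if (!length(cluster)) stop_ssn("cluster must be non-empty")
  cluster <- lex_sort(cluster)
  sub <- D$d[cluster, cluster, drop = FALSE]
  zero <- sub == 0
  diag(zero) <- FALSE
  if (!any(zero)) return(character(0))
  idx <- which(zero & upper.tri(zero), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(cluster[idx[, 1]], cluster[idx[, 2]]), directed = FALSE)
  comp <- igraph::components(g)
  best <- character(0)
  comp_sets <- split(names(comp$membership), comp$membership)
  for (set in comp_sets) {
    set <- lex_sort(set)
    while (length(set) >= 2L) {
      nz <- colSums(sub[set, set, drop = FALSE] > 0)
      if (all(nz == 0)) break
      worst <- set[nz == max(nz)]
      set <- setdiff(set, worst[length(worst)])  # drop lex-largest tied member
    }
    if (length(set) >= 2L &&
        (length(set) > length(best) ||
         (length(set) == length(best) && length(best) &&
          lex_min(set) < lex_min(best)))) {
      best <- set
    }
  }
  lex_sort(best)
}

#' Name clusters by majority family prefix and size rank
#'
#' Each cluster takes the 2-3 character prefix of its majority family
#' (annotation ties resolve to the lexicographically smallest prefix;
#' unannotated members count as prefix `Un`). Within a prefix, clusters are
#' numbered `001`, `002`, ... by decreasing member count, ties going to the
#' cluster holding the lexicographically smallest id, so the largest peptide
#' receptor cluster is `Pe001`.
#'
#' @param p A `partition`.
#' @param ann An `annotation_table` (or `NULL`: everything `Un`).
#' @return Character vector of labels, parallel to `p$clusters`.
#' @export
name_clusters <- function(p, ann = NULL) {
  stopifnot(inherits(p, "partition"))
  prefixes <- vapply(p$clusters, function(cl) {
    majority_label(annotation_for(cl, ann)$prefix)
  }, "")
  sizes <- vapply(p$clusters, length, 0L)
  firsts <- vapply(p$clusters, `[`, "", 1L)
  labels <- character(length(p$clusters))
  for (pref in unique(prefixes)) {
    sel <- which(prefixes == pref)
    ord <- sel[order(-sizes[sel], firsts[sel], method = "radix")]
    labels[ord] <- paste0(pref, sprintf("%03d", seq_along(ord)))
  }
  labels
}

majority_label <- function(x) {
  tab <- table(x)
  lex_min(names(tab)[tab == max(tab)])
}

#' Annotate clusters with majority family and class
#'
#' @param p A `partition`.
#' @param ann An `annotation_table` (or `NULL`).
#' @return A `data.frame` with one row per cluster: `label` columns `family`
#'   and `class` (majority vote; ties to the lexicographically smallest
#'   label; unannotated ids count as `"unknown"`), plus `size`.
#' @export
annotate_partition <- function(p, ann = NULL) {
  stopifnot(inherits(p, "partition"))
  fam <- vapply(p$clusters, function(cl) {
    majority_label(annotation_for(cl, ann)$family)
  }, "")
  cls <- vapply(p$clusters, function(cl) {
    majority_label(annotation_for(cl, ann)$class)
  }, "")
  data.frame(family = fam, class = cls,
             size = vapply(p$clusters, length, 0L),
             stringsAsFactors = FALSE)
}

#' Serialize a hierarchy as JSON
#'
#' Levels, cluster memberships, labels and superdistance edge lists in one
#' JSON document (full double precision).
#'
#' @param h An `msc_hierarchy`.
#' @param ann Optional `annotation_table` used for cluster labels.
#' @param file Optional output path.
#' @return JSON text, invisibly when written to `file`.
#' @export
write_hierarchy_json <- function(h, ann = NULL, file = NULL) {
  stopifnot(inherits(h, "msc_hierarchy"))
  levels <- lapply(seq_along(h$levels), function(k) {
    p <- h$levels[[k]]
    labs <- name_clusters(p, ann)
    meta <- annotate_partition(p, ann)
    sup <- h$superdistances[[k]]
    idx <- which(upper.tri(sup$d), arr.ind = TRUE)
    list(
      level = p$level,
      unit_kind = p$unit_kind,
      clusters = lapply(seq_along(p$clusters), function(i) {
        list(label = labs[i], family = meta$family[i], class = meta$class[i],
             size = meta$size[i], members = p$clusters[[i]])
      }),
      superdistance_edges = if (nrow(idx)) {
        data.frame(a = sup$ids[idx[, 1]], b = sup$ids[idx[, 2]],
                   distance = sup$d[idx], stringsAsFactors = FALSE)
      } else data.frame(a = character(0), b = character(0),
                        distance = numeric(0))
    )
  })
  txt <- as.character(jsonlite::toJSON(list(levels = levels),
                                       auto_unbox = TRUE, digits = I(17),
                                       pretty = TRUE))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
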