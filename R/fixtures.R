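#' Specification for a planted hierarchical distance matrix
#'
#' Describes synthetic cluster structure over `L` nesting levels:
#' `sizes[[1]]` gives the member count of each fine cluster; `sizes[[k]]`
#' for `k > 1` gives how many level-(k-1) clusters each level-k group
#' absorbs (in order). `log10_ranges` has `L + 1` entries `c(lo, hi)` of
#' log10 distance: entry k covers pairs whose deepest shared group is at
#' level k, entry `L + 1` covers pairs split at the top; ranges must be
#' strictly increasing and non-overlapping across levels (deeper = closer).
#'
#' @param sizes List of integer vectors (see above).
#' @param log10_ranges List of `L + 1` numeric `c(lo, hi)` ranges.
#' @param zero_core_fraction Fraction of each fine cluster to plant as an
#'   exact-zero-distance core (default 0).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(sizes, log10_ranges, zero_core_fraction = 0,
                         seed = 1L) {
  if (!is.list(sizes) || !length(sizes)) stop_ssn("sizes must be a non-empty list")
  sizes <- lapply(sizes, as.integer)
  if (any(unlist(sizes) < 1L)) stop_ssn("all sizes must be >= 1")
  L <- length(sizes)
  for (k in seq_len(L - 1L)) {
    if (sum(sizes[[k + 1L]]) != length(sizes[[k]])) {
      stop_ssn("level %d groups must absorb exactly the %d level-%d clusters",
               k + 1L, length(sizes[[k]]), k)
    }
  }
  if (length(log10_ranges) != L + 1L) {
    stop_ssn("need %d log10 ranges for %d levels", L + 1L, L)
  }
  rng <- lapply(log10_ranges, as.numeric)
  if (any(vapply(rng, function(r) length(r) != 2L || r[1] >= r[2], TRUE))) {
    stop_ssn("each range must be c(lo, hi) with lo < hi")
  }
  for (k in seq_len(L)) {
    if (rng[[k]][2] >= rng[[k + 1L]][1]) {
      stop_ssn("ranges overlap: level %d must lie strictly below level %d",
               k, k + 1L)
    }
  }
  if (zero_core_fraction < 0 || zero_core_fraction > 1) {
    stop_ssn("zero_core_fraction must be in [0, 1]")
  }
  structure(list(sizes = sizes, log10_ranges = rng,
                 zero_core_fraction = zero_core_fraction,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

# deepest shared level of two sequences given per-level group assignments
# (matrix: rows sequences, col k = group index at level k; col L+1 all 1)
deepest_shared <- function(assign_mat, i, j) {
  for (k in seq_len(ncol(assign_mat))) {
    if (assign_mat[i, k] == assign_mat[j, k]) return(k)
  }
  ncol(assign_mat)
}

#' Generate a distance matrix with planted hierarchical structure
#'
#' Distances are drawn log-uniformly within the range of the deepest level
#' at which a pair shares a group. Within every cluster (and among the
#' clusters of every higher-level group) one member acts as a hub whose
#' pairs are drawn from the lower half of the level's log10 band while all
#' other pairs use the upper half; this hub-and-spoke profile emulates the
#' highly connected hub sequences seen in real receptor families and
#' guarantees that nearest-neighbor linkage keeps each planted group
#' connected. Exact recovery of every planted level by [build_hierarchy()]
#' is guaranteed when every cluster and every higher-level group has at
#' least 2 children; a singleton group cannot stay separate under
#' nearest-neighbor linkage, since its unit always links to some other
#' unit. With `zero_core_fraction > 0`, the first
#' `ceiling(fraction * size)` members of each fine cluster form an
#' exact-zero-distance core; core members share identical distance rows
#' (zero distance means effectively identical sequences).
#'
#' @param spec A [planted_spec()].
#' @return A list with `matrix` (a [distance_matrix()], `meta =
#'   "synthetic"`) and `truth` (list of `partition`s, one per planted level
#'   plus the all-in-one top level).
#' @export
planted_cluster_matrix <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  withr::with_seed(spec$seed, planted_cluster_matrix_impl(spec))
}

planted_cluster_matrix_impl <- function(spec) {
  L <- length(spec$sizes)
  n_fine <- length(spec$sizes[[1L]])
  n <- sum(spec$sizes[[1L]])
  ids <- sprintf("s%03d", seq_len(n))

  # per-sequence group index at each level; level L+1 = everything together
  assign_mat <- matrix(1L, n, L + 1L)
  assign_mat[, 1L] <- rep(seq_len(n_fine), spec$sizes[[1L]])
  if (L > 1L) {
    grp <- seq_len(n_fine)
    for (k in seq(2L, L)) {
      grp <- rep(seq_along(spec$sizes[[k]]), spec$sizes[[k]])[grp]
      assign_mat[, k] <- grp[assign_mat[, 1L]]
    }
  }

  # hub member of each group at each level: its lexicographically first unit
  draw <- function(range, half) {
    mid <- mean(range)
    lo <- if (half == "low") range[1] else mid
    hi <- if (half == "low") mid else range[2]
    10^stats::runif(1L, lo, hi)
  }

  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      k <- deepest_shared(assign_mat, i, j)
      rng <- spec$log10_ranges[[k]]
      # hub = first member of the shared group (first fine cluster of the
      # shared higher group); pairs touching the hub's cluster-representative
      # take the low half so every group is NN-connected through its hub
      grp_members <- which(assign_mat[, k] == assign_mat[i, k])
      hub <- grp_members[1L]
      hub_pair <- if (k == 1L) {
        i == hub || j == hub
      } else {
        # at higher levels connectivity is between level-(k-1) clusters:
        # low-half distances for pairs involving the hub cluster
        assign_mat[i, k - 1L] == assign_mat[hub, k - 1L] ||
          assign_mat[j, k - 1L] == assign_mat[hub, k - 1L]
      }
      d[i, j] <- d[j, i] <- draw(rng, if (hub_pair) "low" else "high")
    }
  }

  # plant exact-zero cores with identical rows (first core member's row)
  if (spec$zero_core_fraction > 0) {
    for (c_id in seq_len(n_fine)) {
      members <- which(assign_mat[, 1L] == c_id)
      m <- ceiling(spec$zero_core_fraction * length(members))
      core <- members[seq_len(m)]
      if (m >= 1L) {
        for (x in core) {
          d[x, ] <- d[core[1L], ]
          d[, x] <- d[, core[1L]]
        }
        d[core, core] <- 0
      }
    }
    diag(d) <- 0
  }

  truth <- lapply(seq_len(L + 1L), function(k) {
    new_partition(unname(split(ids, assign_mat[, k])), k,
                  unit_kind_for_level(k))
  })
  list(matrix = distance_matrix(d, meta = "synthetic"), truth = truth)
}

#' Generate a planted positive/negative classification set
#'
#' Positive queries receive minimum distances log-uniform in
#' `(0, pos_max]` (spanning ten decades below `pos_max`), negatives in
#' `[neg_min, 10]`; the margin `pos_max < neg_min` guarantees perfect
#' separability, the desk-scale surrogate for a cleanly separated
#' member/non-member query panel.
#'
#' @param n_pos,n_neg Positive/negative counts, both `>= 1`.
#' @param pos_max Upper bound for positive distances (default `1e-4`).
#' @param neg_min Lower bound for negative distances (default `1e-2`).
#' @param seed Integer seed.
#' @return A list `d_min` (numeric) and `labels`
#'   (`"positive"`/`"negative"`).
#' @export
planted_classification_set <- function(n_pos, n_neg, pos_max = 1e-4,
                                       neg_min = 1e-2, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop_ssn("need at least one query per class")
  if (!(pos_max < neg_min)) stop_ssn("margin violated: pos_max must be < neg_min")
  withr::with_seed(as.integer(seed), {
    pos <- 10^stats::runif(n_pos, log10(pos_max) - 10, log10(pos_max))
    neg <- 10^stats::runif(n_neg, log10(neg_min), 1)
    list(d_min = c(pos, neg),
         labels = rep(c("positive", "negative"), c(n_pos, n_neg)))
  })
}

#' Generate a random directed E-value table
#'
#' Each unordered pair gets a base log10 E-value uniform in [-100, 0]; the
#' two directions are jittered apart by up to `asymmetry` decades
#' (`asymmetry = 0` gives exactly symmetric tables, so [symmetrize()]
#' returns the E-values themselves).
#'
#' @param n Number of sequences, `>= 2`.
#' @param asymmetry Maximum log10 spread between the two directions
#'   (default 1).
#' @param seed Integer seed.
#' @return An [evalue_table()] over ids `s001..`.
#' @export
random_evalue_table <- function(n, asymmetry = 1, seed = 1L) {
  if (n < 2L) stop_ssn("need n >= 2")
  if (asymmetry < 0) stop_ssn("asymmetry must be >= 0")
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("s%03d", seq_len(n))
    pairs <- t(utils::combn(seq_len(n), 2L))
    base <- stats::runif(nrow(pairs), -100, 0)
    jit <- stats::runif(nrow(pairs), -asymmetry, asymmetry)
    evalue_table(
      query = c(ids[pairs[, 1]], ids[pairs[, 2]]),
      subject = c(ids[pairs[, 2]], ids[pairs[, 1]]),
      evalue = c(10^(base + jit / 2), 10^(base - jit / 2)),
      ids = ids
    )
  })
}
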