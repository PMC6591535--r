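#' Construct a symmetric sequence-distance matrix
#'
#' The core similarity container: a symmetric, zero-diagonal matrix of
#' nonnegative pairwise distances over named units (sequences, clusters or
#' families). Distances derived from alignment E-values may be exactly zero;
#' zero is preserved, never floored, because zero-distance cores are a
#' meaningful network feature.
#'
#' @param d Square numeric matrix with matching row/column names.
#' @param meta Provenance tag: `"blastp"`, `"psiblast"` or `"synthetic"`.
#' @return An object of class `distance_matrix` with fields `ids`, `d`, `meta`.
#' @export
distance_matrix <- function(d, meta = c("blastp", "psiblast", "synthetic")) {
  meta <- match.arg(meta)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop_ssn("distance matrix must be square")
  ids <- rownames(d)
  if (is.null(ids) || !identical(ids, colnames(d))) {
    stop_ssn("distance matrix needs matching row and column names")
  }
  if (anyDuplicated(ids)) stop_ssn("duplicate unit id")
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_ssn("distances must be finite and >= 0")
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 0))) {
    stop_ssn("distance matrix must be exactly symmetric")
  }
  if (any(diag(d) != 0)) stop_ssn("diagonal must be 0")
  structure(list(ids = ids, d = d, meta = meta), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d units (%s)\n", length(x$ids), x$meta))
  invisible(x)
}

#' Symmetrize directed E-values into a distance matrix
#'
#' The distance between sequences i and j is the geometric mean of the two
#' directed E-values, `d_ij = sqrt(E_ij * E_ji)`. A missing direction is
#' replaced by the cap `e_cap` before the product: unreported similarity is
#' read conservatively as "no better than the search ceiling". Self-hits are
#' ignored; the diagonal is forced to 0. PSI-BLAST-derived tables go through
#' the identical symmetrization with `meta = "psiblast"`.
#'
#' @param ev An [evalue_table()] with at least 2 ids.
#' @param e_cap Cap substituted for missing directed pairs (default 10, the
#'   conventional search E-value ceiling).
#' @param meta Provenance tag for the result.
#' @return A [distance_matrix()].
#' @export
symmetrize <- function(ev, e_cap = 10, meta = "blastp") {
  stopifnot(inherits(ev, "evalue_table"))
  if (length(ev$ids) < 2L) stop_ssn("need at least 2 sequence ids")
  if (!is.numeric(e_cap) || e_cap <= 0) stop_ssn("e_cap must be > 0")
  E <- evalue_lookup(ev, default = e_cap)
  d <- sqrt(E * t(E))
  diag(d) <- 0
  distance_matrix(d, meta = meta)
}

# submatrix restricted to ids (order preserved as given)
dm_subset <- function(D, ids) {
  distance_matrix(D$d[ids, ids, drop = FALSE], meta = D$meta)
}

#' Distances from one query sequence to a base set
#'
#' Computes the symmetrized distance from a single query to every base id
#' using the directed hits available for that query; each missing direction
#' falls back to `e_cap` (so a base sequence with no hits at all sits at
#' distance `e_cap`). Ties on the minimum distance resolve to the
#' lexicographically smallest base id.
#'
#' @param query_hits An [evalue_table()] whose pairs involve one query id.
#' @param query Query id (inferred when the table names exactly one
#'   non-base id).
#' @param base_ids Character vector of base sequence ids (non-empty).
#' @param e_cap Missing-direction cap (default 10).
#' @return A list of class `query_distance_vector`: `query`, `base_ids`,
#'   `distances`, `d_min`, `nearest`.
#' @export
query_distances <- function(query_hits, base_ids, query = NULL, e_cap = 10) {
  stopifnot(inherits(query_hits, "evalue_table"))
  if (!length(base_ids)) stop_ssn("base_ids must be non-empty")
  base_ids <- as.character(base_ids)
  if (is.null(query)) {
    cand <- setdiff(query_hits$ids, base_ids)
    if (length(cand) != 1L) {
      stop_ssn("cannot infer query id; pass 'query' explicitly")
    }
    query <- cand
  }
  p <- query_hits$pairs
  fwd <- setNames(rep(e_cap, length(base_ids)), base_ids)
  rev <- fwd
  sel_f <- p$query == query & p$subject %in% base_ids
  fwd[p$subject[sel_f]] <- p$evalue[sel_f]
  sel_r <- p$subject == query & p$query %in% base_ids
  rev[p$query[sel_r]] <- p$evalue[sel_r]
  d <- sqrt(fwd * rev)
  d_min <- min(d)
  nearest <- lex_min(base_ids[d == d_min])
  structure(list(query = query, base_ids = base_ids,
                 distances = setNames(as.numeric(d), base_ids),
                 d_min = d_min, nearest = nearest),
            class = "query_distance_vector")
}

#' Normalized root-mean-square deviation between two distance vectors
#'
#' Diagnostic for the fixed-database approximation: given the distances of
#' the base sequences computed against the base dataset (`d_b`) and against
#' the base-plus-query dataset (`d_bq`), returns
#' `sqrt(mean((1 - d_b/d_bq)^2))`. Pairs with both entries zero contribute 0
#' (ratio defined as 1); a zero `d_bq` against nonzero `d_b` is an undefined
#' ratio and errors.
#'
#' @param d_b,d_bq Equal-length nonnegative numeric vectors, paired by base
#'   sequence.
#' @return Nonnegative scalar; 0 iff the vectors are identical.
#' @export
nrmsd <- function(d_b, d_bq) {
  if (length(d_b) != length(d_bq)) stop_ssn("d_b and d_bq must be paired")
  if (any(d_b < 0) || any(d_bq < 0)) stop_ssn("distances must be >= 0")
  bad <- d_bq == 0 & d_b != 0
  if (any(bad)) stop_ssn("undefined ratio: d_bq == 0 with d_b != 0 at index %d",
                         which(bad)[1])
  ratio <- ifelse(d_b == 0 & d_bq == 0, 1, d_b / d_bq)
  sqrt(mean((1 - ratio)^2))
}

#' Write a distance matrix as an edge-list TSV
#'
#' One line per unordered pair (upper triangle, ids in matrix order):
#' `id_i<TAB>id_j<TAB>distance`, distances in full double precision. Zero
#' distances are written explicitly (cores depend on them).
#'
#' @param D A [distance_matrix()].
#' @param file Optional output path.
#' @return The TSV text, invisibly when written to `file`.
#' @export
write_distance_tsv <- function(D, file = NULL) {
  n <- length(D$ids)
  idx <- which(upper.tri(D$d), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- paste(D$ids[idx[, 1]], D$ids[idx[, 2]],
                 format_full(D$d[idx]), sep = "\t")
  txt <- paste0(paste(lines, collapse = "\n"), if (n > 1) "\n" else "")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Read a distance matrix from an edge-list TSV
#'
#' Inverse of [write_distance_tsv()]; every unordered pair must be present.
#'
#' @param x File path or character lines.
#' @param meta Provenance tag.
#' @return A [distance_matrix()].
#' @export
read_distance_tsv <- function(x, meta = "blastp") {
  lines <- as_text_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3L)) stop_ssn("expected 3 tab-separated columns")
  a <- vapply(f, `[`, "", 1L)
  b <- vapply(f, `[`, "", 2L)
  v <- as.numeric(vapply(f, `[`, "", 3L))
  ids <- unique(as.vector(rbind(a, b)))
  n <- length(ids)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  d[cbind(a, b)] <- v
  d[cbind(b, a)] <- v
  if (anyNA(d)) stop_ssn("incomplete distance edge list")
  distance_matrix(d, meta = meta)
}
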