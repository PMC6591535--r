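#' Classifier configuration
#'
#' @param tau Membership distance threshold, `> 0`. The default 0.0009 is
#'   the threshold that maximizes the F-measure of receptor identification
#'   on the reference base dataset.
#' @param remote_iterations Iterations for the iterative remote-homology
#'   search engine (default 10).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(tau = 0.0009, remote_iterations = 10L) {
  if (!is.numeric(tau) || tau <= 0) stop_ssn("tau must be > 0")
  if (remote_iterations < 1L) stop_ssn("remote_iterations must be >= 1")
  structure(list(tau = tau, remote_iterations = as.integer(remote_iterations)),
            class = "classifier_config")
}

#' Classify a query sequence by minimum distance to the base set
#'
#' A query is a member iff its minimum symmetrized distance to the base
#' sequences is strictly below `tau`; members are assigned the cluster of
#' their nearest base sequence. A non-member is optionally probed for remote
#' homology: `remote_provider` (a function `query_id -> query_distance_vector`,
#' typically backed by an iterative profile search or a precomputed table)
#' supplies profile-based distances `d'`, and the query is flagged remotely
#' related when `d'_min < tau`. The verdict stays `non_member` even when
#' remotely related: remote evidence qualifies, it does not reclassify.
#'
#' @param qd A `query_distance_vector` from [query_distances()].
#' @param cfg A [classifier_config()].
#' @param cluster_map Named character vector mapping base ids to cluster
#'   labels (may be `NULL`: assigned cluster `NA`).
#' @param remote_provider Optional function taking the query id and
#'   returning a `query_distance_vector` of remote-search distances.
#' @return A list of class `classification_result`: `query`, `d_min`,
#'   `nearest`, `cluster`, `verdict`, and `remote` (fields `attempted`,
#'   `d_min`, `nearest`, `remotely_related`, `error`).
#' @export
classify <- function(qd, cfg = classifier_config(), cluster_map = NULL,
                     remote_provider = NULL) {
  stopifnot(inherits(qd, "query_distance_vector"),
            inherits(cfg, "classifier_config"))
  member <- qd$d_min < cfg$tau
  cluster <- if (!is.null(cluster_map) && qd$nearest %in% names(cluster_map)) {
    unname(cluster_map[qd$nearest])
  } else NA_character_
  remote <- list(attempted = FALSE, d_min = NA_real_, nearest = NA_character_,
                 remotely_related = NA, error = NULL)
  if (!member && !is.null(remote_provider)) {
    remote$attempted <- TRUE
    rqd <- tryCatch(remote_provider(qd$query), error = function(e) e)
    if (inherits(rqd, "error")) {
      remote$error <- conditionMessage(rqd)
    } else {
      remote$d_min <- rqd$d_min
      remote$nearest <- rqd$nearest
      remote$remotely_related <- rqd$d_min < cfg$tau
    }
  }
  structure(list(query = qd$query, d_min = qd$d_min, nearest = qd$nearest,
                 cluster = if (member) cluster else NA_character_,
                 verdict = if (member) "member" else "non_member",
                 remote = remote),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: %s (d_min = %g, nearest %s%s)\n",
              x$query, x$verdict, x$d_min, x$nearest,
              if (!is.na(x$cluster)) paste0(", cluster ", x$cluster) else ""))
  if (x$remote$attempted) {
    cat(sprintf("  remote search: d'_min = %g (%s) -> remotely related: %s\n",
                x$remote$d_min, x$remote$nearest, x$remote$remotely_related))
  }
  invisible(x)
}

#' ROC curve and AUC for minimum-distance classification
#'
#' Queries are ranked by score `-d_min` (smaller distance = more
#' member-like); the ROC sweeps all distinct scores, moving tied scores
#' together, so the trapezoidal AUC equals the pair-counting (Mann-Whitney)
#' statistic with half credit for cross-class ties.
#'
#' @param d_min Numeric vector of per-query minimum distances.
#' @param labels Vector of `"positive"`/`"negative"` (or logical, `TRUE` =
#'   positive); both classes must be present.
#' @return A list of class `roc_curve`: `points` (`data.frame` with `fpr`,
#'   `tpr` from (0,0) to (1,1)), `auc`, and `sweep` (per candidate threshold:
#'   `tau`, `precision`, `recall`, `f_measure`).
#' @export
roc_curve <- function(d_min, labels) {
  lab <- normalize_labels(labels)
  if (length(d_min) != length(lab)) stop_ssn("d_min and labels must be paired")
  if (!any(lab) || all(lab)) stop_ssn("need both positive and negative queries")
  score <- -d_min
  o <- order(score, decreasing = TRUE)
  score <- score[o]
  lab <- lab[o]
  P <- sum(lab)
  N <- sum(!lab)
  grp <- cumsum(!duplicated(score))          # tied scores move together
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  points <- data.frame(fpr = c(0, fp[last] / N), tpr = c(0, tp[last] / P))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  sweep <- fmeasure_sweep(d_min, normalize_labels(labels))
  structure(list(points = points, auc = auc, sweep = sweep),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.6g\n", nrow(x$points), x$auc))
  invisible(x)
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  if (!all(l %in% c("positive", "negative"))) {
    stop_ssn("labels must be 'positive'/'negative' or logical")
  }
  l == "positive"
}

# candidate thresholds are geometric means of consecutive distinct d_min
# values (E-values live on a log scale), plus one a decade above the max;
# a zero lower value is floored at 1e-300 so the candidate stays strictly
# between the two distances
fmeasure_candidates <- function(d_min) {
  v <- sort(unique(d_min))
  cands <- numeric(0)
  if (length(v) > 1L) {
    cands <- sqrt(pmax(utils::head(v, -1), 1e-300) * utils::tail(v, -1))
  }
  c(cands, max(v) * 10)
}

fmeasure_sweep <- function(d_min, lab) {
  taus <- fmeasure_candidates(d_min)
  P <- sum(lab)
  res <- t(vapply(taus, function(tau) {
    pred <- d_min < tau
    tp <- sum(pred & lab)
    prec <- if (sum(pred)) tp / sum(pred) else 0
    rec <- tp / P
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f_measure = f)
  }, c(precision = 0, recall = 0, f_measure = 0)))
  data.frame(tau = taus, res)
}

#' Threshold maximizing the F-measure
#'
#' Sweeps candidate thresholds (geometric means of consecutive distinct
#' `d_min` values, plus one above the maximum) and returns the threshold
#' maximizing F1 = `2 * precision * recall / (precision + recall)`, where a
#' query is predicted positive iff `d_min < tau`. Ties prefer the smallest
#' threshold.
#'
#' @inheritParams roc_curve
#' @return A list `tau_star`, `f_star`, plus the full `sweep` table.
#' @export
optimal_threshold_fmeasure <- function(d_min, labels) {
  lab <- normalize_labels(labels)
  if (length(d_min) != length(lab)) stop_ssn("d_min and labels must be paired")
  if (!any(lab) || all(lab)) stop_ssn("need both positive and negative queries")
  sweep <- fmeasure_sweep(d_min, lab)
  best <- which(sweep$f_measure == max(sweep$f_measure))
  pick <- best[which.min(sweep$tau[best])]
  list(tau_star = sweep$tau[pick], f_star = sweep$f_measure[pick],
       sweep = sweep)
}
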