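#' Assemble a pipeline run configuration
#'
#' Defaults are the reference operating point of the method: membership
#' threshold `tau = 0.0009`, E-value cap 10, transform exponent `q = 0.01`,
#' offset `delta = 1e-200`, 3 clustering levels, and centrality views at
#' thresholds `1e-20, 1e-50, 1e-80, 1e-100`.
#'
#' @param evalues Path to the E-value table (or the parsed
#'   [evalue_table()]).
#' @param evalue_fmt `"three-col"` or `"blast-tab-12col"`.
#' @param fasta Optional FASTA path (sequence ids are cross-checked).
#' @param annotations Optional annotation CSV path.
#' @param query_hits Optional path/table of query-vs-base hits for
#'   classification.
#' @param remote_table Optional path/table of remote-search (profile)
#'   E-values used as the remote-homology fallback.
#' @param out_dir Output directory.
#' @param tau,e_cap,q,delta,levels,thresholds Numeric parameters (see
#'   module functions).
#' @param seed Integer seed threaded to any synthetic-data step.
#' @param graph_fmt Graph export format (default `"graphml"`).
#' @param log_file Optional path for run logs (kept outside data outputs so
#'   artifacts stay byte-deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(evalues, out_dir, evalue_fmt = "three-col",
                       fasta = NULL, annotations = NULL, query_hits = NULL,
                       remote_table = NULL, tau = 0.0009, e_cap = 10,
                       q = 0.01, delta = 1e-200, levels = 3L,
                       thresholds = c(1e-20, 1e-50, 1e-80, 1e-100),
                       seed = 1L, graph_fmt = "graphml", log_file = NULL) {
  stopifnot(tau > 0, e_cap > 0, q > 0, delta > 0, levels >= 1L,
            all(thresholds >= 0))
  structure(list(evalues = evalues, evalue_fmt = evalue_fmt, fasta = fasta,
                 annotations = annotations, query_hits = query_hits,
                 remote_table = remote_table, out_dir = out_dir, tau = tau,
                 e_cap = e_cap, q = q, delta = delta,
                 levels = as.integer(levels), thresholds = thresholds,
                 seed = as.integer(seed), graph_fmt = graph_fmt,
                 log_file = log_file),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file whose keys match
#'   the arguments of [run_config()].
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_ssn("config file not found: %s",
                                   class = "seqsimnet_input_error", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

check_input <- function(path, what) {
  if (is.character(path) && length(path) == 1L && !grepl("\n", path) &&
      !file.exists(path)) {
    stop_ssn("%s file not found: %s", class = "seqsimnet_input_error",
             what, path)
  }
  path
}

pipeline_log <- function(cfg, fmt, ...) {
  if (!is.null(cfg$log_file)) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = cfg$log_file, append = TRUE)
  }
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' End to end: parse E-values, symmetrize into a distance matrix, cluster
#' into the multi-level hierarchy, export per-level minimum spanning trees,
#' compute thresholded centrality views and the MST centrality graph, and,
#' when query hits are supplied, classify each query against the base set
#' (with the remote-homology fallback if a remote table is configured).
#' Outputs are byte-deterministic for identical inputs and configuration;
#' logs go to a side file, never into the data artifacts.
#'
#' Written artifacts: `dist.tsv`, `hierarchy.json`, `level<k>_mst.<fmt>`,
#' `threshold_<t>.<fmt>`, `mst_centrality.<fmt>`, `centrality.tsv` and, if
#' queries are configured, `classification.json`.
#'
#' @param cfg A [run_config()] (or path to a config file).
#' @return Invisibly, a list with the computed objects and `files`, the
#'   vector of artifact paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  art <- function(name) file.path(cfg$out_dir, name)
  ext <- if (cfg$graph_fmt == "cytoscape-json") "json" else
    if (cfg$graph_fmt == "graphml") "graphml" else "tsv"

  ev <- if (inherits(cfg$evalues, "evalue_table")) cfg$evalues else {
    parse_evalue_table(check_input(cfg$evalues, "E-value"), cfg$evalue_fmt)
  }
  pipeline_log(cfg, "parsed %d E-value pairs over %d ids",
               nrow(ev$pairs), length(ev$ids))
  ann <- if (!is.null(cfg$annotations)) {
    read_annotations(check_input(cfg$annotations, "annotation"))
  } else NULL
  if (!is.null(cfg$fasta)) {
    fa <- read_fasta(check_input(cfg$fasta, "FASTA"))
    missing_seq <- setdiff(ev$ids, fa$id)
    if (length(missing_seq)) {
      pipeline_log(cfg, "note: %d table id(s) absent from FASTA",
                   length(missing_seq))
    }
  }

  D <- symmetrize(ev, e_cap = cfg$e_cap)
  write_distance_tsv(D, art("dist.tsv"))
  files <- c(files, art("dist.tsv"))

  h <- build_hierarchy(D, max_levels = cfg$levels)
  write_hierarchy_json(h, ann, art("hierarchy.json"))
  files <- c(files, art("hierarchy.json"))
  pipeline_log(cfg, "hierarchy: %s clusters",
               paste(vapply(h$levels, function(p) length(p$clusters), 0L),
                     collapse = " -> "))

  for (k in seq_along(h$levels)) {
    mst_k <- minimum_spanning_tree(h$superdistances[[k]])
    f <- art(sprintf("level%d_mst.%s", k, ext))
    write_graph_document(mst_k, cfg$graph_fmt, f)
    files <- c(files, f)
  }

  for (t in cfg$thresholds) {
    gd <- threshold_graph(D, t, q = cfg$q, delta = cfg$delta)
    f <- art(sprintf("threshold_%g.%s", t, ext))
    write_graph_document(gd, cfg$graph_fmt, f)
    files <- c(files, f)
  }
  mstc <- mst_centrality_graph(D, q = cfg$q, delta = cfg$delta)
  write_graph_document(mstc, cfg$graph_fmt, art(paste0("mst_centrality.", ext)))
  files <- c(files, art(paste0("mst_centrality.", ext)))

  net <- to_weights(D, q = cfg$q, delta = cfg$delta)
  eng <- centrality_engine(D$ids, net_lengths(net))
  cent <- data.frame(id = D$ids,
                     weighted_degree = as.numeric(eng$weighted_degree),
                     closeness = as.numeric(eng$closeness),
                     betweenness = as.numeric(eng$betweenness),
                     eigenvector = as.numeric(eng$eigenvector),
                     stringsAsFactors = FALSE)
  ctxt <- paste0(paste(c("id\tweighted_degree\tcloseness\tbetweenness\teigenvector",
                         paste(cent$id, format_full(cent$weighted_degree),
                               format_full(cent$closeness),
                               format_full(cent$betweenness),
                               format_full(cent$eigenvector), sep = "\t")),
                       collapse = "\n"), "\n")
  writeLines(ctxt, art("centrality.tsv"), sep = "")
  files <- c(files, art("centrality.tsv"))

  results <- list(distance = D, hierarchy = h, centrality = cent)

  if (!is.null(cfg$query_hits)) {
    qh <- if (inherits(cfg$query_hits, "evalue_table")) cfg$query_hits else {
      parse_evalue_table(check_input(cfg$query_hits, "query hits"),
                         cfg$evalue_fmt)
    }
    remote <- NULL
    if (!is.null(cfg$remote_table)) {
      rt <- if (inherits(cfg$remote_table, "evalue_table")) cfg$remote_table else {
        parse_evalue_table(check_input(cfg$remote_table, "remote table"),
                           cfg$evalue_fmt)
      }
      remote <- function(query) {
        query_distances(rt, base_ids = D$ids, query = query,
                        e_cap = cfg$e_cap)
      }
    }
    labs <- name_clusters(h$levels[[1L]], ann)
    cluster_map <- setNames(
      rep(labs, vapply(h$levels[[1L]]$clusters, length, 0L)),
      unlist(h$levels[[1L]]$clusters)
    )
    queries <- lex_sort(setdiff(qh$ids, D$ids))
    cls <- lapply(queries, function(qid) {
      qd <- query_distances(qh, base_ids = D$ids, query = qid,
                            e_cap = cfg$e_cap)
      r <- classify(qd, classifier_config(tau = cfg$tau), cluster_map, remote)
      list(query = r$query, d_min = r$d_min, nearest = r$nearest,
           cluster = r$cluster, verdict = r$verdict,
           remote = r$remote[c("attempted", "d_min", "nearest",
                               "remotely_related")])
    })
    jtxt <- as.character(jsonlite::toJSON(cls, auto_unbox = TRUE,
                                          digits = I(17), pretty = TRUE,
                                          na = "null"))
    writeLines(jtxt, art("classification.json"))
    files <- c(files, art("classification.json"))
    results$classification <- cls
    pipeline_log(cfg, "classified %d queries", length(queries))
  }

  results$files <- files
  invisible(results)
}
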