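#' Construct an annotated network graph document
#'
#' A `graph_document` is the exchange container for every graph this package
#' exports: nodes with arbitrary typed attributes (cluster level, label,
#' family, class, size, centrality values, core membership) and edges with
#' attributes (distance, weight, betweenness, and an edge role from
#' `{core-shortest, toward-core, tree, plain}` standing in for arrowhead
#' semantics that plain graph formats cannot carry).
#'
#' Integer attribute columns are canonicalized to double so that values
#' survive JSON serialization exactly.
#'
#' @param nodes `data.frame` with a character `id` column (unique) plus
#'   attribute columns.
#' @param edges `data.frame` with character `source` and `target` columns
#'   plus attribute columns; endpoints must exist in `nodes$id`.
#' @param directed Logical; kept as a document property (default `FALSE`).
#' @return An object of class `graph_document`.
#' @export
graph_document <- function(nodes = data.frame(id = character(0)),
                           edges = data.frame(source = character(0),
                                              target = character(0)),
                           directed = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"id" %in% names(nodes)) stop_ssn("nodes need an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop_ssn("duplicate node id")
  if (!all(c("source", "target") %in% names(edges))) {
    stop_ssn("edges need 'source' and 'target' columns")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling)) {
    stop_ssn("edge endpoint not among nodes: %s", dangling[1])
  }
  if ("distance" %in% names(edges) &&
      any(!is.na(edges$distance) & edges$distance < 0)) {
    stop_ssn("edge distance must be >= 0")
  }
  nodes[] <- lapply(nodes, function(col) if (is.integer(col)) as.double(col) else col)
  edges[] <- lapply(edges, function(col) if (is.integer(col)) as.double(col) else col)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
            class = "graph_document")
}

#' @export
print.graph_document <- function(x, ...) {
  cat(sprintf("<graph_document> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

graphml_type <- function(col) {
  if (is.character(col)) "string"
  else if (is.logical(col)) "boolean"
  else "double"
}

graphml_render <- function(col) {
  if (is.character(col)) col
  else if (is.logical(col)) ifelse(col, "true", "false")
  else format_full(col)
}

graphml_parse_value <- function(x, type) {
  switch(type,
         string = x,
         boolean = x == "true",
         double = as.numeric(x))
}

#' Serialize a graph document
#'
#' @param doc A [graph_document()].
#' @param fmt One of `"graphml"`, `"cytoscape-json"`, `"edge-list-tsv"`.
#'   GraphML and Cytoscape JSON round-trip losslessly through
#'   [read_graph_document()]; numeric attributes are serialized with full
#'   double precision because E-value-derived distances span more than 150
#'   orders of magnitude. The edge-list TSV holds `source`, `target`,
#'   `distance` only.
#' @param file Optional output path.
#' @return A single character string of serialized text (invisibly when
#'   `file` is given).
#' @export
write_graph_document <- function(doc,
                                 fmt = c("graphml", "cytoscape-json",
                                         "edge-list-tsv"),
                                 file = NULL) {
  stopifnot(inherits(doc, "graph_document"))
  fmt <- match.arg(fmt)
  txt <- switch(fmt,
                "graphml" = graphml_write(doc),
                "cytoscape-json" = cytoscape_write(doc),
                "edge-list-tsv" = edge_tsv_write(doc))
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Parse a serialized graph document
#'
#' Inverse of [write_graph_document()] for the lossless formats.
#'
#' @param x Text (single string or lines) or a file path.
#' @param fmt `"graphml"` or `"cytoscape-json"`.
#' @return A [graph_document()].
#' @export
read_graph_document <- function(x, fmt = c("graphml", "cytoscape-json")) {
  fmt <- match.arg(fmt)
  txt <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  switch(fmt,
         "graphml" = graphml_read(txt),
         "cytoscape-json" = cytoscape_read(txt))
}

graphml_write <- function(doc) {
  xdoc <- xml2::xml_new_root("graphml",
                             xmlns = "http://graphml.graphdrawing.org/xmlns")
  node_attrs <- setdiff(names(doc$nodes), "id")
  edge_attrs <- setdiff(names(doc$edges), c("source", "target"))
  for (a in node_attrs) {
    xml2::xml_add_child(xdoc, "key", id = paste0("v_", a), "for" = "node",
                        "attr.name" = a,
                        "attr.type" = graphml_type(doc$nodes[[a]]))
  }
  for (a in edge_attrs) {
    xml2::xml_add_child(xdoc, "key", id = paste0("e_", a), "for" = "edge",
                        "attr.name" = a,
                        "attr.type" = graphml_type(doc$edges[[a]]))
  }
  g <- xml2::xml_add_child(xdoc, "graph", id = "G",
                           edgedefault = if (doc$directed) "directed" else "undirected")
  nrend <- lapply(doc$nodes[node_attrs], graphml_render)
  for (i in seq_len(nrow(doc$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = doc$nodes$id[i])
    for (a in node_attrs) {
      v <- nrend[[a]][i]
      if (!is.na(v)) xml2::xml_add_child(nd, "data", key = paste0("v_", a), v)
    }
  }
  erend <- lapply(doc$edges[edge_attrs], graphml_render)
  for (i in seq_len(nrow(doc$edges))) {
    ed <- xml2::xml_add_child(g, "edge", source = doc$edges$source[i],
                              target = doc$edges$target[i])
    for (a in edge_attrs) {
      v <- erend[[a]][i]
      if (!is.na(v)) xml2::xml_add_child(ed, "data", key = paste0("e_", a), v)
    }
  }
  as.character(xdoc)
}

graphml_read <- function(txt) {
  xdoc <- xml2::read_xml(txt)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  keys <- xml2::xml_find_all(xdoc, ".//g:key", ns)
  kid <- xml2::xml_attr(keys, "id")
  kfor <- xml2::xml_attr(keys, "for")
  kname <- xml2::xml_attr(keys, "attr.name")
  ktype <- xml2::xml_attr(keys, "attr.type")
  graph <- xml2::xml_find_first(xdoc, ".//g:graph", ns)
  directed <- identical(xml2::xml_attr(graph, "edgedefault"), "directed")

  read_elems <- function(xpath, id_cols) {
    elems <- xml2::xml_find_all(graph, xpath, ns)
    base <- lapply(id_cols, function(a) xml2::xml_attr(elems, a))
    names(base) <- if (identical(id_cols, "id")) "id" else id_cols
    dom <- if (identical(id_cols, "id")) "node" else "edge"
    sel <- kfor == dom
    df <- as.data.frame(base, stringsAsFactors = FALSE)
    for (j in which(sel)) {
      vals <- vapply(elems, function(e) {
        d <- xml2::xml_find_first(e, sprintf("./g:data[@key='%s']", kid[j]), ns)
        if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
      }, character(1))
      df[[kname[j]]] <- graphml_parse_value(vals, ktype[j])
    }
    df
  }

  nodes <- read_elems("./g:node", "id")
  edges <- read_elems("./g:edge", c("source", "target"))
  graph_document(nodes, edges, directed = directed)
}

row_to_data <- function(df, i, skip = character(0)) {
  out <- list()
  for (a in names(df)) {
    if (a %in% skip) next
    v <- df[[a]][i]
    if (!is.na(v)) out[[a]] <- v
  }
  out
}

cytoscape_write <- function(doc) {
  nodes <- lapply(seq_len(nrow(doc$nodes)), function(i) {
    list(data = c(list(id = doc$nodes$id[i]), row_to_data(doc$nodes, i, "id")))
  })
  edges <- lapply(seq_len(nrow(doc$edges)), function(i) {
    list(data = c(list(source = doc$edges$source[i],
                       target = doc$edges$target[i]),
                  row_to_data(doc$edges, i, c("source", "target"))))
  })
  obj <- list(directed = doc$directed, nodes = nodes, edges = edges)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE))
}

elements_to_df <- function(elems, id_cols) {
  attr_names <- character(0)
  for (el in elems) {
    attr_names <- union(attr_names, setdiff(names(el$data), id_cols))
  }
  cols <- c(id_cols, attr_names)
  out <- lapply(cols, function(a) {
    vals <- lapply(elems, function(el) el$data[[a]] %||% NA)
    if (all(vapply(vals, function(v) is.na(v) || is.logical(v), TRUE))) {
      vapply(vals, function(v) if (is.na(v)) NA else isTRUE(v), NA)
    } else if (all(vapply(vals, function(v) is.na(v) || is.numeric(v), TRUE))) {
      vapply(vals, function(v) if (is.na(v)) NA_real_ else as.numeric(v), 0)
    } else {
      vapply(vals, function(v) if (is.na(v)) NA_character_ else as.character(v), "")
    }
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

cytoscape_read <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  nodes <- elements_to_df(obj$nodes, "id")
  edges <- elements_to_df(obj$edges, c("source", "target"))
  graph_document(nodes, edges, directed = isTRUE(obj$directed))
}

edge_tsv_write <- function(doc) {
  d <- doc$edges$distance %||% rep(NA_real_, nrow(doc$edges))
  lines <- paste(doc$edges$source, doc$edges$target, format_full(d), sep = "\t")
  paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
}
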