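#' Construct a table of directed pairwise E-values
#'
#' An `evalue_table` holds the raw similarity evidence of a sequence set:
#' one E-value per ordered (query, subject) pair. Duplicate ordered pairs are
#' collapsed to their minimum E-value (the best hit), matching how repeated
#' HSP lines in an alignment report are summarized. Sequence ids are kept in
#' first-appearance order.
#'
#' @param query,subject Character vectors of sequence ids (same length).
#' @param evalue Numeric vector of E-values, all `>= 0`.
#' @param ids Optional character vector fixing the id universe and order;
#'   defaults to first appearance over `query`/`subject` interleaved row-wise.
#' @return An object of class `evalue_table` with fields `pairs` (a
#'   `data.frame` with columns `query`, `subject`, `evalue`, one row per
#'   ordered pair) and `ids`.
#' @export
evalue_table <- function(query, subject, evalue, ids = NULL) {
  stopifnot(length(query) == length(subject), length(query) == length(evalue))
  query <- as.character(query)
  subject <- as.character(subject)
  evalue <- as.numeric(evalue)
  if (anyNA(evalue) || any(evalue < 0)) {
    stop_ssn("E-values must be numeric and >= 0")
  }
  if (is.null(ids)) {
    ids <- unique(as.vector(rbind(query, subject)))
  } else {
    ids <- as.character(ids)
    extra <- setdiff(c(query, subject), ids)
    if (length(extra)) {
      stop_ssn("pair ids not in supplied id universe: %s",
               paste(extra, collapse = ", "))
    }
  }
  key <- paste(query, subject, sep = "\r")
  keep <- !duplicated(key)
  best <- tapply(evalue, key, min)
  pairs <- data.frame(
    query = query[keep], subject = subject[keep],
    evalue = as.numeric(best[key[keep]]),
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, ids = ids), class = "evalue_table")
}

#' @export
print.evalue_table <- function(x, ...) {
  cat(sprintf("<evalue_table> %d ids, %d directed pairs\n",
              length(x$ids), nrow(x$pairs)))
  invisible(x)
}

#' Parse a pairwise E-value table from BLAST tabular or three-column text
#'
#' Two dialects are supported: the standard 12-column tabular alignment
#' report (E-value in column 11) and a plain three-column
#' `query<TAB>subject<TAB>evalue` table. Fields may be separated by tabs or
#' spaces; lines starting with `#` and blank lines are ignored. Duplicate
#' ordered pairs collapse to the minimum E-value.
#'
#' @param x Path to a file, or a character vector of lines.
#' @param fmt `"blast-tab-12col"` or `"three-col"`.
#' @return An [evalue_table()].
#' @export
parse_evalue_table <- function(x, fmt = c("three-col", "blast-tab-12col")) {
  fmt <- match.arg(fmt)
  lines <- as_text_lines(x)
  ncol_expect <- if (fmt == "blast-tab-12col") 12L else 3L
  ecol <- if (fmt == "blast-tab-12col") 11L else 3L
  q <- s <- character(0)
  e <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) != ncol_expect) {
      stop_ssn("line %d: expected %d columns, found %d", i, ncol_expect, length(f))
    }
    ev <- suppressWarnings(as.numeric(f[ecol]))
    if (is.na(ev)) stop_ssn("line %d: non-numeric E-value '%s'", i, f[ecol])
    if (ev < 0) stop_ssn("line %d: negative E-value %s", i, f[ecol])
    q <- c(q, f[1]); s <- c(s, f[2]); e <- c(e, ev)
  }
  if (!length(q)) stop_ssn("no E-value records found")
  evalue_table(q, s, e)
}

# accept either a file path or a character vector of text lines
as_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
}

# E-value lookup with a default for missing directed pairs
evalue_lookup <- function(ev, default) {
  n <- length(ev$ids)
  m <- matrix(default, n, n, dimnames = list(ev$ids, ev$ids))
  m[cbind(ev$pairs$query, ev$pairs$subject)] <- ev$pairs$evalue
  m
}
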