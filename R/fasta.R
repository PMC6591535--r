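# allowed residue letters: 20 standard amino acids plus ambiguity/special codes
AA_OK <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y","B","X","Z","J","U","O","*")

#' Read protein sequences from FASTA
#'
#' The record id is the first whitespace-delimited token of the header line
#' (matching the id convention of tabular alignment reports, so tables join
#' without munging) and the remainder is kept as the description. Wrapped
#' sequence lines are concatenated and residues uppercased. Residues outside
#' the 20 standard amino-acid letters plus `B X Z J U O *` are rejected with
#' the offending id and character named, as are duplicate ids and empty
#' input. Validation is strict by design: silently sanitized residues would
#' corrupt downstream identity checks.
#'
#' @param x Path to a FASTA file, or a character vector of FASTA text lines.
#' @return A `data.frame` with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(x) {
  lines <- as_text_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_ssn("no records")
  starts <- which(startsWith(lines, ">"))
  if (!length(starts) || starts[1] != 1L) {
    stop_ssn("no records: input does not start with a '>' header")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  id <- character(length(starts))
  desc <- character(length(starts))
  residues <- character(length(starts))
  for (k in seq_along(starts)) {
    hdr <- sub("^>", "", lines[starts[k]])
    id[k] <- sub("[ \t].*$", "", hdr)
    desc[k] <- if (grepl("[ \t]", hdr)) sub("^[^ \t]+[ \t]+", "", hdr) else ""
    if (!nzchar(id[k])) stop_ssn("record %d has an empty id", k)
    body <- lines[seq(starts[k] + 1L, length.out = ends[k] - starts[k])]
    residues[k] <- toupper(paste(gsub("[ \t]", "", body), collapse = ""))
    if (!nzchar(residues[k])) stop_ssn("sequence '%s' is empty", id[k])
    ch <- strsplit(residues[k], "")[[1]]
    bad <- setdiff(ch, AA_OK)
    if (length(bad)) {
      stop_ssn("sequence '%s' contains illegal character '%s'", id[k], bad[1])
    }
  }
  if (anyDuplicated(id)) {
    stop_ssn("duplicate sequence id: %s", id[duplicated(id)][1])
  }
  data.frame(id = id, description = desc, residues = residues,
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA text
#'
#' @param records A `data.frame` as returned by [read_fasta()].
#' @param file Optional path; when `NULL` the FASTA text is returned.
#' @param width Line-wrap width for residues.
#' @return The FASTA lines, invisibly when written to `file`.
#' @export
write_fasta <- function(records, file = NULL, width = 60L) {
  out <- unlist(lapply(seq_len(nrow(records)), function(k) {
    hdr <- if (nzchar(records$description[k])) {
      paste(records$id[k], records$description[k])
    } else records$id[k]
    seq <- records$residues[k]
    starts <- seq(1L, nchar(seq), by = width)
    c(paste0(">", hdr), substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a sequence annotation table
#'
#' Expects a CSV with a header declaring columns `id`, `family`, `class`,
#' `prefix`, `structures`. `structures` holds `;`-separated structure ids and
#' may be empty. The `prefix` is the 2-3 alphanumeric family tag used to name
#' clusters (e.g. `Pe` for peptide receptors, `MiR` for orphans).
#'
#' @param x Path to a CSV file or a character vector of CSV lines.
#' @return A `data.frame` with columns `id`, `family`, `class`, `prefix` and
#'   a list-column `structures`, of class `annotation_table`.
#' @export
read_annotations <- function(x) {
  lines <- as_text_lines(x)
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "family", "class", "prefix")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ssn("annotation header missing column(s): %s",
                             paste(miss, collapse = ", "))
  if (!"structures" %in% names(df)) df$structures <- ""
  if (anyDuplicated(df$id)) {
    stop_ssn("duplicate annotation id: %s", df$id[duplicated(df$id)][1])
  }
  bad <- !grepl("^[A-Za-z0-9]{2,3}$", df$prefix)
  if (any(bad)) {
    stop_ssn("prefix '%s' (id %s) is not 2-3 alphanumeric characters",
             df$prefix[bad][1], df$id[bad][1])
  }
  df$structures <- lapply(strsplit(df$structures, ";", fixed = TRUE),
                          function(s) s[nzchar(s)])
  df <- df[c("id", "family", "class", "prefix", "structures")]
  class(df) <- c("annotation_table", "data.frame")
  df
}

# annotation fields for a set of ids; unknown ids get family/class "unknown",
# prefix "Un"
annotation_for <- function(ids, ann) {
  if (is.null(ann)) ann <- read_annotations("id,family,class,prefix,structures")[0, ]
  i <- match(ids, ann$id)
  data.frame(
    id = ids,
    family = ifelse(is.na(i), "unknown", ann$family[pmax(i, 1L)]),
    class = ifelse(is.na(i), "unknown", ann$class[pmax(i, 1L)]),
    prefix = ifelse(is.na(i), "Un", ann$prefix[pmax(i, 1L)]),
    stringsAsFactors = FALSE
  )
}
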