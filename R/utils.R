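#' @importFrom stats setNames
NULL

# C-locale (radix) ordering so tie-breaks are platform-independent
lex_sort <- function(x) sort(x, method = "radix")
lex_order <- function(x) order(x, method = "radix")

# first element under C-locale ordering
lex_min <- function(x) lex_sort(x)[1L]

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision decimal rendering; round-trips any double through as.numeric()
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

stop_ssn <- function(fmt, ..., class = "seqsimnet_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
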