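#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number desc
#' @importFrom purrr map map_chr map_int map_dbl map_lgl pmap imap keep
#' @importFrom stringr str_sub str_length str_split str_detect str_c
#' @importFrom Rcpp evalCpp
#' @useDynLib vntrscheme, .registration = TRUE
NULL

# single shared nucleotide alphabet
DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

# Levenshtein distance between character vectors (base R edit distance).
lev <- function(a, b) {
  utils::adist(a, b)
}

# vectorised substring without stringr recycling surprises
substr_v <- function(s, start, end) {
  substring(s, start, end)
}

revchars <- function(s) {
  vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

wrap_fasta <- function(s, width = 60) {
  starts <- seq(1, max(nchar(s), 1), by = width)
  vapply(starts, function(i) substr(s, i, min(i + width - 1, nchar(s))), "")
}

# token label as printed in schema code strings: code immediately followed
# by its variant tag (e.g. "B'", "CTT"), "X" for unclassified
token_label <- function(code, tag) {
  paste0(code, ifelse(is.na(tag), "", tag))
}

# split a code string "A-B-C'-A" into a tibble of (type_code, variant_tag)
parse_code_string <- function(x) {
  if (identical(x, "") || is.na(x)) {
    return(tibble(type_code = character(), variant_tag = character()))
  }
  toks <- strsplit(x, "-", fixed = TRUE)[[1]]
  tibble(
    type_code = substr(toks, 1, 1),
    variant_tag = substr(toks, 2, nchar(toks))
  )
}
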