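# Shared fixtures and independent oracles.

the <- new.env(parent = emptyenv())

test_lib <- function() {
  if (is.null(the$lib)) the$lib <- vntr_ru_library()
  the$lib
}

test_entries <- function() {
  if (is.null(the$entries)) the$entries <- vntrscheme:::ru_entries(test_lib())
  the$entries
}

# consensus lookup by token label ("B'" etc.)
label_seq <- function(labels) {
  ent <- test_entries()
  key <- paste0(ent$code, ent$tag)
  idx <- match(labels, key)
  stopifnot(!anyNA(idx))
  ent$consensus[idx]
}

concat_labels <- function(labels) paste(label_seq(labels), collapse = "")

elements_from_labels <- function(label_lists, subfamily = "TEST",
                                 ids = NULL) {
  if (is.null(ids)) ids <- sprintf("%s_%02d", subfamily, seq_along(label_lists))
  tibble::tibble(
    element_id = ids,
    subfamily = subfamily,
    sequence = vapply(label_lists, concat_labels, "")
  )
}

# token tibble built directly from label vectors (for array analyses that
# do not need nucleotide coordinates)
tokens_from_labels <- function(label_lists, subfamily = "TEST",
                               ids = NULL) {
  if (is.null(ids)) ids <- sprintf("%s_%02d", subfamily, seq_along(label_lists))
  rows <- purrr::imap(label_lists, function(labs, i) {
    tibble::tibble(
      element_id = ids[[i]],
      subfamily = subfamily,
      token_index = seq_along(labs),
      type_code = substr(labs, 1, 1),
      variant_tag = substr(labs, 2, nchar(labs)),
      start = (seq_along(labs) - 1L) * 40L,
      end = seq_along(labs) * 40L
    )
  })
  dplyr::bind_rows(rows)
}

mutate_seq <- function(s, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# ---- independent oracles --------------------------------------------------

# cost of one segment under the tokenizer's cost model (shared definition,
# used by both the exhaustive oracle and for pricing a returned tiling)
oracle_seg_cost <- function(seq, i, j, entries, p) {
  L <- j - i + 1
  s <- substr(seq, i, j)
  targets <- entries$consensus
  if (j == nchar(seq) && L < p$w_min) {
    targets <- substr(targets, 1, L)
  }
  d <- min(utils::adist(s, targets))
  min(d, ceiling(0.5 * L)) + p$tau
}

# exhaustive minimum cost over all admissible tilings (brute force over
# segment costs tabulated up front with utils::adist, with a running-cost
# bound that never excludes an optimal tiling)
oracle_min_cost <- function(seq, lib, p = seg_params()) {
  entries <- vntrscheme:::ru_entries(lib)
  n <- nchar(seq)
  if (n == 0) return(0)
  cost_of <- matrix(NA_real_, n, p$w_max)
  for (L in p$w_min:p$w_max) {
    n_starts <- n - L + 1
    if (n_starts < 1) next
    segs <- substring(seq, seq_len(n_starts), seq_len(n_starts) + L - 1)
    d <- apply(utils::adist(segs, entries$consensus), 1, min)
    cost_of[seq_len(n_starts), L] <- pmin(d, ceiling(0.5 * L)) + p$tau
  }
  for (i in seq_len(n)) {
    rem <- n - i + 1
    if (rem < p$w_min) {
      cost_of[i, rem] <- oracle_seg_cost(seq, i, n, entries, p)
    }
  }
  best <- Inf
  rec <- function(i, acc) {
    if (acc >= best) return(invisible())
    if (i > n) {
      best <<- acc
      return(invisible())
    }
    rem <- n - i + 1
    Ls <- p$w_min:p$w_max
    Ls <- Ls[Ls <= rem]
    if (rem < p$w_min) Ls <- rem
    for (L in Ls) {
      rec(i + L, acc + cost_of[i, L])
    }
    invisible()
  }
  rec(1, 0)
  best
}

# price the tiling a schema describes, using the same cost definition
tiling_cost <- function(schema, element_id, lib, p = seg_params()) {
  entries <- vntrscheme:::ru_entries(lib)
  tb <- as_tibble(schema)
  tb <- tb[tb$element_id == element_id, ]
  seq <- attr(schema, "sequences")[[element_id]]
  sum(vapply(seq_len(nrow(tb)), function(i) {
    oracle_seg_cost(seq, tb$start[i] + 1, tb$end[i], entries, p)
  }, 0))
}

# naive character-scan microhomology oracle
oracle_mh <- function(S, Lf, Rf) {
  right <- 0
  k <- min(nchar(S), nchar(Rf))
  for (m in seq_len(k)) {
    if (substr(S, m, m) == substr(Rf, m, m)) right <- right + 1 else break
  }
  left <- 0
  k <- min(nchar(S), nchar(Lf))
  for (m in seq_len(k)) {
    a <- substr(S, nchar(S) - m + 1, nchar(S) - m + 1)
    b <- substr(Lf, nchar(Lf) - m + 1, nchar(Lf) - m + 1)
    if (a == b) left <- left + 1 else break
  }
  list(left = left, right = right)
}

# a pair-simulation template used across ortholog tests: ten tokens,
# single-token deletions keep >=42 bp of designed flank on each side
pair_template_labels <- function() {
  c("A", "B", "C", "A", "D", "K", "G", "C'", "B", "A")
}
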