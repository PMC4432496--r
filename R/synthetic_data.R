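# Ground-truthed synthetic data: subfamily element sets generated from
# array grammars, and ortholog pairs with planted microhomology-designed
# indels.

rand_other_base <- function(base, rng_bases = DNA_BASES) {
  vapply(base, function(b) sample(setdiff(rng_bases, b), 1), "",
         USE.NAMES = FALSE)
}

#' Construct a subfamily array grammar
#'
#' A grammar describes how a subfamily's VNTR is built from the coded RU
#' alphabet: a fixed 5' token array (prefix), an interior (either a
#' repeated motif with one run-variable position, emulating e.g. the
#' internal `K_nGC'` arrays, or an unstructured random token stretch, as
#' in the older subfamilies), a fixed 3' array (suffix), and per-element
#' noise rates.
#'
#' @param name Subfamily label (e.g. `"SVA_F"`).
#' @param prefix,suffix Character vectors of token labels (code plus
#'   variant tag, e.g. `c("A","B","C","A")`, `c("K","G","C'","T")`).
#' @param interior `NULL`, or a list with `type = "motif"` (`tokens`,
#'   `variable_pos`, `copy_range`, `reps`, optional `first_token`
#'   replacing the first token of the first repeat) or `type = "random"`
#'   (`tokens`, `len_range`).
#' @param mutation_rate Substitutions per bp.
#' @param indel_rate Per-element probability of a token-level
#'   duplication/deletion.
#' @return A list of class `subfamily_grammar`.
#' @export
subfamily_grammar <- function(name, prefix, interior = NULL,
                              suffix = character(), mutation_rate = 0,
                              indel_rate = 0) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (!is.null(interior)) {
    stopifnot(interior$type %in% c("motif", "random"))
    if (interior$type == "motif") {
      stopifnot(length(interior$tokens) >= 1,
                length(interior$copy_range) == 2,
                length(interior$reps) == 2)
    }
  }
  structure(list(name = name, prefix = prefix, interior = interior,
                 suffix = suffix, mutation_rate = mutation_rate,
                 indel_rate = indel_rate),
            class = "subfamily_grammar")
}

grammar_labels <- function(g) {
  labs <- c(g$prefix, g$suffix)
  if (!is.null(g$interior)) {
    labs <- c(labs, g$interior$tokens, g$interior$first_token)
  }
  unique(labs)
}

validate_grammar <- function(g, lib) {
  entries <- ru_entries(lib)
  known <- token_label(entries$code, entries$tag)
  bad <- setdiff(grammar_labels(g), known)
  if (length(bad)) {
    abort(paste0("grammar '", g$name, "' references unknown RU token(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(g)
}

#' Read a subfamily grammar from a key-value text file
#'
#' Lines are `key: value`; `#` starts a comment. Token lists are
#' whitespace-separated labels; ranges are two integers.
#'
#' @param path Grammar file path.
#' @return A `subfamily_grammar`.
#' @export
read_grammar <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) abort(paste0("malformed grammar line: '", ln, "'"))
    kv[[m[2]]] <- m[3]
  }
  toks <- function(x) if (is.null(x) || !nzchar(x)) character() else
    strsplit(x, "\\s+")[[1]]
  nums <- function(x) as.numeric(toks(x))
  interior <- NULL
  itype <- kv$interior %||% "none"
  if (itype == "motif") {
    interior <- list(
      type = "motif",
      tokens = toks(kv$interior_tokens),
      variable_pos = as.integer(kv$interior_variable_pos %||% "1"),
      copy_range = as.integer(nums(kv$interior_copy_range)),
      reps = as.integer(nums(kv$interior_reps)),
      first_token = if (!is.null(kv$interior_first_token) &&
                          nzchar(kv$interior_first_token)) {
        kv$interior_first_token
      }
    )
  } else if (itype == "random") {
    interior <- list(
      type = "random",
      tokens = toks(kv$interior_tokens),
      len_range = as.integer(nums(kv$interior_len_range))
    )
  } else if (itype != "none") {
    abort(paste0("unknown interior type: ", itype))
  }
  subfamily_grammar(
    name = kv$name %||% abort("grammar file lacks a name"),
    prefix = toks(kv$prefix),
    interior = interior,
    suffix = toks(kv$suffix),
    mutation_rate = as.numeric(kv$mutation_rate %||% "0"),
    indel_rate = as.numeric(kv$indel_rate %||% "0")
  )
}

#' List or load the packaged subfamily grammars
#'
#' @param name Optional grammar name; when `NULL`, returns the named
#'   vector of available grammar files.
#' @return A `subfamily_grammar`, or a named character vector of paths.
#' @export
packaged_grammars <- function(name = NULL) {
  dir <- system.file("extdata", "grammars", package = "vntrscheme",
                     mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  names(files) <- sub("\\.txt$", "", basename(files))
  if (is.null(name)) return(files)
  if (!name %in% names(files)) {
    abort(paste0("no packaged grammar named '", name, "'"))
  }
  read_grammar(files[[name]])
}

label_consensus <- function(labels, entries) {
  key <- token_label(entries$code, entries$tag)
  idx <- match(labels, key)
  if (anyNA(idx)) {
    abort(paste0("unknown RU token(s): ",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  entries$consensus[idx]
}

realize_tokens <- function(g) {
  toks <- g$prefix
  if (!is.null(g$interior)) {
    if (g$interior$type == "motif") {
      reps <- sample(g$interior$reps[1]:g$interior$reps[2], 1)
      for (r in seq_len(reps)) {
        mt <- g$interior$tokens
        vp <- g$interior$variable_pos
        cnt <- sample(g$interior$copy_range[1]:g$interior$copy_range[2], 1)
        expanded <- c(rep(mt[vp], cnt))
        block <- c(if (vp > 1) mt[seq_len(vp - 1)], expanded,
                   if (vp < length(mt)) mt[(vp + 1):length(mt)])
        if (r == 1 && !is.null(g$interior$first_token)) {
          block[1] <- g$interior$first_token
        }
        toks <- c(toks, block)
      }
    } else {
      len <- sample(g$interior$len_range[1]:g$interior$len_range[2], 1)
      toks <- c(toks, sample(g$interior$tokens, len, replace = TRUE))
    }
  }
  c(toks, g$suffix)
}

#' Generate a synthetic subfamily element set with recorded ground truth
#'
#' Realises `n` elements from a subfamily grammar: token arrays are drawn
#' from the grammar, nucleotide sequences are concatenated library
#' consensi, token-level duplications/deletions occur per `indel_rate`,
#' and point substitutions are drawn uniformly (excluding the original
#' base) at `mutation_rate` per bp. The truth records, for every element,
#' the generating token string, the clean sequence and every mutation, so
#' the emitted sequence can be replayed byte-exactly.
#'
#' @param grammar A `subfamily_grammar` (or the name of a packaged one).
#' @param n Number of elements.
#' @param seed Integer seed; output is deterministic per seed.
#' @param lib An `ru_library` (default: the packaged library).
#' @param mutation_rate,indel_rate Optional overrides of the grammar's
#'   noise rates (used e.g. to generate noise-free sets).
#' @return A list of class `vntr_simulation` with `elements` (tibble:
#'   `element_id`, `subfamily`, `sequence`) and `truth` (tibble:
#'   `element_id`, `generating_tokens` list-column, `clean_sequence`,
#'   `mutations` list-column of `(position, from, to)`).
#' @export
generate_subfamily_set <- function(grammar, n = 10, seed = 1,
                                   lib = vntr_ru_library(),
                                   mutation_rate = NULL,
                                   indel_rate = NULL) {
  if (is.character(grammar)) grammar <- packaged_grammars(grammar)
  if (!is.null(mutation_rate)) grammar$mutation_rate <- mutation_rate
  if (!is.null(indel_rate)) grammar$indel_rate <- indel_rate
  if (n < 1) abort("n must be at least 1")
  validate_grammar(grammar, lib)
  entries <- ru_entries(lib)
  set.seed(seed)
  elements <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- realize_tokens(grammar)
    if (stats::runif(1) < grammar$indel_rate && length(toks) > 1) {
      k <- sample(length(toks), 1)
      if (stats::runif(1) < 0.5) {
        toks <- append(toks, toks[k], after = k)  # token duplication
      } else {
        toks <- toks[-k]                          # token deletion
      }
    }
    clean <- paste(label_consensus(toks, entries), collapse = "")
    bp <- nchar(clean)
    n_mut <- stats::rbinom(1, bp, grammar$mutation_rate)
    mut <- tibble(position = integer(), from = character(),
                  to = character())
    seq <- clean
    if (n_mut > 0) {
      pos <- sort(sample(bp, n_mut))
      v <- strsplit(clean, "")[[1]]
      from <- v[pos]
      to <- rand_other_base(from)
      v[pos] <- to
      seq <- paste(v, collapse = "")
      mut <- tibble(position = pos, from = from, to = to)
    }
    id <- sprintf("%s_%03d", grammar$name, i)
    elements[[i]] <- tibble(element_id = id, subfamily = grammar$name,
                            sequence = seq)
    truth[[i]] <- tibble(element_id = id, generating_tokens = list(toks),
                         clean_sequence = clean, mutations = list(mut))
  }
  structure(list(elements = bind_rows(elements), truth = bind_rows(truth),
                 grammar = grammar, seed = seed),
            class = "vntr_simulation")
}

#' Replay a simulation truth record
#'
#' Applies the recorded mutations to the clean sequence; equality with the
#' emitted sequence is the generator's core invariant.
#'
#' @param truth_row One row of a simulation `truth` tibble.
#' @return The reconstructed sequence.
#' @export
replay_truth <- function(truth_row) {
  v <- strsplit(truth_row$clean_sequence, "")[[1]]
  mut <- truth_row$mutations[[1]]
  if (nrow(mut)) {
    stopifnot(all(v[mut$position] == mut$from))
    v[mut$position] <- mut$to
  }
  paste(v, collapse = "")
}

#' Create an ortholog pair with planted, microhomology-designed indels
#'
#' Starting from one element, emits an "ancestral" and a "derived"
#' haplotype. Each planted deletion removes a span of whole tokens; a
#' designed breakpoint microhomology of `designed_mh` bp is created by
#' copying the first `designed_mh` bases of the deleted segment onto the
#' right flank beforehand (optionally with designed mismatches inside the
#' tract), and the bases bordering the homology are forced to differ so
#' the designed microhomology is maximal and the planted representation is
#' already left-normalized. Duplications tandem-duplicate the span.
#'
#' @param element One-row tibble with `element_id` and `sequence`.
#' @param events Tibble with columns `token_from`, `token_to` (1-based
#'   token indices, inclusive), `designed_mh` (bp), optional `type`
#'   (`"deletion"` default, or `"duplication"`) and optional list-column
#'   `mismatch_at` (positions within the homology tract to mismatch).
#' @param seed Integer seed (used for forced-base draws).
#' @param lib `ru_library` used to tokenize when `tokens` is not given.
#' @param tokens Optional token table with 0-based `start`, `end` (e.g.
#'   from the simulation truth or a schema); segmentation is run when
#'   absent.
#' @return A list of class `vntr_pair_sim` with `pair` (two-row tibble:
#'   ancestral then derived haplotype) and `truth` (planted events with
#'   1-based `planted_start`, `planted_end` on the segment-carrying
#'   haplotype).
#' @export
make_ortholog_pair <- function(element, events, seed = 1,
                               lib = vntr_ru_library(), tokens = NULL) {
  stopifnot(nrow(element) == 1)
  set.seed(seed)
  if (is.null(tokens)) {
    sch <- segment_vntr(element, lib)
    tokens <- as_tibble(sch)
  }
  tokens <- tokens[order(tokens$start), ]
  if (!"type" %in% names(events)) events$type <- "deletion"
  if (!"mismatch_at" %in% names(events)) {
    events$mismatch_at <- rep(list(integer()), nrow(events))
  }
  events <- events[order(events$token_from), ]
  # spans must not overlap
  if (nrow(events) > 1) {
    if (any(events$token_from[-1] <= events$token_to[-nrow(events)])) {
      abort("planted event spans overlap")
    }
  }
  anc <- strsplit(element$sequence, "")[[1]]
  spans <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$token_from < 1 || ev$token_to > nrow(tokens)) {
      abort("event token span outside the element")
    }
    s <- tokens$start[ev$token_from] + 1L  # 1-based inclusive
    e <- tokens$end[ev$token_to]
    S <- anc[s:e]
    m <- ev$designed_mh
    if (m > length(S)) abort("designed_mh exceeds the span length")
    if (ev$type == "deletion") {
      if (m > 0) {
        if (e + m > length(anc)) {
          abort("designed_mh does not fit in the right flank")
        }
        anc[(e + 1):(e + m)] <- S[seq_len(m)]
        for (q in ev$mismatch_at[[1]]) {
          stopifnot(q >= 1, q <= m)
          anc[e + q] <- rand_other_base(S[q])
        }
      }
      # make the designed homology maximal on both sides
      if (m < length(S) && e + m + 1 <= length(anc) &&
          anc[e + m + 1] == S[m + 1]) {
        anc[e + m + 1] <- rand_other_base(S[m + 1])
      }
      if (s > 1 && anc[s - 1] == S[length(S)]) {
        anc[s - 1] <- rand_other_base(S[length(S)])
      }
    }
    spans[[i]] <- c(s, e)
  }
  # derive the second haplotype (right to left so coordinates hold)
  der <- anc
  shift <- 0L
  truth <- events
  truth$planted_start <- NA_integer_
  truth$planted_end <- NA_integer_
  for (i in rev(seq_len(nrow(events)))) {
    s <- spans[[i]][1]; e <- spans[[i]][2]
    if (events$type[i] == "deletion") {
      der <- der[-(s:e)]
    } else {
      der <- append(der, der[s:e], after = e)
    }
  }
  # planted coordinates on the segment-carrying haplotype
  dup_shift <- 0L
  for (i in seq_len(nrow(events))) {
    s <- spans[[i]][1]; e <- spans[[i]][2]
    if (events$type[i] == "deletion") {
      truth$planted_start[i] <- s  # on the ancestral haplotype
      truth$planted_end[i] <- e
    } else {
      truth$planted_start[i] <- s + dup_shift  # on the derived haplotype
      truth$planted_end[i] <- e + dup_shift
      dup_shift <- dup_shift + (e - s + 1L)
    }
  }
  pair <- tibble(
    element_id = paste0(element$element_id, c("_anc", "_der")),
    subfamily = if ("subfamily" %in% names(element)) element$subfamily else
      NA_character_,
    sequence = c(paste(anc, collapse = ""), paste(der, collapse = ""))
  )
  structure(list(pair = pair, truth = truth, seed = seed),
            class = "vntr_pair_sim")
}
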