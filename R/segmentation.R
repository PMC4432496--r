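#' Segmentation parameters
#'
#' Settings for the dynamic-programming decomposition of a VNTR sequence
#' into repeat-unit tokens.
#'
#' @param w_min,w_max Candidate repeat-unit length window in bp. The
#'   default window 25-60 brackets the 30-50 bp range typical of these
#'   GC-rich units and the 53 bp N type, with margin.
#' @param tau Per-token startup penalty added to every tiled unit;
#'   discourages over-segmentation.
#' @param identity_min Minimum identity for assigning a token to a library
#'   type; below it the token is reported unclassified (`X`).
#' @param max_n_frac Maximum tolerated fraction of `N` bases; sequences
#'   above it are refused as assembly-gap cases.
#'
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(w_min = 25L, w_max = 60L, tau = 2,
                       identity_min = 0.75, max_n_frac = 0.1) {
  stopifnot(w_min >= 1, w_max >= w_min, tau >= 0,
            identity_min > 0, identity_min <= 1)
  structure(list(w_min = as.integer(w_min), w_max = as.integer(w_max),
                 tau = tau, identity_min = identity_min,
                 max_n_frac = max_n_frac),
            class = "seg_params")
}

#' Read VNTR elements from FASTA
#'
#' Headers follow `>element_id|subfamily[|assembly:chr:start-end:strand]`;
#' the locus part is optional.
#'
#' @param path FASTA file of pre-extracted VNTR nucleotide sequences.
#' @return A tibble with columns `element_id`, `subfamily`, `source`,
#'   `sequence`.
#' @export
read_vntr_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  fa <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(fa), "|", fixed = TRUE)
  tibble(
    element_id = map_chr(hdr, 1),
    subfamily = map_chr(hdr, function(h) if (length(h) >= 2) h[2] else ""),
    source = map_chr(hdr, function(h) if (length(h) >= 3) h[3] else NA_character_),
    sequence = toupper(unname(as.character(fa)))
  )
}

#' Write VNTR elements to FASTA
#'
#' @param elements Tibble with `element_id`, `sequence` and optionally
#'   `subfamily`, `source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vntr_fasta <- function(elements, path) {
  sub <- if ("subfamily" %in% names(elements)) elements$subfamily else
    rep("", nrow(elements))
  src <- if ("source" %in% names(elements)) elements$source else
    rep(NA_character_, nrow(elements))
  hdr <- paste0(">", elements$element_id, "|", sub,
                ifelse(is.na(src), "", paste0("|", src)))
  out <- character()
  for (i in seq_len(nrow(elements))) {
    out <- c(out, hdr[i], wrap_fasta(elements$sequence[i]))
  }
  writeLines(out, path)
  invisible(path)
}

# distance from a unit to every library entry; truncated units are matched
# against equal-length consensus prefixes
entry_distances <- function(unit, entries, prefix_match = FALSE) {
  targets <- entries$consensus
  if (prefix_match) targets <- substr(targets, 1, nchar(unit))
  as.integer(lev(unit, targets)[1, ])
}

#' Classify a single repeat unit against an RU library
#'
#' Picks the best base type by minimum edit distance over base-type
#' consensus sequences, then the best variant (including the base itself)
#' within that type. Units whose identity to the chosen entry falls below
#' the threshold are reported as unclassified (`X`). Ties are broken
#' alphabetically (base code; then the untagged base before tagged
#' variants).
#'
#' @param unit Nucleotide string.
#' @param lib An `ru_library`.
#' @param identity_min Identity threshold for assignment (default 0.75).
#' @param prefix_match Match against equal-length consensus prefixes
#'   (used for truncated terminal tokens).
#' @return A list with `type_code`, `variant_tag`, `edit_distance`,
#'   `identity`.
#' @export
classify_token <- function(unit, lib, identity_min = 0.75,
                           prefix_match = FALSE) {
  if (!nzchar(unit)) abort("cannot classify an empty unit")
  u <- lib$units
  targets <- u$consensus
  if (prefix_match) targets <- substr(targets, 1, nchar(unit))
  d_base <- as.integer(lev(unit, targets)[1, ])
  base <- u$code[order(d_base, u$code)][1]
  d_best <- min(d_base)
  cand <- bind_rows(
    tibble(tag = "", consensus = u$consensus[u$code == base]),
    tibble(tag = lib$variants$tag[lib$variants$base_code == base],
           consensus = lib$variants$consensus[lib$variants$base_code == base])
  )
  tg <- cand$consensus
  if (prefix_match) tg <- substr(tg, 1, nchar(unit))
  d_var <- as.integer(lev(unit, tg)[1, ])
  k <- order(d_var, nzchar(cand$tag), cand$tag)[1]
  d <- d_var[k]
  denom <- max(nchar(unit), nchar(tg[k]))
  idy <- 1 - d / denom
  if (idy < identity_min) {
    list(type_code = "X", variant_tag = "", edit_distance = d_best,
         identity = 1 - d_best / max(nchar(unit),
                                     nchar(targets[which.min(d_base)])))
  } else {
    list(type_code = base, variant_tag = cand$tag[k], edit_distance = d,
         identity = idy)
  }
}

#' Classify a table of repeat units
#'
#' Data-frame interface to [classify_token()].
#'
#' @param units Tibble with a `unit` column of nucleotide strings.
#' @param lib An `ru_library`.
#' @param identity_min Identity threshold for assignment.
#' @return The input with `type_code`, `variant_tag`, `edit_distance` and
#'   `identity` columns added.
#' @export
classify_units <- function(units, lib, identity_min = 0.75) {
  res <- map(units$unit, classify_token, lib = lib,
             identity_min = identity_min)
  units |>
    mutate(
      type_code = map_chr(res, "type_code"),
      variant_tag = map_chr(res, "variant_tag"),
      edit_distance = map_int(res, function(r) as.integer(r$edit_distance)),
      identity = map_dbl(res, "identity")
    )
}

# ---- dynamic-programming tiling ------------------------------------------

# per-(start, length) minimum library distance, all window lengths in one
# pass per (start, reference) pair; identical windows (tandem periodicity)
# are computed once
unit_cost_table <- function(seq, entries, p) {
  n <- nchar(seq)
  keys <- substring(seq, seq_len(n), pmin(seq_len(n) + p$w_max - 1, n))
  ustart <- which(!duplicated(keys))
  mat <- min_unit_costs(seq, entries$consensus, p$w_min, p$w_max,
                        ustart - 1L)
  list(mat = mat, row_of = match(keys, keys[ustart]))
}

segment_one <- function(seq, lib, p) {
  n <- nchar(seq)
  empty <- tibble(token_index = integer(), type_code = character(),
                  variant_tag = character(), start = integer(),
                  end = integer(), edit_distance = integer(),
                  identity = double(), truncated = logical())
  if (n == 0) return(empty)
  if (!is_dna(seq, allow_n = TRUE)) abort("sequence is not ACGTN")
  n_frac <- mean(strsplit(seq, "")[[1]] == "N")
  if (n_frac > p$max_n_frac) {
    abort(sprintf("assembly-gap: %.0f%% N exceeds the %.0f%% limit",
                  100 * n_frac, 100 * p$max_n_frac))
  }
  entries <- ru_entries(lib)
  if (!nrow(entries)) abort("empty RU library")
  uc <- unit_cost_table(seq, entries, p)

  # final truncated token: seq[i..n] with length < w_min, matched against
  # equal-length consensus prefixes
  trunc_cost <- function(L) {
    segs <- substr(seq, n - L + 1, n)
    d <- entry_distances(segs, entries, prefix_match = TRUE)
    list(dist = min(d), entry = which.min(d))
  }

  seg_cost <- function(i, L) {
    # cost of tiling seq[i .. i+L-1] as one token (1-based start i)
    if (i + L - 1 == n && L < p$w_min) {
      lib_d <- trunc_cost(L)$dist
    } else {
      lib_d <- uc$mat[uc$row_of[i], L - p$w_min + 1]
    }
    xcost <- ceiling(0.5 * L)
    list(cost = min(lib_d, xcost, na.rm = TRUE) + p$tau, lib_d = lib_d)
  }

  # backward DP over suffix costs; TokS = min token count among cost-optimal
  S <- rep(Inf, n + 1)
  TokS <- rep(Inf, n + 1)
  S[n + 1] <- 0
  TokS[n + 1] <- 0
  for (i in n:1) {
    rem <- n - i + 1
    Ls <- (p$w_min):(p$w_max)
    Ls <- Ls[Ls <= rem]
    if (rem < p$w_min) Ls <- rem  # forced truncated final token
    for (L in Ls) {
      sc <- seg_cost(i, L)
      cand <- sc$cost + S[i + L]
      if (cand < S[i] ||
          (cand == S[i] && 1 + TokS[i + L] < TokS[i])) {
        S[i] <- cand
        TokS[i] <- 1 + TokS[i + L]
      }
    }
  }
  if (!is.finite(S[1])) abort("no admissible tiling")  # cannot happen

  # greedy left-to-right reconstruction: among optimal continuations prefer
  # fewer tokens, then the lexicographically smallest token label, then the
  # longest first token
  toks <- list()
  i <- 1
  while (i <= n) {
    rem <- n - i + 1
    Ls <- (p$w_min):(p$w_max)
    Ls <- Ls[Ls <= rem]
    if (rem < p$w_min) Ls <- rem
    cands <- list()
    for (L in Ls) {
      sc <- seg_cost(i, L)
      if (sc$cost + S[i + L] == S[i] && 1 + TokS[i + L] == TokS[i]) {
        truncated <- (i + L - 1 == n && L < p$w_min)
        cl <- classify_token(substr(seq, i, i + L - 1), lib,
                             identity_min = p$identity_min,
                             prefix_match = truncated)
        cands[[length(cands) + 1]] <-
          c(list(L = L, truncated = truncated), cl)
      }
    }
    labs <- map_chr(cands, function(x) token_label(x$type_code, x$variant_tag))
    Lens <- map_int(cands, function(x) as.integer(x$L))
    k <- order(labs, -Lens)[1]
    ch <- cands[[k]]
    toks[[length(toks) + 1]] <- tibble(
      type_code = ch$type_code, variant_tag = ch$variant_tag,
      start = i - 1L, end = i + ch$L - 1L,
      edit_distance = as.integer(ch$edit_distance),
      identity = ch$identity, truncated = ch$truncated
    )
    i <- i + ch$L
  }
  out <- bind_rows(toks)
  out$token_index <- seq_len(nrow(out))
  out[, c("token_index", "type_code", "variant_tag", "start", "end",
          "edit_distance", "identity", "truncated")]
}

#' Segment VNTR sequences into repeat-unit schemata
#'
#' Decomposes each element's VNTR into an ordered, gap-free tiling of
#' repeat-unit tokens by minimum-cost dynamic programming: every tiling
#' token costs its minimum edit distance to any library consensus (an
#' unclassified option costs `ceiling(len/2)`) plus a startup penalty
#' `tau`. Ties are broken deterministically: fewer tokens, then the
#' lexicographically smallest code string, then leftmost-longest tokens.
#' The final token may be shorter than `w_min`; it is matched against
#' equal-length consensus prefixes and flagged `truncated`.
#'
#' @param elements Tibble with columns `element_id` and `sequence`
#'   (optionally `subfamily`), e.g. from [read_vntr_fasta()] or
#'   [generate_subfamily_set()].
#' @param lib An `ru_library`.
#' @param params A [seg_params()] list.
#' @return A `vntr_schema` tibble of tokens with columns `element_id`,
#'   `subfamily`, `token_index`, `type_code`, `variant_tag`, `start`,
#'   `end` (0-based half-open), `edit_distance`, `identity`, `truncated`.
#'   Sequences and parameters are kept as attributes; see
#'   [code_strings()].
#' @export
segment_vntr <- function(elements, lib, params = seg_params()) {
  validate_ru_library(lib)
  stopifnot(all(c("element_id", "sequence") %in% names(elements)))
  sub <- if ("subfamily" %in% names(elements)) elements$subfamily else
    rep(NA_character_, nrow(elements))
  res <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    tk <- segment_one(elements$sequence[i], lib, params)
    if (nrow(tk)) {
      tk$element_id <- elements$element_id[i]
      tk$subfamily <- sub[i]
    } else {
      tk$element_id <- character()
      tk$subfamily <- character()
    }
    res[[i]] <- tk
  }
  out <- bind_rows(res)
  out <- out[, c("element_id", "subfamily", "token_index", "type_code",
                 "variant_tag", "start", "end", "edit_distance",
                 "identity", "truncated")]
  seqs <- elements$sequence
  names(seqs) <- elements$element_id
  structure(out, sequences = seqs, params = params,
            element_ids = elements$element_id,
            class = c("vntr_schema", class(out)))
}

#' Code strings of a schema table
#'
#' Renders each element's token sequence as the textual repeat scheme used
#' throughout: token labels (code plus variant tag) joined by `-`, e.g.
#' `A-B-C'-A`, with `X` for unclassified tokens.
#'
#' @param schema A `vntr_schema` (or any token tibble with `element_id`,
#'   `token_index`, `type_code`, `variant_tag`).
#' @return A tibble with `element_id`, `n_tokens`, `code_string`.
#' @export
code_strings <- function(schema) {
  ids <- attr(schema, "element_ids") %||% unique(schema$element_id)
  tb <- as_tibble(schema) |>
    arrange(.data$element_id, .data$token_index) |>
    group_by(.data$element_id) |>
    summarise(
      n_tokens = dplyr::n(),
      code_string = paste(token_label(.data$type_code, .data$variant_tag),
                          collapse = "-"),
      .groups = "drop"
    )
  missing <- setdiff(ids, tb$element_id)
  if (length(missing)) {
    tb <- bind_rows(tb, tibble(element_id = missing, n_tokens = 0L,
                               code_string = ""))
  }
  tb[match(ids, tb$element_id), ]
}

#' Write a schema token table as TSV
#'
#' @param schema A `vntr_schema`.
#' @param path Output TSV path. A companion `<path>.codes.tsv` holds one
#'   code string per element.
#' @return `path`, invisibly.
#' @export
write_schema_tsv <- function(schema, path) {
  utils::write.table(as_tibble(schema), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cs <- code_strings(schema)
  utils::write.table(cs, paste0(path, ".codes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- de novo unit discovery ----------------------------------------------

majority_consensus <- function(members) {
  # members: same-length nucleotide strings; per-column majority with
  # alphabetical tie-break; returns consensus plus tie columns
  m <- do.call(rbind, strsplit(members, ""))
  cons <- character(ncol(m))
  ties <- integer()
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) ties <- c(ties, j)
    cons[j] <- sort(best)[1]
  }
  list(consensus = paste(cons, collapse = ""), ties = ties)
}

#' Discover repeat-unit consensus sequences from pre-split units
#'
#' Reproduces the unit-sorting procedure used to erect the RU alphabet:
#' units are grouped by exact length, then clustered within each length
#' class by single-linkage at an identity threshold, and each cluster is
#' summarised by a per-column majority-rule consensus. Ties at a column
#' are resolved to the alphabetically first base and reported.
#'
#' @param units Tibble with a `unit` column of nucleotide strings (e.g.
#'   token substrings from a segmentation), one row per observed unit.
#' @param identity_threshold Single-linkage identity threshold within a
#'   length class (default 0.9).
#' @return A tibble with `cluster_id`, `length`, `support`, `consensus`
#'   and a `members` list-column, ordered by support (descending). Columns
#'   where the majority vote was tied are recorded in the `ties`
#'   attribute.
#' @export
discover_units <- function(units, identity_threshold = 0.9) {
  if (!nrow(units)) abort("discover_units: no units supplied")
  if (!all(is_dna(units$unit))) abort("units must be uppercase ACGT")
  lens <- nchar(units$unit)
  clusters <- list()
  ties <- list()
  for (L in sort(unique(lens))) {
    members <- units$unit[lens == L]
    d <- lev(members, members)
    idy <- 1 - d / L
    g <- igraph::graph_from_adjacency_matrix(idy >= identity_threshold,
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      mem <- members[comp == cc]
      mc <- majority_consensus(mem)
      clusters[[length(clusters) + 1]] <- tibble(
        length = L, support = length(mem), consensus = mc$consensus,
        members = list(mem)
      )
      ties[[length(ties) + 1]] <- if (length(mc$ties)) {
        tibble(consensus = mc$consensus, column = mc$ties)
      }
    }
  }
  out <- bind_rows(clusters) |>
    arrange(desc(.data$support), .data$length) |>
    mutate(cluster_id = row_number()) |>
    select("cluster_id", "length", "support", "consensus", "members")
  tie_tb <- bind_rows(ties)
  if (!nrow(tie_tb)) {
    tie_tb <- tibble(consensus = character(), column = integer())
  }
  structure(out, ties = tie_tb)
}
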