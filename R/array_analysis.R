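# Conserved repeat-unit arrays, position-specific consensi and internal
# motif mining over sets of repeat schemata from one subfamily.

schema_label_lists <- function(tokens, variant_sensitive = TRUE) {
  tb <- as_tibble(tokens) |>
    arrange(.data$element_id, .data$token_index)
  labs <- if (variant_sensitive) {
    token_label(tb$type_code, tb$variant_tag)
  } else {
    tb$type_code
  }
  split(labs, tb$element_id)
}

greedy_conserved <- function(label_lists, theta) {
  n <- length(label_lists)
  alive <- rep(TRUE, n)
  out <- list()
  fail <- NULL
  k <- 0
  repeat {
    k <- k + 1
    kth <- map_chr(label_lists, function(x) {
      if (length(x) >= k) x[k] else NA_character_
    })
    cand <- kth[alive & !is.na(kth)]
    if (!length(cand)) break
    tab <- sort(table(cand), decreasing = TRUE)
    best <- names(tab)[1]
    new_alive <- alive & !is.na(kth) & kth == best
    support <- sum(new_alive) / n
    if (support < theta) {
      # the position where conservation breaks down; a coexisting minority
      # structure diverges here
      fail <- list(k = k, label = best,
                   minority = alive & (is.na(kth) | kth != best))
      break
    }
    out[[k]] <- tibble(position = k, label = best, support = support)
    alive <- new_alive
  }
  tb <- bind_rows(out)
  if (!nrow(tb)) {
    tb <- tibble(position = integer(), label = character(),
                 support = double())
  }
  list(tb = tb, fail = fail)
}

split_labels <- function(tb) {
  if (!nrow(tb)) {
    return(tibble(position = integer(), type_code = character(),
                  variant_tag = character(), support = double()))
  }
  tb |>
    mutate(type_code = substr(.data$label, 1, 1),
           variant_tag = substr(.data$label, 2, nchar(.data$label))) |>
    select("position", "type_code", "variant_tag", "support")
}

#' Derive conserved 5'/3' repeat-unit arrays for a subfamily
#'
#' The conserved 5' array (prefix) is the longest token list `P` such that
#' the fraction of schemata beginning with `P` is at least `theta`; it is
#' grown greedily one position at a time, taking the most common token at
#' each position among the schemata that still match, so the result is
#' maximal: extending it by one further token would drop support below the
#' threshold. The 3' array (suffix) is derived symmetrically from the 3'
#' end. When a sizeable minority carries a different 5' structure, the
#' best alternative prefix over the non-matching schemata is reported as
#' well rather than forced into one consensus.
#'
#' @param tokens A `vntr_schema` token tibble; all rows must carry the
#'   same `subfamily` label and there must be at least two elements.
#' @param theta Support threshold for "conserved" (default 0.7).
#' @param variant_sensitive Compare tokens on `(type_code, variant_tag)`
#'   (default); otherwise on `type_code` only.
#' @return An object of class `array_consensus`: a list with tibbles
#'   `prefix`, `suffix` (columns `position`, `type_code`, `variant_tag`,
#'   `support`; suffix positions count -1, -2, ... from the 3' end in 5'
#'   to 3' order), `alt_prefix` (supports measured within the minority
#'   subset), and fields `subfamily`, `n_elements`, `n_alt`, `theta`.
#' @export
consensus_arrays <- function(tokens, theta = 0.7, variant_sensitive = TRUE) {
  tb <- as_tibble(tokens)
  if (!nrow(tb)) abort("consensus_arrays: empty schema set")
  subs <- unique(tb$subfamily)
  subs <- subs[!is.na(subs)]
  if (length(subs) > 1) {
    abort(paste0("mixed subfamily labels: ", paste(subs, collapse = ", ")))
  }
  lls <- schema_label_lists(tb, variant_sensitive)
  if (length(lls) < 2) abort("consensus_arrays: need at least two schemata")
  n <- length(lls)

  pre_run <- greedy_conserved(lls, theta)
  pre <- pre_run$tb
  suf_rev <- greedy_conserved(map(lls, rev), theta)$tb

  # minority 5' structure: the branch diverging where conservation broke
  alt <- tibble(position = integer(), label = character(),
                support = double())
  n_alt <- 0L
  if (!is.null(pre_run$fail) && sum(pre_run$fail$minority) >= 2) {
    n_alt <- sum(pre_run$fail$minority)
    alt <- greedy_conserved(lls[pre_run$fail$minority], theta)$tb
  }

  suf <- suf_rev
  if (nrow(suf)) {
    suf <- suf |>
      mutate(position = -.data$position) |>
      arrange(.data$position)
  } else {
    suf$position <- integer()
  }

  structure(
    list(
      subfamily = if (length(subs)) subs else NA_character_,
      n_elements = n,
      n_alt = as.integer(n_alt),
      theta = theta,
      variant_sensitive = variant_sensitive,
      prefix = split_labels(pre),
      suffix = split_labels(suf),
      alt_prefix = split_labels(alt)
    ),
    class = "array_consensus"
  )
}

#' Render a conserved array in compact code style
#'
#' @param x An `array_consensus` or a tibble with `type_code` and
#'   `variant_tag` columns.
#' @param which For an `array_consensus`, one of `"prefix"`, `"suffix"`,
#'   `"alt_prefix"`.
#' @return A single string such as `"ABCAAAB'CACAAF"`.
#' @export
render_array <- function(x, which = "prefix") {
  tb <- if (inherits(x, "array_consensus")) x[[which]] else x
  paste(token_label(tb$type_code, tb$variant_tag), collapse = "")
}

#' @export
print.array_consensus <- function(x, ...) {
  cat("<array_consensus> ", x$subfamily, " (n = ", x$n_elements,
      ", theta = ", x$theta, ")\n", sep = "")
  cat("  5' array: ", render_array(x, "prefix"), "\n", sep = "")
  cat("  3' array: ", render_array(x, "suffix"), "\n", sep = "")
  if (nrow(x$alt_prefix)) {
    cat("  alt 5' array (", x$n_alt, " elements): ",
        render_array(x, "alt_prefix"), "\n", sep = "")
  }
  invisible(x)
}

#' Position-specific nucleotide consensus within a conserved array
#'
#' Collects the token substrings occupying one position of the derived
#' conserved 5' (or 3') array across elements and returns their
#' majority-rule nucleotide consensus (column-wise vote over the
#' substrings of the modal length, alphabetical tie-break). If a library
#' is supplied the consensus is also classified to its RU type.
#'
#' @param tokens A `vntr_schema` token tibble (with sequences attached, as
#'   returned by [segment_vntr()]).
#' @param position Array position: counted from 1 at the 5' end for
#'   `side = "prefix"`, and from -1 at the 3' end for `side = "suffix"`.
#' @param side `"prefix"` or `"suffix"`.
#' @param lib Optional `ru_library` used to classify the consensus.
#' @param theta Support threshold passed to [consensus_arrays()].
#' @return A one-row tibble with `position`, `side`, `n_units`,
#'   `consensus` and (if `lib` is given) `type_code`, `variant_tag`.
#' @export
position_specific_consensus <- function(tokens, position,
                                        side = c("prefix", "suffix"),
                                        lib = NULL, theta = 0.7) {
  side <- match.arg(side)
  tb <- as_tibble(tokens)
  seqs <- attr(tokens, "sequences")
  if (is.null(seqs)) abort("tokens must carry element sequences")
  ac <- consensus_arrays(tokens, theta = theta)
  arr <- ac[[side]]
  if (!nrow(arr) || !(position %in% arr$position)) {
    abort(sprintf("position %d lies outside the derived %s array",
                  position, side))
  }
  per <- split(tb[order(tb$token_index), ], tb$element_id[order(tb$token_index)])
  units <- character()
  outside <- 0L
  for (id in names(per)) {
    sch <- per[[id]]
    idx <- if (side == "prefix") position else nrow(sch) + 1L + position
    if (idx < 1 || idx > nrow(sch)) { outside <- outside + 1L; next }
    units <- c(units, substr(seqs[[id]], sch$start[idx] + 1, sch$end[idx]))
  }
  if (outside > length(per) / 2) {
    abort("position falls outside the schema for more than half the elements")
  }
  mode_len <- as.integer(names(sort(table(nchar(units)),
                                    decreasing = TRUE))[1])
  cons <- majority_consensus(units[nchar(units) == mode_len])$consensus
  out <- tibble(position = position, side = side,
                n_units = length(units), consensus = cons)
  if (!is.null(lib)) {
    cl <- classify_token(cons, lib)
    out$type_code <- cl$type_code
    out$variant_tag <- cl$variant_tag
  }
  out
}

# run-length encode a label vector
rle_labels <- function(labels) {
  r <- rle(labels)
  tibble(label = r$values, count = r$lengths)
}

#' Mine repeated internal repeat-unit arrays
#'
#' Run-length-compresses each element's interior token string (the part
#' between the derived conserved 5' and 3' arrays) and reports repeated
#' compressed subsequences of 2-6 symbols that occur at least twice within
#' an element, in at least a fraction `theta` of elements. At most one
#' position of a motif may have a variable run length; its observed range
#' over all occurrences is reported (e.g. the internal `K_nGC'` arrays, or
#' `Q`-scaffolded `C`-runs). Motifs that are contiguous sub-patterns or
#' rotations of a better-supported motif are suppressed.
#'
#' @param tokens A `vntr_schema` token tibble for one subfamily.
#' @param theta Fraction of elements in which a motif must repeat
#'   (default 0.7).
#' @param prefix_len,suffix_len Number of tokens to strip from each end
#'   before mining; derived from [consensus_arrays()] when `NULL`.
#' @param variant_sensitive Compare tokens on `(type_code, variant_tag)`.
#' @return A tibble with `motif`, a `tokens` list-column, `variable_pos`
#'   (NA when all runs are fixed), `copy_min`, `copy_max`, `occurrences`,
#'   `n_elements`, `support`.
#' @export
mine_internal_arrays <- function(tokens, theta = 0.7, prefix_len = NULL,
                                 suffix_len = NULL,
                                 variant_sensitive = TRUE) {
  lls <- schema_label_lists(tokens, variant_sensitive)
  n_el <- length(lls)
  if (is.null(prefix_len) || is.null(suffix_len)) {
    if (n_el >= 2) {
      ac <- consensus_arrays(tokens, theta = theta,
                             variant_sensitive = variant_sensitive)
      if (is.null(prefix_len)) prefix_len <- nrow(ac$prefix)
      if (is.null(suffix_len)) suffix_len <- nrow(ac$suffix)
    } else {
      prefix_len <- prefix_len %||% 0L
      suffix_len <- suffix_len %||% 0L
    }
  }
  empty <- tibble(motif = character(), tokens = list(),
                  variable_pos = integer(), copy_min = integer(),
                  copy_max = integer(), occurrences = integer(),
                  n_elements = integer(), support = double())

  sep <- "\u1f"
  pat_key <- function(toks) paste(toks, collapse = sep)

  # smallest period of a label vector; windows that merely lap a shorter
  # cycle (period < length) are redundant
  smallest_period <- function(toks) {
    w <- length(toks)
    for (p in seq_len(w - 1)) {
      if (all(toks == toks[((seq_len(w) - 1) %% p) + 1])) return(p)
    }
    w
  }

  min_rotation <- function(toks) {
    w <- length(toks)
    rots <- vapply(seq_len(w), function(r) {
      pat_key(toks[((seq_len(w) + r - 2) %% w) + 1])
    }, "")
    sort(rots)[1]
  }

  # first position where a pattern matches a full (uncropped) schema's
  # run-compressed labels; anchors the phase of a cyclic motif to where
  # the repeated region begins in the element
  first_full_match <- function(full_labels, toks) {
    w <- length(toks)
    m <- length(full_labels)
    if (m < w) return(Inf)
    for (s in seq_len(m - w + 1)) {
      if (all(full_labels[s:(s + w - 1)] == toks)) return(s)
    }
    Inf
  }

  # per element: aperiodic window pattern -> occurrence starts and
  # run-count matrices
  hits <- list()
  for (id in names(lls)) {
    lab <- lls[[id]]
    if (length(lab) <= prefix_len + suffix_len) next
    interior <- lab[(prefix_len + 1):(length(lab) - suffix_len)]
    full_r <- rle_labels(lab)
    r <- rle_labels(interior)
    m <- nrow(r)
    for (w in 2:min(6, m)) {
      for (s in seq_len(m - w + 1)) {
        toks <- r$label[s:(s + w - 1)]
        if (smallest_period(toks) < w) next
        hits[[length(hits) + 1]] <- tibble(
          element_id = id, key = pat_key(toks),
          class = min_rotation(toks), w = w, start = s,
          full_start = first_full_match(full_r$label, toks),
          counts = list(r$count[s:(s + w - 1)])
        )
      }
    }
  }
  if (!length(hits)) return(empty)
  hits <- bind_rows(hits)

  # representative rotation per cycle class: the phase that appears
  # earliest in the full schemata
  rep_key <- hits |>
    group_by(.data$class, .data$key) |>
    summarise(first_start = min(.data$full_start), .groups = "drop_last") |>
    arrange(.data$first_start, .data$key) |>
    summarise(key = .data$key[1], .groups = "drop")
  hits <- hits |> filter(.data$key %in% rep_key$key)

  per_key <- hits |>
    group_by(.data$element_id, .data$key, .data$w) |>
    summarise(occ = dplyr::n(), counts = list(do.call(rbind, .data$counts)),
              .groups = "drop") |>
    filter(.data$occ >= 2)
  if (!nrow(per_key)) return(empty)

  agg <- per_key |>
    group_by(.data$key, .data$w) |>
    summarise(
      n_elements = dplyr::n(),
      occurrences = sum(.data$occ),
      counts = list(do.call(rbind, .data$counts)),
      .groups = "drop"
    ) |>
    filter(.data$n_elements >= theta * n_el)
  if (!nrow(agg)) return(empty)

  rows <- list()
  for (i in seq_len(nrow(agg))) {
    cm <- agg$counts[[i]]
    varying <- which(apply(cm, 2, function(x) length(unique(x)) > 1))
    if (length(varying) > 1) next
    toks <- strsplit(agg$key[i], sep, fixed = TRUE)[[1]]
    vp <- if (length(varying)) varying else NA_integer_
    run_col <- if (length(varying)) varying else 1L
    labs <- toks
    if (length(varying)) labs[vp] <- paste0(labs[vp], "_n")
    rows[[length(rows) + 1]] <- tibble(
      motif = paste(labs, collapse = ""),
      tokens = list(toks),
      variable_pos = vp,
      copy_min = min(cm[, run_col]),
      copy_max = max(cm[, run_col]),
      occurrences = agg$occurrences[i],
      n_elements = agg$n_elements[i],
      support = agg$n_elements[i] / n_el
    )
  }
  if (!length(rows)) return(empty)
  out <- bind_rows(rows) |>
    arrange(desc(lengths(.data$tokens)), desc(.data$occurrences),
            .data$motif)

  # longer cycles dominate their contiguous sub-patterns and rotations
  kept <- list()
  for (i in seq_len(nrow(out))) {
    ti <- out$tokens[[i]]
    redundant <- FALSE
    for (k in kept) {
      if (grepl(pat_key(ti), pat_key(c(k, k)), fixed = TRUE)) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept[[length(kept) + 1]] <- ti
  }
  out |>
    filter(map_lgl(.data$tokens, function(t) {
      any(map_lgl(kept, function(k) identical(k, t)))
    })) |>
    arrange(desc(.data$occurrences), .data$motif)
}
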