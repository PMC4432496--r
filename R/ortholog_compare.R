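# Pairwise comparison of orthologous VNTRs: repeat-unit copy-number indel
# calling, breakpoint microhomology measurement, mechanism compatibility.

#' Mechanism-compatibility configuration
#'
#' Thresholds used to label indel events with the copy-number mechanisms
#' they are compatible with: `mh_min` is the shortest breakpoint
#' microhomology considered microhomology-mediated (5 bp, the lower end of
#' the observed 5-42 bp range); `nahr_min` the minimum efficient
#' processing segment for non-allelic homologous recombination (34 bp);
#' `slippage_window` the single-strand distance available to replication
#' slippage, about one Okazaki fragment (200 bp in humans);
#' `relaxed_identity` allows for divergence within a microhomology tract
#' when the two species' sequences have evolved apart.
#'
#' @param mh_min Minimum relaxed microhomology for `mh_mediated` (bp).
#' @param nahr_min Minimum microhomology for `nahr_compatible` (bp).
#' @param slippage_window Maximum `length + mh` for `slippage_compatible`
#'   (bp).
#' @param relaxed_identity Running identity floor when extending a
#'   microhomology across mismatches.
#' @param merge_distance Events closer than this many bp are merged and
#'   re-measured (flagged, not silent).
#' @param match,mismatch,gap_open,gap_extend Nucleotide alignment scoring
#'   within difference windows (favouring contiguous indels over scattered
#'   gaps in GC-rich repeats).
#' @return A list of class `mechanism_config`.
#' @export
mechanism_config <- function(mh_min = 5L, nahr_min = 34L,
                             slippage_window = 200L,
                             relaxed_identity = 0.9,
                             merge_distance = 10L,
                             match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 1) {
  stopifnot(mh_min > 0, mh_min <= nahr_min, slippage_window > 0,
            relaxed_identity > 0, relaxed_identity <= 1)
  structure(list(mh_min = as.integer(mh_min),
                 nahr_min = as.integer(nahr_min),
                 slippage_window = as.integer(slippage_window),
                 relaxed_identity = relaxed_identity,
                 merge_distance = as.integer(merge_distance),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "mechanism_config")
}

nw_align <- function(a, b, cfg) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = cfg$match,
                                                 mismatch = cfg$mismatch,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = cfg$gap_open,
                                      gapExtension = cfg$gap_extend)
  list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa))
  )
}

# walk two aligned strings; return gap runs with coordinates in each
# ungapped sequence (1-based inclusive on the sequence carrying the bases)
gap_events <- function(al_a, al_b, off_a = 0L, off_b = 0L) {
  va <- strsplit(al_a, "")[[1]]
  vb <- strsplit(al_b, "")[[1]]
  pa <- cumsum(va != "-")
  pb <- cumsum(vb != "-")
  in_a <- vb == "-"   # bases present in a only
  in_b <- va == "-"
  out <- list()
  collect <- function(mask, carrier) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      if (carrier == "a") {
        out[[length(out) + 1]] <<- tibble(
          carrier = "a",
          start = off_a + pa[i], end = off_a + pa[j],
          other_pos = off_b + pb[i]  # base before the gap on b
        )
      } else {
        out[[length(out) + 1]] <<- tibble(
          carrier = "b",
          start = off_b + pb[i], end = off_b + pb[j],
          other_pos = off_a + pa[i]
        )
      }
    }
  }
  collect(in_a, "a")
  collect(in_b, "b")
  bind_rows(out) %||% tibble(carrier = character(), start = integer(),
                             end = integer(), other_pos = integer())
}

# token-level edit script (LCS-style) over two label vectors; returns runs
# of non-matching tokens as candidate windows with matched anchors
token_diff_windows <- function(lab_a, lab_b) {
  na <- length(lab_a)
  nb <- length(lab_b)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1, j + 1] <- min(
        d[i, j] + (lab_a[i] != lab_b[j]),
        d[i, j + 1] + 1L,
        d[i + 1, j] + 1L
      )
    }
  }
  # backtrace collecting matched token pairs
  i <- na; j <- nb
  matches <- list()
  while (i > 0 && j > 0) {
    if (lab_a[i] == lab_b[j] && d[i + 1, j + 1] == d[i, j]) {
      matches[[length(matches) + 1]] <- c(i, j)
      i <- i - 1; j <- j - 1
    } else if (d[i + 1, j + 1] == d[i, j] + 1L) {
      i <- i - 1; j <- j - 1
    } else if (d[i + 1, j + 1] == d[i, j + 1] + 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  m <- if (length(matches)) {
    do.call(rbind, rev(matches))
  } else {
    matrix(integer(), ncol = 2)
  }
  # windows between consecutive matched anchors where something differs
  anchors <- rbind(c(0L, 0L), m, c(na + 1L, nb + 1L))
  wins <- list()
  for (k in seq_len(nrow(anchors) - 1)) {
    a0 <- anchors[k, ]; a1 <- anchors[k + 1, ]
    if (a1[1] - a0[1] > 1 || a1[2] - a0[2] > 1) {
      wins[[length(wins) + 1]] <- tibble(
        a_from = a0[1], a_to = a1[1], b_from = a0[2], b_to = a1[2]
      )
    }
  }
  list(script_distance = d[na + 1, nb + 1],
       windows = bind_rows(wins) %||%
         tibble(a_from = integer(), a_to = integer(),
                b_from = integer(), b_to = integer()))
}

left_normalize <- function(seq, start, end) {
  # deletion of seq[start..end] (1-based inclusive); shift maximally 5'-ward
  v <- strsplit(seq, "")[[1]]
  while (start > 1 && v[start - 1] == v[end]) {
    start <- start - 1
    end <- end - 1
  }
  c(start, end)
}

shift_range <- function(seq, start, end) {
  # all equivalent representations right of the normalized one
  v <- strsplit(seq, "")[[1]]
  reps <- list(c(start, end))
  s <- start; e <- end
  while (e < length(v) && v[s] == v[e + 1]) {
    s <- s + 1; e <- e + 1
    reps[[length(reps) + 1]] <- c(s, e)
  }
  reps
}

#' Align an ortholog pair and call repeat-unit copy-number indels
#'
#' Two-stage comparison of a pair of VNTR sequences derived from a common
#' ancestor: a token-level edit script over the two repeat schemata first
#' localises candidate copy-number differences, then a nucleotide-level
#' global alignment inside each difference window (flanked by matched
#' anchor tokens) fixes the breakpoints. Indels are reported on the
#' sequence that carries the extra bases, left-normalized (shifted
#' maximally 5'-ward), and events closer than `merge_distance` are merged
#' and flagged. Polarity (insertion versus deletion) is not assigned:
#' without an outgroup the direction of the change cannot be decided.
#'
#' @param pair Tibble with two rows and columns `element_id`, `sequence`
#'   (e.g. from [read_vntr_fasta()] or [make_ortholog_pair()]).
#' @param lib An `ru_library`.
#' @param params [seg_params()] used for both schemata.
#' @param cfg [mechanism_config()]; alignment scoring and merging.
#' @return An object of class `vntr_alignment`: a list with the two
#'   sequences and schemata (`long`/`short`, assigned by length), the raw
#'   `events` tibble (1-based inclusive `start`, `end` on the carrier),
#'   and the token edit script distance.
#' @export
align_pair <- function(pair, lib, params = seg_params(),
                       cfg = mechanism_config()) {
  stopifnot(nrow(pair) == 2)
  if (any(!nzchar(pair$sequence))) abort("empty sequence in pair")
  ord <- order(-nchar(pair$sequence))
  long <- pair[ord[1], ]
  short <- pair[ord[2], ]
  sch <- segment_vntr(bind_rows(long, short), lib, params)
  tb <- as_tibble(sch)
  sch_long <- tb[tb$element_id == long$element_id, ]
  sch_short <- tb[tb$element_id == short$element_id, ]
  lab_long <- token_label(sch_long$type_code, sch_long$variant_tag)
  lab_short <- token_label(sch_short$type_code, sch_short$variant_tag)

  td <- token_diff_windows(lab_long, lab_short)
  events <- list()
  for (k in seq_len(nrow(td$windows))) {
    w <- td$windows[k, ]
    # nucleotide window: from start of the token after the left anchor's
    # predecessor (i.e. include the anchor tokens themselves as flanks)
    la <- max(w$a_from, 1L)
    lb <- max(w$b_from, 1L)
    ra <- min(w$a_to, nrow(sch_long))
    rb <- min(w$b_to, nrow(sch_short))
    a0 <- if (w$a_from >= 1) sch_long$start[la] + 1L else 1L
    a1 <- if (w$a_to <= nrow(sch_long)) sch_long$end[ra] else nchar(long$sequence)
    b0 <- if (w$b_from >= 1) sch_short$start[lb] + 1L else 1L
    b1 <- if (w$b_to <= nrow(sch_short)) sch_short$end[rb] else nchar(short$sequence)
    sub_a <- substr(long$sequence, a0, a1)
    sub_b <- substr(short$sequence, b0, b1)
    if (!nzchar(sub_a) || !nzchar(sub_b)) next
    al <- nw_align(sub_a, sub_b, cfg)
    ev <- gap_events(al$a, al$b, off_a = a0 - 1L, off_b = b0 - 1L)
    if (nrow(ev)) {
      ev$carrier <- ifelse(ev$carrier == "a", "long", "short")
      events[[length(events) + 1]] <- ev
    }
  }
  events <- bind_rows(events) %||%
    tibble(carrier = character(), start = integer(), end = integer(),
           other_pos = integer())

  # left-normalize on the carrier
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      cs <- if (events$carrier[i] == "long") long$sequence else short$sequence
      se <- left_normalize(cs, events$start[i], events$end[i])
      events$start[i] <- se[1]
      events$end[i] <- se[2]
    }
    events <- events |> arrange(.data$start) |> mutate(merged = FALSE)
    # merge adjacent events on the same carrier closer than merge_distance
    i <- 1
    while (i < nrow(events)) {
      if (events$carrier[i + 1] == events$carrier[i] &&
          events$start[i + 1] - events$end[i] <= cfg$merge_distance) {
        events$end[i] <- max(events$end[i], events$end[i + 1])
        events$merged[i] <- TRUE
        events <- events[-(i + 1), ]
      } else {
        i <- i + 1
      }
    }
  } else {
    events$merged <- logical()
  }
  events$length <- if (nrow(events)) {
    events$end - events$start + 1L
  } else {
    integer()
  }

  structure(
    list(
      pair_id = paste(long$element_id, short$element_id, sep = "|"),
      long_id = long$element_id, short_id = short$element_id,
      seq_long = long$sequence, seq_short = short$sequence,
      schema_long = sch_long, schema_short = sch_short,
      token_distance = td$script_distance,
      events = events,
      cfg = cfg
    ),
    class = "vntr_alignment"
  )
}

mh_exact_right <- function(S, Rf) {
  m <- 0
  k <- min(nchar(S), nchar(Rf))
  while (m < k && substr(S, m + 1, m + 1) == substr(Rf, m + 1, m + 1)) {
    m <- m + 1
  }
  m
}

mh_exact_left <- function(S, Lf) {
  mh_exact_right(revchars(S), revchars(Lf))
}

mh_relaxed_side <- function(S, Fl, relaxed_identity) {
  # largest m with running identity of the first m columns >= floor,
  # ending on a match
  k <- min(nchar(S), nchar(Fl))
  if (k == 0) return(0L)
  s <- strsplit(substr(S, 1, k), "")[[1]]
  f <- strsplit(substr(Fl, 1, k), "")[[1]]
  eq <- s == f
  idy <- cumsum(eq) / seq_len(k)
  ok <- which(eq & idy >= relaxed_identity)
  if (length(ok)) max(ok) else 0L
}

#' Measure breakpoint microhomology for called events
#'
#' For each indel, with deleted/inserted segment `S` and the carrier's
#' left and right flanks `Lf`, `Rf`: the exact right microhomology is the
#' longest prefix of `S` equal to the prefix of `Rf`; the exact left
#' microhomology the longest suffix of `S` equal to the suffix of `Lf`;
#' the relaxed microhomology extends across mismatches while the running
#' identity stays at or above `relaxed_identity` (divergent evolution can
#' erode identity within a genuine homology tract), and is the larger of
#' the two sides.
#'
#' @param alignment A `vntr_alignment` from [align_pair()].
#' @param events Optional subset of `alignment$events` rows to measure
#'   (default: all). Rows must describe indels present in the alignment.
#' @return The events tibble with `mh_exact_left`, `mh_exact_right`,
#'   `mh_relaxed`, `inserted_bases`, `tract_distance` columns added.
#' @export
measure_microhomology <- function(alignment, events = NULL) {
  ev <- events %||% alignment$events
  if (!is.null(events) && nrow(events)) {
    known <- paste(alignment$events$carrier, alignment$events$start,
                   alignment$events$end)
    got <- paste(ev$carrier, ev$start, ev$end)
    if (!all(got %in% known)) {
      abort("window does not contain a called indel")
    }
  }
  n <- nrow(ev)
  ev$mh_exact_left <- integer(n)
  ev$mh_exact_right <- integer(n)
  ev$mh_relaxed <- integer(n)
  ev$inserted_bases <- character(n)
  for (i in seq_len(n)) {
    cs <- if (ev$carrier[i] == "long") alignment$seq_long else alignment$seq_short
    S <- substr(cs, ev$start[i], ev$end[i])
    Lf <- substr(cs, 1, ev$start[i] - 1)
    Rf <- substr(cs, ev$end[i] + 1, nchar(cs))
    el <- mh_exact_left(S, Lf)
    er <- mh_exact_right(S, Rf)
    rl <- mh_relaxed_side(revchars(S), revchars(Lf),
                          alignment$cfg$relaxed_identity)
    rr <- mh_relaxed_side(S, Rf, alignment$cfg$relaxed_identity)
    ev$mh_exact_left[i] <- el
    ev$mh_exact_right[i] <- er
    ev$mh_relaxed[i] <- max(el, er, rl, rr)
    ev$inserted_bases[i] <- ""  # contiguous gaps carry no novel junction bases
  }
  ev$tract_distance <- ev$length
  ev
}

#' Label events with mechanism compatibility
#'
#' Labels are compatibility flags, not exclusive calls, and may co-occur:
#' `precise_ru_indel` when some equivalent representation of the indel
#' spans a whole number of classified repeat-unit tokens with both
#' breakpoints on token boundaries; `ru_conversion_microindel` for micro
#' indels (at most 5 bp) that change the best type of the containing
#' token (e.g. a 3 bp change converting an A-type unit into a C-type
#' unit); `mh_mediated` when the relaxed microhomology reaches `mh_min`;
#' `slippage_compatible` when segment length plus microhomology fits
#' within the slippage window; `nahr_compatible` when the microhomology
#' reaches the minimum efficient processing segment; `mmej_signature`
#' when a microhomology-mediated event also carries inserted junction
#' bases; `unclassified` otherwise.
#'
#' @param events Events tibble from [measure_microhomology()].
#' @param alignment The `vntr_alignment` providing schema context.
#' @param cfg A [mechanism_config()].
#' @param lib Optional `ru_library` for re-classifying converted tokens
#'   (defaults to the packaged library).
#' @return The events tibble with `token_boundary_aligned`,
#'   `converted_tokens` (list-column of `(from, to)` pairs) and `labels`
#'   (list-column) added, plus `pair_id`.
#' @export
classify_mechanism <- function(events, alignment, cfg = NULL, lib = NULL) {
  cfg <- cfg %||% alignment$cfg
  lib <- lib %||% vntr_ru_library()
  n <- nrow(events)
  events$token_boundary_aligned <- logical(n)
  events$converted_tokens <- vector("list", n)
  events$labels <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    cs <- if (ev$carrier == "long") alignment$seq_long else alignment$seq_short
    sch <- if (ev$carrier == "long") alignment$schema_long else alignment$schema_short
    labels <- character()

    # whole-token indel, tested over the indel's equivalent representations
    starts0 <- sch$start
    ends0 <- sch$end
    precise <- FALSE
    boundary <- FALSE
    for (rep in shift_range(cs, ev$start, ev$end)) {
      s0 <- rep[1] - 1L   # 0-based half-open
      e0 <- rep[2]
      if (s0 %in% starts0 && e0 %in% ends0) {
        boundary <- TRUE
        covered <- sch[sch$start >= s0 & sch$end <= e0, ]
        if (nrow(covered) &&
            sum(covered$end - covered$start) == (e0 - s0) &&
            all(covered$type_code != "X")) {
          precise <- TRUE
        }
        break
      }
    }
    events$token_boundary_aligned[i] <- boundary
    if (precise) labels <- c(labels, "precise_ru_indel")

    # micro indel converting the containing token's type
    if (ev$length <= 5) {
      ov <- sch[sch$start < ev$end & sch$end >= ev$start, ]
      if (nrow(ov)) {
        ov <- ov[which.max(pmin(ov$end, ev$end) -
                             pmax(ov$start + 1L, ev$start) + 1L), ]
        unit_before <- substr(cs, ov$start + 1, ov$end)
        rel_s <- ev$start - ov$start
        rel_e <- min(ev$end, ov$end) - ov$start
        unit_after <- paste0(substr(unit_before, 1, rel_s - 1),
                             substr(unit_before, rel_e + 1,
                                    nchar(unit_before)))
        if (nzchar(unit_after)) {
          from <- classify_token(unit_before, lib)
          to <- classify_token(unit_after, lib)
          if (from$type_code != to$type_code) {
            labels <- c(labels, "ru_conversion_microindel")
            events$converted_tokens[[i]] <-
              list(c(from = from$type_code, to = to$type_code))
          }
        }
      }
    }

    if (ev$mh_relaxed >= cfg$mh_min) labels <- c(labels, "mh_mediated")
    if (ev$length + ev$mh_relaxed <= cfg$slippage_window) {
      labels <- c(labels, "slippage_compatible")
    }
    if (ev$mh_relaxed >= cfg$nahr_min) labels <- c(labels, "nahr_compatible")
    if (ev$mh_relaxed >= cfg$mh_min && nzchar(ev$inserted_bases)) {
      labels <- c(labels, "mmej_signature")
    }
    if (!length(labels)) labels <- "unclassified"
    events$labels[[i]] <- labels
  }
  events$pair_id <- alignment$pair_id
  events
}

#' Compare an ortholog pair end to end
#'
#' Convenience wrapper chaining [align_pair()],
#' [measure_microhomology()] and [classify_mechanism()].
#'
#' @inheritParams align_pair
#' @return A `vntr_events` tibble (one row per indel event) with the
#'   alignment attached as attribute `alignment`.
#' @export
compare_orthologs <- function(pair, lib, params = seg_params(),
                              cfg = mechanism_config()) {
  al <- align_pair(pair, lib, params, cfg)
  ev <- measure_microhomology(al)
  ev <- classify_mechanism(ev, al, cfg, lib)
  structure(ev, alignment = al,
            class = c("vntr_events", class(ev)))
}

#' Write called events as JSON lines and a TSV summary
#'
#' @param events A `vntr_events` tibble.
#' @param jsonl_path Output path for one JSON object per event.
#' @param tsv_path Output path for the tabular summary.
#' @return `jsonl_path`, invisibly.
#' @export
write_events <- function(events, jsonl_path, tsv_path = NULL) {
  tb <- as_tibble(events)
  lines <- map_chr(seq_len(nrow(tb)), function(i) {
    row <- as.list(tb[i, ])
    row$labels <- tb$labels[[i]]
    row$converted_tokens <- tb$converted_tokens[[i]]
    jsonlite::toJSON(row, auto_unbox = TRUE, null = "null")
  })
  writeLines(lines, jsonl_path)
  if (!is.null(tsv_path)) {
    flat <- tb |>
      mutate(labels = map_chr(.data$labels, paste, collapse = ",")) |>
      select("pair_id", "carrier", "start", "end", "length",
             "mh_exact_left", "mh_exact_right", "mh_relaxed", "labels")
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(jsonl_path)
}
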