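#' Construct a repeat-unit (RU) library
#'
#' An RU library is the coded alphabet used to decompose VNTR composite
#' retrotransposon central domains: base repeat-unit types (single letters
#' `A`..`T`) with consensus sequences and curated derivation relationships,
#' plus sequence variants of those types denoted by prime or superscript
#' tags (e.g. `B'`, `C''`, `B5'`, `BCCA`).
#'
#' @param units Data frame with columns `code`, `consensus`, `family_scope`,
#'   a list-column `parents`, and optionally `terminal` and `scope_note`.
#' @param variants Data frame with columns `base_code`, `tag`, `consensus`
#'   and optionally `scope_note`. May be empty.
#' @param name Library name.
#' @param provenance Free-text provenance note.
#'
#' @return A validated object of class `ru_library` with tibble components
#'   `units` and `variants`.
#' @export
ru_library <- function(units, variants = NULL, name = "ru_library",
                       provenance = "") {
  units <- as_tibble(units)
  if (is.null(variants) || nrow(as_tibble(variants)) == 0) {
    variants <- tibble(base_code = character(), tag = character(),
                       consensus = character(), scope_note = character())
  }
  variants <- as_tibble(variants)
  if (!"terminal" %in% names(units)) units$terminal <- FALSE
  if (!"scope_note" %in% names(units)) units$scope_note <- ""
  if (!"scope_note" %in% names(variants)) variants$scope_note <- ""
  units$length <- nchar(units$consensus)
  variants$length <- nchar(variants$consensus)
  lib <- structure(
    list(units = units, variants = variants, name = name,
         provenance = provenance),
    class = "ru_library"
  )
  validate_ru_library(lib)
  lib
}

#' Validate an RU library
#'
#' Checks the structural invariants of the coded RU alphabet: codes are
#' unique single uppercase letters in `A`..`T`; the ancestral types `A`
#' (40 bp) and `B` (39 bp) are present; all consensus sequences are
#' uppercase ACGT; every named parent exists (except for types whose
#' derivation is recorded as undetermined); variant keys `(base_code, tag)`
#' are unique, refer to an existing base type, and variant lengths are
#' within 3 bp of their base type.
#'
#' @param lib An `ru_library`.
#' @return `lib`, invisibly; aborts with a validation error otherwise.
#' @export
validate_ru_library <- function(lib) {
  u <- lib$units
  v <- lib$variants
  if (!all(grepl("^[A-T]$", u$code))) {
    abort("RU codes must be single uppercase letters in A..T")
  }
  if (anyDuplicated(u$code)) {
    abort(paste0("duplicate RU code: ",
                 paste(unique(u$code[duplicated(u$code)]), collapse = ", ")))
  }
  if (!all(c("A", "B") %in% u$code)) {
    abort("RU library must contain the ancestral types A and B")
  }
  bad <- !is_dna(c(u$consensus, v$consensus))
  if (any(bad)) {
    abort("RU consensus sequences must be uppercase ACGT only")
  }
  if (any(nchar(u$consensus) == 0)) abort("empty RU consensus")
  if (!all(u$length == nchar(u$consensus))) {
    abort("RU length field disagrees with consensus length")
  }
  undet <- grepl("derivation_undetermined", u$scope_note)
  for (i in seq_len(nrow(u))) {
    ps <- u$parents[[i]]
    ps <- ps[nzchar(ps)]
    if (length(ps) && !all(ps %in% u$code)) {
      abort(paste0("RU ", u$code[i], " names unknown parent(s): ",
                   paste(setdiff(ps, u$code), collapse = ",")))
    }
    if (!length(ps) && !(u$code[i] %in% c("A", "B")) && !undet[i]) {
      abort(paste0("RU ", u$code[i],
                   " has no parent and is not flagged derivation_undetermined"))
    }
  }
  if (nrow(v)) {
    key <- paste(v$base_code, v$tag, sep = "|")
    if (anyDuplicated(key)) {
      abort(paste0("duplicate variant key: ", key[duplicated(key)][1]))
    }
    if (any(!nzchar(v$tag))) abort("variant tag must be non-empty")
    if (!all(v$base_code %in% u$code)) {
      abort("variant refers to unknown base type")
    }
    base_len <- u$length[match(v$base_code, u$code)]
    if (any(abs(v$length - base_len) > 3)) {
      abort("variant consensus length departs from base type by more than 3 bp")
    }
  }
  invisible(lib)
}

#' Read an RU library from FASTA
#'
#' Headers follow the dialect
#' `>CODE|TAG|FAMILY_SCOPE|PARENTS=X,Y|NOTE=...`, with `TAG` empty for base
#' types. Sequences may be wrapped at any width.
#'
#' @param path Path to the library FASTA file.
#' @return A validated `ru_library`.
#' @export
read_ru_library <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  fa <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(fa))
  units <- list()
  variants <- list()
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(parts) < 5 || !grepl("^PARENTS=", parts[4]) ||
        !grepl("^NOTE=", parts[5])) {
      abort(paste0("malformed RU library header in record ", i, ": '",
                   hdr, "'"))
    }
    code <- parts[1]
    tag <- parts[2]
    scope <- parts[3]
    parents <- strsplit(sub("^PARENTS=", "", parts[4]), ",", fixed = TRUE)[[1]]
    parents <- parents[nzchar(parents)]
    note <- sub("^NOTE=", "", paste(parts[5:length(parts)], collapse = "|"))
    if (!is_dna(seqs[[i]])) {
      abort(paste0("non-ACGT characters in record '", hdr, "'"))
    }
    if (tag == "") {
      units[[length(units) + 1]] <- tibble(
        code = code, consensus = unname(seqs[[i]]), family_scope = scope,
        parents = list(parents),
        terminal = grepl("terminal=true", note), scope_note = note
      )
    } else {
      variants[[length(variants) + 1]] <- tibble(
        base_code = code, tag = tag, consensus = unname(seqs[[i]]),
        scope_note = note
      )
    }
  }
  if (!length(units)) abort("RU library contains no base types")
  ru_library(bind_rows(units), if (length(variants)) bind_rows(variants),
             name = sub("\\.[^.]+$", "", basename(path)),
             provenance = path)
}

#' Write an RU library to FASTA
#'
#' Inverse of [read_ru_library()]: emits the structured-header dialect with
#' sequences wrapped at 60 columns.
#'
#' @param lib An `ru_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ru_library <- function(lib, path) {
  validate_ru_library(lib)
  out <- character()
  for (i in seq_len(nrow(lib$units))) {
    u <- lib$units[i, ]
    out <- c(out,
             sprintf(">%s||%s|PARENTS=%s|NOTE=%s", u$code, u$family_scope,
                     paste(u$parents[[1]], collapse = ","), u$scope_note),
             wrap_fasta(u$consensus))
  }
  for (i in seq_len(nrow(lib$variants))) {
    v <- lib$variants[i, ]
    scope <- lib$units$family_scope[match(v$base_code, lib$units$code)]
    out <- c(out,
             sprintf(">%s|%s|%s|PARENTS=|NOTE=%s", v$base_code, v$tag,
                     scope, v$scope_note),
             wrap_fasta(v$consensus))
  }
  writeLines(out, path)
  invisible(path)
}

#' The packaged synthetic RU library
#'
#' Loads the RU alphabet shipped with the package. The alphabet structure
#' (codes `A`..`T`, variant tags, family scopes, derivation relationships,
#' and the consensus lengths of the types whose size is established: A 40,
#' B 39, D 40, E 41, G 41, H 42, I 47, K 49, N 53, O 42, P 42, Q 43, R 38)
#' follows the described RU evolution of SVA/LAVA VNTRs; the consensus
#' *bases* are synthetic stand-ins generated along the derivation path, not
#' genome-derived sequences.
#'
#' @return A validated `ru_library`.
#' @export
vntr_ru_library <- function() {
  read_ru_library(system.file("extdata", "ru_library_synthetic.fasta",
                              package = "vntrscheme", mustWork = TRUE))
}

# all matchable entries: base types (tag "") plus variants
ru_entries <- function(lib) {
  bind_rows(
    tibble(code = lib$units$code, tag = "", consensus = lib$units$consensus,
           length = lib$units$length),
    tibble(code = lib$variants$base_code, tag = lib$variants$tag,
           consensus = lib$variants$consensus, length = lib$variants$length)
  )
}

#' Derivation graph of an RU library
#'
#' Returns the curated parent-to-child derivation relation over base RU
#' codes as an edge tibble, together with the root set (types without a
#' parent) and types whose derivation is recorded as undetermined (these
#' are not counted as roots).
#'
#' @param lib An `ru_library`.
#' @return A tibble of edges `(from, to)` of class `ru_derivation`, with
#'   attributes `roots` and `undetermined`.
#' @export
derivation_graph <- function(lib) {
  validate_ru_library(lib)
  u <- lib$units
  edges <- purrr::map2(u$parents, u$code, function(ps, cd) {
    ps <- ps[nzchar(ps)]
    if (!length(ps)) return(NULL)
    tibble(from = ps, to = cd)
  })
  edges <- bind_rows(edges)
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble(from = character(), to = character())
  }
  undet <- u$code[grepl("derivation_undetermined", u$scope_note)]
  roots <- setdiff(
    u$code[vapply(u$parents, function(p) !length(p[nzchar(p)]), TRUE)],
    undet
  )
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges,
                                       vertices = data.frame(name = u$code))
    if (!igraph::is_dag(g)) {
      abort("cycle detected in RU derivation graph")
    }
  }
  structure(edges, roots = roots, undetermined = undet,
            class = c("ru_derivation", class(edges)))
}

#' @export
print.ru_library <- function(x, ...) {
  cat("<ru_library> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$units), " base RU types, ", nrow(x$variants),
      " variants\n", sep = "")
  cat("  lengths ", min(x$units$length), "-", max(x$units$length),
      " bp\n", sep = "")
  invisible(x)
}
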