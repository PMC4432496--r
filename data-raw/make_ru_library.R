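# Builds the packaged synthetic repeat-unit (RU) library fixture.
#
# The RU alphabet (types A..T plus sequence variants) is a constructed,
# synthetic stand-in: consensus lengths follow the values printed for the
# RU code (A 40, B 39, D 40, E 41, G 41, H 42, I 47, K 49, N 53, O 42,
# P 42, Q 43, R 38), derivation relations follow the described RU
# evolution (A and B ancestral; C..S derived; S undetermined; T terminal),
# and the actual bases are GC-rich random draws edited along the
# derivation path. Run once; output is frozen at
# inst/extdata/ru_library_synthetic.fasta.

set.seed(19400390)  # A=40, B=39 -- mnemonic only

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.65) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

subs_at <- function(s, positions) {
  v <- strsplit(s, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(BASES, v[p]), 1)
  }
  paste(v, collapse = "")
}

rand_subs <- function(s, k) subs_at(s, sample(nchar(s), k))

ins_at <- function(s, pos, frag) {
  paste0(substr(s, 1, pos), frag, substr(s, pos + 1, nchar(s)))
}

del_at <- function(s, pos, k) {
  paste0(substr(s, 1, pos - 1), substr(s, pos + k, nchar(s)))
}

build <- function() {
  A <- rand_seq(40)
  B <- rand_seq(39)

  units <- list(
    list(code = "A", consensus = A, parents = character(), scope = "shared",
         note = "ancestral 40 bp RU"),
    list(code = "B", consensus = B, parents = character(), scope = "shared",
         note = "ancestral 39 bp RU"),
    list(code = "C", consensus = del_at(A, 20, 3), parents = "A",
         scope = "shared", note = "short 37 bp RU; A minus 3 bp"),
    list(code = "D", consensus = rand_subs(A, 4), parents = "A",
         scope = "LAVA", note = "second 40 bp RU of LAVA"),
    list(code = "E", consensus = ins_at(B, 15, "GC"), parents = "B",
         scope = "SVA", note = "41 bp; appears with SVA_B"),
    list(code = "F", consensus = NA, parents = "E", scope = "SVA",
         note = "41 bp; closes the SVA_F 5' array"),
    list(code = "G", consensus = NA, parents = "E", scope = "SVA",
         note = "41 bp; member of the KGC' arrays"),
    list(code = "H", consensus = NA, parents = "E", scope = "SVA",
         note = "42 bp intermediate; lost after SVA_C"),
    list(code = "I", consensus = NA, parents = "H", scope = "SVA",
         note = "47 bp intermediate amplified in SVA_B/SVA_C"),
    list(code = "J", consensus = rand_subs(A, 3), parents = "A",
         scope = "SVA", note = "figure-only"),
    list(code = "K", consensus = NA, parents = "I", scope = "SVA",
         note = "49 bp G-rich RU of the internal K_nGC' arrays"),
    list(code = "L", consensus = NA, parents = "K", scope = "SVA",
         note = "48 bp; SVA_E LL'GC' arrays"),
    list(code = "M", consensus = rand_subs(B, 3), parents = "B",
         scope = "SVA", note = "figure-only"),
    list(code = "N", consensus = NA, parents = "D", scope = "LAVA",
         note = "53 bp; second 5' RU from LAVA_C1 onwards"),
    list(code = "O", consensus = NA, parents = "C", scope = "LAVA",
         note = "42 bp; LAVA_E terminal array"),
    list(code = "P", consensus = NA, parents = "O", scope = "LAVA",
         note = "42 bp; LAVA_E terminal array"),
    list(code = "Q", consensus = NA, parents = "C", scope = "orangutan_SVA",
         note = "43 bp scaffold RU of orangutan central arrays"),
    list(code = "R", consensus = del_at(B, 10, 1), parents = "B",
         scope = "orangutan_SVA", note = "38 bp; orangutan SVA_PA_7-11"),
    list(code = "S", consensus = rand_seq(41), parents = character(),
         scope = "chimp_SVA", note = "derivation_undetermined"),
    list(code = "T", consensus = NA, parents = "B", scope = "SVA",
         note = "terminal=true; 3' terminal RU")
  )
  names(units) <- vapply(units, `[[`, "", "code")

  units$F$consensus <- rand_subs(units$E$consensus, 5)
  units$G$consensus <- rand_subs(units$E$consensus, 3)
  units$H$consensus <- ins_at(units$E$consensus, 30, "G")
  units$I$consensus <- ins_at(rand_subs(units$H$consensus, 2), 12, "GGCAG")
  units$K$consensus <- ins_at(rand_subs(units$I$consensus, 2), 40, "GG")
  units$L$consensus <- rand_subs(del_at(units$K$consensus, 25, 1), 3)
  units$N$consensus <- ins_at(units$D$consensus, 18, "GCCAGGCGTGGCC")
  units$O$consensus <- ins_at(units$C$consensus, 10, "GGCTC")
  units$P$consensus <- rand_subs(units$O$consensus, 4)
  units$Q$consensus <- ins_at(units$C$consensus, 25, "CAGGGC")
  units$T$consensus <- rand_subs(substr(units$B$consensus, 1, 30), 2)

  variants <- list(
    list(base = "A", tag = "5'", src = "A", k = 2,
         note = "LAVA 5'-most A-type RU"),
    list(base = "B", tag = "'", src = "B", k = 2,
         note = "second B-type RU of SVA_B-F 5' arrays"),
    list(base = "B", tag = "5'", src = "B", k = 3,
         note = "5'-most B-type RU; orangutan SVA and LAVA_B2"),
    list(base = "B", tag = "CCA", src = "B", k = 0,
         note = "LAVA_B2C internal B-type RU"),
    list(base = "C", tag = "'", src = "C", k = 1,
         note = "short C-type of the SVA KGC' arrays"),
    list(base = "C", tag = "''", src = "C", k = 2,
         note = "SVA_E LL'GC'/C'' arrays"),
    list(base = "C", tag = "T", src = "C", k = 1,
         note = "LAVA sub-terminal C variant from B1A"),
    list(base = "C", tag = "TT", src = "C", k = 2,
         note = "LAVA sub-terminal C variant, C4/D/E"),
    list(base = "C", tag = "5'", src = "C", k = 2,
         note = "LAVA_B2B 5' C-type RU"),
    list(base = "C", tag = "C2", src = "C", k = 2,
         note = "LAVA_C2 specific"),
    list(base = "D", tag = "C2", src = "D", k = 2,
         note = "LAVA_C2 specific"),
    list(base = "K", tag = "'", src = "K", k = 2,
         note = "5' end of SVA internal K arrays"),
    list(base = "L", tag = "'", src = "L", k = 2,
         note = "SVA_E LL' arrays")
  )

  var_seqs <- list()
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    src <- units[[v$src]]$consensus
    if (v$tag == "CCA") {
      seq <- paste0(substr(src, 1, 9), "CCA", substr(src, 13, nchar(src)))
    } else {
      seq <- rand_subs(src, v$k)
    }
    variants[[i]]$consensus <- seq
  }

  list(units = units, variants = variants)
}

check_library <- function(lib) {
  base_codes <- vapply(lib$units, `[[`, "", "code")
  base_seqs <- vapply(lib$units, `[[`, "", "consensus")
  ok <- TRUE
  # printed lengths
  printed <- c(A = 40, B = 39, D = 40, E = 41, G = 41, H = 42, I = 47,
               K = 49, N = 53, O = 42, P = 42, Q = 43, R = 38)
  for (cd in names(printed)) {
    if (nchar(base_seqs[[cd]]) != printed[[cd]]) {
      message("length mismatch for ", cd); ok <- FALSE
    }
  }
  # each base classifies uniquely to itself
  d <- adist(base_seqs, base_seqs)
  diag(d) <- NA
  if (any(d <= 0, na.rm = TRUE)) { message("duplicate base consensus"); ok <- FALSE }
  # variants classify to their base, and uniquely within the base's variants
  for (v in lib$variants) {
    dv <- adist(v$consensus, base_seqs)[1, ]
    best <- base_codes[which.min(dv)]
    if (best != v$base) {
      message("variant ", v$base, v$tag, " classifies to ", best); ok <- FALSE
    }
    sibs <- Filter(function(w) w$base == v$base &&
                     !(w$tag == v$tag), lib$variants)
    for (w in sibs) {
      if (adist(v$consensus, w$consensus) == 0) {
        message("variant clash ", v$base, v$tag, " vs ", w$base, w$tag)
        ok <- FALSE
      }
    }
  }
  ok
}

wrap60 <- function(s) {
  starts <- seq(1, nchar(s), by = 60)
  vapply(starts, function(i) substr(s, i, min(i + 59, nchar(s))), "")
}

write_fasta <- function(lib, path) {
  out <- character()
  for (u in lib$units) {
    hdr <- sprintf(">%s||%s|PARENTS=%s|NOTE=%s", u$code, u$scope,
                   paste(u$parents, collapse = ","), u$note)
    out <- c(out, hdr, wrap60(u$consensus))
  }
  for (v in lib$variants) {
    hdr <- sprintf(">%s|%s|%s|PARENTS=|NOTE=%s", v$base, v$tag,
                   lib$units[[v$base]]$scope, v$note)
    out <- c(out, hdr, wrap60(v$consensus))
  }
  writeLines(out, path)
}

lib <- build()
stopifnot(check_library(lib))
write_fasta(lib, file.path("inst", "extdata", "ru_library_synthetic.fasta"))
cat("wrote", length(lib$units), "types and", length(lib$variants), "variants\n")
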