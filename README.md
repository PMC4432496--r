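# vntrscheme

Decomposition and comparative analysis of the central VNTR domain of
hominoid composite retrotransposons (SVA, LAVA, PVA, FVA).

The central domain of these elements is a Variable Number of Tandem
Repeats (VNTR) built from a small alphabet of 30–53 bp GC-rich repeat
units (RUs). Far from being a random pile of repeats, the domain is
organised: subfamily-specific conserved RU arrays flank the VNTR at its
5' and 3' ends (e.g. the `ABCA` array shared by the human SVA
subfamilies, expanding to `ABCAAAB'CACAAF` in SVA_F), the younger
subfamilies carry well-defined internal arrays (`K_nGC'` in human
SVA_D–F, `Q`-scaffolded `C`-runs in orangutan), and comparison of
orthologous elements shows that the domain is remodelled at the DNA
level through indels carrying 5–42 bp microhomologies at their
breakpoints — compatible with replication slippage and related
microhomology-driven mechanisms, and generally too short for NAHR's
~34 bp minimal efficient processing segment.

`vntrscheme` makes that whole analysis reproducible and testable:

* **RU library** (`vntr_ru_library()`, `read_ru_library()`): the coded
  RU alphabet `A`–`T` with prime/superscript sequence variants and a
  curated derivation graph (`derivation_graph()`). The packaged library
  is a synthetic stand-in whose unit lengths and derivation relations
  follow the published alphabet.
* **Segmentation** (`segment_vntr()`): optimal decomposition of a VNTR
  sequence into an ordered RU token string ("repeat scheme") by
  minimum-cost dynamic programming over a 25–60 bp unit-length window,
  with deterministic tie-breaking, truncated-terminal handling, and an
  unclassified (`X`) sink. `discover_units()` rebuilds consensus units
  from pre-split sets by length sorting, single-linkage clustering and
  per-column majority rule.
* **Array analysis** (`consensus_arrays()`, `mine_internal_arrays()`,
  `position_specific_consensus()`): maximal conserved 5'/3' arrays at a
  support threshold, minority 5' structures, and cyclic internal motifs
  with one run-variable slot (`K_nGC'`-style).
* **Ortholog comparison** (`compare_orthologs()`, `align_pair()`,
  `measure_microhomology()`, `classify_mechanism()`): token-level
  localisation plus nucleotide-level alignment of ortholog pairs,
  left-normalized indel calls, exact and relaxed breakpoint
  microhomology, and mechanism-compatibility labels
  (`precise_ru_indel`, `ru_conversion_microindel`, `mh_mediated`,
  `slippage_compatible`, `nahr_compatible`, `mmej_signature`).
* **Synthetic data** (`generate_subfamily_set()`,
  `make_ortholog_pair()`): ground-truthed element sets drawn from
  subfamily array grammars (13 packaged grammar files) and ortholog
  pairs with planted, microhomology-designed indels.
* **Pipeline** (`run_pipeline()`, `inst/scripts/vntr-pipeline.R`):
  file-to-file stages (`tokenize`, `discover`, `arrays`, `compare`,
  `simulate`) with run manifests and a thin command-line wrapper.

Functions take data frames first and return tibbles; fitted-style
results support `tidy()`/`glance()` and `autoplot()`.

## Worked example

```r
library(vntrscheme)
lib <- vntr_ru_library()
lib
#> <ru_library> ru_library_synthetic
#>   20 base RU types, 13 variants
#>   lengths 30-53 bp

# simulate a noise-free SVA_F-like subfamily set and tokenize it
sim <- generate_subfamily_set("SVA_F", n = 6, seed = 3, lib = lib,
                              mutation_rate = 0, indel_rate = 0)
sch <- segment_vntr(sim$elements, lib)
code_strings(sch)[1, ]
#>   element_id n_tokens code_string
#> 1 SVA_F_001        38 A-B-C-A-A-A-B'-C-A-C-A-A-F-K'-K-G-C'-K-K-K-K-G-C'-…

consensus_arrays(sch, theta = 0.7)
#> <array_consensus> SVA_F (n = 6, theta = 0.7)
#>   5' array: ABCAAAB'CACAAFK'K
#>   3' array: KGC'KGC'T
#>   alt 5' array (2 elements): ABCAAAB'CACAAFK'KK

mine_internal_arrays(sch, theta = 0.7, variant_sensitive = FALSE)
#>   motif variable_pos copy_min copy_max occurrences n_elements support
#> 1 K_nGC            1        1        4          19          6       1
```

The derived 5' array begins with the printed SVA_F code
`ABCAAAB'CACAAF` and extends into interior positions that happen to be
conserved at the 0.7 support level; the 3' array ends with the terminal
`KGC'T`; the internal motif is the `K_nGC'` array with 1–4 `K` copies
(the prime is dropped in variant-insensitive mining, which merges the
`K'` variant heading each array with `K`).

Planting a deletion with a 12 bp designed breakpoint microhomology in
an ortholog pair and re-calling it:

```r
el <- sim$elements[1, ]
tok <- as.data.frame(sch)[as.data.frame(sch)$element_id == el$element_id, ]
pairsim <- make_ortholog_pair(
  el, tibble::tibble(token_from = 15L, token_to = 16L, designed_mh = 12L),
  seed = 4, lib = lib, tokens = tok)
ev <- compare_orthologs(pairsim$pair, lib)
as.data.frame(ev)[, c("carrier", "start", "end", "length",
                      "mh_exact_left", "mh_exact_right", "mh_relaxed")]
#>   carrier start end length mh_exact_left mh_exact_right mh_relaxed
#> 1    long   560 649     90             0             12         14
ev$labels[[1]]
#> [1] "precise_ru_indel"    "mh_mediated"         "slippage_compatible"
```

The 90 bp event (one `K` plus one `G` unit) is recovered at its planted,
left-normalized breakpoints with the designed 12 bp exact microhomology
(the relaxed tract extends to 14 bp across near-matches); it is
compatible with a microhomology-driven mechanism and with replication
slippage (90 + 14 ≤ 200 bp), but not with NAHR (14 < 34 bp).

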