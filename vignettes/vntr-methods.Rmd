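---
title: "Methods: repeat-unit schemata, conserved arrays and microhomology analysis of VNTR composite retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-unit schemata, conserved arrays and microhomology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrscheme)
```

## The problem

SVA, LAVA, PVA and FVA are non-autonomous, non-LTR composite
retrotransposons of hominoid primates. They share a central VNTR domain
built from tandem copies of short (30–53 bp) GC-rich repeat units (RUs).
Three analyses turn raw VNTR sequences into biology:

1. **Decomposition**: write each element's VNTR as an ordered string of
   coded RU tokens — its *repeat scheme* (e.g. `A-B-C-A-…`).
2. **Array structure**: compare schemata across elements of one
   subfamily to find conserved 5'/3' RU arrays and repeated internal
   arrays; these are subfamily-specific and evolve along the subfamily
   phylogeny.
3. **Remodelling mechanism**: compare orthologous copies of one
   ancestral insertion (e.g. human/chimpanzee SVA_D orthologs, which
   diverged without an RNA intermediate), call RU copy-number indels and
   measure breakpoint microhomology to ask which DNA-level mechanisms
   (replication slippage, MMEJ/MMBIR-type processes, NAHR) the changes
   are compatible with.

The original analyses of this kind were carried out manually (units
split by eye, consensus built in an editor). This package formalises
each step as an explicit, parameterised, tested algorithm; where the
manual procedure left choices open, the choice made here is stated
below.

## The RU alphabet

The alphabet has base types coded `A`–`T` and sequence variants written
with primes or superscripts (`B'`, `B5'`, `BCCA`, `C''`, `CT`, `KC'`-style
tags). `A` (40 bp) and `B` (39 bp) are ancestral — they dominate the
SVA2 elements ancestral to all VNTR composites — and the 17 further
types `C`–`S` derive from them and from each other; the derivation of
the chimpanzee-specific `S` cannot be pinned to a single parent and is
flagged `derivation_undetermined` (and excluded from the root set of
`derivation_graph()`). `T` is the 3'-terminal unit, stored as a regular
type with a `terminal=true` flag; `J` and `M` occur in the figure
record only and are flagged `figure-only`.

**The packaged library is a synthetic stand-in.** The figure panels
carrying the actual consensus bases are not machine-readable in the
source available to this package, so the packaged file
(`inst/extdata/ru_library_synthetic.fasta`) fixes everything the text
does state — the codes, variant tags, family scopes, derivation edges
and the printed lengths (A 40, B 39, D 40, E 41, G 41, H 42, I 47,
K 49, N 53, O 42, P 42, Q 43, R 38) — and fills the bases with GC-rich
random draws edited along the derivation path (e.g. `C` is `A` minus
3 bp, which also reproduces the observed 3 bp A↔C repeat-unit
conversions; `E` is `B` plus a 2 bp insertion; `K` descends from `I`).
Lengths not printed in the text were chosen once from textual cues:
`C` 37 bp (the 5' arrays comprise "37–40 bp" units A, B, C), `F` 41,
`L` 48 (a "long" unit like `K`), `S` 41, `T` 30, `J` 40, `M` 39.
Everything downstream treats the library as an input, so a
genome-derived library can be dropped in via `read_ru_library()`.

## Segmentation as minimum-cost tiling

`segment_vntr()` decomposes a sequence by dynamic programming. With
`D(0) = 0`,

> `D(j) = min over i < j, (j − i) ∈ [w_min, w_max] of
>   D(i) + unitcost(i, j) + τ`

where `unitcost(i, j)` is the minimum Levenshtein distance from the
segment to any library entry, capped by an unclassified option costing
`⌈(j − i)/2⌉`. Parameters, with defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `w_min`, `w_max` | 25, 60 | bp | brackets the 30–50 bp unit range and the 53 bp `N` type with margin |
| `τ` (`tau`) | 2 | cost | startup penalty per token; discourages splitting one unit into two |
| `identity_min` | 0.75 | fraction | assignment threshold; separates 37–53 bp units carrying ≤2–3 substitutions from random GC-rich strings |
| `max_n_frac` | 0.10 | fraction | sequences with more `N` are refused as assembly-gap cases; `N` mismatches every base |

Ties are broken deterministically: lower cost, then fewer tokens, then
the lexicographically smallest code string, then leftmost-longest
tokens. The implementation computes suffix-optimal costs backwards and
reconstructs greedily from the left, which realises exactly that order.
The final token may be shorter than `w_min`; it is matched against
equal-length consensus prefixes and flagged `truncated` (3' ends of
real elements are length-variable). Token classification is
hierarchical: best base type by edit distance first, then the best
variant within that type, so variants can never hijack a unit from a
closer base type. A compiled kernel computes, for each window start and
reference, the distances of all window lengths in one pass, and
identical windows (tandem periodicity) are computed once; the DP itself
is plain R.

The test suite holds the tokenizer to an exhaustive standard: on random
concatenations of 2–5 mutated units (≤200 bp) its tiling cost equals
the brute-force minimum over all admissible tilings (50 sequences in
the acceptance run), unmutated concatenations of up to 12 units are
recovered token-for-token, and with ≤2 substitutions per unit ≥95% of
200 trials recover the generating code string (a repository bar, not a
published number).

`discover_units()` reproduces the way the alphabet was first erected:
pre-split units are grouped by exact length, clustered within a length
class by single linkage at 0.9 identity (the original procedure sorted
"by length and further on by sequence" without a stated cutoff), and
summarised by per-column majority rule. Ties take the alphabetically
first base — IUPAC ambiguity codes are deliberately kept out of the
library — and tied columns are reported in the `ties` attribute.

## Conserved arrays and internal motifs

`consensus_arrays()` derives, for one subfamily, the longest token
prefix `P` such that at least a fraction θ of schemata begin with `P`
(grown greedily, most common token first), and symmetrically a suffix
from the 3' end. The result is maximal by construction: one more token
would drop support below θ. θ defaults to 0.7 — the source describes
conserved arrays over samples of 5–20 elements without stating a
support level, and 0.7 keeps the `ABCA` array (shared by all six human
subfamilies) while tolerating the indel polymorphism visible in real
schemata; it is exposed as a parameter precisely because the original
bar is unstated. Tokens compare on `(type, variant)` by default, with a
variant-insensitive fallback for older subfamilies whose variants are
noisy. When conservation breaks at a position where two structures
coexist (as in LAVA_C1, where elements with and without the 53 bp `N`
unit at position 2 are equally represented), the minority branch is
reported as `alt_prefix` with supports measured within that branch,
rather than being forced into one consensus.

A consequence of maximality worth stating: when the interior is itself
deterministic at some positions (the 3' `KGC'T` array of the younger
SVA subfamilies *is* the terminal copy of the internal `K_nGC'` array),
the derived prefix/suffix legitimately extend into the interior. The
worked examples therefore check *containment* — the derived 5' array
begins with the printed code string, the 3' array ends with it — not
string equality.

`mine_internal_arrays()` run-length-compresses each interior token
string and looks for repeated compressed subsequences of 2–6 symbols
with at most one run-variable position, occurring at least twice per
element in at least θ of elements. Internal arrays are cycles, so the
miner canonicalises rotations into one class, discards windows that
merely lap a shorter cycle (period < length), anchors the reported
phase to where the repeated region first appears in the full schema
(yielding `K_nGC'` and `QC_n` rather than arbitrary rotations), and
suppresses sub-patterns of longer kept cycles. The 6-symbol cap covers
the described arrays (`K_nGC'`, `LL'GC'/C''`, `Q/C_n`) without
combinatorial blow-up.

`position_specific_consensus()` returns the majority-rule nucleotide
consensus of the token substrings occupying one conserved-array
position (column vote over the substrings of the modal length), and
classifies it against the library — e.g. position 7 of an SVA_F-like
set classifies as `B'`, the second B-type unit of the 5' arrays.

## Ortholog comparison and mechanism labels

`align_pair()` works in two stages: an edit script over the two token
strings localises candidate copy-number differences, then a global
nucleotide alignment (match +2, mismatch −3, gap open 5, gap extend 1 —
chosen to favour one contiguous indel over scattered gaps in GC-rich
repeats; Biostrings supplies the aligner) inside each anchored window
fixes the breakpoints. Indels are reported unsigned on the sequence
carrying the extra bases — without an outgroup, insertion cannot be
told from deletion — and left-normalized (shifted maximally 5'-ward),
the canonical representation inside tandem repeats. Events closer than
10 bp are merged and flagged: a large observed indel can mask two
independent events.

`measure_microhomology()` computes, for segment `S` with flanks `Lf`,
`Rf`: exact right homology = longest prefix of `S` equal to the prefix
of `Rf`; exact left symmetrically on suffixes; and a relaxed tract that
extends across mismatches while running identity stays ≥ 0.9 and ends
on a match. The relaxed tract models divergence *within* a genuine
homology block after speciation — observed directly in real ortholog
alignments — and both figures are reported because the published 5–42 bp
range does not state whether mismatches were tolerated.

`classify_mechanism()` attaches compatibility flags (never exclusive
calls; the underlying pathway question is open):

| label | rule (defaults) |
|---|---|
| `precise_ru_indel` | some equivalent representation spans whole classified tokens with both breakpoints on token boundaries |
| `ru_conversion_microindel` | length ≤ 5 bp and the containing token's best type changes (the 3 bp A↔C conversions) |
| `mh_mediated` | relaxed microhomology ≥ `mh_min` = 5 bp |
| `slippage_compatible` | length + microhomology ≤ `slippage_window` = 200 bp (one Okazaki fragment in humans) |
| `nahr_compatible` | microhomology ≥ `nahr_min` = 34 bp (minimum efficient processing segment) |
| `mmej_signature` | microhomology-mediated *and* inserted junction bases present (MMEJ is typically accompanied by insertions; contiguous-gap events carry none) |

Because `nahr_min ≥ mh_min`, NAHR compatibility implies
microhomology mediation — asserted as a property test.

## What the synthetic generator emulates — and what it does not

`generate_subfamily_set()` draws elements from subfamily grammars:
fixed 5'/3' token arrays, an interior that is either a repeated motif
with a run-variable slot or an unstructured token stretch, uniform
point substitutions (excluding the original base), and token-level
duplications/deletions. Thirteen grammar files ship with the package.
The printed code strings (`ABCA`, `ABCAAAB'CACAAF`, `KGC'T`, `K_nGC'`,
`LL'GC'/C''`, `ANBB`, `Q`/`C_n`) are taken as stated; prefixes,
suffixes and interiors beyond them are synthetic emulations consistent
with the narrative (emergence of `D` and the sub-terminal `CT` variant
in LAVA_B1, of `N` in LAVA_C1, of `O`/`P` in LAVA_E; `E/G/H/I` in
SVA_B/C) and say so in their file comments. Study-condition choices
made once: sample sizes follow the 5–20 elements per subfamily of the
source datasets (10 is the default); the `K` copy range is 1–4 as
printed; the number of internal array repetitions per element (4–6) is
not printed anywhere and was set so that emulated interiors are, like
the described ones, "composed exclusively" of repeated arrays rather
than containing one or two copies; per-subfamily mutation rates are not
derivable from the text, so the packaged files carry an illustrative
0.01/bp with `indel_rate` 0.1, and both are zeroed explicitly in
recovery tests.

`make_ortholog_pair()` plants deletions/duplications of whole token
spans. A designed microhomology of `m` bp is created by copying the
first `m` bases of the doomed segment onto the right flank beforehand;
the bases bordering the tract are forced to differ, so the designed
homology is maximal and the planted representation is already
left-normalized — which is what makes "recovered microhomology equals
designed microhomology" a sharp oracle. Designed mismatches inside the
tract exercise the exact/relaxed split (e.g. a 12 bp tract with one
mismatch at position 6 must yield exact 5, relaxed 12).

The generator deliberately omits: sequencing error (elements are
assembly-derived), RNA-level slippage (none was observed in de novo
integrants), SINE-R/3'-domain evolution, and genome-scale retrieval or
subfamily discovery. Passing tests on this synthetic data show the
algorithms are correct under the stated noise model; they do not show
that real VNTRs satisfy that model — real elements carry homoplasy,
assembly gaps and variant units absent from a synthetic library.

## Numerical and degenerate-input choices

* Empty sequence → empty schema (not an error); empty unit list or
  library → error.
* Sequences over 10% `N` are refused ("assembly-gap"); below that, `N`
  mismatches everything.
* All randomness is routed through explicit integer seeds; identical
  seeds give byte-identical FASTA/truth output (hash-checked in tests).
* Distance computations are exact Levenshtein (`utils::adist` at the
  edges, the compiled kernel inside the DP); no heuristic alignment is
  used anywhere a score enters a decision.
* Pipeline stages write outputs atomically (temp file + rename) and
  emit a manifest carrying the full config and its hash, so a run is a
  pure function of (inputs, config, seed).

## Problem sizes

The default test and acceptance runs use: 50 oracle sequences ≤200 bp;
2 elements per packaged grammar for clean recovery (26 elements across
13 grammars); 200 mutated-recovery trials; 100 simulated ortholog pairs
(~400 bp haplotypes, one planted event each, designed microhomology
0–42 bp); 6–10 elements per subfamily for the array worked examples.
These sizes mirror the per-subfamily sample sizes of the original
datasets while keeping a complete run in minutes on one core.

## Known limitations

* The packaged RU consensus bases are synthetic; analyses of real
  elements need a genome-derived library file.
* No per-element gold standard for the manual splitting is recoverable,
  so tokenizer agreement is assessed on synthetic data and against the
  cost-optimality oracle, not against the original hand annotation.
* Conserved-array maximality can absorb deterministic interior
  positions (discussed above); consumers wanting the printed-style
  arrays should read the containment relations, or mine motifs with
  explicit `prefix_len`/`suffix_len`.
* Mechanism labels are compatibility statements under configurable
  thresholds, not causal calls; deciding between slippage, MMEJ and
  MMBIR would need perturbation data the sequence record cannot give.
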