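---
title: "Microdomain detection and structural typing of EcR isoform-specific regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdomain detection and structural typing of EcR isoform-specific regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrmotifs)
```

## The model

The N-terminal isoform-specific regions of the ecdysone receptor A and
B1 isoforms are intrinsically disordered segments that carry the
isoform-specific AF-1 activation function. Comparative analysis across
arthropods shows they are organised as a small number of short conserved
microdomains separated by linkers of variable length and composition.
This package treats that organisation as a formal grammar:

* a **microdomain** is either a degenerate consensus pattern (fixed
  residues, `x` wildcards, the large-hydrophobic class `Ψ`, two-residue
  alternations `(X/Y)`), a compositional rule (every window of length
  *w* inside the region keeps the fraction of residues from a named
  class union at or above *f*), or a hybrid (a compositional run that
  must contain a short core pattern);
* an **architecture** is an ordered inventory of microdomains; twelve
  architectures (five A types, seven B1 types) cover the published
  diversity;
* **classification** is a priority-ordered decision table over the
  detected inventory.

### Residue classes

`ACIDIC = {D, E}`, `NEUTRAL_POLAR = {S, T}`,
`BULKY = {W, A, F, I, L, M, V}`, `BASIC = {K, R}`. The membership of `Ψ`
is never enumerated in the source notation; this package uses
`{F, I, L, M, V, W, Y}` ("large" excludes A and G; the bulky-hydrophobic
class used by the DL-rich rule is enumerated separately, so the two do
not conflict). `Ψ` membership is configurable via the `classes` argument
of `compile_pattern()` and `read_catalog()`.

## Detection rules and tunable parameters

All defaults live in one place, `ecr_config()`, and the motif catalog is
a human-editable TSV (`inst/extdata/motif_catalog.tsv`).

| parameter | default | meaning |
|---|---|---|
| `srich_window`, `srich_min_fraction` | 8, 0.6 | S-rich compositional rule (ACIDIC ∪ NEUTRAL_POLAR) |
| `dlrich_window`, `dlrich_min_fraction`, `dlrich_min_run` | 10, 0.8, 8 | DL-rich rule (ACIDIC ∪ BULKY); runs shorter than 8 residues are noise |
| `n_terminal_window` | 25 | window (residues) for DLKHE, ΨAYRG, D(T/S)S repeats, LQTVPRVPVAGV/LAVPRVPVAGV |
| `n_terminal_window_strict` | 10 | window for motifs described as sitting "at the N-terminus": (K/R)RRW, TxxΨW, YRLN |
| `c_terminal_window` | 40 | the A-box must start inside the last 40 residues |
| `krrw_adjacency_gap` | 3 | KRRW accepted outside its window when it starts ≤ 3 residues after a signature hit |
| `extension_min` | 15 | N-terminal extension length distinguishing B1-5 from B1-4 |
| `fusion_gap` | 5 | S-rich/DL-rich gap at or under which a type-2' call is made |
| `single_threshold`, `class_threshold` | 0.6, 0.8 | consensus emission rule |

A compositional hit is the union of all qualifying windows, merged,
trimmed inward and extended outward to class-member boundaries; its score
is the class fraction over the reported span. If a hybrid motif's core
pattern matches but no compositional run carries it (the shortened
type-2' S-rich motif), the core match extended over contiguous class
members is reported instead, so the fused architectures remain
detectable.

Design choices worth knowing:

* **One hit per motif class** (best score, then leftmost) — each
  microdomain is treated as a single locus per region; the unfiltered
  list is kept in `raw_hits`, and non-overlapping extra candidates
  raise a `duplicate(...)` flag.
* **KRRW adjacency exemption.** The strict 10-residue window would veto
  (K/R)RRW in the type-4/5 architectures, where the
  LQTVPRVPVAGV/LAVPRVPVAGV signature (and in type 5 an N-terminal
  extension) precedes it. KRRW is therefore also accepted immediately
  after a reported signature hit. Inter-motif gap length otherwise never
  vetoes a hit (the vespine S/H-rich insertion between KRRW and the
  S-rich motif is tolerated by construction).
* **SP residues** count only when an SP dipeptide lies strictly between
  the retained S-rich end and DL-rich start; SP inside the S-rich motif
  itself (e.g. ESSPEVSSS) or in an A-box does not.
* **A known overlap**: the DLKHE signature contains an ΨKxE match
  (L-K-H-E), so type-2 A regions report the SUMOylation class at the
  N-terminal signature as well; the leftmost-retention rule then places
  the SUMO hit there and the architecture checker flags it. The
  classifier is unaffected (class presence, not position, drives the
  decision table).
* Lowercase input is uppercased; `U/O/B/Z/X` and other non-canonical
  letters are rejected with the offending position, since every rule is
  defined over the 20 canonical residues. `x` never matches a gap.
* The `(D/E)(D/E)W` residues are treated as a single locus per region
  (the comparative data never show more than one).

## Classification

Rules fire in fixed priority order and only when the type's minimal
motif set is present, so exactly one rule fires per call and a label
always implies its defining inventory. For the A isoform:
A3 (DDW + A-box with both SUMO and NLS absent) → A4 (D(T/S)S repeats) →
A5 (YRLN) → A2 (DLKHE or ΨAYRG; NLS optional, noted as the lepidopteran
variant) → A1 (full scaffold; the KxxR NLS variant satisfies the NLS
requirement). Taxon metadata is optional and only upgrades a call with a
documented exemption: "Diptera" turns a scaffold-only A1 into A5 (the
Drosophila group lost YRLN). For B1: with KRRW — B1-4/B1-5 (signature
adjacent, split on the ≥ 15-residue extension), B1-6 (DL-rich matched
*only* by the modified pattern (D/E)Y(C/G)(E/D)LWxxxxD), else B1-3;
without KRRW but with TxxΨW — B1-2' (gap ≤ 5, fused, or the QVSSS core
variant) else B1-2; else B1-1 (SP optional, noted when absent — the
heteropteran exception). The source text calls the B1 series "six
structural types" in one heading and seven in the body; the seven-label
scheme (type 2' counted separately) is implemented.

## Consensus profiles

`build_consensus()` emits, per column: the residue if its frequency
reaches 0.6; else the alternation of the two most frequent residues if
they jointly reach 0.8; else `x`. Columns that are mostly gaps (> 0.5)
are dropped. Information content is `log2(20) − H` bits with no
small-sample correction. Two deliberate deviations from a stricter
reading of the rule:

* alternations are **not** required to share a catalog class, because the
  published notation itself prints `(C/G)` (no shared class) alongside
  `(M/L)`, `(T/S)`, `(D/E)`; the strict behaviour is available as
  `require_class = TRUE`;
* alternations are rendered alphabetically — the notation uses both
  `(D/E)` and `(E/D)` for the same element, so recovery is asserted at
  canonical pattern form (`render_pattern(compile_pattern(s))`).

A `Ψ` column cannot be recovered by this rule: a 7-residue class has no
representation in two-residue alternation notation, so consensus
recovery is only exact for Ψ-free consensi (all but three of the
printed strings).

`sample_pattern_instances()` defaults to *balanced* (round-robin)
realisation of alternations and wildcards. Random draws would push an
alternation column over the 0.6 single-residue threshold with
probability ≈ 0.10 at n = 50 — a sampler artifact, not a property of the
consensus rule; the balanced mode emulates a taxon set that jointly
covers the variants.

## Motif evolution

`fitch_reconstruct()` is classic unordered two-state Fitch parsimony on
a rooted tree (polytomies resolved deterministically); tests verify the
change count against exhaustive enumeration of ancestral labelings.
`count_gain_loss()` resolves ambiguous nodes top-down with a
root-state policy (default: prefer absence at the root, pushing gains
toward later branches); gains + losses always equals the Fitch minimum.
`dollo_count()` is offered for single-origin motifs such as (K/R)RRW.
The bundled subgroup cladogram and state tables reproduce the published
qualitative models: one holometabolan gain of (K/R)RRW with no losses;
TxxΨW gained with the neopterans and replaced in holometabolans; the
LQTVPRVPVAGV-type signature homoplastic between Hymenoptera and
Mecoptera (the tool reports the homoplasy, it does not resolve it —
the same applies to the Mecoptera/Diptera DL-rich discrepancy).

## The synthetic generator: what it does and does not emulate

`make_exemplar()` realises each template's motif instances from the
printed consensi (alternation → first printed alternative, `Ψ` → L,
wildcard → draw from the linker alphabet) and joins them with linkers
from `{G, N, Q}` — chosen once because those residues lie outside every
motif class, so linkers can never seed compositional hits. Stated-world
defaults: generic linkers 2–8 residues; S-rich→DL-rich gap 10–30 for
B1-1 (the long-linker architecture; real crustacean linkers reach
~137 residues), 8–14 for B1-2, 6–12 for the holometabolan types, 4–5
for B1-2'; type-5 extension 15–22. The SP dipeptide is placed ≥ 5
residues past the S-rich motif (except B1-2', ≥ 2): a compositional
window bridging the S-rich tail can absorb an adjacent serine, which
would silently turn the SP residues into S-rich tail — a real ambiguity
of compositional motifs that the generator avoids by construction rather
than hiding.

Noise substitutes motif-instance residues (uniformly, to a different
canonical residue) with the given per-residue probability; linkers are
already random and are left alone; substitutions never create gaps, and
motif-destroying substitutions are allowed — that is the point of the
stress test. The generator does **not** emulate phylogenetic correlation
of substitutions, indels, alignment error, or compositional drift of
linkers; a green round-trip test therefore establishes that the rules
recover the architectures they define, not that they would recover them
from real, divergent sequences.

## Numerical and degenerate-input choices

Coordinates are 1-based inclusive everywhere user-visible (GFF3
convention). A sequence shorter than the compositional window yields an
empty result, not an error; empty or all-gap input is an error. Score
ties in hit retention break leftmost. Frequency vectors must sum to 1
within 1e-6; information content of an all-gap column is NA and the
column is skipped. All randomness flows from explicit seeds through
`withr::with_seed`, so no call disturbs the caller's RNG state.

## Known limitations

* Detection is consensus-exact (no PSSM/profile-HMM scoring, a stated
  non-goal), so robustness to substitution noise is limited: measured
  label-recovery over the 12 templates is 100 % noise-free but ≈ 0.5 at
  5 % per-residue substitution — e.g. the 12 constrained A-box positions
  survive 5 % noise with probability 0.95¹² ≈ 0.54. The acceptance test
  records this honestly rather than loosening the bar.
* Isoform identity (A vs B1) is an input, not an inference.
* The annotator assumes its input *is* the isoform-specific region
  (plus at most a short flank); it does not locate the region within a
  full-length receptor.
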