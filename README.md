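# ecrmotifs

Comparative sequence analysis of the N-terminal isoform-specific regions
of insect ecdysone receptor (EcR) A and B1 isoforms.

The ecdysone receptor mediates 20-hydroxyecdysone signalling throughout
insect development. Its A and B1 isoforms differ only in the N-terminal
segment of the A/B domain, which carries the ligand-independent AF-1
activation function. Across arthropods these isoform-specific regions are
built from a small set of short conserved *microdomains* embedded in
otherwise variable, disordered sequence:

* **A isoform**: a SUMOylation motif (ΨKxE, Ψ a large hydrophobic
  residue), a monopartite nuclear localization signal (K(K/R)x(K/R), with
  a hymenopteran KxxR variant), conserved (D/E)(D/E)W residues, and the
  C-terminal Ser/Thr-rich **A-box**, plus lineage-specific N-terminal
  signatures (DLKHE, ΨAYRG, D(T/S)S repeats, YRLN).
* **B1 isoform**: an acidic/neutral-polar **S-rich motif** with an
  EV(T/S)SS core, conserved **SP residues**, an acidic-activator-like
  **DL-rich motif** of acidic (D, E) and bulky hydrophobic
  (W, A, F, I, L, M, V) residues, and — in holometabolous insects only —
  an N-terminal **(K/R)RRW** motif, preceded in Hymenoptera/Mecoptera by
  an LQTVPRVPVAGV / LAVPRVPVAGV signature.

The package implements that analysis as a reusable pipeline:

1. **Motif grammar** — a compiler/scanner for the degenerate consensus
   notation (fixed residues, `x` wildcards, `Ψ`, `(X/Y)` alternations)
   and a compositional-window scanner for the S-rich and DL-rich
   low-complexity motifs (`compile_pattern()`, `scan_pattern()`,
   `scan_composition()`).
2. **Annotator** — scans one region with the full catalog, applies
   N-/C-terminal positional rules and the contextual SP rule, and checks
   the expected architecture (`detect_microdomains()`,
   `check_architecture()`).
3. **Classifier** — assigns one of the 12 published structural types
   (A1–A5; B1-1, B1-2, B1-2', B1-3–B1-6) from the motif inventory
   (`classify_region()`).
4. **Profiles** — degenerate consensus strings and per-position
   information content, `log2(20) − H`, from aligned motif instances
   (`build_consensus()`, `information_content()`).
5. **Motif evolution** — Fitch parsimony reconstruction of motif
   gain/loss over a rooted insect cladogram, with a bundled subgroup tree
   and state tables (`fitch_reconstruct()`, `count_gain_loss()`,
   `dollo_count()`).
6. **Synthetic data** — ground-truthed exemplar generator for all 12
   architectures built from the published per-type consensus sequences
   (`make_exemplar()`, `make_panel()`), so every stage is testable
   without downloads.

## Worked example

```r
library(ecrmotifs)

ex <- make_exemplar("B1-3", noise_rate = 0, seed = 1)
region <- detect_microdomains(ex$sequence, "B1", sequence_id = "demo")
region
#> <ecr_region> demo (hint B1, 47 aa): 4 motif hit(s)
#>  motif_id start end          match     score   variant
#>      KRRW     1   4           KRRW 1.0000000 canonical
#>     SRICH    10  20    EESSSEVTSSS 0.9090909 canonical
#>        SP    26  27             SP 1.0000000 canonical
#>    DLRICH    29  42 DIGDVDLEFWDLDL 0.9285714 canonical
classify_region(region)
#> <ecr_type_call> B1-3
```

The four hits are the holometabolan (K/R)RRW motif at the N-terminus,
the S-rich motif (score = fraction of acidic + neutral-polar residues
over the reported run, 10/11), the SP residues between the S-rich and
DL-rich motifs, and the DL-rich motif (13/14 acidic + bulky residues).
The inventory {KRRW, SRICH, SP, DLRICH} without the
LQTVPRVPVAGV-type signature is the type-3 B1 architecture
(Coleoptera and allied orders).

Motif evolution over the bundled cladogram:

```r
tr <- ecr_subgroup_tree()
states <- read_state_table(system.file("extdata", "b1_motif_states.tsv",
                                       package = "ecrmotifs"))
count_gain_loss(fitch_reconstruct(tr, setNames(states$KRRW,
                                               rownames(states))))[c("gains", "losses")]
#> $gains [1] 1    $losses [1] 0
```

— the (K/R)RRW motif is reconstructed as a single gain on the branch to
the holometabolous insects, with no losses.

A command-line surface is installed as `exec/ecrmotifs` with
`annotate`, `classify`, `consensus`, `simulate` and `evolve`
subcommands (exit codes: 0 success, 2 input error, 3 config error).

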