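# degenmix

Design and validate equimolar pools ("mixes") of degenerate PCR primers
for marker genes whose orthologs are too divergent for a single primer
pair.

The motivating use case is functional-gene PCR assays for specific
microbial guilds — for example a glycosyltransferase gene found only in
heterocyte-forming (nitrogen-fixing) cyanobacteria — where a panel of a
few dozen orthologs must be amplified with one pooled assay.  `degenmix`
takes an alignment of those orthologs and automates the whole desk
workflow:

1. **Window scanning** (`scan_windows`, `pair_regions`): find gap-free
   binding windows of 17–22 bp whose per-column majority-base
   conservation averages at least 75 % and whose consensus satisfies the
   guideline screen — melting temperature `Tm ∈ [50, 65] °C` (Wallace
   rule `2(A+T) + 4(G+C)` below 14 nt, `64.9 + 41(GC − 16.4)/L`
   otherwise), GC fraction < 50 %, no homopolymer runs > 4, no hairpin
   with stem ≥ 4 and loop ≥ 3, no 3′-anchored self-dimer run ≥ 4 — then
   pair forward and reverse windows, maximizing the product span subject
   to `|ΔTm| ≤ 4 °C`.
2. **Variant design** (`partition_targets`, `relax_variant`): split the
   target panel into the fewest groups such that each group is covered
   exactly by one degenerate oligo with at most **four non-consecutive
   IUPAC ambiguity codes** (codes never widened beyond the observed
   bases; exact subset-cover search up to 12 distinct sequences, greedy
   set cover beyond).  Optionally relax a variant by **one** extra
   degeneracy where that widens strain coverage (the `G1 → G1n`
   pattern), giving a conservative mix A and a relaxed mix B.
3. **Thermodynamic QC** (`qc_primer`): OligoCalc-style screening of each
   oligo, with Tm/GC applied to the extremes over all expansions of the
   pool and structure checks taken as the worst case over expansions.
4. **In-silico PCR** (`match_primer`, `predict_amplicons`,
   `coverage_matrix`): strict zero-mismatch matching of every expansion
   on both strands (optionally up to 2 mismatches with an exact 3′
   anchor), product prediction with sizes, and the strain × variant
   coverage matrix whose column sums are the "targets *N* strains"
   counts.
5. **Marker resolution** (`pairwise_pdistance`, `nj_tree`,
   `rf_distance`, `amplicon_tree`): p-distance neighbor-joining trees of
   the predicted amplicons versus the full gene, compared by
   Robinson–Foulds distance, to check that the amplified fragment still
   resolves the clades.
6. **Synthetic data** (`simulate_gene_family`, `plant_primer_sites`,
   `synthetic_hglt_panel`): deterministic generators of gene families
   with planted conserved blocks and planted primer sites, plus a fully
   synthetic 24-sequence benchmark panel with designed primer mixes, so
   the entire pipeline is testable offline.

## Worked example

The package ships a synthetic 24-sequence marker-gene panel (8 clades,
1050 bp, no gaps) with a designed primer table — a stand-in for a real
ortholog panel, engineered to show the characteristic coverage
structure of pooled degenerate assays:

```r
library(degenmix)
panel <- synthetic_hglt_panel()

prm <- setNames(panel$primers$sequence, panel$primers$name)
count_degenerate_positions(prm[["Fw1_G1"]])   # 3
count_degenerate_positions(prm[["Fw1_G1n"]])  # 4

cov <- coverage_matrix(list(fw = prm[c("Fw1_G1", "Fw1_G1n")]),
                       panel$templates)
cov$variant_counts
#  Fw1_G1 Fw1_G1n
#       6       8
```

The minimal-degeneracy variant `Fw1_G1` (3 ambiguity codes) covers 6 of
the 24 strains; adding a single extra degeneracy (`Fw1_G1n`, 4 codes)
extends coverage to 8 without violating the design rules.  The pooled
mixes amplify the whole panel with a single product:

```r
ref <- panel$templates[panel$templates$id == panel$reference, ]
predict_amplicons(panel$mixes$Fw1_mixB, panel$mixes$Rv1, ref)[
  , c("fw_variant", "rv_variant", "product_length")]
#   fw_variant rv_variant product_length
# 1    Fw1_G1n     Rv1_G1            857
```

One product of 857 bp — the span between the forward window (columns
112..133) and the end of the reverse window (968) — is predicted for
every strain in the panel (`Fw1_mixB` holds 7 variants, `Rv1` holds 5,
each mix covering all 24 targets).

A command-line interface wraps the same functions
(`inst/cli/degenmix.R`; subcommands `simulate`, `scan`, `design`,
`ispcr`, `tree`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/degenmix.R", package="degenmix"))')
Rscript "$CLI" ispcr --fw mixB.fasta --rv rv1.fasta \
  --templates genes.fasta --max-mismatch 0 \
  --out amplicons.fasta --matrix coverage.tsv
```

All coordinates in inputs and outputs are 1-based and inclusive.

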