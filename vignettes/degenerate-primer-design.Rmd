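---
title: "Designing degenerate primer mixes with degenmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate primer mixes with degenmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenmix)
```

## The problem

Functional marker genes — genes diagnostic of a metabolic guild rather
than of taxonomy, such as the glycosyltransferase catalyzing the final
step of heterocyte glycolipid synthesis in nitrogen-fixing
cyanobacteria — are often too divergent across the target panel for any
single primer pair to amplify them all.  The standard remedy is a
*degenerate primer mix*: several oligos per binding region, each
carrying a few IUPAC ambiguity codes, pooled in equimolar amounts.
Designing such a mix is a constrained covering problem:

* each oligo may carry at most **four** degenerate positions, and no
  two of them may be adjacent (rules that keep the pool size and the 3′
  stability of every variant acceptable);
* degenerate codes are never widened beyond the bases actually observed
  in the panel, so each variant is the *minimal* IUPAC consensus of the
  group it covers;
* the set of variants should jointly cover the whole panel with as few
  oligos as possible.

`degenmix` implements this design procedure end to end together with
the screening, validation and resolution checks around it.

## Binding-region guidelines

Candidate windows are screened on the alignment with the following
defaults (`design_rules()`), all configurable:

| parameter | default | unit | role |
|---|---|---|---|
| `primer_len_min/max` | 17 / 22 | bases | window and oligo length |
| `tm_min/max` | 50 / 65 | °C | Tm bounds, at the *extremes over expansions* |
| `gc_max` | 0.50 | fraction | strict upper bound on worst-case GC |
| `conservation_threshold` | 0.75 | fraction | mean majority-base fraction over the window |
| `max_degenerate` | 4 | positions | per-oligo degeneracy budget |
| `pair_tm_delta_max` | 4 | °C | Tm compatibility within a pair |
| `polyN_max_run` | 4 | bases | longest allowed homopolymer |
| `hairpin_stem_min/loop_min` | 4 / 3 | bases | hairpin geometry flagged |
| `dimer_run_max` | 4 | bases | 3′-anchored complementary run flagged |

Melting temperatures are composition-based, in the style of OligoCalc's
basic mode: the Wallace rule $T_m = 2(A{+}T) + 4(G{+}C)$ below 14 nt
and $T_m = 64.9 + 41\,(GC - 16.4)/L$ from 14 nt on.  We chose these
formulas because they need no salt or concentration parameters and
reproduce the customary manual workflow; nearest-neighbour
thermodynamics is deliberately out of scope.  Because both formulas are
monotone in the G+C count at fixed length, the Tm and GC extremes of a
degenerate oligo are computed combinatorially from per-position GC
bounds rather than by enumerating expansions.

A consequence worth knowing: under these exact bounds the joint
constraint "Tm ≥ 50 °C and GC < 50 %" is satisfiable only by 21–22-mers
with 9–10 G+C (a 20-mer with 9 G+C reaches only 49.7 °C).  The screen
applies the rules verbatim and therefore emits 21/22-base windows; users
wanting the classical 18–20-mers should relax `tm_min` or `gc_max`.

Conservation is operationalized per column as the fraction of rows
carrying the majority base (ties broken alphabetically), with a window
score equal to the mean over its columns; any gap in any row disqualifies
a window.  This is the simplest aggregation consistent with colouring
columns "conserved" at a 75 % threshold; alternatives (minimum over
columns, entropy) were rejected as either too brittle or not matching
practice.  Reverse-orientation windows are QC'd on the reverse
complement, since that is the oligo actually synthesized.  Forward and
reverse windows are paired under the ±4 °C rule and ranked by product
span, largest first — the design favours the longest amplifiable
fragment, and a `min_product` floor (default 400 columns) suppresses
trivially short pairs.

## Variant design

For a chosen window, the target rows are partitioned into groups, each
represented by its minimal degenerate consensus.  Feasibility of a group
(≤ 4 degeneracies, non-consecutive) is *downward closed* — any subset of
a feasible group is feasible — so the minimum partition equals a minimum
set cover and can be solved exactly by dynamic programming over subsets.
The exact search is used up to 12 distinct window sequences; beyond that
a grow-from-seed greedy takes over (repeatedly emit the feasible group
covering most uncovered targets; ties favour fewer degeneracies, then
the lexicographically smallest variant).  Variants are named `G1`,
`G2`, … in order of decreasing coverage.

`relax_variant` implements the one-extra-degeneracy escape: among all
non-degenerate positions that would not create adjacent degeneracies, it
widens the one (to exactly the bases observed in the newly covered
targets) that gains the most strains, breaking ties toward better-spread
degeneracies.  "Covers" always means an exact full-length match of some
expansion; mismatch tolerance is a property of the *in-silico PCR*
layer, not of the design layer, so that reported coverage counts are
reproducible sequence-identity statements.

## In-silico PCR

Matching uses per-position bitmask compatibility on both strands.  The
default policy is strict — zero mismatches, `N` in a template matches
nothing — because coverage counts are meant to mirror design-time
identity.  A permissive mode (`max_mismatch` up to 2 with an exact 3′
anchor of 3 bases) models the empirical observation that PCR can
amplify slightly beyond the designed panel.  Products are every
forward(+)/reverse(−) placement pair within the size window (default
100–3000 bp, primers included); duplicate products keep the
fewest-mismatch variant pair.  Templates are treated as linear; circular
wrap-around is not considered.

## Marker resolution

To ask whether the amplified fragment retains phylogenetic signal, the
package cuts the fragment out of the design alignment (no re-alignment
needed), computes p-distances with pairwise gap deletion, builds a
neighbor-joining tree (`ape::nj`, consistent on additive matrices), and
compares topologies by Robinson–Foulds distance over non-trivial
bipartitions.  Maximum-likelihood inference and support values are out
of scope by design; the NJ/RF pair keeps the resolution claim testable
at desk scale, and alignments are exported so users can run external ML
tools.  One caveat: NJ tie-breaking follows `ape`'s internal order; for
the continuous distances arising here ties have probability zero, and
the determinism contract is stated for tie-free matrices.

## Synthetic data

Two generators make the pipeline testable without downloads.

`simulate_gene_family` draws a uniform root sequence, applies
Jukes–Cantor-like substitutions (uniform over the three alternatives) —
half shared within clades when a clade structure is given, half private
per taxon — and plants conserved blocks whose per-column minority count
is capped at `⌊max_minor_fraction · n⌋`, guaranteeing the advertised
conservation bound by construction (the generator self-validates after
sampling).  No indels are simulated, so the family is its own
alignment; gap handling is exercised by post-hoc gap injection in the
tests.  `planted_design_family()` fixes the study conditions used in
the recovery checks: 24 taxa, 1050 columns, invariant 20-base blocks at
112..131 and 970..989 inside a 50 %-divergent background.  The block
contents were chosen once so that every single-flank window extension
passes the QC screen, making the planted truth recoverable for any
background seed; with 9 G+C they also guarantee (by the composition
arithmetic above) that no window shorter than 21 bases can pass, so
recovery is never accidental.

`synthetic_hglt_panel()` is a deterministic, fully synthetic stand-in
for a real ortholog panel: 24 sequences in 8 clades whose two designed
binding regions (112..133 forward, 948..968 reverse) use only A↔T and
G↔C polymorphisms, so every variant's expansions share one GC count and
the Tm rule applies uniformly.  The panel is engineered to exhibit the
canonical coverage structure of pooled assays — a 3-degeneracy variant
covering 6/24 whose single relaxation covers 8/24, a 7-variant forward
mix B and a 5-variant reverse mix each covering all 24, and a single
857 bp product per strain.  What passing these checks shows is that the
design, matching and counting machinery is exact on a panel with known
truth; it does not show field performance on real genomes, which bring
alignment error, paralogs and length variation that the panel
deliberately omits.

## Numerical and edge-case conventions

* Coordinates are 1-based inclusive everywhere (R's native convention);
  internal code uses the same convention to avoid off-by-one seams.
* `U` is accepted on input and stored as `T`; input case is ignored.
* Homopolymer runs of degenerate oligos are worst case over expansions
  (longest run of positions whose codes share a base), as are hairpin
  and dimer screens ("possible complement" bitmask semantics; a
  position never pairs with itself within one molecule, while self-dimer
  screening allows two different expansions of the pool to pair).
  The poly-N rule flags runs *longer than* 4 (a run of exactly 4 is
  allowed); the 3′ dimer rule flags runs of 4 *or more*.
* Empty results are empty data frames, never errors; infeasibility and
  uncoverable targets are reported with the violated rule named.
* Problem sizes in the tests and the acceptance script (panels of
  4–8 targets for exhaustive partition comparison, oligos ≤ 13 nt for
  hairpin enumeration, 100 NJ trials on 6–10 leaves) were chosen as the
  largest sizes where the brute-force oracles stay exact and fast.

## Known limitations

* Tm estimates are composition-only; no salt, concentration or
  nearest-neighbour corrections, no ΔG for structures.
* The greedy partition beyond 12 distinct sequences is a heuristic; it
  is exact-checked only at small sizes.
* Published variant groupings of real assays are often
  phylogeny-informed by hand; `degenmix` reproduces coverage-equivalent
  mixes, not necessarily the same literal grouping.
* Cross-amplicon multiplexing and pooling stoichiometry are out of
  scope.
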