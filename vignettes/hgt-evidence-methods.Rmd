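---
title: "Detecting horizontal gene transfer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtEvidence)
```

## The problem

When a bacterium carries a gene whose closest relatives live in a distant
lineage, three explanations compete: horizontal acquisition, differential
loss in every intervening lineage, or artefact (contamination,
misannotation). No single observation settles the question, which is why
this package implements several independent lines of evidence and keeps
each one separately inspectable. The motivating system is bacterial
poly(A) polymerase I (PAP I, encoded by *pcnB*), a nucleotidyltransferase
that several phyla outside the β/γ-Proteobacteria appear to have acquired
from those classes; its closest paralogue, the CCA-adding tRNA
nucleotidyltransferase (TNT), is vertically inherited and serves as the
recipient-lineage reference throughout.

## The alien index

For a query protein, let $E_r$ be the E value of its best homology hit in
its own (recipient) lineage and $E_d$ the best hit in the candidate donor
lineage. The alien index is

$$\mathrm{AI} = \ln(E_r + 10^{-200}) - \ln(E_d + 10^{-200}).$$

The pseudocount $10^{-200}$ makes the statistic finite when a search tool
reports $E = 0$; it also caps the statistic. A missing hit is substituted
by $E = 1$ before the formula (`alienIndex(NA, 0)`), because the stated
maximum $460.5 = \ln 1 - \ln 10^{-200}$ presumes exactly that convention.
Both choices are exposed (`epsilon` argument) but should not normally be
touched: every published value the package reproduces uses them.

Categories follow the three-way rule: AI > 30 with donor identity < 70 %
is `very_likely_hgt`; AI > 0 with identity < 70 % is `possible_hgt`;
AI > 0 with identity ≥ 70 % is `likely_contamination`; AI ≤ 0 is
`no_hgt_signal`. The 70 % identity stipulation exists to catch
contamination in prokaryote-to-eukaryote screens and is disabled by
default (`identityRule = FALSE`): for prokaryote-to-prokaryote transfers a
near-identical donor hit is the expected signature of a recent transfer,
not an artefact. The thresholds (30, 0) are configurable in the pipeline
config but the defaults are the published ones.

Best-hit selection within each lineage group takes the minimal E value;
exact ties are broken by larger bit score, then larger percent identity,
then lexicographic subject id, so results are deterministic for any input
order. E values are consumed as reported by the search tool and never
recomputed from alignments.

Recomputing the index for the 15 curated species rows
(`papBestHits()`) reproduces the curated integer for 13 of 15; the
Campylobacter and Mesorhizobium rows differ by 1 and 3 from the formula
applied to their own E values. The package follows the formula and
documents, rather than reconciles, those two cells.

## Signature-motif scanning

The PAP I signature consensus
`[LIV][LIV]G[RK][RK]Fx-[LIV]h[HQL][LIV]` is parsed as eleven positional
residue classes. Design choices, each of which the parser exposes:

* the hyphen is a cosmetic separator, not a gap: both worked 13-mer
  signatures align to an 11-position window under that reading;
* `h` (hydrophobic) defaults to the conventional aliphatic/aromatic set
  {A, V, L, I, M, F, W, C}, configurable, since the consensus's source
  never defines it; the canonical example (…L**A**H…, A at the h
  position) is consistent with this set;
* mismatch tolerance defaults to 0; all overlapping windows within
  tolerance are reported, with no greedy masking.

`bestWindow()` reports the minimal-mismatch window regardless of
tolerance, which matters for near-matches: the reported spirochaete
signature `IIGRFFVIHVHIL` violates the strict consensus at four positions
under any standard hydrophobic set, so the scanner deliberately does not
match it at zero tolerance and instead surfaces the violation count.

## G+C compositional affinity

mol% G+C weights each IUPAC code by its expected G+C fraction (S = 1,
R = 0.5, B = 2/3, …) over the full sequence length, so the value is
defined for every valid sequence and reduces to the plain count on ACGT
input — the regime of all published numbers. The affinity verdict simply
compares $|gene - host\ genome|$ against $|gene - donor\ gene|$; exact
ties are reported as ties. The fold ratio (element G+C / genome G+C) is
reported to one decimal, matching the tabular convention. Composition is
corroborating evidence only: amelioration erodes it over time, and a
donor with host-like composition produces an uninformative verdict.

## Phylogenetic congruence

A best homology hit need not be the nearest phylogenetic neighbour, so
the pipeline checks congruence explicitly: the query leaf's nearest
neighbour by patristic distance must equal the best donor hit. Ties are
flagged and broken lexicographically rather than silently, because this
is the headline qualitative check. Whether "closest neighbour" means
patristic proximity or clade sisterhood is a genuinely open reading; the
result object carries the query's sister-clade leaf set so either can be
inspected. `congruenceCheck()` is invariant to re-rooting.

Support values attach to the child node of each internal edge (the
standard Newick resolution) and the scale is auto-declared on parse:
values above 100 imply a per-mille scale (of-1000 bootstrap scores).
`collapseLowSupport()` contracts internal edges whose child support falls
below the threshold (default 700 in the pipeline, i.e. the 0.7 consensus
fraction). Consensus procedures operate on topology only, so by default
the contracted edge's length is discarded — with a warning that
post-collapse distances are topology-biased; `redistribute = TRUE` adds
the contracted length to each re-attached child edge instead, preserving
path lengths through the former node.

## Mobile-element proximity

Windows of 5 kb (configurable) flank the focal gene on both sides,
clipped at contig bounds, with upstream/downstream defined on the gene's
strand. The distance convention names two terminal bases — from the
gene's 3′-terminal base to the element's proximal base on that side, and
mirrored on the 5′ side — and counts their simple coordinate difference,
so an abutting element is at distance 1 and an overlapping one at 0 with
a flag. The published distance table lists a few entries slightly beyond
5 kb; this implementation filters strictly at the configured flank, so
such borderline elements are excluded unless the flank is widened.
Element detection itself (HMMs, database mirroring) is out of scope:
element hits arrive as a tabular file or as `mobile_element` features.

## The synthetic-data generator

The generator exists so that every stage is testable, deterministically,
without downloads. A `transferScenario()` fixes the study conditions:

* recipient genome at 33 mol% G+C, donor at 71 — the strongest
  compositional contrast in the curated species set (an AT-rich
  Bacteroidetes recipient and a GC-rich β-proteobacterial donor);
* genome 100 kb, gene 1200 bp (400 codons, a typical PAP length). At
  100 kb a GC-rich insert of this size shifts genome-wide mol% by under
  0.5 points, so the genome/gene contrast stays clean;
* donor-orthologue identity drawn in [80, 100] %, recipient-paralogue
  identity in [29, 38] % — the identity regimes of the curated hit table;
* tree supports drawn in [700, 1000] so every clade survives collapse at
  the default threshold; the transferred gene's leaf is grafted as sister
  to the donor leaf on a short branch;
* two mobile elements inside the 5 kb flanks, one outside.

Simulated E values come from a Karlin–Altschul-shaped map
$E = K m n\, e^{-\lambda S}$ with $S = s_0 + s_1 \cdot \mathrm{identity}
\cdot L / 100$ (defaults $K = 0.041$, $\lambda = 0.267$, $m = n = 450$,
$s_0 = 0$, $s_1 = 2$, $L$ the gene length in bp). Only monotonicity and
range coverage matter — the alien index consumes E values, not
alignments. The calibration is chosen so that 100 % identity falls far
below the $10^{-200}$ pseudocount (the "donor E value is 0" regime, about
$5 \times 10^{-275}$ at 1200 bp) while 30 % identity gives a clearly
resolvable paralogue-level E value (about $10^{-80}$); a single linear
score cannot simultaneously put 30 % identity above $10^{-40}$ and 100 %
below $10^{-180}$, and the donor-side regime is the one the evidence
chain depends on.

Mutation of the transferred copy swaps bases within the strong (G/C) and
weak (A/T) classes, so the copy keeps the donor's composition exactly, as
a recently transferred gene would before amelioration; in-frame stop
codons are repaired by a middle-base substitution. The embedded signature
motif is re-spliced after mutation — it models a conserved functional
element. Insertion replaces recipient sequence rather than extending it,
keeping genome length constant.

What the generator does **not** emulate: codon usage, amelioration over
time, indels, alignment-level evolution, paralogue families, assembly
artefacts, or compositional heterogeneity along real genomes. Passing the
synthetic recovery tests therefore demonstrates that the pipeline's logic
is correct under its stated assumptions, not that the thresholds are
optimal for any particular real dataset.

## Verdict aggregation

Per gene: `hgt_supported` iff the alien-index category is
`very_likely_hgt` **and** (the G+C verdict is donor-consistent **or** the
tree is congruent); `no_support` iff the category is `no_hgt_signal`;
`ambiguous` otherwise. The source analyses aggregate these strands
narratively; the explicit AND/OR rule is this package's codification, and
the thresholds behind it live in the run configuration. Disabled or
missing stages (no tree, no elements) leave their fields `NA` and can
only remove, never add, support.

## Numerical conventions and degenerate inputs

* Exact zero E values are preserved on parse and round-trip, and are
  distinguishable from the smallest positive double.
* Coordinates are 1-based inclusive everywhere (the GFF3 convention).
* Unstranded features are mapped to "+" with a `strand_missing` flag.
* Protein `*` (stop) characters are stripped on FASTA read with a
  warning; `U` is stored as `T`.
* Empty homology tables produce an empty report and a success exit;
  a gene at a contig edge gets a clipped (possibly empty) flank window.
* All tie-breaks (best hits, nearest leaves) are deterministic and
  documented above; reports are byte-identical across reruns.

## Problem sizes in the test suite

The suite verifies the scanner against a brute-force window oracle on
1000 random sequences, patristic distances against an all-pairs path-sum
oracle on trees of up to 12 leaves, and detection calibration on 100
simulated transfer scenarios plus 100 null scenarios (expected: at least
99 of 100 transfers flagged, 0 of 100 nulls). These sizes give binomial
noise well below the asserted margins while keeping the default test run
fast.

## Known limitations

* Lineage groups (donor/recipient) are caller-supplied; the package does
  no taxonomic inference.
* The alien index inherits every bias of the underlying homology search
  (database composition, low-complexity filtering); it is a screen, not
  a test with a calibrated null distribution.
* Congruence uses patristic distance on the provided tree as-is; tree
  inference quality is the caller's responsibility, and collapsing
  support without redistributing lengths biases distances (flagged).
* Whether reported hit coverage is query- or subject-side is left open by
  the upstream format; the reader accepts either via `columnSpec` and the
  pipeline labels it "coverage" without committing.
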