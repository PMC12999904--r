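---
title: "Comparative genomics of a plant gene family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of a plant gene family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscape)
```

famscape re-implements, as a tested and reusable pipeline, the comparative
analysis typically applied to a plant gene family across a panel of related
genomes: which genes belong to the family, how they partition into
subfamilies and orthologous gene groups (OGGs), how strongly selection has
constrained them, how the family expanded (whole-genome versus small-scale
duplication), what regulatory elements sit in their promoters, and which
members respond to abiotic stress. The motivating application is the MAPKKK
(mitogen-activated protein kinase kinase kinase) family — the upstream tier
of the three-kinase MAPK cascade, with RAF, MEKK and ZIK subfamilies — in a
panel of composite (Asteraceae) genomes, but every stage is generic over a
roster of gene models and the standard file formats.

This vignette documents the models and procedures, the tunable parameters,
the synthetic-data generator that backs the validation suite, and the design
choices made where the methodology was genuinely open.

## Family identification

Candidate members come from protein kinase domain hits (HMMER3 domain
tables against PF00069). A protein is accepted when at least one hit passes
all three filters:

* full-sequence E-value ≤ `evalue_cutoff` (default **1e-10**);
* model coverage `(model_to − model_from + 1) / model_len` ≥
  `domain_completeness_fraction` (default **0.8**) — our operationalisation
  of "has a complete kinase domain", which domain-annotation services judge
  but do not quantify; the fraction is configurable;
* protein length ≥ `min_protein_length` (default **100 aa**).

Each locus then keeps only its longest transcript (greatest summed CDS
length; ties broken by the lexicographically smallest transcript id in the C
locale, so `t10 < t2` — an arbitrary but fixed rule), and members are renamed
by chromosomal position: chromosomes in natural numeric order (`chr2` before
`chr10`), then start coordinate, then gene id, with zero-padding to the
digit count of the family size so names sort correctly.

## Gene structure

On the retained transcript we report total gene length, CDS segment count,
intron count (`exons − 1`), total intron length (transcript span minus
summed exon length), and protein length (CDS/3, excluding a terminal stop
codon when the CDS sequence is available to detect one). Group differences
are assessed with a two-sided Wilcoxon rank-sum test. Because published
analyses of this kind report per-panel significance without multiplicity
adjustment, no multiple-testing correction is applied across panels. The
test uses exact enumeration of all group assignments (with midranks under
ties) when both groups have at most 8 observations, and the tie-corrected
normal approximation otherwise; `stats::wilcox.test` cannot enumerate
exactly under ties, which is why the statistic is computed here, and the two
implementations are cross-checked in the test suite where their definitions
coincide.

## Subfamily and cluster assignment

Protein alignments are trimmed with the keep-if rule: a column is kept when
its non-gap fraction is ≥ `gap_threshold` (default **0.2**, boundary
inclusive). Distances are p-distances over columns where neither row is
gapped (pairs with no comparable columns get distance 1, with a warning).
Trees are built by Saitou–Nei neighbor joining. Maximum-likelihood inference
is deliberately out of scope: NJ on p-distances is deterministic, fast at
desk scale, and sufficient for label propagation, which only needs local
neighbourhoods to be right. Negative NJ branch lengths are clamped to zero
with the deficit moved to the sister branch, and Q-matrix ties break on the
lexicographically smallest pair of cluster representatives, so the tree is a
pure function of the distance matrix.

Subfamily (RAF/MEKK/ZIK) and cluster (1–5 MEKK, 6–7 ZIK, 8–14 RAF) labels
propagate from a user-supplied reference panel: each leaf takes the labels
of its nearest reference by patristic distance, ties to the smallest
reference id. Nearest-reference was chosen over smallest-monophyletic-clade
because it stays robust when the NJ topology differs locally from an ML
topology. There is no objective criterion for cutting a family tree into
clusters, so cluster identity is always anchored to the reference partition
rather than inferred de novo.

## Orthogroups and conservation categories

With no published construction procedure to follow, orthogroups are built by
the most transparent standard method: reciprocal best hits (per gene and
partner species, the top-scoring cross-species partner, ties to the smallest
id; edges kept iff mutual) followed by connected components. Externally
computed membership tables can be substituted. Categories over an
`N`-species panel follow the presence width: **conserved** = present in all
`N`; **variable** = present in exactly `N − 1` (single loss allowed);
**rare** = present in 1 to `N − 2`. Copy number is recorded separately from
presence so copy-number heatmaps can be reproduced. Reported shares use
half-up rounding at two decimals.

## Selection pressure (Ka/Ks)

Pairwise protein alignments are back-translated to codon alignments (each
residue replaced by its source codon, gaps by `---`; mistranslations are a
hard error naming the column). Rates come from the Nei–Gojobori (1986)
counting method with Jukes–Cantor correction:

* per-codon synonymous site fractions from one-step mutations, with changes
  through stop codons excluded and sites renormalised over the valid
  changes;
* S and N averaged over the two sequences;
* multi-position codon differences averaged over all orderings of single
  steps, orderings through stops discarded (if every ordering is blocked —
  possible only in degenerate corners — all orderings are averaged);
* `ps = Sd/S`, `pd = Nd/N`, `d = −(3/4)·ln(1 − (4/3)p)`;
* `ω = Ka/Ks`, undefined when `Ks = 0` or a correction is undefined
  (`p ≥ 3/4`); undefined ratios are excluded from means and logged.

NG86 was chosen over approximate maximum-likelihood variants because every
quantity has a closed form that synthetic data can verify exactly: the
generator plants at most one substitution per codon, so the planted
synonymous/nonsynonymous counts are integers that the estimator must return
exactly. The trade-off is that absolute values will differ somewhat from
estimators with transition/transversion and codon-frequency corrections, so
published cluster means are treated as qualitative context, not as targets.

Aggregation is two-level, matching the field's reporting convention: the
orthogroup value is the arithmetic mean of all defined pairwise values
within the group; the cluster value is the unweighted mean of its
orthogroups' means (not pooled over pairs).

## Duplication modes and collinearity

Collinear blocks are chains of anchor pairs, found per chromosome pair by
longest-chain dynamic programming in both orientations: side-A ranks
strictly increasing, side-B strictly increasing (`same`) or decreasing
(`inverted`), consecutive rank gaps ≤ `max_rank_gap` on both sides. Blocks
need ≥ `min_block_size = 10` anchors — the block minimum is counted in
anchors, the stricter reading of "minimum ten genes". `max_rank_gap`
defaults to **25**, in the spirit of MCScanX's defaults. Chains are
extracted greedily by length (ties: `same` orientation, then leftmost
start), and each anchor joins at most one block.

Duplication modes are assigned with the DupGen-style priority
WGD > TD > PD > TRD > DSD:

* **WGD** — the gene anchors an intra-species block;
* **TD** (tandem) — a homolog on the same chromosome at rank distance 1;
* **PD** (proximal) — rank distance 2..`proximal_max_gap` (default 10);
* **TRD** (transposed) — in a homolog pair where only the partner sits in a
  block with the outgroup, the copy *lacking* outgroup synteny is the
  transposed one (its ancestral partner falls through to DSD);
* **DSD** (dispersed) — any remaining gene with a homolog; genes without
  homologs are singletons.

Tandem/proximal distance conventions follow DupGen_finder, since the
methodology literature leaves them implicit.

## Promoter cis-elements

Promoters are the `window = 2000` bp immediately 5′ of the translation
start (the first CDS base — not the transcript start), reverse-complemented
for minus-strand genes and truncated (and flagged) at chromosome ends. Web
services for plant cis-element annotation are not scriptable and their
matrices not redistributable, so scanning is exact IUPAC-consensus matching
against a packaged, editable library of the 14 high-frequency elements
(MYC, MYB, ARE, STRE, MYB-like / Box-4, G-box, GT1-motif / ABRE, ERE,
CGTCA-motif, TGACG-motif, as-1 / AAGAA-motif) in the four functional
classes (stress, light, hormone, development). Element totals therefore are
not comparable to counts from the full 86-type annotation. Matching rules
that make counts well-defined: overlapping matches all count; both strands
are scanned, minus-strand hits reported at the plus-strand window start;
palindromic matches are deduplicated by coordinates; `N` never matches.
Proportion matrices are per group (species, subfamily or orthogroup)
relative to the group's total hits; heatmap scaling is per column,
`(x − mean)/sd` with the population sd, constant columns mapping to zeros.

## Expression and qPCR

FPKM is `count × 1e9 / (length × library size)`. The responsiveness screen
is `|log2((treated + c)/(control + c))| > 1` (strict), with pseudocount
`c = 1` by default — the published screens do not state their fold-change
floor, so it is configurable; condition means over replicates feed the
ratio. qPCR analysis is 2^−ΔΔCt against a reference gene and the 0 h
control, reporting the mean and SD (not SEM) of replicate folds. Letters in
time-course figures come from one-way ANOVA on log2 folds followed by Tukey
HSD at α = 0.05, with a greedy compact letter display assigned from the
highest mean downward — a documented stand-in, since such figures rarely
name their test.

## The synthetic-data generator

`generate_dataset()` replaces the ten real genome assemblies and the SRA
expression data with a panel in which every downstream answer is planted and
therefore checkable. Its defaults are the package's study conditions and are
not tuned per test: **10 species × 5 chromosomes × 40 gene slots, 50
orthogroups at a 0.30/0.50/0.20 conserved/variable/rare mix** (the validation
panel's calibration; other mixes and panel sizes are plain configuration),
planted ω targets {0.1, 0.2, 0.35, 0.5, 1.0},
duplication events {WGD 2, TD 3, PD 2, TRD 2, DSD 3}, 12-anchor collinear
blocks, two cross-species blocks, and a motif plan of seven insertions per
promoter.

Key constructions, and what they do and do not emulate:

* **Sequences** are hierarchical: one 300-codon root, subfamily ancestors
  mutated at 25 dedicated codon positions each, cluster ancestors at 6 more,
  members at 3 synonymous plus ω-scaled nonsynonymous positions drawn
  without replacement per orthogroup. Because positions are disjoint within
  an orthogroup and each carries one single-base change, every pairwise
  Sd/Nd is an exact integer — the Ka/Ks oracle. The fixed coding length
  isolates structure differences to introns (log-uniform per subfamily:
  intronless MEKK clusters 1–4, short introns in MEKK 5, intermediate in
  ZIK, long in RAF); real families also vary in coding length.
* **Homology scores** separate cleanly: true within-group pairs 90–97,
  block-context pairs 61–80, decoys 30–60. Duplicate copies get one
  designated "buddy" species scored above the primary pair so that every
  copy keeps a mutual best hit and RBH recovery stays exact even with
  planted duplications. Real similarity scores overlap across these strata;
  the recovery criteria hold under the stated separation, not in general.
* **Duplication geometry**: WGD pairs sit at matched offsets inside planted
  intra-species blocks; tandem copies at rank distance 1, proximal at 3;
  transposed parents inside planted outgroup-synteny windows with the copy
  elsewhere; dispersed copies on a chromosome pair chosen to avoid planted
  block corridors, so a dispersed anchor cannot be absorbed into a block
  chain. The transposed event's ancestral partner is truthed as DSD,
  which is what the stated priority implies for a gene with a homolog but
  no block membership.
* **Promoters** are built on backgrounds iteratively scrubbed of all library
  matches, with planted instances spaced ≥ 30 bp; after planting, the
  generator verifies that scanning returns exactly the planted set and
  deterministically re-draws the rare placements whose junctions would
  create an extra match. The verifying scanner is the same primitive the
  pipeline uses; it is itself pinned by hand-derived unit tests, which is
  what keeps this check meaningful.
* **Noise anchors** in the block-recovery fixtures are resampled out of the
  gap-reach corridor of planted chains; otherwise a noise anchor adjacent to
  a chain end would *legitimately* extend the chain and the exact-recovery
  oracle would be ill-posed.
* **Expression** plants responsive fold changes of magnitude 1.5–3.5 and
  non-responsive ones within ±0.5, on FPKM baselines ≥ 10 with ±3%
  replicate noise, so the strict threshold at 1 is never approached from
  either side; recovery is exact by margin, not by luck.

All randomness flows from one seed through fixed per-section sub-seeds, so
datasets are byte-identical across runs and partially-changed configurations
perturb only the sections they touch.

What passing these suites shows is internal correctness — each stage
recovers what was planted under the stated conditions — not performance on
real genomes, where domain hits are noisy, orthology is reticulate,
similarity strata overlap, and promoter backgrounds contain true motif
instances.

## Problem sizes and numerical choices

The validation suite runs the full pipeline twice (a 4-species smoke panel
and the 10-species study panel, ~420 family genes, ~1,800 Ka/Ks pairs), 100
500-codon Ka/Ks recovery pairs, 50 random 8-taxon NJ additivity matrices,
and 20 seeded anchor sets of 5 planted blocks over 200 noise anchors —
sizes chosen so the whole suite completes in a few minutes on a laptop
while still exercising every code path at the panel scale the analysis
targets. Tolerances: NJ additivity and closed-form Ka/Ks agreement at 1e-9;
planted integer counts exactly; proportions at the printed rounding.
Degenerate inputs have defined behaviour throughout: empty rosters pass
through, all-gap alignment pairs get distance 1 with a warning, orthogroups
whose ratios are all undefined are omitted with a warning, constant
rows/columns z-score to zero, and every precondition violation is a typed
error naming the offending record.

## Known limitations

* NJ replaces ML tree inference; no bootstrap support is computed, and the
  14-cluster partition is taken from the reference panel, not re-derived.
* NG86 is a counting estimator; absolute Ka/Ks values differ from
  likelihood-based estimators on real, multiply-substituted sequences.
* The motif library covers 14 elements, not a full annotation's 86 types.
* RBH + connected components cannot separate in-paralogs within an
  orthogroup, and "variable" is fixed at exactly one missing species.
* The expression module starts from count/FPKM tables; read processing and
  dispersion-aware differential testing are out of scope.
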