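---
title: "Methods: CAZyme cluster enrichment and genome architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAZyme cluster enrichment and genome architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazclust)
```

# The problem

Lignocellulolytic fungi carry large repertoires of carbohydrate-active
enzymes (CAZymes), and in several species those genes cluster: they sit in
enzyme-dense stretches of the genome, often near chromosome ends, and
often directly adjacent to one another. Each of these observations needs a
statistic and a set of operational definitions before it can be reported
for a new assembly. This vignette documents the definitions `cazclust`
uses, the reasoning behind each tunable parameter, and what the validation
on synthetic genomes does and does not establish.

# The enrichment model

## Candidate clusters

Genes on each scaffold are ranked by position into *ordinals*
`0..n-1` (ties on start position broken by end, then gene ID — an
arbitrary but fixed convention; annotations rarely contain exact ties). A
*candidate cluster* is any ordinal interval whose first and last genes
both carry the label of interest (all CAZymes, or the PCWDE subset), with
at least `min_hits = 2` labelled genes — the two distinct bounding genes —
and at most `max_window_genes = 50` genes in total. Every such interval is
enumerated; a dense stretch therefore contributes many overlapping
candidates, which is intentional: the merging step below restores
maximality.

The window cap bounds the otherwise quadratic enumeration. Enzyme-dense
regions reported in fungal genomes contain at most a few tens of genes, so
a 50-gene cap does not truncate biologically plausible clusters; it is a
configurable parameter and is recorded in the pipeline log.

## The test

With `N` genes genome-wide, `K` of them labelled, a window of `n` genes
containing `k` labelled genes is scored with the hypergeometric upper tail

$$P(X \ge k) \;=\; \sum_{j=k}^{\min(n,K)}
\frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}.$$

The background is deliberately *genome-wide*, not per-scaffold: the null
hypothesis is that the genome's single census of labelled genes is spread
uniformly over all gene positions, and a cluster is surprising relative to
that census. Windows are measured in genes rather than base pairs so that
the draws of the hypergeometric model are well defined (each gene is one
draw); a bp-based window would make `n` depend on local gene density and
invalidate the model.

The tail is computed in log space from `lchoose` with a log-sum-exp
reduction. Against exact rational arithmetic the relative error is below
`1e-10` for populations up to `1e4` (the test suite sweeps every
configuration with `N <= 25` exhaustively and cross-checks `stats::phyper`
at genome scale; the implementation itself never calls `phyper`, keeping
the two routes independent).

## Significance and multiple testing

Candidates with `P <= alpha` are retained; the default `alpha = 0.001` is
applied to the *raw* p-value, inclusively. No multiple-testing correction
is applied by default because the screen is descriptive — the output is a
set of regions to inspect, not a family-wise error claim — and because
overlapping candidates are highly dependent, which makes a Bonferroni
correction on their count severely conservative. A Bonferroni option
(`enrichment_params(bonferroni = TRUE)`) is exposed for users who want it.

## Merging into regions

Significant candidates on the same scaffold whose ordinal intervals
overlap or abut (share a gene, or sit on consecutive ordinals) are unioned
transitively into maximal *enzyme-dense regions*. Region bp bounds run
from the first member gene's start to the last member gene's end; the
region records its distinct labelled genes, its member-cluster count and
the minimum member p-value. Merging abutting intervals (not only
overlapping ones) was a design choice: two significant clusters separated
by zero intervening genes describe one dense stretch. An optional
`top_regions` cap selects the regions with smallest minimum p-value when
only the strongest regions should be highlighted.

`summarize_regions()` reports the two headline fractions — total region
length as a percentage of the genome, and labelled genes inside regions as
a percentage of the label census — rounded to one decimal, the customary
printed precision for such figures.

# Telomeres and chromosome calls

Telomeric repeats in this group of fungi are short tandem motifs, default
`5'-TTAGGGG-3'`. `scan_terminus()` searches a terminal window (default
500 bp) for the longest run of head-to-tail motif copies: the forward
motif near the 3' end and its reverse complement near the 5' end, because
the repeat reads outward on both strands. A hit requires `min_copies = 3`;
a single motif occurrence arises by chance roughly once per 16 kb of
random sequence, whereas three exact tandem copies essentially never do,
so three copies inside a 500 bp terminal window is a conservative yet
sensitive call. Both thresholds are configurable because assemblies differ
in how much telomeric sequence survives scaffolding. Matching is exact by
default; a per-copy mismatch allowance exists but is off, because variant
telomeric repeats would otherwise have to be modelled explicitly, and `N`
bases never match under any setting.

A scaffold with arrays at *both* termini is a putative chromosome;
scaffolds without sequence are classified `NA`.

# Sub-telomeric classification

A region is sub-telomeric when its nearest edge lies within a cutoff
(default 200 kb, inclusive) of a scaffold end, i.e. any overlap of the
terminal window counts. Two conventions were open and are resolved as
follows: distance is measured from the region *edge* (an inclusive reading
of "within"), and to the *scaffold end* rather than to the telomere array
itself (the array's inner boundary depends on assembly completeness, while
the scaffold end is always defined). Classification is only applied to
putative chromosomes — on unanchored scaffolds a "distance to the end"
does not estimate distance to a real chromosome end, so such regions
return `FALSE` with an explanatory note.

# Adjacent runs and the paralogy filter

Adjacency is purely positional: a maximal run of consecutive ordinals
whose genes all carry the label, reported once (a triplet is not also two
pairs). Intergenic distance and strand are ignored — gene order is the
property of interest, and imposing a bp or strand rule would add
parameters without a clear biological justification.

Runs of adjacent enzymes can arise from tandem duplication rather than
functional clustering, so each within-run protein pair is aligned with a
global Needleman–Wunsch alignment (match +1, mismatch −1, linear gap −2;
ties in the traceback prefer diagonal, then up, then left, making the
alignment deterministic). A pair is paralogous when identity — matches
over all aligned columns, gaps included — reaches 30% *and* coverage — the
fraction of the shorter protein aligned opposite a residue — reaches 50%.
These are conventional coarse homology heuristics; both thresholds and the
scoring scheme are parameters of `paralogy_params()` so the filter is
fully disclosed and adjustable. A precomputed paralog-group table, when
available from an orthology pipeline, overrides alignment. Random
unrelated proteins align far below 30% identity under this scheme, while
even heavily mutated duplicates stay far above it, so the filter is
insensitive to the exact threshold within a wide band.

# Annotation statistics

`compute_stats()` reports genome-report statistics. Conventions the
annotation format leaves open are resolved as follows:

* introns are the gaps between consecutive exons of one mRNA;
* multi-isoform genes are represented by the mRNA with the largest total
  exon length;
* gene length is the annotated gene span, so UTRs are included when the
  annotation includes them;
* the "genes of at least 60 aa" count uses total exon bp / 3 as the
  protein-length proxy, since the model deliberately carries no CDS
  features;
* GC content is computed over A/C/G/T only, excluding `N` from the
  denominator.

All averages are returned unrounded; `genome_stats_table()` applies the
presentation rounding (lengths to whole bp, introns per gene to two
decimals).

# Comparative normalisation

`percent_of_max()` rescales each category row of a species-by-category
count table so the per-row maximum is 100%; ties at the maximum all map to
100, and all-zero rows stay zero. The operation is idempotent. It is a
display normalisation — it makes profiles comparable across categories
with very different absolute counts, at the cost of hiding absolute scale.

# The synthetic genome simulator

The simulator generates what the analyses consume: a multi-scaffold gene
annotation with exon structure, scaffold DNA, a category table and
per-gene proteins, plus a ground-truth record of every planted feature.
Its defaults describe a realistic ~30 Mb filamentous-fungus assembly:

* nine scaffolds of 1,113 genes each (~10,000 genes);
* gene spans uniform on 500–3,000 bp, intergenic gaps on 100–2,000 bp;
* background CAZyme rate 371/10,013 (the CAZyme share of a typical
  lignocellulolytic fungal gene census), with 114/371 of CAZymes also
  flagged PCWDE;
* telomere arrays (`TTAGGGG` × 8) at both ends of eight of the nine
  scaffolds;
* ~77.6% of genes with at least one intron and a conditional
  `1 + Poisson(1.513)` intron count (overall mean ≈ 1.95), intron lengths
  uniform on 50–190 bp (mean ≈ 120) — the intron geometry of a compact
  fungal genome.

Planted clusters place an exact number of labelled genes inside a chosen
ordinal window with the window's first and last genes labelled; planted
telomere arrays are written verbatim at the termini (reverse complement at
5'); paralog injections copy one gene's protein onto another with a
per-residue mutation rate. Everything is reproducible: a spec with a given
seed yields byte-identical serialised outputs.

What the simulator does *not* emulate — and therefore what passing tests
do not establish about real data: DNA and protein sequences are uniform
random (no codon structure, GC heterogeneity, repeats or low-complexity
regions), gene density is homogeneous outside planted windows, background
labels are independent Bernoulli draws (real CAZyme families cluster for
historical reasons even under the null), and annotations are error-free.
Detection power and calibration measured on simulations are therefore
statements about the method under its own null model, not about any
particular assembly or annotation pipeline.

# Numerical and degenerate-input choices

* The tail statistic returns exactly 1 at `k = 0` and is capped at 1;
  argument-constraint violations are errors, not NA.
* Scaffolds with fewer than two labelled genes yield no candidates; an
  empty candidate set propagates as empty (not missing) tables through
  merging, summarising and BED export.
* BED scores are `-10 log10(min p)` capped at 1000, with p floored at
  1e-300 to avoid infinities.
* Sequences shorter than the telomere window are scanned over their full
  length.
* `sample()`-style size-one pitfalls are avoided by index-based sampling
  in the simulator, so a planted window with exactly one interior
  position behaves correctly.

# Validation problem sizes

The test suite validates each stage at sizes chosen to make the oracles
exact and the run fast: exhaustive hypergeometric enumeration up to
`N = 25`; calibration against 100,000 random label placements of 40
labels among 1,000 genes in a 12-gene window; planted-cluster recovery
(10 labelled of 12 consecutive genes among 1,000, ~40 background labels)
over 100 simulated genomes, requiring recovery in at least 99; a
nine-scaffold telomere simulation; and byte-identity of two pipeline runs
on identical inputs. These sizes exercise every code path while keeping
the full suite to a couple of minutes on one CPU.

# Known limitations

* The hypergeometric null ignores gene-length and density heterogeneity;
  on genomes with strong regional gene-density variation a permutation
  null (`permute_labels()`) is the honest comparison and is provided.
* Overlapping candidates are counted individually before merging, so the
  "significant clusters" count depends on local label density as well as
  on distinct dense stretches; both the candidate-level and region-level
  counts are reported for that reason.
* The paralogy filter is a coarse duplicate detector with a simple linear
  gap model, not a homology search; borderline ancient duplicates below
  30% identity will pass as non-paralogous.
* Telomere detection requires assembled telomeric sequence; scaffolds
  trimmed of terminal repeats are unavoidably classified as
  non-chromosomes.
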