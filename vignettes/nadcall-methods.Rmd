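---
title: "Calling nucleolus-associated domains with nadcall: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling nucleolus-associated domains with nadcall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadcall)
```

## The measurement and the model

Nucleoli can be purified from cells, and the DNA they carry sequenced
alongside a whole-cell (genomic) control library. Chromosomal regions
over-represented in the nucleolar library are nucleolus-associated domains
(NADs); the genes inside them are nucleolus-associated genes (NAGs). The
measurement is therefore a pair of count profiles over a fixed genomic
partition, and the estimand is the set of enriched regions.

`nadcall` works on a bin grid (default 100 kb, the standard NAD-mapping
resolution) tiling an arbitrary assembly supplied as a `chrom.sizes` file.
For bin $i$ and replicate library pair $j$ the enrichment ratio is

$$
r_{ij} \;=\; \frac{(no_{ij} + \alpha)\,/\,No_j}{(n_{ij} + \alpha)\,/\,N_j},
$$

where $no$ and $n$ are nucleolar and genomic bin counts, $No_j$ and $N_j$
the library totals, and $\alpha$ a pseudocount (default 0.5) that keeps
every ratio finite and positive. Replicates are combined by the geometric
mean, i.e. the mean log-ratio: DNA libraries of this kind are commonly
prepared in triplicate, and averaging on the log scale reduces the
standard deviation of the per-bin log-ratio by $\sqrt{k}$ for $k$
replicates without biasing the ratio scale. A single-replicate table is
the $k = 1$ special case, and pre-merged counts are accepted unchanged.

### Background correction

Library-size normalization alone leaves the two-fold rule poorly
calibrated whenever a substantial genome fraction is enriched: the
enriched compartment inflates the nucleolar library total, which deflates
every ratio by the same factor (with a quarter of the genome at 4-fold
enrichment, unenriched bins sit near $1/1.75 \approx 0.57$ rather than 1,
and enriched bins near $2.3$ rather than 4). `compute_enrichment()`
therefore offers `background = "median"`, which divides all combined
ratios by their genome-wide median so the unenriched background is
re-centered at 1. This is valid whenever NADs cover less than half the
genome, an assumption that holds for every reported NAD census we are
aware of. The high-level caller `call_nads()` applies the correction by
default; `compute_enrichment()` alone defaults to the uncorrected
library-size formula so its output is the plain normalized ratio.

### Segmentation

A bin is NAD-positive iff $r_i \ge$ `threshold` (default 2; the
comparison is inclusive, and thresholding the linear ratio at 2 is
identical to thresholding the log2 ratio at 1). Runs of positive bins are
merged into segments whose boundaries coincide with bin boundaries;
`max_gap_bins` (default 0) optionally bridges short sub-threshold gaps.
Both views are retained in the fitted `nad_call` object — per-bin calls
for track-style displays, merged segments as the headline "regions" —
because region counts and dot-per-bin plots answer different questions.
Terminal bins shorter than the bin size are truncated, not dropped, so
genome-fraction arithmetic stays exact.

Summary statistics follow directly: the NAD genome fraction is covered bp
over assembly bp; per-chromosome contributions are reported both as share
of segment count and share of covered bp (each summing to 1); and the
cross-cell-line `shared_nad_fraction(a, b)` is the fraction of `a`'s NAD
base pairs that fall inside `b`'s segments — directional on purpose,
since two lines with very different NAD loads share asymmetrically.

## Coordinates and I/O conventions

All coordinates are 0-based half-open internally. BED is read and written
natively in that convention (round-tripping canonical BED6 exactly); GTF
gene rows are converted on read, with the TSS taken as the first
transcribed base (`start` on `+`, `end - 1` on `-`). Attribute keys
follow the Ensembl dialect but are configurable. Reads are assigned to
bins by their midpoint — an unambiguous single assignment that conserves
totals; a midpoint exactly on a bin boundary belongs to the downstream
bin. Bins are genome-wide fixed windows; no assembly-gap exclusion is
applied (on real assemblies, excluded regions can simply be filtered from
the bin-count table upstream, and on synthetic assemblies there are no
gaps to exclude).

## Gene annotation and activity integration

A gene is a NAG iff its body overlaps a NAD segment by at least
`min_overlap` bp (default 1). The paperless question of whether promoters
or bodies define membership is resolved in favour of the gene body, the
default of interval-annotation tools, with `min_overlap` exposed.

Transcriptional activity of NAGs is classified at the promoter, defined
as TSS $-2000$ / $+500$ bp by default. No single promoter convention is
universal, so the window is a first-class parameter applied uniformly to
all three assays: a gene is flagged for ATAC, H3K4me3 or RNA Pol II when
at least one peak of that assay overlaps its promoter window, "double"
genes carry both H3K4me3 and Pol II, and "active" is the three-way
conjunction (ATAC-accessible promoter, H3K4me3, Pol II). Flag-by-window
rather than flag-by-assigned-peak keeps the classification well defined
even where promoter windows of distinct genes overlap. A missing assay
is excluded from the conjunction and reported, never silently treated as
negative. Peak-level annotation (`annotate_peaks()`) uses the priority
promoter > gene body > intergenic, resolving multi-gene hits to the
nearest TSS with lexicographic gene-id tie-break.

Cross-sample peak structure uses Merged Regions: connected components of
the pairwise-overlap graph, each spanning from its most upstream member
start to its most downstream member end, with per-sample presence flags.
Overlap is strict under half-open coordinates, so touching peaks are not
merged. TSS metaprofiles average binary peak occupancy per bp in a
$\pm$ 2 kb frame, orientation-flipped for minus-strand genes, then binned.

## Nucleolar RNA enrichment

Expression tables are normalized to counts per million per sample. A gene
is nucleolar-enriched iff

$$
\frac{\overline{\mathrm{CPM}}_{nucleolar} + \alpha}
     {\overline{\mathrm{CPM}}_{total} + \alpha} \;\ge\; 2
$$

(inclusive, $\alpha = 0.5$ CPM). The published decision rule for this
class of data is the plain two-fold enrichment, so that rule is
implemented directly; a negative-binomial differential model would add an
inferential layer the rule itself does not use. NAGs are then partitioned
exhaustively into `nucleolar` (enriched), `nuclear_only` (not enriched
but nuclear abundance $\ge$ `min_expr`, default 1 CPM — a detection
threshold the data themselves do not pin down), and `silent`. Repeat
association reports, per repeat class (SINE, LINE, other), the fraction
of genes overlapping at least one element, counting each gene once per
class.

## The synthetic study

Raw nucleolar sequencing data for this kind of study is rarely available
at desk scale, so the generator is a first-class module: it defines the
conditions under which every claim about the pipeline is tested.

* **Genome and genes.** 3 chromosomes $\times$ 20 Mb, 100-kb bins (600
  bins), 1000 genes of 5–20 kb placed uniformly without overlap and with
  a minimum 4 kb inter-gene gap — twice the promoter upstream extent, so
  promoter windows are provably disjoint and a planted promoter peak
  identifies exactly one gene. Biotypes are protein-coding with
  probability 0.87, matching the composition reported for NAG censuses.
* **Planted NADs.** A quarter of the bins, allocated across chromosomes
  by weights (default 1:1:3, emulating the strong concentration of NADs
  on one small chromosome that real censuses show), arranged in runs of
  mean 6 bins — about 600 kb, the order of magnitude implied by
  thousands of regions covering tens of percent of a genome.
* **Counts.** Negative-binomial per bin and replicate: genomic mean =
  depth (100), nucleolar mean = depth $\times$ 4 inside NADs and
  $\times$ 1 outside, dispersion (size) 10, three replicate pairs.
  Negative-binomial rather than Poisson because sequencing libraries are
  overdispersed; Poisson is recovered as the large-size limit.
* **Peaks.** Each planted-active gene (13% of NAGs) receives one
  promoter peak per assay with probability $1 - fnr$ ($fnr = 0.05$);
  every other gene with probability $fpr = 0.02$; positions jittered
  within the window.
* **Expression.** Expressed genes (active NAGs plus half the non-NAG
  genes) draw log-normal(meanlog 4, sdlog 1) baselines; nucleolar
  abundance is baseline $\times 4$ for retained transcripts (10% of
  active NAGs, plus 5% of expressed non-NAGs — the nucleolar RNA pool is
  largely of non-NAD origin) and $\times 0.25$ for exported ones, with
  Poisson count noise that can be switched off for exact-identity
  checks.

Ground truth (planted segments, NAG/active/retained id sets, full
config) is serialized alongside the generated files, so tests compare
against stored truth rather than re-deriving it from generator
internals. Identical configs produce byte-identical output.

What the generator does **not** emulate: GC and mappability bias,
assembly gaps, copy-number structure, fragment-level read placement,
splice structure, and correlated noise between libraries. Passing the
recovery suites therefore demonstrates that the estimator inverts its own
generative model at realistic noise levels — not that it is robust to
artifacts of real sequencing, which upstream QC must handle.

## Numerical choices and degenerate inputs

* Pseudocounts: 0.5 throughout (counts and CPM), configurable; zero is
  allowed and reproduces plain ratios with possible infinities.
* Empty inputs error loudly and early: empty libraries (total 0),
  empty NAG sets, all-zero expression samples, zero-segment results
  where a contribution or shared fraction would be undefined.
* Ties in peak-to-gene assignment break by nearest TSS, then smallest
  gene id — deterministic across platforms.
* Determinism: every stochastic stage derives its stream from the
  config seed with fixed small offsets; reruns are byte-identical.
* Reported percentages round half-up to whole percent
  (`report_percent()`), the convention that reproduces the published
  worked examples exactly.

## Problem sizes used by the test suite

The default synthetic study (600 bins, 1000 genes, triplicate libraries)
runs the full pipeline in a few seconds. Oracle-equivalence suites
compare against brute-force enumeration (quadratic overlap, union-find
components, power-set membership, per-bp masks) on 100 random instances
of a few dozen intervals each — sizes chosen so the quadratic oracles
themselves stay fast while still exercising every boundary case.

## Known limitations

Per-bin thresholding with run merging is deliberately simple; an HMM or
changepoint segmentation could trade calibration transparency for power
at low depth. The two-fold rule is applied to a point estimate of the
ratio, without a per-bin significance statement. The activity
classification binarizes peaks and ignores peak strength. All Table-2
style counts depend on the promoter-window convention, which is why the
window is exposed as a single configuration key rather than buried in
the implementation.
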