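---
title: "Curating single-cell count corpora: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating single-cell count corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccorpus)
```

This vignette is the package's account of the science behind each stage:
what is computed, under which assumptions, which constants matter, and
where the design was genuinely open.

## The quality-control cascade

Curation starts from raw integer counts, cells × genes, with per-cell
sample and organ labels. A gene is *detected* in a cell when its count is
strictly positive — the only reading consistent with the zero-rate
statistics used later. The cascade runs in a fixed order, each stage seeing
the survivors of the previous one:

1. cells with fewer than `min_genes_per_cell = 200` detected genes;
2. samples with fewer than `min_cells_per_sample = 3` surviving cells —
   the per-sample census is taken *after* stage 1, so low-quality cells
   cannot keep a sample alive;
3. cells expressing fewer than `min_coding_genes_per_cell = 7` genes of
   biotype protein-coding or miRNA (pooled); genes missing from the
   annotation count as biotype `other`;
4. cells whose mitochondrial share of total counts *exceeds*
   `max_mito_fraction = 0.15`; cells with zero total counts are removed
   here too;
5. cells whose detected-gene count exceeds mean + `outlier_sd_multiplier
   = 3` standard deviations of *their own sample's* cells (upper tail
   only; samples with fewer than two cells skip the stage);
6. optional restriction of the gene axis to a user-supplied core gene
   list (matrix order preserved); with no list supplied, all genes are
   kept — there is no universal definition of a "core" gene set, so it is
   an input;
7. optional removal of annotated cell types with fewer than
   `min_cells_per_annotated_type = 20` cells, when type labels are given.

All threshold comparisons follow the rules' wording literally: "fewer
than", "less than" and "exceeding" are strict, so retention is `>=` for
counts and `<=` for fractions and the outlier bound. A cell detecting
exactly 200 genes, a sample of exactly 3 cells, a cell at exactly 15%
mitochondrial counts are all retained. The per-sample cell floor is 3, not
4: the two figures circulate and the procedural description is taken as
authoritative; the threshold is configurable regardless. The 200-gene rule
is applied per cell, not per sample.

Attrition is reported per stage (`before`, `removed`, `after`), the chain
is internally consistent, and the cascade is idempotent: running it on its
own output removes nothing.

## Sex inference from X/Y expression ratios

Biologically, males carry Y-linked transcription (most specifically the
testis-determining gene *SRY*/*Sry*) and a different balance of X-linked
expression, because several chrX genes have chrY homologs that mask true
X-dosage. Two per-sample statistics capture this, computed on pseudo-bulk
FPKM (sum counts per sample, then FPKM):

* **Y-Ratio** = FPKM of the Y marker / summed FPKM of all chrY genes,
* **X-Ratio** = summed FPKM of chrX-unique genes (chrX genes without a
  chrY homolog — which genes qualify is annotation input, since it depends
  on the genome build) / summed FPKM of all chrX genes.

When a denominator is zero the ratio is defined as 0, so an all-female
corpus (no chrY signal at all) classifies female rather than erroring.

Classification applies a species preset of calibrated constants
(`sex_thresholds("human")`, `sex_thresholds("mouse")`) with a fixed branch
precedence that turns the published rule list into a total function of
(X-Ratio, Y-Ratio): male first, then mixed before female for human
(female before mixed for mouse), then unknown. "Between a and b" is read
as the open interval; endpoints belong to the `>=`/`<=` branches that cite
them, so e.g. a mouse sample at Y-Ratio exactly 0.000065 is male. Every
pair of ratios receives exactly one of the four labels, and the calls are
monotone in the expected direction (raising Y-Ratio at fixed X-Ratio never
turns a male call female). `NaN` ratios yield `unknown` with a warning.

The presets are overridable, and `calibrate_sex_thresholds()` refits the
dominant male Y cut by a one-dimensional grid search over midpoints of
observed Y-Ratios, maximizing accuracy on samples of known sex — intended
for gonadal (testis/ovary) samples where sex is unambiguous. The original
calibration loop is not specified beyond "initial thresholds, then
refinement", so a transparent exhaustive search was chosen over anything
cleverer.

## Stable-expression genes

Two complementary stability notions are combined:

* **zero-rate** — the fraction of cells with a zero count, computed on the
  post-QC corpus; a gene expressed everywhere has zero-rate near 0;
* **CV** — standard deviation over mean of pseudo-bulk FPKM across
  samples, using the sample SD (n − 1). Genes with zero mean get an
  infinite CV and rank last.

Genes are ranked ascending on each statistic and the two ranks are summed;
the final stability order is ascending in that sum. How the two rankings
are merged is not pinned down anywhere, so the package uses the sum of
ranks: symmetric in the two statistics, scale-free and deterministic. All
ties — in the statistics, and in the combined score — break
lexicographically by gene symbol, making the order a reproducible total
order that is invariant to input gene order. Improving both of a gene's
statistics can never worsen its combined rank.

The SEG set is the top of this order, sized by the housekeeping reference
list after dropping reference genes absent from the matrix (with a
warning). `hkg_overlap()` reports |SEG ∩ HKG| / |HKG|.

FPKM itself is the standard definition `1e9 * c / (L * C)` with `L` the
user-supplied exonic length in bp and `C` the group's total counts; it is
invariant to uniform count scaling within a group and inversely
proportional to gene length. Pseudo-bulk groups for the CV are per-sample:
the natural unit of biological replication here, and the same grouping the
sex ratios use.

## Organ-specific genes

A gene counts as *expressed* in an organ when its zero-rate there is at
most 0.90 (the boundary counts as expressed: "no more than 90%"). OSGs are
genes expressed in at least one and at most two organs — at least one,
because a gene expressed nowhere is vacuously "specific" to nothing; at
most two including the focal organ, the stricter and simpler reading. The
same zero-rate criterion defines "expressed" in both halves of the rule;
no second definition exists to borrow. Organs with fewer than
`min_cells_per_organ = 50` cells are excluded before calling (a floor
added to avoid degenerate zero-rates from tiny organs; configurable).
Raising the expression threshold can only grow a gene's expressed-organ
set.

For downstream network analyses, `pool_pseudocells()` sums random
(seeded) pools of 100 cells within a cluster. A remainder pool is kept iff
it reaches half the pool size — a compromise between discarding depth and
emitting under-powered pseudo-cells; the choice is exposed and the rule is
documented because nothing prescribes it.

## Evaluating gene sets by clustering

`evaluate_gene_sets()` asks how much cell-type structure a gene set
retains: per seeded repeat, subsample cells, library-size normalize
(counts per 10,000 over *all* genes, so normalization does not depend on
the set under test), log1p, restrict to the set, run k-means, and score
the found partition with the Calinski–Harabasz index

CH = [B/(k−1)] / [W/(n−k)]

and the mean silhouette (b − a)/max(a, b). k-means is Lloyd's algorithm
with the best of `n_init = 10` seeded random starts (`stats::kmeans`);
silhouette uses `cluster::silhouette`; CH is computed directly from its
definition. Both indices are checked against independent brute-force
implementations in the test suite.

Two numerical facts shape how these scores must be read. First, both
indices have a strong dimensionality-dependent null level: on pure iid
noise, k-means overfits small gene sets much more than large ones (at 20
dimensions and a few hundred cells the null CH is an order of magnitude
above 1). Comparisons are therefore most meaningful between sets of
similar size, which is why the canonical three-way comparison uses a
reference list sized like the SEG set. Second, selecting genes *by
variance* enriches for cluster signal — a top-variable set generally
clusters *better* than all genes (that is why highly-variable-gene
selection is standard practice), so the instructive middle point between
"all genes" and "stability-selected genes" is a housekeeping-style
reference list, whose members are mostly stable with a modestly variable
minority. `top_variable_genes()` is provided for when a variance-selected
set is wanted explicitly.

Classification metrics follow the usual definitions: accuracy
(TP+TN)/(TP+TN+FP+FN), recall TP/(TP+FN), precision TP/(TP+FP); a metric
whose denominator is zero is reported as absent (`NA`), never propagated
as `NaN`.

## AI-ready encoding

Rank-based transcriptome models consume per-cell gene sequences ordered by
relative expression. `compute_gene_medians()` takes, per gene, the median
of its strictly *non-zero* counts (including zeros would collapse most
medians to 0 and break division); genes never expressed are absent from
the table. `rank_encode()` divides a cell's counts by these medians and
orders expressed genes descending, ties broken ascending by symbol — a
deterministic encoding that is invariant to scaling a cell's counts.
`export_corpus()` writes either one JSON line per cell plus a vocabulary
(ids by descending cell-frequency, then symbol) for rank-sequence models,
or a counts-matrix directory with a medians sidecar for matrix models.
Both exports are byte-deterministic.

## Serialization

The on-disk corpus format is a plain-text directory: a Matrix Market
triplet in the 10x orientation with barcodes and features files, a
`cells.tsv` carrying sample/organ labels, and a small JSON for the species
tag. Text serialization was chosen deliberately: it diffs cleanly, needs
no binary toolchain, and the write/read round trip is exact on counts, ids
and labels. The MTX reader auto-detects orientation from the barcode and
feature counts, maps barcodes to samples via an explicit two-column map
(which wins) or the `-<sample>` suffix convention, and rejects duplicate
barcodes or symbols, negative entries, and non-integer counts.

## What the synthetic corpus emulates

`sim_config()` defaults describe the reference corpus used throughout the
tests: 8 samples of 250 cells across 4 organs (both sexes in every organ),
plus one under-sized 2-cell sample — 2002 cells × 1000 genes, 4 cell
types. Counts are negative binomial per (cell type, gene) with a constant
Bernoulli dropout on top. Most zeros come from the negative binomial
itself, so — as in real data — a gene's detection probability tracks its
per-type mean and the zero pattern carries cell-type information; raising
`dropout_rate` reaches the regime where most genes are zero in well over
80% of cells. Planted structure:

* 20 stable genes: high mean (30), tight dispersion, no dropout, no
  type/organ modulation — mimicking high-expression housekeeping genes,
  which in real data have essentially no dropout;
* 5 near-stable genes: identical but with mild (sdlog 0.25) type
  modulation; together with 15 stable genes they form the housekeeping
  reference list, mirroring the fact that real HKG lists contain modestly
  tissue-variable members;
* 5 organ-specific genes per organ: moderate expression in their organ,
  exactly zero elsewhere;
* 10 marker genes per cell type (strongly enriched in their type) and
  log-normal per-type modulation (sdlog 1.0) of every background gene —
  distinct major cell types differ across much of the transcriptome, and
  this is what lets the all-genes view cluster best;
* chrY genes (including *SRY*) at baseline mean in male samples and zero
  in female ones; 15 of 20 chrX genes flagged chrX-unique;
* mitochondrial counts allocated per cell from a Beta distribution around
  5%, clipped safely below the QC threshold;
* exactly one violator roster per QC rule (5 low-complexity cells, 5
  low-coding cells, 5 high-mito cells, 5 detected-count outliers, one
  2-cell sample), each violator built to fail *only* its own rule, and
  ordinary cells' detected counts clipped into a 2-SD band so the planted
  outliers are the only 3-SD exceedances.

Everything derives from a single integer seed, bit-for-bit.

The generator deliberately omits batch effects, ambient RNA, doublets and
library-size gradients between samples. Passing tests on this corpus
therefore demonstrate that the decision rules, rankings and encodings are
implemented correctly and recover planted structure with wide margins —
not that the pipeline is robust to every artifact of real data.

## Problem sizes and runtime choices

The test and evaluation workloads are sized for interactive use: the
2002 × 1000 reference corpus, clustering evaluations on subsamples of 400
cells with 20 repeats, and oracle comparisons on 200 random instances of
at most 50 points. The decision-boundary probes bisect the classifier to
machine precision and verify one-sidedness on a 2001-point grid.

## Known limitations

* Sex inference is per-sample; mixed-sex pools are flagged `mixed` but
  not deconvolved per cell.
* The SEG statistic ranks; it does not test. No uncertainty accompanies
  the combined rank, so SEG set boundaries should be read as ordinal.
* FPKM requires trustworthy exonic lengths; with UMI data a length-free
  unit would be more natural, but FPKM is kept as the pipeline's pseudobulk
  currency.
* The clustering evaluation inherits k-means' spherical-cluster bias and
  the dimensionality caveats above.
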