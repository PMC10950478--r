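---
title: "Methods and design of apaviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of apaviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `apaviz`, in the spirit of a methods section: what each quantity
means, where the defaults come from, and what the built-in simulator does
and does not emulate.

## Data model

A `PACDataset` couples a sites × observations count matrix with a site
table (chromosome, strand, 1-based cleavage coordinate, and — after
annotation — gene and region) and an observation table (group label).
A poly(A) site is a single strand-aware base: upstream callers report the
cleavage position as a point, and GTF coordinates are 1-based, so no
half-open conversion is needed internally; BED-style inputs would be
converted at the boundary. Counts are stored sparse (`dgCMatrix`) but the
API is value-level; no operation depends on the storage format.
Observations without a group label are rejected at read time rather than
dropped, because every downstream operation (pseudo-bulk aggregation,
marker testing, per-group tracks) is group-aware and silent dropping would
change results invisibly.

On-disk layout is MatrixMarket (`counts.mtx`) or dense TSV plus
`sites.tsv`/`obs.tsv` sidecars, tab-separated with a header, no quoting.
The round trip is exact (bit-identical TSVs under a fixed seed), which is
what makes the CLI pipeline's byte-determinism checkable.

## Region assignment

`load_annotation()` parses GTF/GFF via `rtracklayer` and merges features
per gene across transcripts: poly(A) sites are gene-level points, so a
transcript-resolved model would add ambiguity without adding information.
Introns are the within-gene gaps between merged exons. When a file has no
explicit `three_prime_utr` records, the 3'UTR is derived per transcript as
the exonic region strand-downstream of the CDS 3' end, then unioned.

`annotate_sites()` assigns each site one gene and one region with the
priority **UTR3 > ext_UTR3 > exon > intron > intergenic**, strand-matched.
The extended 3'UTR (`ext3utr`, default 1000 bp) is the window downstream
of the gene's 3' end minus any same-strand gene span; it captures distal
cleavage sites beyond the annotated end, which are common in 3' tag data.
The 1000 bp default is conventional practice for unannotated distal
sites; it is configurable and recorded nowhere else, so reproducing a
different convention only requires passing a different value. Ties between
same-strand overlapping genes are broken by region priority, then by
distance to the gene's 3' end (a cleavage site is more plausibly assigned
to the gene whose 3' end it is near), then lexicographically — the last
step only to make output deterministic. The implementation uses
`GenomicRanges` interval machinery; the test suite holds it to exact
agreement with a brute-force all-pairs oracle written in plain arithmetic,
on random instances up to 1000 sites × 100 genes.

## The RUD index

For each gene with ≥ 2 usable sites (regions `UTR3`/`ext_UTR3`),

RUD(g, o) = count(distal site) / count(all usable sites of g in o),

with the distal site the usable site farthest 3' in strand-aware order.
Two choices here were genuinely open:

* **More than two sites.** RUD is distal-over-all rather than
  distal-over-proximal-only. This keeps RUD in [0, 1] for any site count
  and reduces exactly to the standard two-site definition; for two-site
  genes, proximal usage is 1 − RUD identically.
* **Count floor.** A per-gene, per-observation total below `min_counts`
  (default 5) yields a missing value rather than a noisy ratio; at
  single-cell depth a ratio of 1/2 reads is not a usage estimate. Missing
  stays missing — no smoothing or imputation across cells, because any
  such step belongs upstream of, not inside, a usage index.

`mean_rud_per_obs()` averages each observation's defined gene values; it
is the per-cell summary used as the embedding overlay.

## Marker detection

Markers between groups X and Y are tested per gene on per-cell RUD values
with a two-sided Wilcoxon rank-sum test. Rank-sum is the standard
distribution-free choice for per-cell single-cell statistics and is
checkable against an enumeration oracle. Small samples (≤ 10 per group)
are handled by full enumeration over rank assignments using midranks, so
tied values are exact too; tie-free samples up to 25 per group use the
exact null distribution; larger samples use the normal approximation with
tie and continuity correction. A fully degenerate gene (identical value in
every cell) gets p = 1. Cells with missing RUD are excluded from that
gene's test; genes need `min_cells` (default 10) defined values per group.

P-values are Benjamini–Hochberg adjusted **within one pairwise
comparison**, so each pair's marker count stands on its own; markers are
rows with `q ≤ alpha` (default 0.05) and `|ΔRUD| ≥ min_delta` (default
0.1, screening out significant-but-tiny shifts at large n). Direction is
the sign of ΔRUD = mean RUD(X) − mean RUD(Y). `count_markers_pairwise()`
reports each unordered pair once with X the earlier group in the group
order, so a progressive loss of distal usage along an ordered time course
appears as an excess of positive markers for early-vs-late pairs.

## Embeddings

`compute_embedding()` runs UMAP (via `uwot`) on either source:

* `site_expression`: counts per observation scaled to 10,000, `log1p`,
  then at most 50 principal components before the neighbor graph —
  standard single-cell practice that stabilizes neighbor search;
* `rud_usage`: the RUD matrix with missing values imputed by the per-gene
  median *for the embedding only*; the `RUDMatrix` is never modified.

Defaults `n_neighbors = 15`, `min_dist = 0.1`, `seed = 42` are recorded in
the result. Runs are single-threaded with a fixed seed so coordinates are
exactly reproducible. Observations with identical profiles are embedded
once and share coordinates: stochastic gradient descent otherwise gives
duplicates slightly different positions, which is visual noise with no
information content, and collapsing them makes duplicate handling an exact
contract rather than an accident of optimization.

On simulated data the group structure lives in usage, not expression
(groups have equal depth and equal gene-level expression by construction),
so the usage-source embedding is the one that cleanly separates planted
groups; this is a property of the generator, and on real data either
source may be the informative one — which is why both are exposed.

## Figures

All figure builders are pure functions of their inputs. `viz_tracks()`
first assembles a `TrackFigure` specification — region, per-track data,
shared x-limits — and only rasterizes on demand; tests assert on the
specification (track count and order, mark coordinates, axis limits), not
on pixels, which keeps them robust to theme changes. Coverage tracks are
computed from sorted/indexed BAMs, counting aligned (match or deletion)
bases; the default is unstranded (`strand_mode = "both"`) with a
same-as-gene filter available. The cells track orders cells by group and
then by total regional count, descending, for a reproducible and readable
heatmap. The bubble chart is the dot chart with the size and color
encodings swapped. Output is PNG or PDF by file extension.

## The simulator

`simulate_pac()` emulates a multi-group single-cell 3' tag experiment:
`n_genes` two-site genes on a toy chromosome (2 kb genes every 3 kb,
alternating strands, both sites in an explicit 3'UTR), per-cell gene
totals drawn negative binomial with mean `depth_mean` and dispersion
`dispersion` (variance μ + μ²/dispersion, the standard single-cell
overdispersion model), and the distal count binomial given the gene's true
RUD in that cell's group. A fraction `frac_shifted` of genes shifts its
true RUD linearly across the group order by a total `delta_rud`, downward
by default — the 3'UTR-shortening pattern of a differentiation time
course. All randomness flows from one seed and the caller's RNG state is
restored afterwards.

Two presets fix the study conditions used throughout the tests: **strong**
(3 groups × 100 cells, 200 genes, 30% shifted, total ΔRUD 0.4, depth 10,
dispersion 2) for recovery and embedding checks, and **null** (50
cells/group, no shift) for false-positive control. The dispersion value 2
gives variance ≈ 60 at depth 10, a realistic overdispersion for UMI-level
single-cell counts.

`simulate_gtf()` writes the matching annotation, so annotating simulated
data labels every site `UTR3` with its generating gene — a by-construction
check of the whole input path. `simulate_alignments()` places, per
aggregated group count, that many reads with strand-aware 3' ends exactly
on the site coordinate — the stacked-read geometry of 3' tag protocols —
as sorted, indexed BAM, feeding the coverage track.

What the simulator does **not** emulate: more than two sites per gene
(multi-site RUD is tested with hand-built fixtures instead), ambient
RNA/doublets, gene-level expression differences between groups, batch
effects, or non-UTR site categories (intronic/intergenic sites appear in
tests via hand-built fixtures and random annotation instances, not via the
generator). Passing recovery checks on this generator therefore
demonstrates correctness of the computational pipeline under its stated
model, not robustness to every artifact of real single-cell data.

## Verification workflow and problem sizes

The test suite and `scripts/acceptance.R` hold the implementation to
independent oracles: brute-force all-pairs interval logic for annotation
(20 random instances, ≤ 1000 sites × ≤ 100 genes), direct summation for
RUD, exhaustive rank enumeration for small-sample p-values, per-read CIGAR
accumulation for coverage (20 random read sets with matches, deletions,
skips, clips and insertions), 100 null replicates of the null preset for
false-positive control, the strong preset for recovery (planted-marker
recovery at q ≤ 0.05, min_delta 0.1; nearest-centroid group recovery on
the usage embedding; monotone mean-RUD gradient), and a twice-run CLI
pipeline for byte determinism. These sizes were chosen as the smallest
instances that exercise every code path with stable statistics.

## Known limitations

* Annotation adapters are file-based GTF/GFF only; no online retrieval.
* Marker detection tests usage (RUD) only, with a rank-sum test; count
  level GLMs and site-expression markers are out of scope.
* No alternative usage indices (e.g. length-weighted scores) and no
  alternative manifold methods.
* Coverage input is BAM only (no BigWig).
* The extended-3'UTR length and the region priority order are this
  package's conventions; other APA toolchains may differ, and both are
  explicit parameters or documented constants here.
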