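---
title: "Methods: cross-species occupancy conservation and chromatin-based expression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species occupancy conservation and chromatin-based expression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopeaks)
```

# The analysis in one paragraph

orthopeaks compares transcription-factor (TF) occupancy and promoter
chromatin between two species linked by a whole-genome chain alignment.
Peak summits from species A are mapped onto species B with liftOver-style
semantics, each site is classified as conserved, lost, compensatory,
gained or strongly gained, combinatorial co-occupancy regions
(cis-regulatory modules, CRMs) are tracked across the alignment, category
membership is related to chromatin states by permutation and base-fraction
enrichment, and gene expression is modeled from promoter epigenomic marks
with an L1-penalized (lasso) consensus regression whose coefficients also
predict between-species expression differences. A synthetic paired-genome
generator with planted ground truth exercises every stage.

# Coordinate and mapping model

All intervals are 0-based, half-open (BED convention). Chain alignments
keep their UCSC layout: ordered blocks `(size, dt, dq)` with query
coordinates of `-`-strand chains stored in the reverse-complement frame
and converted to forward-strand coordinates only when a mapped interval
is emitted — one conversion point, pinned down by per-base oracle tests.

`lift_interval()` selects the chain with the most aligned bases
overlapping the interval (ties: higher chain score, then lower id). The
interval maps when at least `min_match` (default 0.10, the liftOver
setting used throughout) of its bases fall in aligned blocks; a second
chain independently covering `min_match` triggers `unmapped_split`,
implementing one-to-one matching. The mapped interval is the bounding
span of the images of the first and last aligned bases — internal gaps
are spanned, not excised, matching liftOver's behavior on simple
regions. Peak-level mapping uses the narrow window `summit ± 50 bp`
(`lift_summit_window()`), which avoids spurious rejections from
low-similarity peak edges.

# Conservation categories

For each source peak the lifted summit window is intersected with
destination peaks; ≥ 1 shared base counts as overlap (the window width
makes the rule robust; nothing in the classification depends on deeper
overlap). Unmapped peaks are excluded from every denominator, so
`rate_conserved = n_conserved / n_mapped`. Lost peaks whose window,
expanded by `comp_window = 5000` bp on each side, regains an overlap are
counted as "lost with a compensatory site"; the compensatory *fraction*
is therefore a fraction of lost source peaks, while the destination peak
that explains it carries an `is_compensatory` flag for the category
analyses. A destination peak that is already conserved never doubles as
compensatory (priority conserved > compensatory). Destination peaks that
are neither are gained, and the top `strong_fraction = 0.10` of gained
peaks by read score — per TF, since occupancy strength scales differ
between factors; a pooled variant is available — are relabeled strongly
gained, with score ties broken by genomic order for determinism.

# Co-occupancy regions

`build_regions()` single-linkage clusters the summits of all panel TFs
at `radius = 1000` bp; on a line this is simply "break where consecutive
summits are farther apart than the radius", and it equals the transitive
closure of the pairwise relation (tested). A panel of k TFs yields up to
2^k − 1 combinatorial groups. For transfer, a region is represented by
its full span when narrower than 500 bp and otherwise by the ± 50 bp
window around its median summit, keeping the mapping behavior close to
the single-peak convention; the assignment to a destination region uses
largest overlap, then nearest median summit. Proportions are computed
over mapped regions only and rows of the transfer matrix are
row-stochastic by construction. Conserved CRMs are the source regions
carrying the full panel whose image lands in a full-panel destination
region. Regions are assigned to the gene with the nearest TSS within
50 kb (a conventional enhancer-proximity cap; configurable), ties broken
lexicographically.

# Enrichment statistics

`permutation_enrichment()` re-places the query segments uniformly at
random inside the workspace, preserving segment lengths, forbidding
overlap among placed segments, and requiring each placement to sit
wholly inside one workspace interval. The statistic is shared bases with
the reference; p-values use the add-one rule
`(1 + #{perm ≥ obs}) / (1 + n_perm)` and can never be zero. The default
`n_perm` is 100,000; the pipeline's bundled configuration uses 2,000,
which already gives a p-value floor of 5 × 10⁻⁴ — ample for the fold
estimates the summary reports. Richer conditioning (GC/isochore matching
as in dedicated genomic association testers) is intentionally out of
scope; the uniform-within-workspace null is exactly the null the
calibration tests verify.

`state_overlap_enrichment()` is deterministic arithmetic: per state,
(fraction of query bases in the state) / (fraction of workspace bases in
the state). Query bases outside the segmentation are tallied to an
"unassigned" state with a warning rather than silently dropped. The
workspace-weighted mean of the folds is 1 whenever the query lies inside
the workspace — a useful internal check. Gene-level association uses a
2×2 odds ratio (gene body ± 10 kb proximity window) with the
Haldane–Anscombe 0.5 correction when a cell is empty, plus Fisher's
exact p; distribution comparisons use the two-sided Mann–Whitney test.

# Signal quantification

Tags are extended to `fragment_length = 200` bp from their 5' end and
piled into `bin = 25` bp bins (mean per-base coverage per bin; oracle
tests run at bin = 1, and promoter means interpolate linearly inside
bins so the two agree up to one bin of edge effect). Treatment and input
are each scaled to reads-per-million before subtraction and the
difference is floored at 0 — negative input-subtracted signal has no
physical reading and flooring keeps the subsequent `log2(1 + x)` defined
while preserving zeros. Promoter windows are TSS ± 2 kb, strand-aware;
the ± 2 kb choice mirrors the metagene flank convention since "proximal
promoter" has no universal definition, and it is configurable. Metagene
profiles keep flanks at native bin resolution and resample the gene body
to 100 slices. Promoter activity classes threshold H3K4me3 at 1 and
H3K27me3 at 0.5 input-subtracted RPM (pre-log scale).

# Expression models

Promoter matrices of the two species are quantile normalized per mark
(mean-of-order-statistics; ties share their block mean). Exact
idempotence of quantile normalization holds on tie-free columns; with
ties the block-averaging that makes tied values consistent can shift
values slightly on re-application, which is why the idempotence property
is stated (and tested) on continuous data.

The lasso is fit by coordinate descent (glmnet) on internally
standardized predictors over a log-spaced penalty grid reaching three
decades below the all-zero solution. Cross-validation uses 10 folds,
stratified by response decile under a caller-supplied seed; the penalty
is the largest lambda within one standard error of the CV minimum (the
sparser side), and the reported R² is the in-sample coefficient of
determination of the full-data refit at that penalty, with the
cross-validated R² reported alongside. Ten folds is the default because
the one-SE selection is insensitive to using many more folds at these
sample sizes; `n_folds` is exposed for users who prefer leave-few-out
schedules. The consensus model stacks both species' rows after
normalization and reports per-species R² from the single coefficient
vector. The difference model applies those coefficients to the per-gene
mark difference with no intercept — identical marks predict identical
expression by construction — and is scored against the observed
log-expression difference, optionally restricted to species-specific
genes (the top and bottom 10% by signed `log2((FPKM_a+1)/(FPKM_b+1))`
at the reference stage). Genes near peaks of several conservation
classes take the highest-priority class, conserved > strongly_gained >
compensatory > gained > lost, mirroring the activity ordering those
classes show; the order is configurable.

# The synthetic study

The generator emulates the statistical structure the analyses assume,
not sequence. Two species are linked by per-chromosome chains of ~100 kb
aligned blocks separated by target gaps realizing a 10% unmappable
fraction and small query insertions. The default genome is 2 chromosomes
of 200 Mb: with 2,000 source peaks and ~1,300 destination peaks per TF
this gives about one destination peak per 300 kb, the order of magnitude
of real ChIP-seq peak sets. Density matters: on a toy-sized genome the
± 5 kb compensatory search windows would contain an unrelated peak tens
of percent of the time, and the planted compensatory rate would be
unrecoverable — the ~3% collision background at the default density is
visible as a small upward bias in the recovered compensatory fraction,
exactly as it would be in real data.

Planted conditions: conservation rates 0.25 for the three
master-regulator-like TFs and 0.60 for the KLF1-like TF; 25% of lost
sites receive a compensatory partner placed 0.5–4.5 kb away; 500 pure
gain peaks per TF with heavy-tailed (log-normal) scores so the top-decile
rule is exercised; per-peak conservation probability rises with score
rank (mean preserved, and the `p(1-p)` scaling keeps degenerate rates
exact) so that restricting to stronger peaks raises the conserved rate,
as the top-25% sensitivity analysis expects. The co-occupancy sub-study
plants 400 triple, 800-per-pair and 1,600-per-single regions with
full-set retention 0.35 / 0.15 / 0.05. Promoter marks follow
`y = Xβ + ε` with ten marks, five nonzero coefficients
(3, 2, −1.5, 1, 0.5) and noise set so each species' true variance
explained is 0.60; between-species mark divergence is per-gene Gaussian
with SD 0.83 for a planted 20% "species-specific" subset and 0.44
elsewhere, magnitudes chosen so the difference model's closed-form
R² — `Var(X_Δ β) / (Var(X_Δ β) + 2σ²)` — lands near 0.17 overall and
~0.33 on the divergent subset, the regime the analyses are meant to
probe. Expression is exported as `FPKM = 2^y − 1` floored at 0, so the
pipeline's `log2(1 + FPKM)` response inverts the generative scale
exactly (up to the small replicate noise and the rare floor at 0).
Chromatin states tile 200 bp bins; bins over conserved/strongly-gained
sites draw the active state with probability `fold/n_states` (5/15 by
default), others uniformly.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: sequence content and motifs, read-level
error and mappability structure, correlated mark co-occurrence,
peak-width and score heterogeneity beyond log-normal scores,
non-uniform gene density, and any non-linearity in the
expression–chromatin relationship.

# Problem sizes and determinism

Default problem sizes (2,000 genes and peaks per TF, 8,000 co-occupancy
regions, 2,000 permutations in the bundled pipeline configuration) run
the full pipeline in well under two minutes on one CPU core. Every
random step derives its stream from the single configured seed
(per-stage sub-seeds keep stages independently reproducible), so a rerun
under the same seed reproduces the summary JSON byte-identically;
nothing is threaded.

# Known limitations

- The permutation null ignores genomic covariates (GC, isochores,
  gene density); folds against strongly structured references should be
  read accordingly.
- The lifted interval spans internal alignment gaps; for regions
  crossing large insertions the mapped span can be much wider than the
  source window.
- Compensatory detection inherits a density-dependent background from
  random nearby peaks; it is a property of the definition, not of the
  implementation.
- The expression model is linear in log-scale promoter signal; it is a
  deliberately naive, interpretable baseline, not a mechanism model.
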