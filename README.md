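# orthopeaks

Comparative epigenomics of transcription-factor (TF) occupancy between
two species — built for studies like the human/mouse erythroid
(proerythroblast) comparisons in which master regulators (GATA1, TAL1,
NFE2, KLF1) and histone modifications are profiled in both species and
the question is *what is conserved, what moved, and how much of gene
expression the chromatin explains*.

## What it computes

Given peak calls, a UCSC chain alignment, gene annotations with 1:1
orthologs, a chromatin-state segmentation and expression tables,
orthopeaks:

- **Maps occupancy across species** with a from-scratch liftOver-style
  mapper: a summit window *s* ± 50 bp maps iff ≥ 10% of its bases lie in
  aligned blocks of a unique chain (`lift_interval()`,
  `lift_summit_window()`).
- **Classifies each site** as *conserved* (mapped window overlaps a peak
  in the other species), *lost* (mapped, no overlap), *compensatory*
  (a new site within ± 5 kb of a lost one), *gained*
  (species-specific), or *strongly gained* (top 10% of gained sites by
  read score). Rates use mapped peaks as denominator.
- **Builds combinatorial co-occupancy regions** (CRMs) by single-linkage
  clustering of summits at ± 1 kb, measures how each combinatorial group
  transfers across species as a row-stochastic matrix x<sub>ij</sub>/n<sub>i</sub>,
  extracts fully retained panel CRMs and assigns them to nearby genes.
- **Tests genomic association** by length-preserving uniform permutation
  of query segments within a workspace (fold = observed/expected
  overlap, add-one permutation p), and computes per-state
  chromatin-state fold enrichments as base-fraction ratios.
- **Models expression from promoter marks**: quantile-normalized
  promoter matrices, lasso regression (10-fold CV, one-standard-error
  penalty) fit as a single *consensus* model over both species, with
  per-species R²; the same coefficients applied to the per-gene mark
  difference X<sub>Δ</sub> predict between-species expression
  differences, y&#770;<sub>Δ</sub> = X<sub>Δ</sub>β.
- **Simulates a full paired-species study** with planted ground truth
  (conservation/compensatory rates, CRM retention tiers, a linear
  mark→expression model with known β and noise, state enrichment), so
  every stage is testable offline.

## Worked example

```r
library(orthopeaks)
library(dplyr)

study <- simulate_study(sim_config(seed = 1))

gata1 <- classify_source_peaks(
  filter(study$peaks$src, factor == "GATA1"),
  filter(study$peaks$dst, factor == "GATA1"),
  study$genomes$chains)
gata1
#> peak conservation: 2000 source peaks, 2000 mapped, 541 conserved (rate 0.271), 407 compensatory

resp_a <- expression_response(study$marks$expr_a)
resp_b <- expression_response(study$marks$expr_b)
model <- fit_consensus(study$marks$pm_a, resp_a,
                       study$marks$pm_b, resp_b, seed = 1)
model
#> lasso expression model: n = 3600, lambda = 0.2034 (1-SE), R^2 = 0.605, 5/10 nonzero
round(model$r_squared_by_species, 3)
#>     a     b
#> 0.605 0.605
tidy(model)
#> # A tibble: 10 x 2
#>   term     estimate
#> 1 H3K9ac      2.91
#> 2 H3K4me3     1.78
#> 3 H3K27me3   -1.35
#> 4 H3K36me3    0.879
#> 5 GATA1       0.250
#> # i 5 more rows
```

Reading this: of 2,000 simulated GATA1 sites all mapped across the
chain, 27.1% overlap an occupancy site in the other species (the
generator planted 25%), and 407 of the lost sites have a compensatory
site within ± 5 kb. The consensus lasso keeps 5 of 10 marks — exactly
the planted support — and explains 60.5% of expression variance in each
species (planted truth: 60%).

`run_pipeline(run_config(seed = 1), out_dir = "out")` runs every stage
and writes TSV/JSON artifacts plus a `summary.json`;
`autoplot()`, `plot_conservation()`, `plot_transfer()`,
`plot_state_enrichment()` and `plot_metagene()` draw the standard views.
A thin CLI wrapper lives at `inst/cli/orthopeaks.R`
(`orthopeaks.R simulate|run --out DIR --seed N`).

## Package layout

- `R/io.R`, `R/intervals.R` — readers/writers (narrowPeak, chain, gene
  table, segmentation BED, expression TSV) and interval algebra.
- `R/chain-lift.R` — the chain mapper.
- `R/conservation.R`, `R/cooccupancy.R` — site classification and CRM
  transfer.
- `R/signal.R` — tag pileup, RPM/input normalization, promoter matrix,
  metagene profiles.
- `R/enrichment.R` — permutation and state enrichment, odds ratios,
  rank-sum wrapper.
- `R/expression-model.R` — quantile normalization, lasso/consensus/
  difference models, species-specific gene sets, category summaries.
- `R/synthetic.R` — the ground-truth generator.
- `R/pipeline.R`, `R/plots.R` — orchestration and ggplot views.
- `vignettes/orthopeaks-methods.Rmd` — the methods vignette (models,
  parameters, design decisions, limitations).
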