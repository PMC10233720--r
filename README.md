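# phasePeak

Integrative analysis of oscillatory gene expression and
transcription-factor binding across the *C. elegans* molting cycle.

During each larval stage the nematode rebuilds its cuticle, and a few
thousand genes oscillate in expression once per stage. Each oscillating
gene is summarized by a peak **phase** φ (degrees of one 360° cycle) and
an **amplitude** A. phasePeak is for researchers who have (i) per-gene
oscillation annotations, (ii) a set of genes regulated by a
molting-clock transcription factor, (iii) replicate ChIP-seq peak calls
and a signal track for that factor, and (iv) a gene annotation — and who
want to know *when* in the molt the regulated genes peak and *where*
the factor binds relative to them.

The package implements:

- **Phase geometry.** Polar coordinates *x* = A·cos φ, *y* = A·sin φ;
  developmental time on a molt-anchored clock (9 h stage, 1 h = 40°,
  lethargus at 45°, ecdysis ending at 135°), with adjusted hour
  *t*(φ) = ((φ − 135°) mod 360°)/40° and hour bins ⌊t⌋ + 1 ∈ {1..9};
  the early/middle/late tripartition [135°, 255°), [255°, 15°),
  [15°, 135°) of the cycle.
- **Replicate-validated peak assignment.** Peaks kept only when both
  replicates call them, then assigned to the gene body and to 0–1 kb,
  1–3 kb and 3–5 kb strand-aware flanking bins whenever the overlap is
  ≥ 100 bp, and summarized as mean peaks per gene per hour bin.
- **Metagene profiles.** TSS/TES-anchored average signal: 1 kb real
  flanks, gene bodies rescaled to 2 kb, 25 bp windows (160 windows),
  mean ± z·s/√n confidence bands per gene class (early/middle/late/all
  genes/lowest-expressed 20%).
- **Oscillation enrichment.** One-degree-of-freedom χ² goodness of fit
  of the oscillatory count in a regulated set against a genome-wide null
  proportion p₀ (default 0.20): χ² = (k − np₀)²/(np₀) +
  ((n−k) − n(1−p₀))²/(n(1−p₀)).
- **Synthetic data.** A seeded generator of genomes, oscillation tables,
  regulated sets, replicate peak calls and wiggle tracks with the
  statistical structure the analysis assumes, so the full pipeline runs
  and is tested without any external download.

Everything is built on Bioconductor containers: `GRanges` for
intervals, `RleList`-backed signal tracks, S4 classes with validity
checks for the clock, configurations and results.

## Worked example

The headline desk calculation — 236 of 265 regulated genes annotated
oscillatory, against the 20% genome-wide null:

```r
library(phasePeak)
chi2Enrichment(236, 265, 0.20)
#> EnrichmentResult: 236/265 oscillatory (89.1%) vs null 20%
#>   chi-squared = 789.8 (1 df), p = 8.75e-174

hourBin(178.11)            # the regulator's mRNA peak phase ...
#> [1] 2                    # ... falls in larval-stage hour bin 2
polarToCartesian(178.11, 2.11)
#>           x          y
#> 1 -2.108852 0.06958936
```

An end-to-end run on a synthetic study (defaults: 900 genes on three
2 Mb chromosomes, a 265-gene regulated set that is 89% oscillatory,
binding density decaying with circular distance from the regulator's
activity peak):

```r
cfg   <- SimConfig(seed = 42)
paths <- simulateAll(cfg, "demo")
res   <- runPipeline(paths[["genes"]], paths[["oscillation"]],
                     paths[["regulated"]], paths[["rep1"]],
                     paths[["rep2"]], paths[["signal"]], "demo_out",
                     expressionTsv = paths[["expression"]])
res$enrichment
#> EnrichmentResult: 236/265 oscillatory (89.1%) vs null 20%
#>   chi-squared = 789.8 (1 df), p = 8.75e-174
subset(res$peakCounts, feature == "total")
#>  hour_bin feature mean_peaks n_genes
#>         1   total  1.2456140      57
#>         2   total  3.1527778      72
#>         3   total  2.1034483      29
#>         4   total  0.9047619      21
#>         5   total  0.2857143       7
#>         6   total  0.2500000       4
#>         7   total  1.5000000       4
#>         8   total  0.5555556       9
#>         9   total  0.5151515      33
#>   non_osc   total  1.1379310      29
```

The mean number of validated peaks per regulated gene is maximal for
genes peaking in hour bin 2 — the hour after the regulator's own mRNA
peak — and declines through the rest of the stage, while non-oscillating
regulated genes sit near the background rate. `demo_out/` holds the
same results as TSV (`phase_coordinates.tsv`, `peak_assignments.tsv`,
`peak_counts_by_hour.tsv`, `metagene_profiles.tsv`, `enrichment.tsv`)
plus a `run_manifest.json` with input checksums for exact re-runs.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/phasepeak.R", package="phasePeak"))')" \
    enrich --k 236 --n 265 --null-p 0.20
```

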