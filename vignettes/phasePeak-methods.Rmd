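---
title: "phasePeak: models, conventions and design choices"
author: "phasePeak authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phasePeak: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasePeak)
```

# The analysis

*C. elegans* rebuilds its cuticle at the end of every larval stage, and
several thousand genes oscillate in expression with this molting cycle,
each summarized by a peak phase (degrees of one 360° cycle per stage)
and an amplitude. phasePeak connects three data types around a
molting-clock transcription factor: per-gene oscillation annotations, a
regulated gene set, and ChIP-seq binding (replicate peak calls plus a
signal track). The questions it answers are *when* in the stage the
regulated genes peak, whether the regulated set is enriched for
oscillation relative to the genome, and *where* and *how strongly* the
factor binds relative to genes of each phase class.

# Phase geometry and the molt-anchored clock

Phases are degrees in [0, 360), the API unit throughout (conversion to
radians is internal). The polar coordinates behind radar/scatter views
are $x = A\cos\varphi$, $y = A\sin\varphi$, so the vector norm equals
the amplitude.

`MoltClock` fixes the developmental anchoring: a 9 h larval stage
(hence 1 h = 40°), lethargus starting at 45° and ecdysis ending at
135°. Adjusted larval-stage time is

$$t(\varphi) = \frac{(\varphi - 135°) \bmod 360°}{40°/\mathrm{h}},$$

i.e. the clock starts at the end of ecdysis. This origin is the unique
choice under which the regulator reference oscillation (peak phase
178.11°, amplitude 2.11) lands in hour bin
$\lfloor t \rfloor + 1 = 2$ — the hour after the regulator's mRNA peak
— which is how the per-hour binding summaries are conventionally read.
The molt window is the half-open interval [45°, 135°).

The early/middle/late tripartition is implemented with half-open
boundaries at 135°, 255° and 15°: early = [135°, 255°), middle =
[255°, 360°) ∪ [0°, 15°), late = [15°, 135°). Published figure legends
render these as "135–254.9°" style one-decimal endpoints; reading them
as half-open bins is the only interpretation that partitions the circle
exactly, gives each class a 120° (3 h) width, and makes the classes
coincide exactly with hour-bin triples (early ⇔ bins 1–3, middle ⇔ 4–6,
late ⇔ 7–9). Both the partition property and the class/bin equivalence
are enforced by grid-based property tests at 0.01° resolution.

Non-oscillating genes are an explicit fourth class carried through
every table (`phase_class = "non_oscillating"`, `NA` coordinates and
times); they are never dropped silently.

# Coordinates and interval conventions

All interval containers are `GRanges`/`IRanges`, which are 1-based
closed — the Bioconductor norm. BED input (0-based half-open) and
wiggle input (1-based, `span`-expanded) are converted on read exactly
as `rtracklayer` converts them; a BED record `chrI 0 100` becomes
`chrI:1-100`. Overlap lengths, flank-bin spans and assignment rules are
unchanged by the convention; only the printed coordinates differ.

Overlap is strand-blind everywhere; strand is used solely to orient
upstream/downstream. Around each gene body the seven assignment
features are the body plus 0–1 kb, 1–3 kb and 3–5 kb bins on each side,
mirrored for minus-strand genes, truncated at chromosome boundaries and
omitted when truncated to nothing. Flank bins of neighboring genes may
overlap; no masking is applied, so one peak can legitimately count for
several genes — and for several features of one gene, since the
≥ 100 bp assignment rule is stated per feature with no exclusivity.

Replicate validation keeps each replicate-1 peak overlapping any
replicate-2 peak by at least 1 bp (the threshold and the coordinate
policy — keep replicate-1 coordinates, or intersect/union with the
best-overlapping partner — are `AssignmentConfig` knobs, since the
original consensus rule is not recorded anywhere we can consult).
Keeping replicate-1 coordinates is the default as the simplest
reproducible choice.

Per-hour summaries use *all* genes of the oscillation table as
denominators: a regulated gene with no assigned peak contributes a zero
to its bin's mean rather than disappearing. A dedicated test checks
that explicit zero rows and implicit zero-filling agree.

# Metagene profiles

Each gene contributes a 160-window profile at the defaults: 40 windows
of 25 bp of real upstream flank, 80 windows of the body rescaled to
2 kb, 40 windows of downstream flank, oriented TSS→TES regardless of
strand. Body rescaling treats the per-base signal as a
piecewise-constant function of position, stretches it linearly to the
target length, and takes exact area-weighted window means. This makes
scaling preserve constants exactly and leave the body-wide mean
unchanged (tested to 1e-6 against per-base means, and against a
brute-force dense resampler for short genes); the popular plotting
tools the defaults mirror do not document their interpolation, so the
integral-preserving choice is the one we can verify.

Aggregation over a gene set is a per-window mean with a
normal-approximation confidence interval, mean ± z·s/√n at the 95%
level by default. With hundreds to thousands of genes per class the
difference from a t-interval is negligible; a coverage simulation in
the test suite confirms ~95% per-window coverage. Windows that fall off
a chromosome edge are *missing* for that gene — excluded from that
window's n — not zero-filled, so edge genes do not drag profile ends
toward zero (zero-filling is the alternative the data cannot
distinguish; exclusion is the conservative choice). A single-gene class
yields a degenerate interval equal to the mean and a `degenerate` flag
rather than an error.

Gene classes are the three phase classes (from the oscillation records
of the regulated set), all genes, and the "no expression" reference —
the lowest 20% of `expression_percentile`.

# Oscillation enrichment

The enrichment statistic is the classical 1-df goodness-of-fit χ² of
observed [k, n−k] against expected [np₀, n(1−p₀)], with a two-sided
p-value from the χ² distribution; it is algebraically identical to the
squared binomial z-score, which the tests assert to 1e-9. The default
null proportion p₀ = 0.20 is the upper end of the 10–20% of genes
estimated to oscillate genome-wide — the conservative end for
enrichment claims — and the worked example (236 of 265 oscillatory,
χ² ≈ 789.8) rejects at p < 10⁻⁴ for every p₀ in [0.10, 0.20]. No
continuity correction is applied by default (a Yates-corrected variant
is available via `correct = TRUE`); at n = 265 the uncorrected test's
exact size at α = 0.05 is 0.054 — the residual discreteness of the
binomial — which a 40,000-draw calibration test verifies to lie within
5% ± 1%. Regulated genes absent from the oscillation table are counted
non-oscillatory, with a warning, rather than excluded: missingness
should not inflate the enrichment.

# The synthetic study

`SimConfig` defines the simulated conditions; its defaults are the
package's standard study and are exercised, unchanged, by the test
suite:

- **Genome**: 900 genes of 0.4–2 kb placed uniformly without overlap on
  three 2 Mb chromosomes (one gene per ~6.7 kb, close to the real
  genome's one per ~5 kb). Uniform placement is deliberate: sparser or
  clustered real layouts change how often flank bins of neighbors
  overlap, which the assignment rule tolerates by design.
- **Oscillation**: 15% of genes oscillate genome-wide (inside the
  published 10–20% range); a 265-gene regulated subset oscillates at
  89%. Regulated phases are von Mises around the 178.11° reference with
  concentration κ = 1.5 (circular SD ≈ 50°, wide enough to populate
  every hour bin); background phases are uniform; amplitudes are
  lognormal(0.5, 0.35), spanning roughly 1–4 like the published radar
  charts. κ = 0 recovers a uniform phase distribution (tested), so the
  null of "no phase structure" is reachable.
- **Binding**: each oscillatory gene draws a Poisson peak count at rate
  $r(\varphi) = r_0 \exp(-\lambda\, d(\varphi, \varphi_b))$ with
  $r_0 = 4$, decay λ = 0.05 per degree (e-folding 20° ≈ 30 min) and
  $d$ the circular distance; non-oscillatory genes use a floor rate of
  0.3. The decay center $\varphi_b$ is the regulator's mRNA peak plus a
  17° activity lag (~25 min): protein accumulation follows
  transcription, so binding is maximal for genes peaking shortly
  *after* the regulator transcript — without the lag the decay center
  sits 3° from an hour-bin boundary and bins 1 and 2 are symmetric by
  construction, which no real per-hour profile shows. Peaks (~300 bp)
  center near the TSS, with 20% near the TES, mirroring the
  promoter-proximal and end-site enrichment seen in real binding data.
  Setting λ = 0 with floor = r₀ removes the phase coupling entirely
  (tested with a Kruskal–Wallis bin-effect check).
- **Replicates and signal**: replicate 2 jitters replicate-1 peaks by
  N(0, 25 bp) and drops 5% independently; the wiggle track is the sum
  of per-peak triangular bumps plus truncated Gaussian noise on a 25 bp
  grid.

One master seed drives fixed per-stage streams (genome, oscillation,
peaks, replicate 2, signal), so regenerating a later stage never
perturbs an earlier one, and identical configurations produce
byte-identical files (asserted on checksums).

What the generator does *not* emulate: nucleotide sequence, read-level
noise, peak-caller artifacts, irregular gene length/spacing
distributions, correlated replicate structure beyond jitter/dropout,
and any expression–binding feedback. Passing the recovery tests
therefore demonstrates that the pipeline's arithmetic and statistics
recover planted structure of this form — not that the biological
conclusions transfer to any particular real dataset.

The end-to-end recovery contract, checked over 100 seeds in the test
suite and recomputed for one seed by `scripts/acceptance.R`: the
regulated oscillatory fraction lands within 3 binomial SD of 0.89, the
20% null is rejected at p < 10⁻⁴, and the per-hour mean peak-count
profile is maximal at hour bin 2.

# Numerical and interface choices

- Pipeline TSVs print floats at 6 significant digits; identical inputs
  and configuration give byte-identical outputs, and the JSON manifest
  (input MD5 checksums, clock/assignment/metagene settings, package
  version) suffices to reproduce a run exactly.
- `which.max` tie-breaks (first maximum) decide the "maximal bin" in
  summaries; ties are practically impossible with continuous rates.
- Degenerate inputs: empty replicate lists validate nothing (with a
  warning); empty metagene classes are omitted (with a warning); a
  chromosome absent from a signal track profiles as zeros (with a
  warning); hour bins without genes are omitted from summary tables.
- The wiggle writer emits fixedStep blocks on a fixed grid (25 bp by
  default) — exact for tracks constant within windows, such as the
  generator's own — because run-length-collapsed tracks have
  variable-width runs that the wiggle format's fixedStep/variableStep
  blocks cannot represent span-faithfully in general.
- Problem sizes in the test suite (900-gene genomes for the 100-seed
  recovery loop, 60–90-gene genomes for file round-trips, 40,000 draws
  for the size calibration, 200 random instances for the assignment
  oracle) are the package's chosen balance between statistical
  resolution and a test suite that runs in a couple of minutes.

# Known limitations

- The assembly is never pinned: coordinates are taken as given, and
  annotation/peak/signal inputs must simply agree with each other.
- Only text wiggle is supported for signal (no native bigWig); convert
  with standard tools first.
- The metagene module offers only the scaled TSS→TES anchor mode, no
  per-gene heatmaps.
- The enrichment module is a single test against a fixed null
  proportion — no multiple-testing machinery, and no gene-ontology
  analysis (database-version dependent by nature).
- Whether clipped flank windows should be missing or zero-filled is not
  decidable from published figures; the package makes the
  missing-window choice and documents it above.
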