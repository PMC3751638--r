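---
title: "Relating promoter histone acetylation to gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating promoter histone acetylation to gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylscan)
```

## The analysis

acetylscan integrates two genome-wide measurements made on the same
biological material: an expression matrix from a four-group treatment
design, and single-position ChIP-seq tag libraries (an immunoprecipitated
library and an input control per condition) for a promoter-associated
histone-acetylation mark. The four groups follow a chronic/acute design —
SS (control/control), SM (control/acute drug), MS (chronic drug/control),
MM (chronic/acute) — so that SM-vs-SS captures the acute transcriptional
response of naive animals and MM-vs-SS the response after chronic
pre-exposure, which is typically *blunted*.

The questions the pipeline answers, in order:

1. **Where does the mark bind?** Tags are assigned to the nearest
   transcription start site and summarized as a strand-signed metagene
   profile; the mark concentrates at TSSs.
2. **Does binding track expression?** Genes are ranked by standardized
   expression (Z score), grouped into 100-gene bins, and mean normalized
   promoter tag count is regressed on mean Z per bin.
3. **Where is binding enriched over background?** A sliding-window Poisson
   test against the input-scaled expectation calls enrichment sites, which
   are reduced to gene sets and compared across conditions as a Venn
   partition.
4. **Do expression changes coincide with binding changes?** Differentially
   expressed genes are classified by their input-corrected binding fold
   change as increased / decreased / no-change (NC) / absent, reproducing
   the published per-gene summary tables.

## Models and statistics

**Differential expression.** The per-gene fold change is the ratio of
linear-scale group means, reported in the signed convention used by array
tables (−1.85 means a 1.85-fold decrease, so |fold| ≥ 1 always). The
p-value is Welch's two-sample t on log2 intensities. The original analysis
suite's per-gene statistic is unpublished; Welch's t is our documented
stand-in. Calls use the conventional thresholds |fold| ≥ 1.7 and p < 0.01
(strict on p, inclusive on fold). No multiple-testing adjustment enters the
calls, matching the raw-p filtering convention; BH-adjusted values are
reported alongside. A degenerate gene with zero variance in both groups
receives p = 1 when the means agree and p = 0 otherwise (the limit of the
statistic).

**Normalization.** Expression samples are median-scaled to the grand median
of the whole matrix ("global normalization"; the grand median is our
reading of the unspecified reference point). Tag libraries are scaled to
tags per million: a gene with *n* raw tags has normalized count
*n* × 10⁶ / total.

**Nearest-promoter assignment.** Each tag goes to the gene whose TSS is
nearest on the same chromosome. Promoter windows are TSS-centred (default
half-width 2 kb), so nearest-promoter and nearest-TSS assignment coincide;
we implement the latter and document the equivalence. Ties are broken
deterministically: smaller TSS coordinate, then lexicographically smaller
gene id. Tags on chromosomes absent from the annotation are counted as
unassigned so that assigned + unassigned always equals the library total.

**Enrichment-site calling.** The published analysis reports binding-site
counts without describing the caller; ours is therefore a clearly labelled
generic stand-in with every knob exposed. Windows of width *w* slide by
step *s* (defaults 1000/500 bp); the expected IP count in a window is the
input count scaled by the library-size ratio and floored at a pseudocount
(0.5); a window is significant when the exact Poisson upper tail
P(X ≥ ip | expected) < α and ip/expected ≥ a minimum fold (2); overlapping
or adjacent significant windows merge into a site that keeps the minimum
window p. α is per-window by default (the published counts carry no stated
correction); a Benjamini–Hochberg option exists. Because the expectation
treats the input count as fixed, the matched null for calibration is an IP
library that is a count-thinned copy of the input; under that design the
empirical false-site rate stays below 2α. Reproducing the publication's
absolute site counts is out of scope — they depend on the deposited raw
data and the unstated caller.

**Binned regression.** Z scores standardize log2 mean expression across
genes within a condition (sample SD, all-zero for constant input). Genes
sorted by Z form consecutive 100-gene bins; a trailing remainder bin is
kept, flagged partial, and excluded from the regression by default (how
the original 22,523-probe array divided by 100 was handled is unstated).
The regression is ordinary least squares across bins with
R² = 1 − SSres/SStot and the convention R² = 0 for a constant response.
Two response scales are offered: the plain linear scale, and
`response = "log2"` (log2 of mean tags-per-million + 1). Binding intensity
couples *log-linearly* with expression — both in chromatin biology and in
our generator, where tag probability is proportional to
exp(slope × log2 expression) — so on the linear scale bin means are
exponential in Z and a straight line systematically underfits (R² ≈ 0.6 on
our coupled simulations) while the log2 scale linearizes the relationship
(R² ≈ 0.9). The pipeline therefore reports the log2-scale regression; the
linear scale remains the default of the standalone function for users who
want the untransformed fit.

**Concordance classification.** For each differentially expressed gene, the
binding change between conditions is the ratio of input-corrected
enrichments, (ip + c)/(input + c) per condition with pseudocount c = 0.5,
in the signed convention. A gene absent from the ChIP-detected set is
`absent`; a detected gene with |binding fold| below the NC threshold (or
with no fold available) is `NC`; otherwise `increased`/`decreased` by sign.
The NC threshold defaults to 1.4 because the smallest changed binding
magnitude in the packaged tables is 1.49; the published criterion is
unstated and the threshold is configurable. The packaged tables transcribe
the printed binding codes verbatim (numeric fold, `NC`, `*` for
not-detected), and probe-level duplicate symbols are kept as distinct
records so that the printed arithmetic (29 + 3 = 32 up-regulated genes on
both platforms) is reproduced exactly.

## The synthetic-data generator

The generator exists so every stage can be tested against known ground
truth without the deposited raw data. It emulates the study's structure,
not the rat genome:

* **Annotation** — equally sized chromosomes; TSSs placed uniformly under a
  minimum-spacing constraint (a sorted uniform draw plus fixed offsets);
  random strands; gene lengths uniform on 1–10 kb (gene bodies are
  otherwise unused).
* **Expression** — per-gene log2 baselines Normal(7, 1.5), a typical
  bead-array intensity scale; four groups with a configurable number of
  replicates (default 5 — the study does not state its per-group array n);
  planted SM effects at an exact population fold (default 4); MM effects
  scaled on the log2 scale by a blunting factor (default 0.5), emulating
  the attenuated acute response after chronic exposure; MS at baseline;
  log-normal noise (default SD 0.25 log2 units). Truth labels are returned
  per gene and contrast.
* **Tag libraries** — exactly `librarySize` single-base tags. Input
  libraries are uniform over the genome. IP libraries mix a uniform
  background fraction (default 0.2) with TSS-centred tags: gene chosen
  with probability ∝ exp(couplingSlope × log2 expression), position at
  TSS + Normal(0, 200 bp) signed along the gene strand. Tags model
  fragment midpoints of the 300–600 bp sheared range (default fragment
  length 450 bp); a 5′-end mode shifted by half a fragment is available
  for realism, paired with the corresponding midpoint shift in the
  quantifier. Every operation draws from its own explicitly seeded stream
  and restores the caller's RNG state.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: mappability and GC structure, duplicate
reads, nucleosome-scale peak shape, replicate-to-replicate ChIP
variability, probe-level array artefacts, and correlated gene neighbours.
The simulations calibrate the machinery, not the biology.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed in memory (the native GRanges convention);
  BED is converted on I/O, GFF3 passes through `rtracklayer`. A single
  internal convention avoids off-by-one drift.
* Assignment and window counting use sorted positions with binary search
  (`findInterval`), and are verified against brute-force oracles in the
  tests.
* Constant inputs: all-equal expression gives all-zero Z scores; a constant
  regression response gives slope 0 and R² = 0; zero-variance DE groups get
  the limiting p-values described above.
* The site caller floors expectations at the pseudocount, so regions with
  empty input cannot produce infinite enrichment.
* Determinism: every simulation is reproducible from its seed; the pipeline
  fans one global seed out to per-stage streams by fixed offsets so stages
  are individually reproducible.

## Problem sizes

The packaged analyses and tests run at desk scale by design: simulations
use 500–1000 genes on a few megabase-scale chromosomes, 2 × 10⁴–10⁵ tags
per library, 5000 genes for the null-calibration screens, and 50–100
replicates for the stochastic controls. These sizes give stable estimates
for every reported quantity (the binned regression, for instance, varies by
only a few hundredths of R² across seeds) while keeping a full run in
seconds to minutes.

## Known limitations

* The enrichment caller and the DE test are stand-ins for unpublished
  methods; absolute site counts and gene lists from the original study are
  not reproducible and are not attempted.
* Binding "detected" status in the pipeline derives from the site caller's
  gene sets, whereas the published tables' `*` codes reflect the original
  platform's detection; the two agree only in structure.
* The overlap partition reports set cardinalities, not statistical
  enrichment of overlaps.
* Window-level Poisson calling treats the input as fixed; for very shallow
  input libraries the per-window false-positive rate against an
  *independent* background exceeds the nominal α (the matched,
  count-thinned null stays calibrated).
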