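---
title: "Cross-frequency multiplex brain networks: model, metrics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-frequency multiplex brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplexfc)
```

## The model

Resting-state BOLD fluctuations are not spectrally homogeneous: the
canonical slow bands — slow5 (0.01–0.027 Hz), slow4 (0.027–0.073 Hz),
slow3 (0.073–0.198 Hz) and slow2 (0.198–0.25 Hz) — carry partly distinct
connectivity structure. `mplexfc` treats each band's binarized functional
network as one layer of a *multiplex* network over the same parcellated
regions, with each region coupled to its own counterparts across layers
(identity interlayer blocks in the supra-adjacency representation). Two
node metrics summarize how a region uses the frequency dimension:

* **EMD** (entropy of the multiplex degree). With per-layer degrees
  $K_{i\alpha}$ and overlapping degree $O_i = \sum_\alpha K_{i\alpha}$,

  $$E_i = -\sum_{\alpha=1}^{M} \frac{K_{i\alpha}}{O_i}
        \ln\!\frac{K_{i\alpha}}{O_i},$$

  with $0\ln 0 \equiv 0$ and $E_i = 0$ for isolated nodes. $E_i$ ranges
  from 0 (all links in one band — the node cannot relay information
  between bands) to $\ln M$ (links spread evenly — maximal
  cross-frequency integration).

* **MCC** (multilayer clustering coefficient). The ratio of cross-layer
  closed triples centred on $i$ to cross-layer connected triples:
  numerator $\sum_{\alpha}\sum_{\alpha'\neq\alpha}\sum_{\alpha''}
  \sum_{j \ne i, m \ne i, j \ne m} a_{ij}^{\alpha} a_{jm}^{\alpha'}
  a_{mi}^{\alpha''}$, denominator
  $\sum_{\alpha}\sum_{\alpha'\neq\alpha}\sum_{j\ne i, m\ne i, j \ne m}
  a_{ij}^{\alpha} a_{mi}^{\alpha'}$ — a cross-frequency segregation
  measure.

Network-level values are plain node means. For $M$ identical layers the
literal MCC collapses to $M$ times the single-layer clustering
coefficient and EMD to $\ln M$; these analytic reductions anchor the
test suite.

### Two MCC conventions

The numerator constrains the *first two* edges of the triangle to lie in
different layers while leaving the third layer free, whereas the
denominator constrains the two *node-incident* edges. The two sums
therefore count differently-anchored objects, and a node can have a
positive numerator with a zero denominator (three nodes; both of node
1's edges in layer 1, the closing edge in layer 2). We implement the
definition literally, define $C_i \equiv 0$ whenever the denominator is
zero, and expose a `strict_three_layer` convention in which the third
edge must occupy a third distinct layer. Neither convention is asserted
as uniquely correct; both are matched exactly (integer numerators and
denominators) by an independent brute-force enumeration oracle,
`mcc_bruteforce_oracle()`.

## The analysis chain

For each subject: (1) zero-phase Butterworth band-pass filtering of the
region × timepoint matrix into the four slow bands plus the full band
(series are demeaned first; the forward–backward pass squares the
magnitude response, and order 2 per skirt gives ≥ 0.9 passband gain and
≤ 0.1 amplitude one octave outside the edges); (2) Pearson connectivity
per band, diagonal excluded; (3) proportional-sparsity binarization at
each grid value 0.10–0.40 (step 0.05), retaining exactly
`round(s · N(N−1)/2)` strongest edges (half rounded away from zero —
conventions differ by one edge otherwise — with cutoff ties broken
lexicographically for determinism); (4) node metrics — EMD and MCC on
the 4-layer stack, clustering coefficient and local efficiency per
single-layer network (the full band joins only the single-layer
analyses); (5) normalized AUC over the sparsity grid.

Group statistics use pooled-variance t-tests (the equal-variance design
is asserted upstream), Benjamini–Hochberg FDR within each family (one
family per metric per scale: the N nodes of one metric, the five RSNs of
one metric), and Spearman correlations between node metrics and symptom
scores within the patient group only, since controls carry no symptom
scores. BH was chosen over local-fdr style empirical-null methods for
transparency and determinism.

Choices worth restating with units and defaults:

| parameter | default | meaning |
|---|---|---|
| sparsity grid | 0.10–0.40 step 0.05 | fraction of possible edges kept |
| filter order | 2 per skirt | squared by the forward–backward pass |
| threshold mode | `signed` | rank raw r; negatives enter last (`absolute` available) |
| AUC | normalized | trapezoid / grid width; preserves metric scale |
| MCC convention | `literal` | printed-definition semantics |
| alpha | 0.05 | significance level after FDR |

The *normalized* AUC (a trapezoid-weighted mean) rather than the raw
integral keeps aggregated EMD below its $\ln 4 \approx 1.386$ entropy
ceiling; a raw integral over the 0.3-wide grid would cap at 0.416 and
lose the metric's natural scale. The raw mode remains available.

Edge cases are fixed as follows: nodes with degree < 2 have clustering
and local efficiency 0; unreachable neighbour pairs contribute inverse
distance 0; isolated multiplex nodes have EMD 0; a zero MCC denominator
yields MCC 0; a constant clustering sequence yields `NA` (with a
warning) in layer-correlation matrices, never a silent 0; slow2's upper
edge equals Nyquist at TR = 2 s and is realized as a high-pass filter.

## The synthetic cohort generator

No public generative model exists for band-specific functional
connectivity, and the analysis consumes nothing but band-wise Pearson
correlations — so the generator produces exactly that structure, as
simply as possible. Each band partitions the regions into modules
(partitions differ across bands by a cyclic shift); each module carries
a latent signal (white noise filtered into the band, standardized); a
region's series is the coupling-weighted sum of its module latents plus
broadband white noise. Defaults mirror the reference cohort design:
90 regions, 142 volumes at TR = 2 s, 69 controls and 50 patients, with
patient symptom scores drawn around SANS 35.9 (SD 19.21) and SAPS 30.92
(SD 21.04), truncated at zero.

The planted patient effect `degree_rebalance` targets EMD directly: at
baseline an effect node keeps shared signal only in its two "home"
bands (links concentrate there, EMD low); in patients the remaining
bands' coupling is restored in proportion to `effect_size`
(`1` = full rebalance, the documented strong setting), spreading links
evenly and raising EMD. A per-patient multiplier (uniform on
[0.4, 1]) makes the realized effect heterogeneous, and symptom scores
are drawn with slope `score_coupling` on that planted proxy, so
score–metric correlation recovery is a testable property.
`coupling_shift` instead scales a node's coupling amplitudes uniformly.

What the generator does *not* emulate: hemodynamics, head motion,
physiological noise spectra, spatial autocorrelation, or voxel-level
structure. Passing tests therefore demonstrate that the pipeline
recovers the *correlational* structure it is designed to read, not that
it is robust to the full noise anatomy of real fMRI.

One interaction is worth knowing about: proportional thresholding fixes
each layer's edge count, so strengthening an effect node's edges in a
band necessarily displaces edges elsewhere in that layer. A strong
planted effect therefore induces small, real group differences at
non-effect nodes; in recovery experiments the handful of "false
positive" nodes are largely this displacement, not miscalibration of
the tests (null cohorts hold the nominal 5% rate).

## Validation scales

The test suite runs the statistical validations at deliberately modest
problem sizes, chosen as the smallest designs that leave the checked
properties comfortably identified: calibration uses 50 null,
noise-dominated cohorts of 12 + 12 subjects × 40 regions (2000
node-tests; noise-dominated so that node-level tests are nearly
independent and the binomial band applies); effect recovery uses 10
cohorts of 30 + 30 subjects × 30 regions with 10 effect nodes at full
rebalance; monotonicity uses 20 cohorts per effect level at 20 regions.
Oracle-agreement checks run on hundreds of random stacks with N ≤ 12,
M ∈ {2, 3, 4}, where brute-force enumeration is exact and fast.

## Known limitations

* The MCC definitional asymmetry is inherited, not resolved; both
  conventions ship.
* The AAL-90 → RSN table shipped as
  `extdata/aal90_rsn_synthetic.tsv` is a reconstruction from the
  template literature (14 regions each for the attention, sensorimotor,
  subcortical, and visual networks; 34 default-mode), not a published
  table; real analyses should pass their own mapping.
* Degrees of freedom are always computed from sample sizes
  (`n1 + n2 − 2`).
* Interlayer coupling is the unweighted identity; MCC and EMD never
  read it, so weighted interlayer variants are out of scope.

## A small worked run

```{r example, eval = FALSE}
cfg <- synth_config(n_regions = 30, n_controls = 30, n_patients = 30,
                    effect_nodes = seq(1, 28, 3), effect_size = 1,
                    score_coupling = 40, score_noise_sd = 8, seed = 1)
cohort <- synthesize_cohort(cfg)
res <- run_pipeline(cohort, pipeline_config(include_single_layer = FALSE))
subset(res$analysis$comparisons, unit == "node" & p_fdr < 0.05)
```
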