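# mplexfc — multilayer frequency-band brain network analysis

Resting-state BOLD connectivity differs across the canonical slow
frequency bands (slow5: 0.01–0.027 Hz, slow4: 0.027–0.073 Hz, slow3:
0.073–0.198 Hz, slow2: 0.198–0.25 Hz). Treating each band's binarized
functional network as one layer of a **multiplex network** over the same
parcellated regions makes the interaction *between* bands measurable.
`mplexfc` implements that analysis for researchers studying
cross-frequency integration and segregation in clinical cohorts (e.g.
schizophrenia vs typically-developing controls), end to end from region
× timepoint time series to FDR-corrected group statistics.

The two core node metrics, with per-layer degrees `K_ia` and overlapping
degree `O_i = Σ_a K_ia`:

* **EMD** — entropy of the multiplex degree,
  `E_i = − Σ_a (K_ia/O_i) ln(K_ia/O_i)`; 0 when a node's links
  concentrate in one band, `ln M` when they spread evenly across all `M`
  bands. Cross-frequency *integration*.
* **MCC** — multilayer clustering coefficient: the ratio of cross-layer
  closed triples centred on a node
  (`Σ_{a, a'≠a, a''} Σ_{j,m} a_ij^a a_jm^a' a_mi^a''`) to cross-layer
  connected triples (`Σ_{a, a'≠a} Σ_{j,m} a_ij^a a_mi^a'`).
  Cross-frequency *segregation*. Computed by matrix products, verified
  against a brute-force enumeration oracle; two conventions for the
  third layer are provided (`literal`, `strict_three_layer`).

Around the core: zero-phase Butterworth band-pass filtering, Pearson
connectivity, proportional-sparsity thresholding (grid 0.10–0.40, step
0.05, exact edge quotas), supra-adjacency export, single-layer
clustering and local efficiency, normalized AUC aggregation over the
grid, resting-state-network summaries, pooled t-tests with
Benjamini–Hochberg FDR, symptom-score (SANS/SAPS) Spearman correlations,
between-layer clustering-sequence correlations, and a synthetic
two-group cohort generator with controllable band structure and planted
effects.

## Worked example

Simulate a 30 + 30 cohort with a strong planted rebalance effect at ten
regions, run the pipeline, and inspect the node-level EMD comparisons:

```r
library(mplexfc)

cfg <- synth_config(n_regions = 30, n_controls = 30, n_patients = 30,
                    effect_nodes = seq(1, 28, 3), effect_size = 1,
                    score_coupling = 40, score_noise_sd = 8, seed = 1)
cohort <- synthesize_cohort(cfg)
res <- run_pipeline(cohort, pipeline_config(include_single_layer = FALSE))
subset(res$analysis$comparisons, unit == "node" & metric == "emd" & p_fdr < 0.05)
```

```
   name metric mean_schz mean_td    t df    p_fdr
1  R001    emd      1.17   0.894 7.69 58 2.10e-09
4  R004    emd      1.16   0.887 6.82 58 4.35e-08
7  R007    emd      1.10   0.845 6.63 58 7.20e-08
10 R010    emd      1.10   0.871 6.50 58 1.01e-07
...
```

The planted effect nodes (R001, R004, ..., R028) surface with patient
EMD around 1.1 nats against control EMD around 0.85: patients spread
their links more evenly across the four bands (the theoretical ceiling
is `ln 4 ≈ 1.386`). The whole-brain EMD mean is also elevated
(`t(58) = 10.8`), and within patients the node EMD correlates positively
with the simulated symptom scores (mean Spearman rho 0.372 at the effect
nodes), recovering the planted score coupling.

File-based workflows mirror the in-memory one: `write_cohort()` /
`read_cohort()` for tab-separated cohorts, `write_results()` for the
statistics tables, and a thin CLI at
`inst/scripts/mplexfc-pipeline.R` (`simulate`, `run-all`).

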