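# icapattern

Derivation of a disease-related resting-state fMRI pattern from the
**spatial variability of group ICA components**, with a synthetic-cohort
generator for end-to-end recovery testing.

In several neurodegenerative diseases the informative signal is not the
strength of a resting-state network but its spatial reorganisation. The
package implements the full chain that turns that idea into a single
pattern image and one score per subject:

1. **Group spatial ICA** — temporal concatenation, two-stage PCA,
   Infomax unmixing repeated `n_runs` times and aggregated ICASSO-style
   (components clustered on `1 − |spatial r|`, each cluster represented
   by its centrotype), with MDL model-order estimation and a
   per-component stability index.
2. **Dual-regression back-reconstruction** of subject-specific maps,
   z-scored per component.
3. **Variability loadings** `C[i, j] = Σ_v (z_subject − z_group)²` — the
   squared Euclidean (L2) distance between subject *i*'s map for
   component *j* and the group map.
4. **Bootstrapped lasso feature selection**: stratified resampling, an
   L1-penalised logistic regression per iteration with the
   one-standard-error lambda rule, and a component set cut at the
   **inflection point** of the descending selection-frequency histogram
   (discrete first derivative: forward/centred/backward differences).
5. **Bootstrapped logistic-regression pattern**: per iteration the
   coefficients linearly combine the selected group maps and every
   subject's loadings; the pattern image is the mean map, voxels whose
   bootstrap 99% CI straddles zero are masked as non-informative, and
   subject scores are the mean combined loadings scaled by the absolute
   coefficient sum.
6. **Source-based morphometry** — the same ICA core on stacked
   grey-matter maps, yielding a mixing matrix `A[i, j]` of structural
   component expressions.
7. **Clinical statistics** — Shapiro–Wilk-gated Pearson/Spearman
   (partial) correlations, t/Mann–Whitney/chi-square group tests, and
   Benjamini–Hochberg FDR adjustment.

Because no patient data ship with the method, a first-class synthetic
module (`generate_sources()`, `generate_cohort()`, `generate_gm_maps()`)
builds cohorts with known ground truth: smooth spatial sources, patients
whose affected components are spatially perturbed in proportion to a
per-component severity, a SARA-like clinical score, and grey-matter maps
with a planted atrophy component.

## Worked example

The numbered scripts under `analysis/` run the whole derivation on the
standard synthetic cohort (10 sources on a 20×20×10 grid, 17 patients +
16 controls, components 1–3 affected at effect size 1.5, T = 150):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_decompose.R
Rscript analysis/03_loadings.R
Rscript analysis/04_select_pattern.R
Rscript analysis/05_sbm.R
Rscript analysis/06_clinical_stats.R
```

Step 2 reports the decomposition quality — the MDL estimate counts the
patients' deviation directions as well as the sources, so the fit uses
the design order:

```
MDL-estimated model order: 16
fitting at the generative order: 10
fitted 10 components; stability 0.94-0.96
planted sources recovered with |r| 0.93-1.00
```

Step 4 prints the selection histogram and the derived pattern. The three
planted components occupy the top of the histogram and the inflection
cut keeps them (here together with one leakage component, IC4 — see the
vignette on the cut's sensitivity):

```
selection frequencies (descending):
 IC6  IC7  IC3  IC4  IC2 IC10  IC5  IC8  IC9  IC1
 499  488  481  190  170  111   42   41   19   18
selected components: IC6 IC7 IC3 IC4
stable voxels (99% CI off zero): 69.5%
patient-vs-control AUC of subject scores: 1.000
```

Step 6 relates the subject scores to the clinical table within the
patient group (FDR-adjusted as one family): the score tracks clinical
severity, and the group difference in scores is unambiguous:

```
                     y  method estimate p_value q_value  n
        severity_score pearson    0.630 0.00668  0.0267 17
                  sdmt pearson   -0.246 0.34135  0.4551 17
               fluency pearson    0.172 0.50885  0.5089 17
external_pattern_score pearson    0.438 0.07895  0.1579 17

group difference in pattern scores (t test): p = 1.5e-12
```

So a subject's score — the coefficient-weighted sum of their L2
distances on the selected components — separates patients from controls
perfectly on this cohort and correlates r = 0.63 with the planted
severity.

All artifacts (group maps, pattern image, CI stability mask, loadings,
scores, statistics) are written under `results/demo/` as NIfTI/TSV. The
same chain is available as one call, `run_pipeline(config)`, driven by a
strictly-validated YAML/list config and emitting a JSON manifest that
makes re-runs bit-identical.

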