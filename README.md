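# dissectr

Virtual dissection and tractometry of commissural white matter tracts,
with the complete structure–cognition statistics layer that typically
follows — built as a desk-scale, fully testable R pipeline.

## What problem this solves

Commissural tracts such as the dorsal hippocampal commissure (DHC) cross
between the hemispheres beneath the corpus callosum and, near the
hippocampus, run alongside the fornix — so seeding tractography from a
hippocampal region reconstructs a mixture of pathways. The semiautomated
remedy is ROI-gated *virtual dissection*: deterministic streamlines are
seeded from one hippocampus (64 supersampled grid points per voxel),
retained only if they pass through the contralateral hippocampal AND
region, discarded if they touch any NOT region blocking fornix, callosal
or cingulum routes, and the procedure is repeated seeding from the other
side. Each reconstruction is then cut down to a *transverse segment*
between sagittal planes five slices either side of the midline, where
the tract is unambiguous, and per-side mean FA/MD are combined by vertex
count:

    VW mean = (N_L2R * mean_L2R + N_R2L * mean_R2L) / (N_L2R + N_R2L)

Across a cohort, those vertex-weighted tract metrics are correlated with
memory scores (bootstrap CIs, Bonferroni–Holm over each 6-test family),
significant associations are compared across tracts with one-tailed
Steiger Z tests and Cohen's q, regional gray matter volumes are
ICV-adjusted (raw − β·(ICV − mean ICV)) before their own 15-test family,
and sensitivity analyses add Spearman's rho, boxplot-rule outlier
re-runs, and a default Bayes factor for the key correlation
(stretched-beta prior, width 1).

`dissectr` implements all of it: tensor fitting (log-linear LLS, FA/MD
maps, principal-eigenvector peak field), deterministic angle-thresholded
tracking over per-voxel peak fields, SEED/AND/NOT gating with declarative
slab ROIs, bilateral orchestration, segment cutting, vertex-weighted
tractometry, and the statistics layer — plus a synthetic multi-bundle DWI
phantom (commissural arc, fornix-like decoy, second commissure, full
protocol preset, ground truth) and a cohort simulator with planted
effects, so the whole pipeline runs and is tested without any external
imaging data. Standard formats are supported throughout: NIfTI,
FSL-style bvals/bvecs, TRK/TCK tractograms, YAML configs, delimited
cohort tables.

## Worked example

```r
library(dissectr)

# synthetic phantom: commissural arc + fornix-like decoy + 2nd commissure
phantom <- build_phantom("dhc_default")
maps    <- compute_fa_md(fit_tensor_lls(phantom$dwi))
params  <- tracking_params(step_size_mm = 0.5, angle_threshold_deg = 60,
                           supersample_per_axis = 4)
dissect_and_measure(phantom$field, phantom$truth$protocols$dhc,
                    params, maps$fa, maps$md)
#>   tract   n_l    n_r  fa_l  fa_r     md_l     md_r fa_vw    md_vw
#>     dhc 59048 130532 0.318 0.318 0.001478 0.001478 0.318 0.001478
```

The gated, midline-cut reconstruction recovers the phantom's assigned
bundle microstructure exactly (FA 0.318, MD 1.478e-3 mm²/s); the decoy
bundle, which touches the same seed blob, contributes nothing because its
route crosses a NOT slab.

```r
cohort <- make_cohort(cohort_spec(n_subjects = 95), seed = 1)
res    <- run_structure_cognition_analysis(cohort, seed = 1)
res
#> <structure_cognition_analysis> n = 95 complete cases
#>   12 structure-cognition correlations (1 significant after Holm, alpha = 0.05)
#>   1 dependent-correlation comparison(s)
#>   15 volume-cognition correlations (0 significant)

dplyr::filter(tidy(res), significant)
#>   tract metric task       r  ci_lo   ci_hi p_holm
#>   dhc   md     cpwm  -0.279 -0.458 -0.0675 0.0369
```

The simulator plants a single negative MD–memory correlation
(rho = −0.269) in the first tract; the pipeline flags exactly that pair
after Holm correction, compares it against the second tract's
corresponding correlation (Steiger Z, Cohen's q), and leaves all 15
ICV-adjusted volume–cognition tests null. The Bayesian re-analysis of
the planted effect size at the cohort's n:

```r
correlation_bf10(r = -0.269, n = 95)
#>    bf10   ci_lo    ci_hi      r  n kappa
#>   3.924 -0.4383 -0.06725 -0.269 95     1
```

i.e. the data are about 3.9 times as likely under a nonzero correlation
than under the null, with a 95% credible interval for rho of roughly
(−0.44, −0.07).

`autoplot(res)` draws the forest-style correlation panel;
`plot_tractogram()` gives quick projection renderings of reconstructions.

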