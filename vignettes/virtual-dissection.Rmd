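---
title: "Virtual dissection and tractometry of commissural tracts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual dissection and tractometry of commissural tracts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissectr)
```

## The problem

Commissural white matter tracts such as the dorsal hippocampal commissure
(DHC) and the anterior commissure (AC) carry interhemispheric fibres that
are hard to isolate: near the hippocampus the DHC shares the alveus with
the fornix, so naive tractography from a hippocampal seed reconstructs a
mixture of pathways. The semiautomated answer is *virtual dissection*:
deterministic streamline tractography seeded from one hippocampus, gated
by an AND region in the contralateral hippocampal/parahippocampal area and
by NOT regions that exclude fornix, corpus callosum and cingulum routes;
repeated with seeding from the other side; then reduced to a *transverse
segment* between two sagittal planes five slices either side of the
midline, where the tract is unambiguous. Per-subject microstructure (FA,
MD) sampled along that segment feeds a structure–cognition correlation
analysis across a cohort.

`dissectr` implements that entire pipeline at desk scale. Real
acquisitions are replaced by a synthetic multi-bundle diffusion phantom
with known ground truth and by a cohort simulator with planted effects, so
every stage — tensor fitting, tracking, gating, cutting, tractometry, and
the statistics layer — is exercised and tested without external data.

## The diffusion model and the phantom

Inside each bundle, diffusion is modelled by a single tensor with
eigenvalue triple $(\lambda_1, \lambda_2, \lambda_3)$, $\lambda_1$
aligned with the local bundle tangent. The noise-free signal for gradient
direction $g$ at b-value $b$ is $S = S_0\,e^{-b\,g^\top D g}$. Where two
bundles share a voxel the signal is an equal-weight mixture of the two
single-tensor decays, and the voxel's orientation field carries both unit
tangents — the simplest construction that forces the tracker to resolve a
crossing. Elsewhere inside the brain mask the tensor is isotropic with
diffusivity $d_{iso} = 0.9 \times 10^{-3}\,\mathrm{mm^2/s}$ (a
grey-matter-like background), and the default acquisition is a single
$b = 1000\,\mathrm{s/mm^2}$ shell of 30 Fibonacci-lattice directions plus
6 $b=0$ volumes at $S_0 = 1000$.

The default (`"dhc_default"`) layout places, on a
$48 \times 58 \times 48$ grid of 1.25 mm isotropic voxels (an
`"exvivo"` flavour uses $60 \times 72 \times 60$ at 0.5 mm):

* a **commissural arc** joining two bilateral "hippocampal" seed blobs
  across the midline, with eigenvalues solved so its tensor reproduces the
  reference human DHC microstructure (FA 0.318, MD
  $1.478\times10^{-3}\,\mathrm{mm^2/s}$);
* a **fornix-like decoy** that leaves the *left* blob only, at about
  72° to the arc's tangent, and descends through a whole-section coronal
  NOT slab — the gating problem the protocol exists to solve;
* a **straight second commissure** (AC-like: FA 0.439, MD
  $0.854\times10^{-3}$) crossing lower, which the decoy traverses at
  roughly 79°, providing crossing voxels away from any seed region.

The decoy's departure angle matters: anything under the 60° tracking
threshold would let streamlines switch bundles at the junction, and the
dissection test would no longer measure what the gates do. The blob radius
(2.5 voxels) is kept below the arc radius (4.5 voxels) so most seeds start
well inside the tube and the transverse segment samples essentially pure
bundle voxels; trilinear interpolation near a tube boundary blends bundle
and background values, which is the main reason fatter bundles recover
assigned MD more accurately.

What the phantom does **not** emulate: susceptibility and eddy artifacts,
motion, partial-volume CSF, axonal dispersion, and anatomically realistic
curvature or calibre. Passing tests therefore demonstrate correctness of
the pipeline's geometry, gating logic and arithmetic — not robustness to
real acquisition physics.

## Tensor fitting and the peak field

Fitting is ordinary least squares of $\log S$ on the six unique tensor
elements plus intercept, per voxel (weighted or robust variants are
deliberate non-goals: the acceptance battery rests on noise-free
exactness, where the log-linear inversion is exact). Multishell input is
reduced to $b \le 1000$ by the default shell predicate, mirroring the
practice of deriving DT-MRI maps from the 1000-shell; volumes with
$b < 50$ count as $b=0$. Nonpositive signals are floored at a
machine-epsilon-scaled value before the log; voxels with non-finite
results are flagged, never silently zeroed. Eigenvalues come from a
vectorised trigonometric closed form for symmetric $3\times3$ matrices
(validated against `eigen()`), MD is their mean, FA the
Basser–Pierpaoli normalised dispersion clipped to $[0,1]$ (negative
eigenvalues are clamped for FA only, and flagged). The tracker's
substrate is an orientation field: from a tensor fit, one peak per voxel
(principal eigenvector, amplitude FA, support FA $\ge$ `fa_floor`,
default 0.1); from the phantom, the ground-truth multi-peak field.

## Tracking

Deterministic and RNG-free by construction. Seeds are the $k^3$ centres
of a uniform subdivision of every seed voxel ($k = 4$, i.e. 64 initiation
points per voxel, matching the supersampled protocol). Propagation is
bidirectional Euler integration at a fixed step (0.5 mm human flavour,
0.1 mm ex vivo): at each step the resident nearest-voxel peak (or its
negation) minimising the turning angle from the incoming direction is
followed; an arm ends on leaving the support, on a turning angle above
the 60° threshold, or on exhausting the 250 mm combined length budget;
tracks shorter than 3 vertices are rejected with a reason code.
Design points that were genuinely open and the choices made:

* **nearest-voxel peak lookup, no interpolation** — interpolating
  *sets* of peaks across voxels is ill-posed without a fibre-bundle
  correspondence model;
* **Euler, not RK4** — steps are at most 0.4 voxel, and the acceptance
  battery is phantom-geometric rather than curvature-critical;
* **turning angle per step, not per mm** — the common semantics of
  deterministic trackers at fixed step;
* the per-step angle check plus fixed step size means interior
  inter-vertex spacing is *exactly* the step, which the invariant tests
  assert to $10^{-6}$ mm.

## Dissection

Gating keeps a streamline iff it has a vertex in every AND mask and no
vertex in any NOT mask (NOT dominates; order preserved). Vertex-in-mask
is a nearest-voxel membership test — with steps at or below half a voxel
a segment cannot jump a mask it geometrically crosses, which is the
documented limitation of not doing segment–voxel intersection. An
alternative AND semantics requiring *termination* inside the gate
(`and_mode = "terminate"`) is available because engine descriptions are
ambiguous between passage and termination; passage-through is the
default. Bilateral orchestration seeds from the SEED blob with the
contralateral blob as AND, then swaps them. Declarative slab ROIs
(axial/coronal/sagittal, whole-section or boxed, with carve-out boxes for
the whole-plane-except-the-temporal-lobes idiom) rasterize
deterministically; an ROI that rasterizes empty is an error, not a
silent no-op.

Segment cutting retains, per streamline, every maximal vertex run
*strictly* between the two sagittal planes (open interval: boundary
vertices are excluded deterministically and side-symmetrically). The
five-slice midline offset is interpreted in native voxel units —
$\pm 6.25$ mm at 1.25 mm voxels, $\pm 2.5$ mm ex vivo — because the
protocol states slice counts, not millimetres; a mm override exists.

## Tractometry

FA and MD are sampled at each retained vertex by trilinear interpolation
(nearest-neighbour behind a flag for sensitivity checks; intersecting a
segment with a voxel-wise map does not by itself fix an interpolation
scheme, and trilinear is the smoother default). Per-side means pool *vertices*, not
streamlines — the combination formulas are written in vertex counts — and
the two sides combine as the vertex-weighted mean

$$\overline{m}_{vw} \;=\;
\frac{N_{L\to R}\,\overline{m}_{L\to R} + N_{R\to L}\,\overline{m}_{R\to L}}
     {N_{L\to R} + N_{R\to L}},$$

applied once for FA and once for MD. A subject with both segments empty
raises an undefined-metric error and is excluded downstream, mirroring
per-subject availability accounting.

## The statistics layer

* **ICV adjustment**: $\mathrm{adj}_i = \mathrm{raw}_i -
  \beta(\mathrm{ICV}_i - \overline{\mathrm{ICV}})$ with $\beta$ the OLS
  slope; the output is exactly uncorrelated with ICV (asserted to
  $10^{-10}$) and keeps the raw mean.
* **Pearson families**: r with the $t$-transform two-sided p
  ($df = n-2$); 95% CI as the percentile interval over 1000 paired
  bootstrap resamples (percentile chosen over BCa as the default, since
  common statistics packages differ on which they report and percentile
  is the more reproducible choice; BCa is a flag). Per tract, the 2 metrics × 3 tasks family is Holm-corrected at
  $m = 6$; ICV-adjusted volume–cognition correlations at $m = 15$.
* **Dependent correlations**: significant associations are compared
  against the other tract's corresponding correlation with Steiger's
  $\bar Z_1^*$ (pooled-$\bar r$ covariance approximation — the common
  recommendation; the overlap correlation $r_{12}$ is a required input),
  one-tailed in the direction of $r_1 - r_2$, reported with Cohen's
  $q = |\operatorname{atanh} r_1 - \operatorname{atanh} r_2|$.
* **Sensitivity block**: Spearman's rho (average ranks, then the Pearson
  machinery), a boxplot-rule ($1.5\times$IQR) outlier flagging with a
  re-run — never the headline analysis — and the default Bayes factor.
* **Bayes factor**: $BF_{10}$ for a Pearson correlation under a
  stretched-beta prior of width $\kappa = 1$ on $(-1,1)$
  (nondirectional), computed by adaptive quadrature of the exact sampling
  density of $r$ (the Gauss $_2F_1$ evaluated by series; an independent
  trapezoid quadrature agrees to $10^{-6}$ relative in tests). The 95%
  central posterior credible interval for $\rho$ comes from a 4001-point
  grid posterior.

## The cohort simulator

Defaults are the reference cohort's published scales: $n = 95$ complete
cases; DHC MD $1.478 (0.163)\times10^{-3}$, DHC FA 0.318 (0.059), AC MD
$0.854 (0.051)\times10^{-3}$, AC FA 0.439 (0.050); task scores 35.79
(2.78), 112.15 (14.34), 110.15 (11.49); ICV 1 587 548 (176 652) mm³ with
five temporal-lobe regional volumes at their published means and SDs. One
effect is planted: (DHC MD, first task score) are bivariate normal with
$\rho = -0.269$ by default; every other structure–cognition pair is null.
Volumes are $\gamma \cdot \mathrm{ICV}$ plus independent noise with
$\gamma$ set per region so the volume–ICV correlation is 0.5 — the
adjustment exists because regional volumes are routinely confounded by
head size, and 0.5 is a typical reported magnitude for that confound. The
simulator emulates second-moment structure only: no skew, no outliers, no
missingness beyond what a user introduces, and no shared variance among
tasks — so calibration results here bound what the pipeline does on
clean, not on messy, data.

## Numerical choices and degenerate inputs

* All voxel/world conversions run through the affine; voxel indices are
  0-based and name voxel centres. Streamlines live in world mm; TRK's
  corner-based voxel-mm convention is normalised at the I/O boundary.
* Tractogram coordinates survive TRK/TCK round trips to float32
  precision (tested at $10^{-5}$ mm on a 70 mm field of view).
* Ties in peak selection resolve to the first slot (deterministic);
  the isotropic-voxel eigenvector defaults to $+x$ but is excluded from
  support by any positive `fa_floor`.
* Degenerate gates: an empty gated tractogram is a warning plus an empty
  result — the dissection layer, not the tracker, decides failure; both
  bilateral passes empty constitutes reconstruction failure for the
  subject.
* $_2F_1$ series: converges for the needed argument range
  $z = (1+\rho r)/2 < 1$ with $c = n - 1/2$ large; non-convergence is a
  hard numeric error with diagnostics, never a silent fallback.

## Problem sizes used by the test battery

The shipped tests run the human-flavour phantom ($48^2\times58$ grid, 36
volumes), a bilateral dissection of roughly $10^4$ supersampled seeds,
2000 simulated cohorts at $n = 95$ for calibration of the mean sample
correlation and bootstrap CI coverage, and 1000 null cohorts for the
Holm family-wise error check. These sizes were chosen so the full suite
documents the method at cohort scale while remaining a desk-scale run.

## Known limitations

Vertex-in-mask gating can in principle miss a sub-step mask crossing if
the step exceeds half a voxel (not the shipped defaults). The tracker has
no FOD-amplitude stopping criterion because it consumes discrete peak
fields, not FODs; constrained spherical deconvolution itself is out of
scope, and on real multishell data the tensor-derived single-peak field
is a weaker substrate than CSD in crossing regions — the phantom's
ground-truth field is the intended tracking substrate for protocol
validation. The Steiger comparison requires $r_{12}$, which published
reports rarely print; it must come from the cohort data themselves.
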