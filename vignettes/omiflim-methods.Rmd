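---
title: "Methods: optical metabolic imaging analysis with omiflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical metabolic imaging analysis with omiflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiflim)
```

omiflim implements the analysis chain for label-free optical metabolic
imaging (OMI) of immune cells in vivo: per-pixel fluorescence-lifetime
fitting of NAD(P)H and FAD autofluorescence, reporter-based single-cell
segmentation and activation scoring, per-cell optical endpoints, and
cohort-level inference that respects cells nested in larvae nested in
experiment days. A synthetic TCSPC generator with known ground truth
drives every stage, so the whole pipeline is testable without microscope
data. This vignette records the models, the defaults and why they were
chosen, and the numerical decisions a maintainer would want to know.

## The decay model and its assumptions

TCSPC instruments histogram photon arrival times into `n_bins` bins over
one laser repetition period. The per-pixel histogram is modelled as a
two-component exponential decay convolved with the instrument response
function (IRF):

$$ I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C,
   \qquad \alpha_1 + \alpha_2 = 1, $$

where the short and long lifetimes correspond to the free and
protein-bound pools of NAD(P)H (and the converse for FAD), and $C$ is a
constant background per bin. The two-component form is the standard
interpretation for these coenzymes; detector afterpulsing and dark counts
are absorbed into $C$, which matches the fitted model and keeps the
forward and inverse problems consistent. `model_decay()` evaluates the
shape at bin centres, convolves with the IRF, and rescales so the
decay-component counts over the recorded window sum to the amplitude —
making photon conservation exact by construction rather than approximate.

**Time axis.** Acquisition uses 256 time bins; the bin width and laser
period are instrument properties, so the default window is 12.5 ns
(80 MHz repetition, typical of the femtosecond sources used for
two-photon NAD(P)H/FAD excitation), giving ~48.8 ps bins. Both are
configurable via `time_axis()`.

**IRF.** The measured second-harmonic IRF of such systems has a full
width at half maximum of about 260 ps. `make_irf()` uses a Gaussian
stand-in parameterised only by FWHM (default 260 ps) and peak position
(default bin 25), normalised to unit sum. `irf_fwhm()` measures the FWHM
by linear interpolation of the half-maximum crossings; for the default
kernel it reproduces the construction parameter within one bin width.

**Incomplete decay.** With lifetimes below ~6 ns and a 12.5 ns window,
the previous pulse's tail contributes under 1% of amplitude, so the
single-pulse (linear convolution) model is the default. A `wrap` option
models periodic excitation via a circular convolution of the wrapped
bi-exponential — circular, because a linearly convolved wrap cannot place
the previous pulse's tail in pre-peak bins. The renderer and fitter must
use the same setting; `run_all()` plumbs one flag through both.

## Per-pixel fitting

`fit_pixel()` minimises Neyman-weighted least squares — per-bin weights
$1/\max(y_i, 1)$, the weighting used by the commercial SPCImage-style
analysis this mirrors — with a bounded Levenberg–Marquardt optimiser
(`minpack.lm`), an analytic Jacobian, and an FFT-cached convolution. A
Poisson-deviance objective (`objective = "poisson"`) is available and
agrees with the weighted fit at high counts (asserted in the tests).

- **Bounds** (`fit_bounds()`): $\tau_1 \in [0.05, 1]$ ns,
  $\tau_2 \in [1, 6]$ ns, $\alpha_1 \in [0, 1]$, offset $\ge 0$. The
  disjoint lifetime boxes enforce $\tau_1 < \tau_2$ by construction, so
  no post-hoc component swapping is needed.
- **Initials** (`fit_init()`): NAD(P)H $\tau_1 = 0.4$, $\tau_2 = 2.5$ ns;
  FAD $\tau_1 = 0.4$, $\tau_2 = 2.0$ ns; $\alpha_1 = 0.7$ —
  literature-typical free/bound values. Amplitude starts at the
  background-corrected total count; the offset at the mean of the
  pre-IRF-rise bins (or the minimum count when the IRF peaks too early to
  leave any).
- **Convergence.** Tolerances $10^{-8}$ on the objective and parameters,
  at most 1000 function evaluations per run. The Neyman objective has a
  long shallow valley in $(\tau_1, \tau_2, \alpha_1)$ — a single LM run
  can stop there prematurely — so the fit performs adaptive polish
  restarts (up to 8, each starting at the current solution, stopping when
  the relative improvement drops below $10^{-9}$). The test suite holds
  the result to a brute-force grid oracle. Non-convergent pixels are
  returned flagged, never thrown, and `fit_image()` masks them invalid.
- **Identifiability.** For a truly single-exponential decay the
  component split is degenerate but the mean lifetime
  $\tau_m = \alpha_1\tau_1 + \alpha_2\tau_2$ remains identifiable; tests
  assert $\tau_m$, not the split, in that limit.

`fit_image()` applies a per-image background threshold (default: at
least 500 total photons per fitted pixel — the interactive analysis set
this by eye per image, so it is explicit and recorded here) and optional
non-overlapping $k \times k$ binning, which pools block photons before
fitting and reports the block fit on every pixel of the block. Block
(rather than sliding-window) pooling was chosen because the original
tool's binning semantics are unreported and blocks are $k^2$ cheaper;
the variance of $\tau_m$ estimates then scales inversely with the pooled
photon count, which the tests verify.

## Segmentation and activation scoring

The in vivo procedure is reproduced as explicit, recorded steps: divide
the mCherry macrophage-marker image by its brightest pixel, threshold at
0.15, fill holes, label 8-connected components, and drop objects under
25 pixels (`segment_macrophages()`). Rescale-by-max makes the result
invariant under positive intensity scaling. Touching cells are not split
(no declumping) — a deviation from interactive editing, noted here; a
user-supplied mask can override the computed segmentation, standing in
for manual correction. In the infected model, bacteria also carry
mCherry; `exclude_bacteria()` removes pixels above a bacteria threshold
(default 0.6 x the image maximum — bacteria are the brightest objects)
from every cell before averaging.

A cell is TNFα+ when any pixel inside it exceeds the GFP threshold.
"Any signal" needs a number: the default is median + 3 x MAD of the GFP
intensity over background pixels, falling back to the background maximum
when the MAD is zero (as happens when detector noise is clipped at
zero). `tnfa_proportional_area()` provides the larva-level
quantification: GFP+ area within marker-positive area.

## Per-cell endpoints

The optical redox ratio is computed per pixel as
$I_{NAD(P)H} / (I_{NAD(P)H} + I_{FAD})$, using fitted decay-component
counts (offset removed, because the offset is background light, not
coenzyme signal). Computing per-pixel ORR and then averaging per cell
differs from a ratio of summed intensities; the per-pixel-then-average
convention is used because endpoints are averaged per cell the same way.
All endpoints are arithmetic means over the pixels valid in the relevant
map; cells with no valid pixel are dropped with a warning and cells
below 5 valid pixels are flagged `low_coverage` but retained, so the
statistics stage can filter explicitly.

The OMI index of cell $i$ is
$ORR_i/\langle ORR\rangle + \tau^{N}_{m,i}/\langle\tau^{N}_m\rangle -
\tau^{F}_{m,i}/\langle\tau^{F}_m\rangle$ with means taken over a declared
normalisation group. Whether such means should pool an experiment, a
day, or a condition is a genuinely open choice; the default pools all
cells in the analysis and the grouping is recorded in the output
(`omi_index(by = ...)` for per-day or per-condition centring). By
construction the mean OMI over each normalisation group is exactly 1,
which the tests assert to $10^{-12}$.

## Cohort statistics

Every data point is one macrophage. `fit_glm()` fits ordinary least
squares with treatment indicators, the experiment day as a fixed
blocking factor, and an interaction when two experimental factors are
present. Cells from one larva are correlated, so uncertainty comes from
a cluster-robust CR1 sandwich covariance (cluster-summed scores,
$G/(G-1) \cdot (n-1)/(n-k)$ scaling) with a $t_{G-1}$ reference — the
flavor is a documented choice since none is named in the source
analyses. With singleton clusters this reduces exactly to HC1.
Estimated group means weight the day blocks equally; with
`log_transform = TRUE` the outcome is modelled on the natural-log scale
and means and pairwise contrasts are back-transformed, so comparisons
read as fold changes. No multiplicity adjustment is applied anywhere.
`glm_diagnostics()` emits residual-versus-fitted and normal-quantile
tables and flags a doubling of residual SD across fitted-value quartiles
— the situation in which the log transform is warranted. Larva-level
outcomes (e.g. proportional area) can be analysed with the same
fixed-block GLM without clustering; the mixed-model path used elsewhere
for those outcomes is out of scope, a documented deviation.

## What the synthetic generator emulates — and what it does not

`make_scene()` places non-overlapping disk "macrophages" with per-cell
decay parameters drawn from per-group distributions; TNFα+ cells default
to 15% shifts in the directions reported for activated (M1-like)
macrophages: lower ORR (via the NAD(P)H photon budget), lower NAD(P)H
$\tau_1$ and $\tau_2$, higher $\alpha_1$; FAD lifetimes unshifted. Cell
radii default to 5–9 px on 256 x 256 fields; baseline photon budgets are
5000 expected decay photons per pixel per channel with a background
offset of 0.1 counts/bin. `render_decay_cube()` draws independent
Poisson counts around the IRF-convolved expectation (variance/mean of
per-bin counts is asserted to lie in [0.9, 1.1] over 1000+ pixels);
`render_reporter_images()` renders filled masks for mCherry and for GFP
in TNFα+ cells with optional additive noise.
`simulate_imaging_cohort()` nests fields in larvae in days, with
log-scale day shifts and shared per-larva deviations (defaults 0.02)
applied to lifetimes and budgets, inducing the within-larva correlation
the statistics must absorb; `simulate_cohort()` generates the same
nesting directly at the endpoint-table level (defaults: day SD 0.05,
larva SD 0.05, cell SD 0.10 on the log scale, giving intraclass
correlation $\sigma_l^2 / (\sigma_l^2 + \sigma_c^2)$, which tests check
against an ANOVA decomposition).

Not emulated: membrane-localised (CAAX) marker patterns (cells render as
filled disks, so segmentation is exercised on intensity only), cell
motion and shape irregularity, depth attenuation and scattering,
wavelength mixing, mCherry bleed-through into lifetime channels, and
spatially varying background. Passing tests therefore demonstrate that
the computations are correct and that the chain recovers injected
effects under idealised geometry and pure Poisson statistics — not that
segmentation or fitting would be robust to the artefacts of real tissue.

## Problem sizes and determinism

Every stochastic stage takes an explicit seed and records it in output
metadata; identical configurations reproduce byte-identical artifacts
(manifest checksums are compared in the tests). The test suite uses desk
scales chosen to keep the full run to minutes on one CPU: a
200-replicate recovery study at 5000 photons/pixel (median relative
$\tau_m$ error under 10%), noiseless $10^6$-photon recovery within 1%,
500 simulated cohorts of 16 larvae for 95% CI coverage (asserted within
[92%, 98%]), 500 simulations for the robust-versus-classical SE
ordering under intraclass correlation 0.5, and 20 end-to-end runs on
64 x 64 fields with 2 x 2 binning for sign-and-significance recovery of
the injected activation signature. These sizes are the package's own
validation choices; larger studies only tighten the same checks.

## Known limitations

- One decay model (two components, constant offset); no phasor analysis,
  no three-component or global fitting, no fluorophore unmixing.
- Segmentation is a global threshold with connected components; no
  declumping of touching cells, no tracking, no 3-D.
- The synthetic generator's realism limits are listed above; in
  particular real IRFs are asymmetric, while the stand-in is Gaussian.
- Per-pixel fitting in R costs a few milliseconds per pixel; full-frame
  256 x 256 fits are feasible but slow — use `binning`, the photon
  threshold, or crop to regions of interest for interactive work.
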