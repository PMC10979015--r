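---
title: "Methods: compartmentalized mRNA decay kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmentalized mRNA decay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbodykinetics)
```

# The kinetic model

After synchronous induction of decay, a tagged mRNA population distributes
between the cytoplasm and P-bodies. We model the per-cell mean counts
$n_{CT}(t)$ and $n_{PB}(t)$ with the linear system

$$\dot n_{CT} = -(k_{CT} + k_R)\, n_{CT} + k_L\, n_{PB}, \qquad
  \dot n_{PB} = k_R\, n_{CT} - (k_{PB} + k_L)\, n_{PB},$$

where $k_{CT}, k_{PB}$ are first-order decay rates in each compartment and
$k_R, k_L$ are recruitment and release rates (all per hour; the
experimental time courses span 0–9 h). Counts are continuous: they model
replicate means of per-cell counts, not individual molecules. The initial
P-body count is 0 by default — before induction essentially no reporter
RNA resides in granules — and the initial cytoplasmic count enters as an
amplitude.

`solve_trajectory()` evaluates the closed-form solution. For nonnegative
rates the rate matrix has real eigenvalues
$\lambda_{1,2} = \tfrac12\big(-(a+b) \pm \sqrt{(a-b)^2 + 4 k_R k_L}\big)$
with $a = k_{CT}+k_R$, $b = k_{PB}+k_L$, and the matrix exponential is
assembled from the spectral projectors. When
$|\lambda_1-\lambda_2| < 10^{-12}\max(|\lambda_1|,|\lambda_2|,1)$ the
matrix may be defective, so the solver switches to the degenerate limit
$e^{Mt} = e^{\lambda t}(I + t(M - \lambda I))$; random parameter sweeps do
hit this neighbourhood, and continuity across the switch is tested.
Because the system is a Metzler matrix acting on nonnegative initial
conditions, the exact solution is nonnegative; the implementation clamps
the last few ulps of floating-point undershoot at zero.

Four nested variants are considered: the full model, `no_pb_decay`
($k_{PB}=0$, granules as pure storage), `equal_decay` ($k_{PB}=k_{CT}$, no
kinetic advantage), and `no_leave` ($k_L=0$, recruited RNA decays in
place). Each constrained variant has three free rates. Two decaying
exponentials against two observed curves carry limited information, which
is why the unconstrained four-rate fit is weakly identified and the
constrained scenarios are the scientifically meaningful comparison.

# Fitting

`fit_variant()` minimizes the weighted residual sum of squares over both
curves jointly with a bounded Levenberg–Marquardt optimizer
(`minpack.lm::nls.lm`, rates bounded below by zero). Choices that the data
do not dictate, and how we made them:

* **Weights.** The dispersion is the standard deviation of the replicate
  means per timepoint — the same quantity the error bars show. Late
  timepoints approach zero counts with near-zero spread, which would
  otherwise dominate the fit, so each curve's dispersion is floored at 5%
  of that curve's maximum (configurable, `sigma_floor_frac` /
  `sigma_floor_abs`). `reduced_chi_square()` itself applies no floor.
* **Amplitudes.** By default the initial cytoplasmic count is fitted as
  one extra free parameter and the initial P-body count is fixed at zero;
  `fit_n0 = "fixed"` instead pins the amplitude to the $t=0$ measurement.
  Free parameters are counted accordingly (4 for constrained variants with
  a free amplitude, 5 for the full model).
* **Multi-start.** The optimizer runs from 16 seeded initializations by
  default: one data-driven guess plus rates drawn log-uniformly from
  $[10^{-3}, 10]$ per hour. The best deviance wins; the fit records
  whether any start converged. Identical seed, data and options give
  bitwise-identical results because the random-number state is isolated
  and restored.
* **Model comparison.** `compare_models()` ranks variants by reduced
  $\chi^2 = \chi^2/(N-p)$ with $N$ the pooled number of points of both
  curves. Exact ties go to fewer parameters, and a simpler variant is
  flagged *sufficient* when its reduced $\chi^2$ is within a factor 1.2
  (configurable) of the best more-complex variant — a pragmatic parsimony
  rule, not a formal test. AIC/BIC were deliberately left out of the
  primary interface.
* **Degenerate input.** An all-zero time course is an error, not a fit.

`bootstrap_uncertainty()` offers two reporting modes: resampling the
biological replicates with replacement and refitting (percentile
intervals), or fitting each replicate separately and reporting the mean ±
SD of the fitted parameters across replicates — the conventional summary
when only 3–4 replicates exist.

# The count simulator

`simulate_counts()` emulates the sampling structure of a fixed-cell
time-course experiment: timepoints $\{0, 0.25, 0.5, 1, 2, 4, 6, 9\}$ h,
4 biological replicates, 200 cells per timepoint — sizes chosen to match
the scale of such experiments (hundreds of cells per condition, 3–4
replicates). Noise has two levels:

* per-cell counts are negative binomial around the replicate mean with
  size 10 (CV ≈ 35% at mean 100); `Inf` gives Poisson, `NA` disables
  dispersion for noiseless limits;
* each replicate carries one shared lognormal factor (CV 10%) applied to
  both compartments, representing replicate-to-replicate expression-level
  differences. A shared factor rescales the whole curve without distorting
  its shape, which is how replicate spread manifests in this kind of data;
  making the factors compartment-independent would instead inject shape
  noise. Both CVs are calibration choices, not measured values.

The pooled `time_course` carries the mean of replicate means and its
standard deviation, exactly what the fits weight by.

# The image renderer and quantification

`render_stack()` builds a two-channel $(z, y, x)$ stack: the RNA channel is
a sum of 3D Gaussian PSFs (default $\sigma_{xy} = 1.3$ px,
$\sigma_z = 2.5$ px, plausible for a 60×/1.4NA widefield system at 107 nm
pixels and 300 nm z-steps) over an autofluorescent background with Poisson
shot noise and Gaussian read noise; the P-body channel holds soft blobs at
granule loci. Placement enforces two physical constraints: planted single
molecules keep 4 px of lateral separation when their z planes are within
$2\sigma_z$ (molecules closer than the diffraction limit are a single spot
to any detector, and would simply be undercounted), and P-body centers
keep four blob-widths of lateral separation (overlapping organelles would
have merged, and axially stacked granules are not additive in a max
projection). Granule molecules share their granule's z plane with small
lateral jitter, so the max-projected granule intensity is exactly linear
in molecule content.

Quantification follows the standard smFISH pipeline:

1. **P-body segmentation** — Laplacian-of-Gaussian filtering of the
   max-projected IF channel, thresholded at a quantile of the response
   (0.995 default; Otsu available) with a robust guard of median +
   5 MAD so featureless images segment nothing, then connected-component
   labeling with a 4 px minimum area.
2. **Spot detection** — difference-of-Gaussians band-pass at the PSF
   scale, 26-neighbourhood local maxima above median + 8 MAD, greedy
   deduplication within 2 px laterally / 1 plane axially.
3. **3D Gaussian fitting** — per candidate, a local least-squares fit of
   amplitude, background, sub-voxel center and widths. Spots are accepted
   when the amplitude exceeds 3 local-noise SDs and the widths stay
   strictly inside $[0.5, 3]\times$ the nominal PSF; candidates within the
   ROI half-width of a border are rejected.
4. **Unit intensity** — the median integrated max-projection intensity of
   accepted spots outside P-bodies, computed from the fit as
   $2\pi A \sigma_{xy}^2$. A windowed pixel sum measures the same
   quantity but is contaminated by neighbouring spots at realistic spot
   densities; the fit-based integral is robust to that, which is why it is
   the default.
5. **Granule RNA equivalents** — integrated max-projected RNA intensity
   over each segmented region, grown by 2 px so the diffraction-limited
   tails of the granule signal are included, minus a local background
   (median of a 2 px annulus outside all grown regions, scaled by area),
   divided by the unit intensity.
6. **Partitioning** — cytoplasmic count = accepted spots inside the cell
   mask and outside P-bodies; P-body count = summed RNA equivalents. Cell
   masks are accepted as input; a whole-field default covers the rendered
   single-cell scenes.

The LoG scale, thresholds and minimum area are configuration parameters
with the defaults above; the source experiments do not specify them.

# Live-cell traces

`simulate_livecell()` emulates 5-min-interval imaging over 2 h: each
cell's trace is the analytic $n_{PB}(t)$ times per-cell lognormal factors
(amplitude CV 30%, detection CV 10%). A photostress mode multiplies
$k_{PB}$ by a factor < 1 to emulate slowed granule dissolution under
light stress. `aggregate_traces()` divides each trace by its own maximum
and averages across cells with the standard error.

The default generator deliberately puts all trace noise at the cell level.
With independent per-frame noise, two things break regardless of the noise
amplitude: normalizing by the observed maximum divides by an upward-biased
order statistic, depressing the whole normalized trace by an amount that
does not shrink with more cells; and the per-frame discrepancy between the
aggregated mean and the population curve, measured in units of its own
standard error, is a t-statistic whose size is independent of the noise
scale — so "the mean tracks the analytic curve within 2 SE at every one of
25 frames" would fail somewhere by chance in most realizations. Per-frame
jitter (`frame_noise_cv`) and per-cell kinetic heterogeneity
(`kinetic_cv`) are available as options for users who want those effects;
they are off by default, and tests of the 2-SE tracking property hold only
under the default cell-level noise model.

# Problem sizes in the test suite

The suite verifies: closed-form/RK4 agreement over 100 random parameter
sets (tolerance $10^{-8}$ relative); exact exponential limits; noiseless
parameter recovery to $10^{-4}$ for every variant; median rate-recovery
error under the default noise over 200 simulations; model-variant
preference over 100 simulations; reduced-$\chi^2$ calibration over 200
simulations with correctly specified Gaussian noise; spot-detection F1 and
per-cell count recovery over 20 rendered stacks (96×96×12 voxels, 50
spots, 2 granules) plus a 20-molecule calibration granule; and trace
aggregation against the analytic granule curve. These sizes keep the full
suite under a couple of minutes while leaving comfortable statistical
margins.

# Known limitations

* The renderer uses point-sampled Gaussians, not pixel-integrated optics,
  and models no aberrations, camera gain statistics or cell-shape realism.
  Passing recovery tests on rendered stacks therefore demonstrates the
  correctness of the quantification logic, not robustness to every
  real-microscope artifact.
* Spots closer than the diffraction limit merge and are undercounted; the
  default scenes plant resolvable spots, so real data with very high spot
  density will need intensity-based multi-spot decomposition that this
  package does not implement.
* Max-projection granule quantification undercounts when distinct granules
  overlap laterally at different depths; the renderer avoids creating that
  geometry, and real fields where it occurs should be quantified per
  z-plane instead.
* The kinetic model is deterministic and compartment-homogeneous: no
  per-molecule stochasticity, no spatial diffusion, no transcription (the
  experiments it models inhibit transcription at induction).
* The full four-rate variant is retained for nesting checks but is weakly
  identified on smooth biexponential data; constrained variants are the
  intended workhorses.
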