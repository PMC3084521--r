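---
title: "Gated-decay models and fitting methods in flimgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated-decay models and fitting methods in flimgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimgate)
```

## The measurement and the model

A wide-field time-gated FLIM instrument records, for every pixel, the
number of photons detected while a gated optical intensifier is open
during a window of width $W$ (typically 2000–3000 ps) starting at a delay
$d_g$ after the excitation pulse. A seven-gate protocol is typical: five
gates sampling the decay, one *offset* gate recording the background with
the gate far from the decay, and one *motion-check* gate repeating the
first delay at the end of the acquisition so that sample movement can be
detected by comparing two nominally identical frames.

The emission of a pixel is modelled as a multiexponential decay with a
constant per-gate background,
$$ I(t) \;=\; I_0 \sum_{i=1}^{n} \alpha_i\, e^{-t/\tau_i} + Z,
   \qquad \sum_i \alpha_i = 1 ,$$
with lifetimes $\tau_i$ (ps), normalised pre-exponential factors
$\alpha_i$, initial intensity $I_0$ and offset $Z$ (counts per gate). The
unnormalised amplitudes are $a_i = I_0\alpha_i$. Components are kept in
canonical order ($\tau_1 \ge \tau_2 \ge \dots$, ties broken by the larger
amplitude); components closer than 1 ps are merged with a warning, since
they are not identifiable from gated data.

The expected counts in a decay gate are the boxcar integral over the gate
window of the decay convolved with the instrument response function (IRF),
in the *periodic steady state* of the excitation source. Three IRF
representations are supported: an ideal impulse with offset $t_0$, a
Gaussian of given FWHM (a convenient stand-in for IRFs measured with
sub-150-ps-lifetime dyes such as DASPI or erythrosin B), and a measured
IRF given as (time, weight) samples. The offset gate expects $Z$ alone,
and a motion-check gate duplicates the expectation of its partner decay
gate; motion-check gates never enter fitting residuals.

### Exact gate integrals instead of a quadrature grid

All three IRF kinds admit closed forms for the gated integral, and
`flimgate` uses them rather than numerical convolution on a time grid:

* *delta*: the boxcar integral
  $\tau\,(e^{-a/\tau} - e^{-b/\tau})$ over gate $[a, b]$;
* *Gaussian*: the exponentially-modified-Gaussian antiderivative
  $\int c_1 = \tau\,[\Phi((t-t_0)/\sigma) - c_1(t)]$ where
  $c_1$ is the EMG, evaluated on the log scale via
  `pnorm(..., log.p = TRUE)` so that neither the $e^{\sigma^2/2\tau^2}$
  factor nor the erfc tail under- or overflows;
* *measured*: a weight-sum of shifted delta antiderivatives (a measured
  IRF is exactly a mixture of impulses). A measured IRF sampled more
  coarsely than a tenth of the gate width is rejected as unable to resolve
  the gate edges.

This is both faster and more accurate (machine precision versus the
$O(h^2)$ error of a trapezoidal grid); the test suite checks the Gaussian
path against an independent 1-ps midpoint double quadrature to $10^{-6}$
relative.

### Incomplete decays

At a 60 MHz repetition rate ($T \approx 16\,667$ ps) fluorophores with
nanosecond lifetimes have not fully decayed when the next pulse arrives.
In the periodic steady state the single-pulse response $c_1$ is summed
over all previous pulses; for gates lying inside one period this collapses
exactly to the geometric factor
$$ s(\tau, T) = \frac{1}{1 - e^{-T/\tau}} \;\ge 1 $$
(`steady_state_factor()`), which is how the correction is usually stated.
`flimgate` implements the general pulse sum, which additionally covers
gates that *wrap* past the period boundary and there pick up the next
pulse's early, bright emission. Two consequences are worth noting:

* for a mono-exponential with a delta IRF and non-wrapping gates, the
  factor is a pure amplitude rescaling and is absorbed by $I_0$ — ignoring
  it then biases *nothing but* $I_0$;
* for a gate straddling the period boundary the effect on the decay
  *shape* is large. The incomplete-decay acceptance check therefore uses a
  schedule whose last gate crosses $T$: fitting with the periodic model
  recovers $\tau = 3000$ ps to within 0.5 % (residual small-sample bias of
  the nonlinear estimator), while a model without the correction
  underestimates the lifetime by roughly 570 ps — the sign is *negative*
  because the model, unable to explain the wrapped gate's excess with a
  per-gate constant, shortens the decay and inflates the background.

A conservation identity pins the calibration: contiguous gates covering
$[0, T)$ with a delta IRF integrate to exactly $I_0\sum_i\alpha_i\tau_i$
photons per period.

## Fitting

All fits minimise the weighted residual sum of squares
$\chi^2 = \sum_g w_g\,(y_g - \hat y_g)^2$ over the decay gates plus, when
present, the offset gate (which constrains $Z$; optionally $Z$ can be
pinned to the offset-gate counts). The default weighting is Poisson.
Weights based on the *observed* counts ($1/\max(y,1)$) are known to bias
lifetime estimates downward at low counts, because downward-fluctuating
gates get overweighted; `flimgate` therefore re-estimates the weights from
the fitted expectations ($1/\max(\hat\mu,1)$) and refits, twice by default
(`n_reweight`). At 300 photons per pixel this reduces the bias of a
two-component donor-fixed global fit on the FRETing-donor lifetime from
roughly +28 % to under 2 %.

### Variable projection

For fixed lifetimes the model is linear in $(a_1,\dots,a_n, Z)$, and the
amplitudes of one pixel depend only on that pixel's counts. Global fitting
with image-wide shared lifetimes therefore eliminates the amplitudes by
independent small weighted linear solves per pixel — non-negative, using
an exact active-set enumeration for up to three columns (every support
subset has a closed-form batched solve; the feasible candidate of smallest
$\chi^2$ is the NNLS optimum) — and searches only over the lifetimes with
a Levenberg–Marquardt iteration on the reduced residuals (finite-difference
Jacobian, relative $\chi^2$ tolerance $10^{-8}$, at most 100 outer
iterations, multi-start from a log-spaced lifetime grid). Memory holds the
per-pixel solutions and residuals only, so it scales linearly with pixel
count. Any subset of lifetimes can be fixed, e.g. the donor lifetime from
donor-only wells; with all lifetimes fixed the fit is a single linear
pass. The test suite verifies on 8×8 images that the variable-projection
optimum coincides with a brute-force simultaneous optimisation over the
lifetimes *and* every pixel's amplitudes (194 parameters), to $10^{-6}$
relative $\chi^2$.

Per-pixel mono-exponential image fitting uses the same profile idea in a
vectorised form: a shared 48-point logarithmic lifetime grid brackets each
pixel's minimum, and a vectorised golden-section iteration (40 steps)
refines every pixel simultaneously; amplitude and offset come from
closed-form 2×2 weighted solves. Lifetime search bounds default to a tenth
of the gate width up to the repetition period.

### Degenerate and boundary cases

Duplicate candidate lifetimes (within $10^{-9}$ relative) make the design
rank-deficient and are rejected during the search; fitted components
closer than 1 ps are merged with a warning. Amplitudes and background are
constrained non-negative; a fitted fraction of exactly zero is therefore
common on donor-only data, and the *mean* of such clipped per-pixel
fractions is positively biased at low photon counts (half-normal
folding) — binned or global estimates should be used for null checks, and
the null tests use 2000 photons per pixel. Pixels below `min_photons`
(default 300, the budget at which a mono-exponential fit is generally
considered reliable) are masked rather than fitted.

### Linked time-series fits

Two linkage modes handle FLIM time courses (e.g. calcium dyes with bound
and unbound states): *linked lifetimes* shares both lifetimes across the
whole series while every pixel at every timepoint keeps its own
amplitudes; *linked ratio* shares the amplitude ratio across the series
while lifetimes are shared within each timepoint but free between
timepoints. The second mode is an interpretation choice: the alternative
reading (lifetimes also linked across the series) is available by simply
running the first mode, so both workflows are exposed. Both donor
calibration paths (global single-exponential fit, per-pixel mean) are
likewise exposed, since free global fits and fixed-donor fits give
slightly different donor lifetimes on real data and there is no principled
criterion for preferring one.

## Mean lifetimes and FRET quantities

The summary lifetime of a multiexponential fit is amplitude-weighted,
$\bar\tau = \sum_i \alpha_i\tau_i$, which is proportional to the photon
yield per excitation; the intensity-weighted alternative
$\sum_i\alpha_i\tau_i^2 / \sum_i\alpha_i\tau_i$ is available as an option
(`mean_lifetime(type = "intensity")`). FRET efficiency is the
donor-quenching ratio $E = 1 - \tau_{DA}/\tau_D$; it is a convenience
output — gated instruments really measure the lifetime contrast — and
apparent negative efficiencies ($\tau_{DA} > \tau_D$) are reported with a
warning rather than clipped, so refractive-index or homo-FRET artefacts
stay visible. The effective efficiency map is
$\alpha_2 (1 - \tau_2/\tau_D)$ per pixel (the fraction of FRETing donors
times their efficiency); an intensity-weighted variant is also emitted.

## Plate automation

The prescan logic mirrors instrument seek behaviour: fields are scanned in
acquisition order and qualify when their above-threshold pixel fraction
reaches `min_fraction`, stopping after `n_required` fields; a shortfall
flags the well as having insufficient cells, which is how empty wells
arise on plate maps. The qualifying fraction has no canonical value and is
plain configuration. Well aggregation pools pixel lifetimes across a
well's fields without field weighting (each pixel counts once) and
summarises them with mean, SD and a 10-ps-bin histogram. The motion-check
metric is the $L_1$ distance between the unit-normalised motion-check and
partner frames (equivalently mean absolute difference over mean level);
it is zero for identical frames, sits at the shot-noise floor
(≈0.1–0.15 at 300 photons per pixel) for a static sample, and the default
tolerance of 0.2 flags genuine motion.

## Tomographic FLIM

Projections are parallel-beam line integrals about the plane centre
(telecentric assumption), with detector sampling equal to the voxel
pitch. Filtered back-projection filters each projection with the discrete
band-limited ramp (Ram–Lak kernel; $h(0)=1/4$, odd taps
$-1/(\pi^2 n^2)$), optionally apodised with a Hamming window, and
back-projects with bilinear interpolation, scaled by $\pi/n_{\rm angles}$.
On a disc phantom the 360-angle round trip reconstructs the interior
(eroded by 2 px to exclude partial-volume boundary pixels) to better than
1 % RMS; fidelity degrades monotonically as angles are removed.

Per-gate volumes are reconstructed independently, negative reconstructed
values are clipped at zero, voxels below 10 % of the maximum summed
intensity are masked, and the remaining voxels are fitted
mono-exponentially across gates with *uniform* weights — reconstructed
values are dense linear combinations of many counts and are no longer
Poisson. The voxel fits omit the background term: the reconstruction has
no physical per-gate offset, and fitting a non-negative $Z$ against pure
reconstruction noise systematically drags lifetimes down (about −5 % on a
noisy homogeneous phantom; removing the term removes the bias). With
noiseless projections the reconstruct-then-fit pipeline recovers a
homogeneous phantom's lifetime to machine-level accuracy, so the remaining
error on noisy data is statistical, not geometric; reconstruct-then-fit
and fit-then-reconstruct commute only in that homogeneous
mono-exponential case.

## The synthetic generator, and what passing tests do not show

Every scenario returns its ground truth alongside the data, and all
recovery tests consume only (data, schedule, IRF). Poisson noise is the
only noise source by default; the gated-intensifier excess noise, CCD read
noise, detector nonlinearity and bleed-through of real instruments are not
emulated, nor are optical sectioning, photobleaching or cell motility. The
default seven-gate schedule (width 2000 ps, decay delays
0/1000/2500/4500/7000 ps, one offset and one motion-check gate, 60 MHz
repetition) represents a typical protocol; actual instrument delay
settings vary and are configuration, not calibration. The two-dye mixture
plate uses an invented rhodamine-like lifetime pair (1500/3900 ps) —
recovery is always judged against the returned truth, never against
literature dye values. Simulated FRET cell fields place an elevated
FRETing fraction on elliptical-annulus "membranes" (CFP-like defaults:
donor 2580 ps, FRETing donor 1586 ps); real membrane geometry, expression
heterogeneity and acceptor maturation are outside the model. Consequently,
passing recovery tests demonstrate estimator correctness and photon-budget
behaviour under the stated noise model, not instrument performance on
cells.

Scenario sizes used by the test-suite and acceptance runs are chosen for
statistical sufficiency at interactive runtimes: 8×8 images for oracle
equivalence (20 instances), six 24×24 fields at 300 photons per pixel for
the donor-fixed recovery, 24 wells of 16×16 fields for the mixture plate,
12 replicates of 16×16 binned fields for the incomplete-decay contrast,
48×48 phantoms at 180 angles for tomography, and five 100×100 wells at
300 photons per pixel for the lifetime-resolution figure (twice the pooled
standard error of the well means, ≈1 ps under these conditions — amply
below the ≈20 ps regime that matters in practice).

## Known limitations

Stretched-exponential and lifetime-distribution models, phasor analysis,
Bayesian or maximum-likelihood (non-least-squares) estimation, spectral or
acceptor-channel FRET corrections, scattering/diffuse tomography and any
instrument control are out of scope. Fits with more than three linear
components per pixel fall back to a slower per-pixel NNLS path. The
per-pixel incidental-parameter bias of global fits (each pixel contributes
its own amplitude and offset nuisance parameters) vanishes with photons
per pixel, not with pixel count; at or below ~100 photons per pixel,
binned-ROI fits are the more reliable tool.
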