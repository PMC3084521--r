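# flimgate

Analysis of time-gated fluorescence lifetime imaging (FLIM) data from
automated wide-field plate readers, in R.

High-content FLIM instruments sample each pixel's fluorescence decay with a
handful of wide time gates behind a gated optical intensifier: typically
seven gates of 2–3 ns width, one of them an offset (background) image and
one a motion-check duplicate. The readout of interest is usually a donor
lifetime contrast — e.g. FRET shortening the donor decay near the cell
membrane — extracted from only 5–7 numbers per pixel at a few hundred
photons each. `flimgate` implements the computational chain such
instruments need:

* **Forward model.** Multiexponential decays
  `I(t) = I0 (α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂) + …) + Z` with `Σαᵢ = 1`,
  convolved with a delta, Gaussian or measured instrument response function
  (IRF) and integrated over boxcar gates. Incomplete decays at high
  repetition rates are handled exactly through the periodic steady state,
  which reduces to the geometric pile-up factor `1/(1 − e^(−T/τ))` for
  gates inside one period and also covers gates that wrap past the next
  excitation pulse.
* **Fitting.** Weighted nonlinear least squares with Poisson weights
  re-estimated from the fitted expectations: per pixel (`fit_mono_pixel`,
  `fit_multi_pixel`, `fit_image_per_pixel`), per region of interest after
  photon binning (`fit_binned_roi`, `per_roi_analysis`), and globally
  across whole images or plates with shared lifetimes by **variable
  projection** (`varpro_global_fit`): the per-pixel amplitudes are
  eliminated through independent small non-negative linear solves, so the
  outer Levenberg–Marquardt search runs over the lifetimes alone and memory
  scales linearly with pixel count. Time series can be fitted with linked
  lifetimes or a linked amplitude ratio (`linked_series_fit`).
* **FRET readouts.** Donor calibration from donor-only wells
  (`calibrate_donor`), FRETing-donor-fraction maps (`fretting_fraction_map`),
  FRET efficiency `E = 1 − τ_DA/τ_D` and effective-efficiency maps
  `α₂ (1 − τ₂/τ_D)`, condition comparisons.
* **Plate automation logic.** Intensity images, threshold masks, prescan
  field selection, motion checks, per-well aggregation and plate maps.
* **Tomographic FLIM.** Parallel-beam forward projection, filtered
  back-projection with a band-limited ramp (optional Hamming apodisation),
  and per-voxel lifetime fitting of reconstructed gate volumes
  (`tomo_flim`).
* **Synthetic data.** Every input above can be generated with known ground
  truth (`simulate_stack`, `make_mixture_plate`, `make_fret_cell_field`,
  `make_series`, `make_well_phantom`), with Poisson noise and seeded
  reproducibility.

## Worked example: a donor-fixed global FRET fit

Simulate three donor-only fields (EGFP-like, 2516 ps) and three fields
containing a FRETing fraction (47 % of donors at 1068 ps), calibrate the
donor, then run the donor-fixed two-component global fit:

```r
library(flimgate)

donor <- lapply(1:3, function(s)
  simulate_stack(sim_scenario(taus = 2516, dims = c(24, 24),
                              photons_per_pixel = 300, seed = s))$stack)
cal <- calibrate_donor(donor, opts = fit_options(min_photons = 0))
cal

sample <- lapply(4:6, function(s)
  simulate_stack(sim_scenario(taus = c(2516, 1068), alphas = c(0.53, 0.47),
                              dims = c(24, 24), photons_per_pixel = 300,
                              seed = s))$stack)
g <- varpro_global_fit(sample, n_components = 2,
                       opts = fit_options(min_photons = 0,
                                          fixed_taus = c("1" = round(cal$tau_D))))
summary(g)
fretting_fraction_map(g)$mean_alpha2
fret_efficiency(cal$tau_D, g$taus[2])
```

which prints

```
Donor calibration: tau_D = 2512.8 ps (global_fit over 3 field(s))
Shared lifetimes (ps): 2513.0 (fixed), 1104.3
Mean amplitude fractions: 0.543, 0.457
Global chi2 5033.57 over 1728 pixels
FRETing donor fraction (field 1): 0.465
FRET efficiency of the FRETing population: 0.561
```

The calibrated donor lifetime lands within 0.2 % of the 2516-ps truth; the
free FRETing-donor lifetime (1104 ps vs 1068 ps truth) and the FRETing
fraction (0.465 vs 0.47) are recovered from ~300 photons per pixel — the
regime in which per-pixel double-exponential fitting would fail, which is
the point of sharing the lifetimes globally.

A thin command-line wrapper with `simulate-plate`, `fit`, `prescan`,
`fret`, `series-fit`, `opt` and `report` subcommands is installed at
`system.file("cli", "flimgate", package = "flimgate")`.

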