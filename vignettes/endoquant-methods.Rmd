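---
title: "endoquant: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{endoquant: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

endoquant quantifies five kinds of measurement that recur in studies of
ultrafast synaptic-vesicle endocytosis. This vignette explains what each
pipeline computes, the assumptions behind it, the parameters that
matter, and the choices we made where more than one reasonable design
existed. Every empirical claim here is one the package's own test suite
or `scripts/acceptance.R` recomputes.

## Conventions

Images are numeric matrices; the first index is the row (y, increasing
downward), the second the column (x). Pixel centers sit at integer
1-based (row, col) coordinates — the natural R convention — and all
physical distances are obtained by multiplying pixel distances by the
field's `pixel_size` (nm/px). The default pixel size of 30 nm/px makes
the conventional 30 × 30 px bouton ROI cover 0.81 µm². Since distances
are differences of coordinates, the index origin has no effect on any
reported quantity.

## STED distance analysis

**Problem.** In two-color STED images of presynaptic boutons, a
reference channel (an active-zone scaffold such as Bassoon) defines a
boundary, and a query channel (a GFP-tagged endocytic protein) forms
puncta whose position relative to that boundary is the readout: puncta
of proteins that act at the endocytic zone sit at or just outside the
active-zone edge.

**Pipeline.** `sted_distances()` chains:

1. `gaussian_denoise()` — convolution with a normalized Gaussian
   (default σ = 1.2 px) to suppress Poisson shot noise. Borders use
   reflective padding, which maps constants to themselves and conserves
   the intensity of interior objects (checked to 0.1%).
2. `blind_deconvolve()` — blind Richardson–Lucy: multiplicative updates
   alternate between the PSF and the image, 10 iterations per round, two
   rounds, the second restarting from the original image with the first
   round's returned PSF ("enhanced PSF"). The initial PSF either comes
   from `estimate_psf_from_spots()` — a background-subtracted,
   peak-aligned average of isolated sub-resolution spots such as
   non-specifically bound antibodies — or defaults to a σ = 1 px
   Gaussian. RL updates are positivity-preserving and flux-conserving
   (within 1% for interior objects); a delta-function PSF and constant
   images are exact fixed points, which the tests assert.
3. `find_local_maxima()` — strict 8-neighbor maxima above a prominence
   floor, greedily thinned to a minimum mutual separation (default
   3 px). Plateaus are never maxima.
4. `extract_half_max_boundary()` — the sub-pixel iso-contour at
   `background + 0.5 × (peak − background)`, traced by marching squares
   with linear interpolation (`grDevices::contourLines`). Measuring half
   maximum *above local background* rather than absolute half maximum
   matters whenever the offset is nonzero; the background is the median
   of the region's dimmest decile. Among closed contours enclosing the
   seed, the smallest-area one is kept; a contour cut by the ROI edge
   raises a classed condition and the bouton is excluded and logged,
   since its true boundary is unknowable.
5. `signed_distance()` — minimum Euclidean point-to-segment distance
   over the contour polyline, × pixel size, negated when the punctum
   lies inside the polygon (winding-number test). The tests verify both
   parts against independent oracles: a scalar brute-force minimum over
   a 10,000-point resampling (agreement ≤ 1e−6 nm) and an even–odd
   ray-casting sign test, over 100 random punctum/contour pairs.
6. `colocalization_summary()` — fraction of puncta at distance ≤ 0,
   fraction of boundaries containing ≥ 1 punctum, and the ECDF of
   signed distances.

**Choices that were genuinely open.**

* *Prominence floor in the pipeline.* `find_local_maxima()` defaults to
  3 × the background SD, a standard choice on raw or denoised images.
  After Richardson–Lucy deconvolution, however, the background is
  compressed toward zero and an SD-based floor admits amplified noise
  grains. The pipeline therefore floors each ROI at 20% of its own peak
  height above background (`prominence_frac`), which is stable across
  the processing chain. Both defaults are configurable.
* *Punctum localization.* Distances are measured from the local-maximum
  pixel center, not a sub-pixel centroid; with ~30 nm pixels this
  contributes at most ~0.5 px of quantization, visible in the recovery
  RMSE budget below.
* *Merged clusters.* When one closed half-max contour contains two
  called maxima, the brighter maximum seeds the boundary and the
  structure is treated as a single cluster.

**Synthetic fields.** `gen_sted_field()` places one Gaussian blob
(reference; default σ = 4 px, i.e. FWHM ≈ 280 nm, a realistic
active-zone extent) and one point punctum (query) per bouton on a tile
grid, at a stated signed radial offset from the blob's analytic
half-maximum circle. Both channels are convolved with a Gaussian PSF
analytically — so the pre-noise image equals the object-model integral
exactly — and Poisson-sampled at the requested photon budget (default
10⁴ photons per object over ~2 photons/px background). With 200 puncta
at offsets −120…+120 nm, the full pipeline recovers the planted offsets
with RMSE ≤ 1 px; the acceptance script reports ≈ 0.35–0.41 px across
seeds. What this does *not* exercise: real antibody labeling noise,
non-Gaussian active-zone shapes, neighboring-synapse crosstalk, or
chromatic misregistration.

## EM morphometry

Annotations are coordinate traces recorded on single synaptic profiles:
a plasma-membrane polyline, a postsynaptic-density segment, closed
vesicular traces (with a visual ferritin flag), and open pit traces
whose endpoints mark the pit base. The on-disk dialect is JSON with
pixel coordinates and a `scale_nm_per_px` field; `parse_annotation()`
converts to nm and rejects feature names outside the fixed vocabulary.

* `classify_vesicle()`: diameter < 60 nm → synaptic vesicle; 60–100 nm
  inclusive → large endocytic vesicle; > 100 nm → endosome. The class
  boundaries are inclusive on the LEV side, reading "60–100 nm" as a
  closed interval. Diameter of a closed trace is measured as twice the
  mean vertex distance from the vertex centroid (exact for circles).
* `pit_geometry()`: width = distance between the trace's endpoints (the
  base chord); depth = maximum perpendicular distance from any trace
  point to that chord. These operators are this package's definition —
  the measurement used upstream of published pit-size figures is rarely
  stated — and they are validated against their own analytic oracles: a
  semicircle of radius r returns width 2r and depth r exactly, an
  exhaustive point-to-chord scan reproduces the depth, and both
  quantities are invariant under rigid motion to 1e−9 nm.
* `summarize_time_course()`: per condition × time point, mean count per
  profile, SEM = SD/√n (NA for n = 1), and the stimulus-evoked increase
  relative to the same condition's unstimulated group (the `no_stim`
  label), which is required and its absence an error.

`gen_em_profiles()` builds pits as circular arcs with exact analytic
base width and depth (depth ≤ width/2 gives a shallow U; depth >
width/2 an Ω profile with a constricted neck), randomly rotated and
translated, and vesicles as exact-diameter circles — so noiseless
round-trips of geometry and counts are exact by construction. It does
not attempt realistic membrane ultrastructure, section-thickness
effects, or annotation jitter; it provides exactly the statistical
structure the counting and geometry operators assume.

## pHluorin kinetics

pHluorin reports exo/endocytosis as a fluorescence rise at stimulation
and a decay as vesicles are retrieved and reacidified. The chain is:

1. `subtract_background()` — rolling-ball estimate via grayscale
   opening with a disc (default radius 50 px; implemented with
   `EBImage::opening` after affine rescaling to [0, 1], which commutes
   with flat-structuring-element morphology).
2. `extract_roi_traces()` — mean intensity over discs of 2 µm²
   (single-bouton ROIs); a pixel belongs to a disc when its center is
   within the radius; discs clipped by the frame edge are errors.
3. `estimate_bleach_rate()` — `F(t) = F0·e^{−Kt}` fitted to a
   no-stimulation control (log-linear start, Levenberg–Marquardt
   refinement; the log-linear solution is used directly when the
   refinement is degenerate, e.g. on noiseless data).
4. `bleach_correct()` — multiply by `e^{tK}`, t in seconds from imaging
   start. This is algebraically exact: correcting then uncorrecting
   returns the input to machine precision.
5. `normalize_trace()` — min–max between the frame immediately before
   the stimulus (→ 0) and the post-stimulus peak (→ 1). The peak is the
   global maximum within 5 s after the stimulus. The result is
   invariant to positive affine rescaling of the raw trace.
6. `fit_decay()` — one-phase decay on the post-peak frames,
   `N(t) = (Y0 − plateau)·e^{−(t−t_peak)/τ} + plateau`, with Y0 free.
   Fitting Y0 (rather than pinning the curve to 1 at the detected peak
   frame) matters: noise biases the *detected* peak upward and late, and
   a pinned two-parameter fit under the default study conditions
   (τ = 15 s, 5% noise) underestimates τ by ~13%, while the free-Y0 fit
   recovers the median τ within ~2%. The percent remaining at 40 s from
   imaging start is read from the raw normalized sample at the nearest
   frame, not from the fitted curve — the raw sample is what a
   per-cell readout uses, and the choice is recorded here because
   either is defensible.

`fit_trace_cohort()` applies steps 4–6 per trace and excludes, with
reasons, traces that fail (no dynamic range, non-convergence, τ at a
parameter bound) — mirroring how outlier traces are dropped in
practice. Time is measured from imaging start (t = 0 at the first
frame) for both the bleach correction and the 40 s readout.

`gen_phluorin_traces()` draws the model trace — 5 s baseline, step
rise, exponential decay to a plateau, multiplied by `e^{−Kt}` — plus
additive Gaussian noise, at 2 Hz for 60 s by default; `amplitude = 0`
yields a proper no-stimulation control. Under the default conditions
(n = 50, τ = 15 s, plateau 0.3, K = 0.005/s, noise SD 0.05) the median
fitted τ is within 5% of truth and the median plateau within 0.05. The
generator does not emulate stimulus-train structure, vesicle-pool
heterogeneity, or focus drift.

## CSP mapping, saturation binding, SRM

**CSP.** `compute_csp()` pairs free and bound peak lists by residue and
evaluates `Δδ = √(ΔδH² + (ΔδN/5)²)` — the conventional combined ¹H/¹⁵N
shift with nitrogen down-weighted by 5 for its wider ppm range. It is
invariant to the sign of the shifts. Residues present in only one list,
or undetectable (prolines have no amide proton), are reported as
missing, never imputed to zero — imputation would depress the profile
mean and corrupt site calling. `call_perturbed_residues()` uses the
strict profile mean as threshold ("higher than average"), computed per
profile; `k_sd` raises it to mean + k·SD for conservative calls. The
CSP used for calling is the one at the final (saturating) titration
point; intermediate points are retained for plotting saturation curves.

`gen_titration_series()` moves site residues toward per-residue maximal
composite shifts along a saturation curve in the ligand ratio
(fast-exchange population-weighted average), splits each composite
shift into H and N components at a random angle, and leaves non-site
residues fixed. Site calling returns exactly the planted residues
without noise, and recalls ≥ 95% of them at 10:1 shift-to-noise.

**Binding.** `fit_binding_curve()` fits one-site specific binding
`S = Bmax·[L]/(Kd + [L])` without a nonspecific term — appropriate for
a washed plate assay reporting a single affinity per construct — by
Levenberg–Marquardt from a half-maximum starting guess, requiring ≥ 4
distinct concentrations and flagging fits at parameter bounds. The fit
is scale-equivariant (signal × c ⇒ Bmax × c, Kd unchanged, to 1e−6
relative). On a noiseless 8-point doubling dilution the planted Kd
(e.g. 44 nM) is recovered within 0.1%; with 2% noise and 4 replicates
the mean error across 100 seeds is ~3%, within the 10% guarantee. No
weighting is applied; with uniform additive noise ordinary least
squares is the maximum-likelihood estimator.

**SRM.** `srm_protein_abundance()` sums transition areas into peptide
totals and peptide totals into protein totals; relative abundances are
fractions of the most abundant protein, and zero-total proteins get an
undefined (NA) ratio rather than a misleading 0. The aggregation
conserves the grand sum exactly and is invariant to row order.
`gen_srm_table()` splits planted totals across ≥ 3 peptides × ≥ 3
transitions with fractions pinned to sum exactly to 1, so conservation
round-trips are exact.

## Problem sizes and determinism

Every generator is a pure function of its `sim_config()` (seed, pixel
size, frame rate): the same configuration yields bit-identical outputs,
and the session RNG stream is untouched. The test suite and the
acceptance script run the STED recovery at 200 synapses (a ~615 × 574
px field), the pHluorin cohort at 50 traces, the Kd recovery at 100
seeds, and the geometry oracles at 100 random configurations — sizes at
which every stochastic guarantee has comfortable margin while the whole
suite completes in well under a minute per pipeline on a single CPU.

## Known limitations

* The STED chain assumes an isotropic Gaussian PSF model for its
  defaults; empirical PSFs are supported through
  `estimate_psf_from_spots()` but anisotropic depletion patterns are
  not modeled by the generator.
* Boundary extraction returns one boundary per seeded maximum; touching
  active zones that share a half-max contour are merged by design.
* `pit_geometry()` presumes the annotator traced base-to-base; a trace
  that overshoots the base chord inflates the width.
* The decay model is a single exponential; endocytosis with two
  kinetically distinct components will show plateau/τ trade-offs that
  the fit diagnostics (`at_bound`, excluded traces) only partially
  surface.
* CSP site calling with the strict-mean threshold is deliberately
  liberal; use `k_sd` ≥ 1 when profiles contain many perturbed
  residues, since a large site inflates the mean and can mask weaker
  shifts.
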