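# endoquant

Quantification pipelines for synaptic endocytosis experiments, packaged
as tested, reusable R functions. The package covers the five analysis
chains that this kind of study runs on its raw data:

1. **STED distance analysis** — where do endocytic-protein puncta sit
   relative to the active zone? Two-channel STED fields are denoised
   (Gaussian, σ = 1.2 px), blind Richardson–Lucy deconvolved (10
   iterations, two rounds chained through the returned "enhanced" PSF),
   the active-zone boundary is traced as the sub-pixel iso-contour at
   half the local maximum's intensity above background, and each query
   punctum gets a signed minimum distance to that contour (negative =
   inside), in nm.
2. **EM morphometry** — per-synaptic-profile counts of endocytic pits,
   ferritin-positive synaptic vesicles (< 60 nm), large endocytic
   vesicles (60–100 nm) and endosomes (> 100 nm) from annotated
   coordinate traces, plus pit width (base chord) and depth (maximum
   perpendicular distance to the chord), and stimulus-evoked increases
   over the unstimulated control.
3. **pHluorin kinetics** — rolling-ball background subtraction, ROI
   trace extraction, photobleach correction `F_corr(t) = F(t)·e^{tK}`
   with `K` fitted from a no-stimulation control, min–max normalization
   between the pre-stimulus frame and the post-stimulus peak, and a
   one-phase decay fit `N(t) = (Y0 − plateau)·e^{−(t−t_peak)/τ} +
   plateau` giving τ and the percent of peak fluorescence remaining at
   40 s.
4. **NMR chemical-shift perturbation** — per-residue
   `Δδ = √(ΔδH² + (ΔδN/5)²)` between free and titrated ¹⁵N-HSQC peak
   lists, with binding-site residues called where Δδ exceeds the profile
   mean.
5. **Binding & SRM** — one-site saturation fits
   `S = Bmax·[L]/(Kd + [L])` for equilibrium affinity, and
   transition→peptide→protein peak-area aggregation for SRM relative
   quantification.

None of the analyses require real microscope or spectrometer output: a
family of seeded generators (`gen_sted_field()`, `gen_phluorin_traces()`,
`gen_em_profiles()`, `gen_titration_series()`, `gen_binding_curve()`,
`gen_srm_table()`) produces every input with recorded ground truth, so
each stage is validated by parameter recovery. See the methods vignette
(`vignettes/endoquant-methods.Rmd`) for the models, assumptions and
numerical choices.

## Worked example

Simulate 25 boutons whose puncta are planted at known signed offsets
(−120 … +120 nm) from the active-zone boundary, then measure them back:

```r
library(endoquant)

sim <- gen_sted_field(sim_config(42), n_synapses = 25,
                      punctum_offsets = c(-120, -60, 0, 60, 120),
                      photon_budget = 1e4)
res <- sted_distances(sim$field, sim$truth[, c("roi_row", "roi_col")],
                      max_puncta_per_roi = 1)
head(round(res$records[, c("roi", "distance_nm")], 1), 5)
#>   roi distance_nm
#> 1   1      -119.5
#> 2   2       -74.9
#> 3   3       -30.5
#> 4   4        61.8
#> 5   5       109.3
res$summary$fraction_puncta_within
#> [1] 0.56
```

The measured distances track the planted offsets to a fraction of a
pixel (30 nm), and the colocalization summary reports which fraction of
puncta fall inside their boundary. The same recovery pattern holds for
the other chains:

```r
bc <- gen_binding_curve(sim_config(42), kd = 44, bmax = 2,
                        noise_sd = 0.04, replicates = 4)
fit_binding_curve(bc$curve)
#> <binding_fit> Kd = 42.8 nM, Bmax = 1.98

ph <- gen_phluorin_traces(sim_config(42), n_traces = 20)
fits <- fit_trace_cohort(ph$traces, bleach_K = 0.005)
median(fits$fits$tau)    # planted tau = 15 s
#> [1] 14.9
```

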