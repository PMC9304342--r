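# csdwi

Desk-scale simulation of compressed-sensing reconstruction for liver
diffusion-weighted MRI (DWI), for imaging scientists who want to study —
with full ground truth — a trade-off that matters clinically: **L1-regularized
iterative SENSE raises SNR and stabilizes ADC maps, but its wavelet
denoising can level small focal liver lesions into the parenchyma, and
signal averaging does not bring them back.**

The package provides the whole chain as tested R code:

1. **Digital liver phantoms** — deformed-ellipse parenchyma, curvilinear
   vessels, circular focal lesions (3–15 mm) with per-pixel `S0` and ADC
   ground truth, and the mono-exponential signal model
   `S(b) = S0 · exp(−b · ADC)` over `b = 0/100/400/800` s/mm²
   (ADC stored in 10⁻³ mm²/s).
2. **Multi-coil Cartesian encoding** — smooth RSS-normalized coil
   sensitivities, unitary centered FFT, equidistant single-shot-EPI style
   undersampling at acceleration factor `R`, complex Gaussian noise, NSA
   averaging, and signal-free *noise scans* (the sequence "run without RF
   excitation").
3. **Both reconstructions** —
   * `sense_recon()`: conventional SENSE, solved exactly by per-group
     unfolding when `R` divides the line count (conjugate gradients
     otherwise);
   * `l1_sense_recon()`: minimizes
     `½‖Ex − y‖² + λ_abs‖Ψ_detail x‖₁`
     with an orthogonal Daubechies-4 wavelet `Ψ`, by FISTA with
     function-value restart (monotone objective, exact soft-thresholding
     proximal step, power-iteration step size).
4. **Quantification** — ROI statistics, noise-map SNR with enforced
   operator provenance (signal and noise map must share method, λ_abs and
   mask), per-pixel log-linear ADC fitting, and analytic SENSE noise
   propagation as an independent oracle.
5. **Lesion detectability** — `run_sweep()` scores contrast retention and
   CNR over diameter × contrast × λ × R × NSA × seed;
   `nsa_rescue_test()` measures whether averaging rescues suppressed
   lesions.
6. **Reader-study statistics** — weighted Cohen's kappa with CI and
   Landis–Koch bands, plus paired-comparison wrappers.

## Worked example

A volunteer-style comparison on one noisy realization: conventional SENSE
at `R = 2` versus wavelet-L1 SENSE at `R = 3`, NSA 4, with a 5 mm
hyperintense lesion (20 % contrast) in the phantom.

```r
library(csdwi)

spec <- phantom_spec(grid_size = 96, vessel_fraction = 0.03,
                     lesion_specs = list(lesion_spec(c(43, 38), diameter_mm = 5,
                                                     S0_contrast = 0.2)))
truth  <- make_phantom(spec)
series <- simulate_dwi_series(truth)              # b = 0/100/400/800
coils  <- make_coil_maps(8, 96, seed = 2)

k2 <- add_noise(undersample(encode(series, coils, n_averages = 4), 2), sd = 8, seed = 3)
k3 <- add_noise(undersample(encode(series, coils, n_averages = 4), 3), sd = 8, seed = 3)
n2 <- simulate_noise_scan(k2, sd = 8, seed = 4)
n3 <- simulate_noise_scan(k3, sd = 8, seed = 4)

conv <- reconstruct_series(k2, coils, recon_config("sense"))
l1   <- reconstruct_series(k3, coils, recon_config("l1_sense", lam = 0.01,
                                                   max_iter = 60, tol = 1e-5))
nconv <- reconstruct_series(n2, coils, recon_config("sense"))
nl1   <- reconstruct_series(n3, coils,
           recon_config("l1_sense", lam_abs = l1$provenance$lam_abs,
                        max_iter = 60, tol = 1e-5))   # identical operator

rois <- auto_parenchyma_rois(truth, n_rois = 2, radius_px = 5, seed = 5)
snr_from_noise_map(conv, nconv, rois[[1]], rois[[1]], b_index = 1)
snr_from_noise_map(l1,   nl1,   rois[[1]], rois[[1]], b_index = 1)
adc_roi_summary(fit_adc(conv), rois[[1]])
adc_roi_summary(fit_adc(l1),   rois[[1]])
lesion_cnr(conv, truth, 1, roi_stats(nconv$magnitude[, , 1], rois[[1]])$sd)
lesion_cnr(l1,   truth, 1, roi_stats(nl1$magnitude[, , 1],   rois[[1]])$sd)
```

Output (condensed):

```
<snr_report> sense:    SNR 22.17 (signal 101 / noise SD 4.55)
<snr_report> l1_sense: SNR 28.96 (signal 101 / noise SD 3.5)
ADC (1e-3 mm2/s): conv 0.883 +/- 0.200 | L1 1.051 +/- 0.111
5 mm lesion: retention conv 0.69 (CNR 3.0) | L1 0.30 (CNR 1.7)
```

Read it as: the L1 reconstruction measures *higher* SNR (its noise map,
pushed through the same nonlinear operator, has lower SD) and a visibly
*tighter* ADC distribution — and at the same time the 5 mm lesion has lost
most of its contrast (retention 0.30 vs 0.69; at larger λ or smaller
lesions it disappears outright, which is what `run_sweep()` maps
systematically).

## Layout

```
R/                  phantom, coils, encoding, operators, recon, quantify,
                    detectability, stats_report, io
tests/testthat/     unit + property + end-to-end acceptance tests
scripts/acceptance.R
vignettes/liver-dwi-cs-simulation.Rmd   methods and design rationale
```
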