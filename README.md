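# hyprpvc

MR-free partial volume correction (PVC) for dynamic brain PET.

The limited spatial resolution of PET (point spread function, PSF, of
roughly 4–8 mm FWHM) makes thin structures such as the cortical
grey-matter ribbon exchange apparent activity with their surroundings.
Measured grey-matter concentrations end up biased low by 20–40%, and the
bias propagates into kinetic parameters like the distribution volume
*V*<sub>T</sub>. Most corrections need a coregistered, segmented MR scan;
`hyprpvc` implements a PET-only alternative for users who lack consistent
MR data (multicentre or longitudinal studies, or none at all):

* **Iterative deconvolution (IDM)** against an isotropic Gaussian PSF —
  Van Cittert (classic `I_{k+1} = I_k + (g − S I_k)`, plus the
  current-estimate and reblurred variants) and Lucy–Richardson, with
  optional 3×3×3 median or Gibbs (local-mean) spatial priors applied per
  iteration. Defaults: 8 iterations, Gibbs prior, weight 0.15, 6.75-mm
  FWHM.
* **HYPR denoising** of the dynamic series: each frame becomes
  `C × blur(I_i) / blur(C)` with `C` the duration-weighted composite —
  spatial detail from the low-noise composite, temporal information from
  the smoothed ratio.
* **Composition orders** `idm`, `idm_hypr`, `hypr_idm` and the recommended
  `hypr_idm_hypr` (denoise → deconvolve per frame → denoise).
* A **digital Hoffman-style brain phantom** (ellipsoidal envelope, folded
  cortical ribs, uniform deep-WM noise VOI) with PSF blurring and
  duration-scaled Poisson noise over realistic dynamic framing schemes.
* A **kinetic layer**: reversible two-tissue-compartment simulation,
  Levenberg–Marquardt NLR fitting, and Logan graphical analysis (regional
  and voxelwise parametric *V*<sub>T</sub> images), plus a synthetic bolus
  plasma input.
* NIfTI-1 I/O with JSON frame-timing sidecars, evaluation reports
  (per-frame grey-matter bias, white-matter CoV), and a thin command-line
  front end (`inst/cli/pvc.R`).

## Worked example

Simulate a noisy dynamic acquisition of a small digital brain phantom and
correct it with the full HYPR–IDM–HYPR pipeline:

```r
library(hyprpvc)

spec <- phantom_spec(shape = c(48, 48, 36))     # 2-mm voxels, GM 25 kBq/mL
ph   <- make_phantom(spec)
dyn  <- simulate_dynamic(ph$activity, psf_model(6.75),
                         framing_scheme(c(5, 5, 60, 300)), noise_model())

cat(sprintf("uncorrected GM bias (frame 1): %.1f%%\n",
            gm_bias(dyn$frames[[1]], ph$mask, 25)))

corrected <- run_pvc(dyn, pvc_config("hypr_idm_hypr"))

cat(sprintf("corrected   GM bias (frame 1): %.1f%%\n",
            gm_bias(corrected$frames[[1]], ph$mask, 25)))
cat(sprintf("WM noise CoV, 5-s frame: %.1f%% -> %.1f%%\n",
            voi_cov(dyn$frames[[1]], ph$mask, "WM_core"),
            voi_cov(corrected$frames[[1]], ph$mask, "WM_core")))
```

```
uncorrected GM bias (frame 1): -37.5%
corrected   GM bias (frame 1): -20.6%
WM noise CoV, 5-s frame: 58.5% -> 30.9%
```

The blur spills roughly a third of the grey-matter signal out of the thin
cortical ribs; the pipeline recovers close to half of that loss while
*reducing* the noise of the 5-second frame — plain deconvolution would have
amplified it several-fold instead. On the full-size phantom the residual
grey-matter bias at the default settings is about −12%, consistent with the
tissue-fraction limit of deconvolution-based PVC.

A Logan analysis of a corrected series then quantifies the kinetic impact:

```r
input <- synth_plasma_input()
tac   <- extract_tac(corrected, ph$mask, "GM")
logan_vt(tac, input, t_star = 1200)$vt
```

## Command line

```sh
Rscript inst/cli/pvc.R run --order hypr-idm-hypr --iterations 8 \
    --prior gibbs --prior-weight 0.15 --psf-fwhm 6.75 --hypr-fwhm 6.75 \
    in.nii.gz timing.json out.nii.gz
Rscript inst/cli/pvc.R phantom --framing hoffman18 --out-dir phantom/
Rscript inst/cli/pvc.R evaluate --out report.json
```

Frame timing travels in a JSON sidecar
(`{"FrameTimesStart": [...], "FrameDuration": [...]}`, seconds) or a
two-column text file.

See `vignettes/methods.Rmd` for the model, its assumptions, parameter
choices, and what the synthetic phantom does and does not establish about
real scanner data.
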