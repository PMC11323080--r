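# mugatools

Quantitative analysis of gated blood-pool (MUGA / radionuclide
angiography) cine scans in R.

Serial MUGA scans are the workhorse for monitoring cardiotoxicity during
chemotherapy, but the one number routinely read from them — the
left-ventricular ejection fraction, LVEF = 100·(EDC − ESC)/EDC on
background-corrected counts — is a late marker of damage. The same scans
carry earlier information in the *timing* of contraction (per-pixel
first-harmonic phase), its *disorder* (entropy, approximate entropy,
synchrony, phase SD) and the chamber's *shape* (circularity, elongation,
fractional shortening). `mugatools` extracts all of these in one pass and
supplies the statistics needed to relate them to outcome. It is aimed at
nuclear-medicine physicists and imaging researchers running retrospective
or prospective cardiotoxicity studies.

The package provides:

* **I/O** — multi-frame nuclear-medicine DICOM reading (gating tags:
  frame time, heart rate, accepted/rejected beats, pixel spacing; absent
  tags stay absent), a portable JSON fixture container with exact
  round-trip, and CSV parameter-table export.
* **Preprocessing** — six-location arc-band background ROIs with
  mean-subtraction, and a four-filter bank (mean, median, adaptive
  Wiener, median-modified Wiener) at 3×3 / 5×5 kernels.
* **Phase analysis** — per-pixel fit of c(t) = A₀ + A₁cos(2πt/T − φ):
  DC, amplitude and phase images, amplitude-weighted phase histograms.
* **Segmentation** — a hybrid algorithm: seeded region growing on each
  frame initialises a shrink-only two-phase active contour on the phase
  image (gated to ±90° of the ventricular reference phase), whose result
  bounds a final region growth on the amplitude image; ED/ES from the
  time-activity curve.
* **Biomarkers** — LVEF, phase LVEF, peak ejection rate, entropy (raw
  and bounded to [0,1]), approximate entropy (fast implementation with a
  brute-force reference mode; plain and range-bounded; spatial
  diastolic/systolic variants), synchrony, phase SD, lung-to-heart
  ratio, shape metrics, beat statistics.
* **A beating-LV phantom** — ellipsoidal chamber with a raised-cosine
  volume pulse whose counts are exactly volume-proportional, with
  configurable true EF, Poisson noise, background/lung levels and
  per-sector phase delays; every downstream claim is validated against
  its ground truth.
* **Statistics** — univariate screen (p < 0.2), stepwise regression with
  partial-F enter/remove tests and VIF checks, rank-based ROC at the
  LVEF < 54 % abnormality cutoff, Bland–Altman / Lin's concordance / ICC
  agreement reports, Bonferroni utility.

## Worked example

Generate a noisy phantom with a known ejection fraction of 60 % and run
the full pipeline (the seed is the operator's click inside the LV):

```r
library(mugatools)

ph <- generatePhantom(phantomConfig(trueEf = 0.6, poisson = TRUE,
                                    rngSeed = 11L))
ph$cine
#> GatedCine: 64 x 64 pixels, 16 frames
#>   total counts 2.869e+05; frame time 50 ms; heart rate 75 bpm

ps <- computeAll(ph$cine, seed = c(32, 24))
ps
#> ParameterSet
#>   lvef                 61.2203
#>   phase_lvef           57.8455
#>   ejection_rate        3.38451
#>   ...
#>   synchrony            0.957516
#>   phase_sd             16.9902
#>   lhr                  0.387831
#>   counts_ed            9424.02
#>   counts_es            3654.61
#>   heart_rate           75
```

The count-based LVEF of 61.2 % recovers the configured 60 % to about one
point under Poisson noise at ~10⁴ end-diastolic counts; `phase_lvef` is
the independent first-harmonic estimate of the same quantity;
`ejection_rate` is the peak systolic emptying rate in EDC-fractions/s;
`synchrony` near 1 and a phase SD of ~17° under this noise level describe
contraction-timing uniformity; `lhr` is the lung-to-heart count ratio.
`exportParameters(list(ps), "params.csv")` writes the full vector, one
scan per row, with absent values as empty cells.

A thin command-line front end over the same functions ships in
`inst/cli/rnatool.R` (`phantom`, `analyze`, `model`, `agree`
subcommands).

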