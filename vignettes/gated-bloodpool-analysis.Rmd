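---
title: "Quantifying gated blood-pool scans: methods and design notes"
author: "mugatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gated blood-pool scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mugatools)
```

## The problem

Equilibrium radionuclide angiography (MUGA) images the cardiac blood pool
over many heartbeats, folding the cycle into a fixed number of gated frames
(16 in routine practice). Because counts are proportional to blood volume,
the left-ventricular ejection fraction follows directly from
background-corrected counts:

$$\mathrm{LVEF} = 100\,\frac{\mathrm{EDC}-\mathrm{ESC}}{\mathrm{EDC}},$$

with EDC/ESC the summed counts inside the LV at end-diastole and
end-systole. Serial MUGA is the standard tool for monitoring cardiotoxicity
during chemotherapy, but an LVEF drop is a late sign. The premise of this
package is that the same scans carry earlier, largely ignored information:
the timing structure of contraction (phase analysis), its regularity
(entropy and approximate entropy), and the chamber's shape. `mugatools`
extracts all of these in a single pass and provides the statistical layer
needed to relate them to outcome.

## Processing model

The pipeline in `computeAll()` runs, in order:

1. **Spatial filtering.** Four window filters at 3×3 or 5×5:
   mean, median, adaptive Wiener
   $\hat x = \mu + \frac{\max(\sigma^2-\nu^2,0)}{\max(\sigma^2,\nu^2)}(x-\mu)$
   (local mean $\mu$, local variance $\sigma^2$, noise power $\nu^2$ =
   image-wide mean of the local variances), and the median-modified Wiener
   filter (MMWF), the same estimator with the local median replacing $\mu$
   in both occurrences. MMWF keeps the Wiener filter's adaptivity while
   inheriting the median's robustness to count outliers; its behaviour is
   nearly independent of kernel size, which is why MMWF 5×5 is the
   pipeline default. Borders use reflect padding so count images gain no
   dark rim. The Wiener noise-power convention is stated here because
   several conventions circulate: we estimate $\nu^2$ image-wide from the
   local variances, the classic adaptive-filter choice.
2. **Background correction.** Six candidate arc-band ROIs of configurable
   width (default 4 px) are placed at 60° intervals on a ring 2 px outside
   the LV bounding box; location 1 sits on the inferolateral border, where
   clinical packages draw their automatic background. The mean gray value
   of the chosen ROI — measured on the time-averaged frame by default,
   because the background plateau is stationary over the cycle — is
   subtracted from every pixel of every frame, clipping at zero. The exact
   arc geometry is this package's own construction (parameterised so
   alternatives drop in); what matters downstream is only the scalar mean.
3. **First-harmonic analysis.** Every pixel's count-time curve is fit with
   $c(t) = A_0 + A_1\cos(2\pi t/T - \phi)$ via the first DFT coefficient;
   $\phi$ is in degrees in $[0,360)$, positive = later contraction.
   Pixels with $A_1$ below $10^{-9}\times\max A_1$ (plus an absolute
   floor absorbing FFT round-off on exactly constant pixels) are flagged
   low-amplitude: their phase is meaningless and they are excluded from
   all phase statistics.
4. **Hybrid LV segmentation.** Four steps per scan:
   (a) seeded region growing on each frame — a pixel joins the 8-connected
   region when its value is at least a fraction of the running region
   maximum; (b) a shrink-only two-phase (piecewise-constant) active
   contour on the phase image, restricted to the ventricular phase gate
   (±90° of the reference phase), refines each initial contour;
   (c) region growing on the amplitude image, bounded by the step-b mask,
   gives the final contour; (d) the final masks are applied to the frames
   and ED/ES are the argmax/argmin of the time-activity curve (earliest
   frame on ties).
5. **Parameter extraction.** The full vector: LVEF; phase LVEF
   $100\cdot 2\Sigma A_1/(\Sigma A_0+\Sigma A_1)$ (the first-harmonic EF
   estimate over the ED mask); peak ejection rate; Shannon entropy of the
   amplitude-weighted phase histogram, raw ($-\sum p_i\log_2 p_i$, bits)
   and normalised by $\log_2 n_{bins}$ to $[0,1]$; approximate entropy of
   the time-activity curve (plain, $r=0.2\,\mathrm{SD}$, and range-bounded,
   $r=0.2\,\mathrm{range}$); spatial ApEn of the phase values inside the
   ED and ES masks and their mean; synchrony
   $|\Sigma A e^{i\phi}|/\Sigma A$; amplitude-weighted phase SD;
   lung-to-heart ratio; circularity, elongation and long/short-axis
   fractional shortening of the ED/ES masks; LV sizes and counts; and the
   beat statistics from the gating metadata.

## Key design choices

Several points were genuinely open; the choices and their reasons:

**Region-growing inclusion rule and thresholds.** The inclusion criterion
(value ≥ fraction × running region maximum) is the classic count-based
edge rule. `regionGrow()` defaults to the textbook 0.5, but the *pipeline*
default is 0.25. The reason is geometric: a blood-filled chamber projects
as $2c\sqrt{1-\rho^2}$ thickness, so a 50 %-of-max cut keeps only
$\rho^2 \le 0.75$ — three quarters of the chamber area, a Dice ceiling of
0.857 against the full chamber. At 0.25 the cut sits at $\rho^2\le0.94$
and the segmentation recovers the chamber to Dice ≥ 0.95 while Poisson
noise (filtered, background-corrected) stays an order of magnitude below
the threshold. Because mask extent scales identically at ED and ES, the
count-based EF is essentially unbiased to this choice.

**The reference phase.** The operator's seed supplies *location* only.
Its *timing* is estimated as the amplitude-weighted circular mean phase
over the first frame's initial contour: the chamber centre is where
amplitude is lowest, so a single pixel's phase is the least reliable in
the whole ventricle, and anchoring the phase gate to it makes the
segmentation fragile under counting noise.

**The active-contour feature image.** The two-phase evolution runs on the
absolute angular distance from the reference phase ($[0°,180°]$), not on
a signed difference: random background phases average to zero *signed*
difference, which destroys the inside/outside contrast the evolution
needs, while their absolute distance concentrates near 90°. Low-amplitude
pixels are assigned the maximal distance 180° — their stored phase of 0
is an arbitrary convention, not a measurement. The evolution shrinks only
(each iterate is intersected with its predecessor), applies one 3×3
majority-smoothing pass per iteration, keeps the component containing the
seed, and stops after 200 iterations or when fewer than 0.1 % of pixels
change.

**Which pixels enter the phase statistics.** Entropy, synchrony and phase
SD are computed over the pixels inside the LV mask on *every* frame (the
intersection of the per-frame masks). Pixels at the ED border empty
completely during systole; their count curves are on/off pulses whose
first-harmonic timing reflects wall *motion*, not chamber emptying, and
they carry the largest amplitudes. On a perfectly synchronous phantom
they alone contribute ~4° of spurious amplitude-weighted phase SD;
interior pixels give 0.5°. The all-cycle intersection is the cleanest
"blood pool throughout" ROI. `phaseStatistics()` itself accepts any mask
for users who want the ED-mask convention.

**Amplitude weighting.** The phase histogram and all phase statistics are
amplitude-weighted, the convention of the dyssynchrony literature: a
pixel's confidence in its timing is proportional to its contraction
amplitude. An unweighted mode is available (`weighted = FALSE`). The
histogram default of 64 bins is configurable; entropy is normalised by
$\log_2 n_{bins}$ so the bounded value stays in $[0,1]$ regardless.

**Approximate entropy.** Pincus conventions throughout: Chebyshev
distance, self-matches included, natural log, defaults $m=2$ and
$r = 0.2\,\mathrm{SD}$ (plain) or $r = 0.2\,\mathrm{range}$ (bounded,
which makes the statistic invariant to affine rescaling). The vectorised
implementation is checked against a literal brute-force triple loop to
$10^{-9}$ on random signals. The "diastolic/systolic" spatial variants
run bounded ApEn over the row-major sequence of phase values inside the
ED and ES masks; this construction is isolated in `apenSpatial()` so
alternative readings (e.g. ApEn of regional time-activity curves) can be
swapped in. A perfectly uniform phase region has zero range; it reports 0
with a warning rather than erroring, so fully synchronous scans still
produce complete parameter sets.

**Phase LVEF vs ejection rate.** Both readings of an "EF-like quantity
from the phase domain" are provided: `phaseLvef()` (the first-harmonic
EF estimate) and `ejectionRate()` (peak systolic emptying rate in
EDC-fractions/s, the steepest frame-to-frame fall between ED and ES
divided by EDC). They measure different things and both enter the
parameter vector.

**Lung ROI.** By default a rectangle of the LV-bbox height, half a
bbox-width wide, placed a quarter bbox-width lateral to the LV; the
lung-to-heart ratio is measured on the time-averaged *uncorrected* frame
(background subtraction would distort the ratio). If the default
rectangle leaves the image or touches the LV mask, the LHR is reported
absent rather than silently mismeasured; a user-supplied ROI overrides.

**Statistics layer.** The univariate screen keeps predictors at
$p < 0.2$; the stepwise model uses partial-F tests with the classic
0.05/0.10 enter/remove thresholds (exposed as arguments, since any such
choice is conventional); collinearity is reported by naming the offending
columns; VIFs come from the auxiliary-regression formula $1/(1-R_j^2)$
with values above 10 flagged. The ROC orientation is fixed and explicit:
*lower* predicted LVEF means *more abnormal*, with abnormality defined as
observed LVEF strictly below 54 %. AUC uses the rank (Mann–Whitney)
formulation with tie correction. Agreement between two measurement series
reports Bland–Altman statistics (t-based CIs; the limit standard error is
$\mathrm{SD}\sqrt{3/n}$), Pearson r, Lin's concordance
$2s_{xy}/(s_x^2+s_y^2+(\bar x-\bar y)^2)$ on $1/n$ moments with its bias
correction factor $C_b = \mathrm{CCC}/r$, and the intraclass correlation
in the two-way random-effects, absolute-agreement, single-measure flavour
(the appropriate one for "reliability of a single rating"; other flavours
would need a different mean-squares combination).

## The phantom: what it emulates and what it does not

`generatePhantom()` builds the ground-truth object every test rests on.
The LV is an ellipsoid (default ED semi-axes 14×10×10 px in a 64×64
matrix) whose volume follows $V(t)=V_{ED}(1-\mathrm{EF}\,s(t))$ with a
raised-cosine systolic pulse ($s=0$ at frame 0 = ED, $s=1$ at
end-systole, smooth recovery over diastole; systolic fraction 0.375 of
the cycle, about right for a resting heart). Pixel intensity is
`activity` × projected chamber thickness, so summed LV counts are
*exactly* proportional to volume and count-based EF equals volumetric EF
— EF recovery is a sharp test, not a biased one. Defaults give ≈10⁴
end-diastolic LV counts (activity 1.705), a background plateau of
2 counts/px, a lateral lung field of +6 counts/px, 16 frames at 50 ms
(75 bpm) and 4 mm pixels. Dyssynchrony is modelled by splitting the LV
into six angular sectors and time-shifting up to six of them by a
configurable cycle-phase delay; Poisson sampling under a fixed seed makes
every noisy phantom bit-reproducible.

What it does **not** emulate: atria and great vessels (an opposite-phase
structure can be emulated with a delayed sector at 180°), attenuation and
scatter, septal overlap, patient motion, arrhythmic gating errors, or
inter-patient anatomical variability. Passing the phantom suite therefore
demonstrates that the algorithms are correct under their stated model —
not that clinical accuracy on patient scans is guaranteed.

Two phantom subtleties worth knowing. First, the stored truth EF is the
EF of the analytic per-frame volume curve; with dyssynchronous sectors
the summed curve's excursion is slightly below the configured per-sector
EF, and the stored value is the honest one. Second, histogram entropy
*plateaus* once two phase modes are fully separated: measured directly on
the harmonic maps, a 90° single-sector delay can yield no more entropy
than a 45° one. Through the full pipeline the filter's boundary mixing
spreads intermediate phases between the modes, and all three
dyssynchrony indices order strictly with delay; this is a property of
the entropy statistic, not a defect of the implementation.

## Numerical conventions and degenerate inputs

* Indexing is 1-based (row, col), pixel (1,1) top-left, frame 1 = first
  gated frame after the R-wave.
* Ties in ED/ES detection go to the earliest frame.
* Region growing traverses in fixed breadth-first raster order; identical
  inputs give identical masks — there is no hidden randomness anywhere in
  the pipeline.
* `phase ∈ [0,360)` is enforced after every modular reduction (a tiny
  negative argument would otherwise reduce to exactly 360).
* Constant time-activity curves error in ED/ES detection; constant
  signals error in bounded ApEn (zero range) except in `apenSpatial()`
  where they report 0 with a warning; a background seed (zero amplitude
  or zero counts) errors immediately.
* Shape metrics need ≥5 pixels and a non-degenerate second-moment matrix;
  the perimeter uses the two-weight (0.948 axial / 1.340 diagonal)
  digital-length estimator, which is close to unbiased on smooth
  boundaries — a rasterised disc of radius 20 measures circularity within
  5 % of 1.
* ApEn can be marginally negative on near-periodic signals because the
  two template counts are normalised over different numbers of windows;
  this is a property of the estimator.

## Validation problem sizes

The shipped tests validate on 64×64, 16-frame phantoms: noise-free EF
recovery and per-frame Dice ≥ 0.90; twenty Poisson replicates at ≈10⁴ ED
counts for mean |EF error| ≤ 5 points and mask overlap; dyssynchrony
ordering across 0°/45°/90° single-sector delays; 100 random signals for
ApEn implementation agreement; closed-form hand oracles for the agreement
statistics; and brute-force pair-ordering equivalence for the AUC on
inputs up to n = 50. `scripts/acceptance.R` recomputes all of these from
scratch plus a 16-phantom EF cohort (EF 0.40–0.70) for ROC discrimination
and cross-filter agreement.

## Limitations

The seed is manual by design (semi-automated operation was a reliability
choice, not a shortcoming to engineer away); fully automatic seed finding
is out of scope. Only the left ventricle is segmented. The background ROI
geometry is a parameterised reconstruction of standard practice, not a
copy of any vendor's. Clinical validation requires patient data that
cannot ship with a package; the statistics layer (screen → stepwise →
VIF → ROC, and the agreement suite) is the toolset for exactly that
study, and the phantom suite is the evidence that the measurement side
behaves correctly under a known ground truth.
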