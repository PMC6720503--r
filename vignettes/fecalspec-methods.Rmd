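---
title: "Multispectral fluorescence screening of fecal contamination: models and methods"
author: "fecalspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral fluorescence screening of fecal contamination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecalspec)
```

## The measurement and the problem

Fecal residues on poultry carcasses carry porphyrin fluorophores —
protoporphyrin IX above all — that emit near 630–635 nm under UV-A
excitation, while uncontaminated chicken skin fluoresces weakly and
smoothly, with a signal valley around 490 nm, a slope ascension near
515 nm, and no emission peak anywhere between 500 and 680 nm. A push-broom
line-scan imager therefore sees contamination as a spectral peak riding on
a dull skin baseline: each conveyor position contributes one spatial line,
each pixel of which carries a 27-band spectrum on an even 410–690 nm grid
(about 10.77 nm between band centers, behind a 400 nm long-pass filter).

`fecalspec` implements three analysis tracks over such cubes:

1. **Spectral classification** (`run_case1`): pixel spectra from labelled
   regions of interest are classified as `upper` (ceca/colon material,
   strong fluorescence), `bottom` (small intestine/duodenum, weak) or
   `skin` by PLS-DA, compared across preprocessing methods, and
   cross-validated.
2. **Chemical-image classification** (`run_case2`): the fitted
   decompositions are applied pixelwise to whole scenes — PC score images,
   PLS-DA coefficient projections, band-ratio images — then auto-thresholded
   and segmented into candidate spots scored against ground truth.
3. **Color-image classification** (`run_case3`): an ordinary RGB image is
   reduced to its blue channel (fecal spots are darkest there), enhanced
   (histogram equalization, sharpening, disc median filter) and
   thresholded.

## The synthetic study

No public image set exists for this instrument class, so the package ships
a first-class scene generator whose defaults define the reproducible study
conditions; every simulation is bit-reproducible from its seed.

A scene is a dark conveyor background carrying elliptical carcasses of
skin spectrum, each with four circular 50 µL-scale fecal spots: two
upper-class spots in the upper third and two bottom-class spots in the
lower third, jittered by the seeded RNG. The spectral model per pixel is

\[ x(\lambda) \;=\; g \cdot s(\lambda) \;+\; a_c \, p_c(\lambda) \;+\;
   \varepsilon(\lambda), \qquad \varepsilon \sim N(0, \sigma^2), \]

clipped at zero, where \(s\) is the skin curve scaled by `skin_level`
(default 0.8, arbitrary detector units — the instrument class reports no
absolute radiometric scale, so units are arbitrary by design), \(g\) a
per-pixel log-normal brightness texture (log-sd `texture_sd`, default
0.35) applied to the skin baseline only — the deposit's emission
originates in the fecal material itself, not in the underlying skin — and
\(p_c\) a Gaussian emission band per class: the upper class peaks at
635 nm with 25 nm FWHM and amplitude 1.0; the bottom class, a mixed
bile/porphyrin deposit, has a broader band (630 nm, 32 nm FWHM) at
amplitude 0.35. Detector noise is additive Gaussian with `noise_sd`
(default 0.05), an EMCCD read-noise-dominated approximation; a Poisson
shot-noise option was deliberately deferred.

Three modelling choices deserve comment:

* **Speed as line decimation.** A bird covered by `lines_per_bird_at_1bps`
  scan lines at 1 bird/s is covered by `lines %/% speed` lines at 3 or 5
  birds/s — the simplest model consistent with push-broom scanning at
  fixed exposure per line; motion blur is not modelled. Spots therefore
  compress along track at higher speed, which is what stresses the
  detection pipeline.
* **Why the brightness texture.** With it, overall brightness dominates
  the first principal component and the porphyrin contrast falls on the
  second and third — the structure on which the chemical-image track rests
  (and the reason "the PC2 image" is the interesting one). Without
  texture, PC1 itself would be the contamination axis, which real
  fluorescence images of biological tissue do not show.
* **Why class-specific peak positions.** Three classes whose mean spectra
  differ only by the *amplitude* of one band shape have collinear
  centroids, and linear indicator regression (which PLS-DA is) then masks
  the middle class — no number of latent variables fixes this. The
  physically supported difference in peak position (ceca/colon emission at
  635 nm versus a small peak near 630 nm for the intestinal material)
  breaks the collinearity and is what makes three-class PLS-DA viable, for
  this package and for the instrument it models.

What the generator does **not** emulate: radiometric calibration, lamp
spatial non-uniformity, specular reflection, real carcass geometry,
motion blur, or shot noise. Green tests on synthetic scenes therefore
demonstrate the correctness and internal consistency of the algorithms
under controlled conditions — not field performance on real carcasses.

The default study (`study_config()`) mirrors a three-speed acquisition
with three replicas of ten birds per speed; two replicas calibrate, the
third validates (the 2-of-3 rule, generalized by
`calibration_fraction`). The on-line validation pool for spot detection
holds 10 birds split 4/3/3 across the speeds — 40 ground-truth spots.
Spectral evaluations use 600 pixels per class, matching the 480–700
pixels-per-ROI convention enforced (as a warning) by
`extract_roi_spectra()`.

## Preprocessing

Multiplicative scatter correction regresses each spectrum on a reference
(the training-set mean by default) as \(x = a + b\,r\) and returns
\((x-a)/b\); rows with numerically zero slope cannot be corrected and are
returned unchanged, flagged. Savitzky–Golay derivatives fit a local
polynomial (window 5, order 2 by default — the smallest sensible choice on
a 27-band grid; both are exposed as `prep.sg_window`/`prep.sg_polyorder`)
and differentiate per band *index*; on this uniform grid that differs from
a per-nm derivative only by a constant, which a linear classifier absorbs.
Edge bands are refitted on the truncated one-sided window so the output
keeps all 27 bands. Preprocessing is a fit/apply pair, and
cross-validation refits it inside every fold, so the MSC reference never
leaks information from held-out pixels.

## Chemometric models

`pca_fit()` is column-centered SVD; components are sign-fixed so the
largest-magnitude loading element is positive, making results
deterministic. `plsda_fit()` extracts latent variables with the improved
kernel PLS algorithm, which is algebraically identical to NIPALS PLS2 but
deterministic and driven only by the \(K\times K\) and \(K\times C\)
cross-products — at full rank it reproduces the multivariate least-squares
solution, and its predictions are verified in the test suite against an
independent PLS-DA implementation to 1e-8. Classes are one-hot coded and
predicted by arg-max; the classical binary 0/1 coding with the 0.5 cut is
available as `coding = "binary"`.

The default of three latent variables (one per class) is a deliberate
fixed choice: the discriminative subspace of this problem is
two-dimensional (brightness plus two peak shapes), low latent-variable
counts are the regime this instrument class operates in, and a fixed
default keeps the pipeline deterministic. `select_ncomp()` performs the
cross-validated selection over 1..10 for users who prefer it.

Reported metrics follow the field's convention: per-class one-vs-rest
sensitivity and specificity, **balanced accuracy** (the mean over classes
of (sensitivity+specificity)/2 — the headline number), overall accuracy
(trace/total, reported alongside because the two are often conflated), and
Cohen's kappa from the pooled confusion matrix, with kappa defined as 1
when both observed and chance agreement are perfect. Leave-one-out
cross-validation is exact: for unpreprocessed spectra each fold's model is
obtained by downdating the cross-product matrices (algebraically a full
refit); beyond `loo_cap` (2500) samples a stratified k-fold fallback
engages with a warning.

On the default generator the three-class LOO evaluation lands near 98–99%
balanced accuracy with kappa about 0.96–0.98, upper-class sensitivity at
1.0 and the errors concentrated in the bottom-versus-skin pair — the
pattern expected when one class is weakly expressed. These numbers are
recomputed, not quoted, by `scripts/acceptance.R` and the acceptance test
suite.

## Chemical images and thresholds

Band ratios use nearest-band lookup and a guarded denominator (`eps`,
invalid pixels flagged and zeroed). The 630/600 ratio orders the classes
upper > bottom > skin and separates upper from skin more strongly (Fisher
separation \(|\mu_1-\mu_2|/\sqrt{\sigma_1^2+\sigma_2^2}\)) than the
620/600 and 512/492 alternatives, because 630 nm sits on the porphyrin
peak while 600 nm sits off it; the test suite asserts exactly this
ordering. Ratio distributions per class are summarised by Gaussian kernel
densities with Silverman's bandwidth.

Because the histogram auto-thresholds are defined on 0–255 gray levels,
float images pass through `to_8bit()` — linear min–max scaling with
optional percentile clipping, with the (min, max) recorded so the mapping
is invertible. The Shanbhag threshold minimises the absolute difference of
the two classes' fuzzy-membership information measures; the Huang
threshold minimises the Shannon entropy of memberships
\(\mu(g) = 1/(1+|g-m_{\text{class}}|/C)\). Both follow the widely used
Auto_Threshold ports, break ties toward the lower threshold, and are
verified against exhaustive scans of independently re-implemented
objectives on random histograms; Huang is translation-equivariant and
Shanbhag mirror-symmetric, both tested. The sharpening kernel
(\([[-1,-1,-1],[-1,12,-1],[-1,-1,-1]]/4\)) and the radius-2.0 disc median
(13 pixels, reduced neighbourhood at borders) follow the conventions of
the same image-processing lineage.

### A known limitation: fuzzy thresholds and weak spot classes

The Huang threshold on a PC2 score image must split a histogram with one
dominant mode (background and skin, ~97% of pixels) and two small spot
modes — the bottom class at roughly 0.37 of the upper class's contrast
under the default amplitudes. For a concave membership-entropy the cost of
merging the two spot modes into one object class exceeds the cost of
absorbing the weak mode into the background side unless the weak mode
rises to within ~80% of the strong one. The fuzzy threshold therefore
isolates the upper spots only: clean (zero false-positive pixels on the
default scenes) but blind to the weak class, and the noiseless limit does
not change this, since the mode structure is signal, not noise. This is a
property of the method, not of an implementation: whenever the two
contamination classes differ several-fold in chemical contrast, a global
fuzzy threshold on a single score image cannot recover both. The package
keeps the PC2+Huang chain as specified and reports it honestly; on the
same scenes the PLS-DA projection map (arg-max over classes, a per-pixel
classifier rather than a global histogram cut) and the Huang-thresholded
630/600 ratio image both recover 40 of 40 spots, and the `case2` report
carries all three tracks side by side.

Spot candidates are 8-connected components of the binary mask; components
under `min_area_px` (default 5 — single-pixel noise suppression, below the
~26 px of the smallest legitimate spot at 5 birds/s) are discarded. A
ground-truth spot counts as detected when a single component covers at
least 50% of its area; that containment criterion is this package's
convention (only detection counts, not a criterion, are conventional in
the field). False-positive pixels are mask pixels outside every truth
spot.

## Color-image track

The blue channel (spots darkest) is equalized (0.3% saturation),
sharpened, median-filtered (disc radius 2.0), and thresholded below an
auto (Shanbhag) or overridden cut. On the default color model — smooth
low-frequency shading, since a color camera under diffuse halogen light
does not see the per-pixel fluorescence texture — the auto threshold
recovers all four spots per bird at the price of substantial
false-positive pixels, and lowering the threshold monotonically trades
recall for false-positive suppression, with the revised threshold 1
driving false positives to zero. One caveat is structural: rank-based
equalization maps the darkest cluster of *any* noisy image to black, so a
spotless image still yields a few small artifacts under a low threshold —
the same false-positive pathology that motivates threshold revision in
practice.

## Numerical and degenerate-input conventions

* Coordinates are 0-based and half-open everywhere (ROIs, masks, bounding
  boxes, centroids); a round-trip property test enforces it.
* Cubes are non-negative finite float; ENVI rasters are float32, so a
  write/read round trip is exact at float32 precision and bit-exact from
  the second write on. Negative rasters and band/wavelength mismatches
  are rejected with diagnostics.
* Constant images map to zero with a warning in `to_8bit()`; constant
  spectra are flagged and passed through by MSC; single-class inputs,
  empty masks, all-zero confusion matrices and out-of-range components
  raise errors rather than guessing.
* Ties: auto-thresholds break toward the lower gray level; nearest-band
  lookup breaks toward the lower band; arg-max class assignment takes the
  first maximal column.

## Problem sizes

The shipped configurations are sized so the whole test suite and the
acceptance script run in minutes on a single CPU: unit tests use 80×80
scenes of 1–4 birds; the default study uses 120-line, 120-pixel birds, ten
per calibration scene, 600 spectra per class for the LOO evaluation
(N = 1800), and a 40-spot validation pool. All are configuration
parameters, not constants.
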