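---
title: "DNA-content image cytometry: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-content image cytometry: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocycle)
```

## The measurement

cytocycle quantifies cell-cycle phase distributions of adherent ("spread")
cells imaged in place, for example in microfluidic culture channels, from
single-channel fluorescence microscopy of DNA-stained nuclei (DAPI, Hoechst
or any stoichiometric DNA dye — the pipeline is dye-agnostic once it has
per-nucleus intensities). The physical premise is the same as in flow
cytometry: bound dye is proportional to nuclear DNA, so G0/G1 cells carry a
2N signal, G2/M cells a 4N signal, and S-phase cells lie in between. Unlike
flow cytometry, which needs on the order of a million suspended cells, image
cytometry works on a few hundred attached cells without disturbing them.

The pipeline is: segment nuclei in each field, estimate and subtract
background, integrate per-nucleus intensity, pool nuclei into a
fixed-interval histogram, locate the 2N and 4N peaks, place gates, and
report phase fractions with replicate statistics.

## Per-nucleus quantification

**Segmentation.** Nuclei are bright compact objects on a dark background, so
a global automatic threshold (Otsu's method by default; a fixed numeric
threshold can be supplied) defines nucleus cores. Holes are filled and cores
are grown by a 3 px binary dilation before connected-component labelling, so
each label also captures the dim rim of its nucleus — without the growth,
the thresholded core systematically clips a content-independent amount of
signal from every nucleus, which shifts the apparent 4N:2N ratio above 2.
Regions smaller than `min_area` (default 30 px, noise specks) are removed.
On fields where the threshold separates nothing (no signal), "foreground"
would cover about half the pixels because Otsu simply splits the noise band;
such fields are treated as blank rather than segmented.

**Background.** The background level is the median pixel value outside the
(dilated) foreground — robust to dense fields, and equal to the mean for
Gaussian noise. Background subtraction matters increasingly at long
exposures, where the offset becomes a large share of each integrated
intensity. Integrated intensities are clamped at zero since they feed a
non-negative DNA-content axis.

**Quality flags.** Nuclei touching the field border are flagged (partial
nuclei bias content low). Nuclei with more than `sat_frac` (default 5%) of
their pixels at the detector maximum are flagged as saturated. Objects whose
area exceeds `clump_factor` (default 1.8) times the median object area are
flagged as probable clumps: two touching nuclei merged into one object carry
roughly the summed DNA signal and would be mis-read as a 4N (or higher)
event. Clumps are flagged and excluded, never split: no watershed is
attempted, because a mis-split contaminates the histogram more subtly than
an exclusion. All flagged records are excluded from cytometry by default.

## Histogram and gating

Integrated intensities are binned with a fixed interval (default 60
intensity counts, the conventional interval for these histograms) starting
at the origin; bins are half-open `[lo, hi)` so boundary events are handled
deterministically. Counts are normalized by total cell number, and the
intensity axis is rescaled so the G1 peak maps to 2 N units.

Peak finding smooths the counts with a 3-bin centered moving average (the
minimum that suppresses single-bin noise at this granularity without
flattening real peaks) and pairs local maxima whose center ratio lies in
[1.6, 2.4] — DNA doubling implies a ratio near 2; the slack absorbs binning
quantization and saturation shifts. Two guards make the pairing robust:
a candidate peak must reach 5% of the tallest mode (and 2 smoothed counts),
and the 2N candidate must be a major mode (half the tallest), since G1
dominates these populations. Among qualifying pairs, the product of the two
smoothed heights weighted by a Gaussian prior on the ratio (centered at 2,
scale 0.4) decides; the prior keeps a weak but genuine 4N peak from losing
to noise bumps on the S-phase plateau when the G2/M population is small, as
happens after prolonged G1-arrest treatment. When no pair qualifies the
histogram is reported as unimodal — the characteristic failure of
over-concentrated staining.

Automatic gates are symmetric multiplicative bands around the detected
peaks: G1 = `g1_peak * (1 ± w)`, G2/M = `g2_peak * (1 ± w)`, S the residual
window between them; sub-G1 and super-G2/M events stay ungated, which is why
gated fractions sum to less than 100% on real data. The default half-width
is `w = 0.15`. A wider band (0.2) was considered and rejected: the residual
S window then covers only ~40% of a uniform 2N–4N S population, so the
S-population spill-over into the G2/M band can exceed the entire G2/M gate
content of a strongly G1-arrested culture, making such published fraction
sets unrepresentable. At `w = 0.15` the S window covers ~55% of the S
population and all fraction sets this package is validated against are
representable. Manually set gates, when supplied, always take precedence
over automatic ones.

The `two_peak_score` quantifies histogram quality as
`1 - valley / min(peaks)` on the smoothed counts (valley = minimum between
the detected peaks), clamped to [0, 1], and 0 when peak pairing fails.

## Exposure quality control

Over-exposure is detector clipping: the fraction of in-nucleus pixels at
the detector maximum ("flat peaks" in an intensity surface plot) above
`clip_threshold` (default 1%). Under-exposure is a median per-nucleus peak
signal-to-noise ratio below `snr_threshold` (default 3, the conventional
detection floor; "missing peaks"). Over-exposure takes precedence; each
field gets exactly one status. Intensity surfaces for visual inspection are
downsampled by block *maximum*, not mean, precisely so clipped plateaus
survive downsampling.

## The synthetic microscope

Because no raw image data are published for this kind of experiment, the
package ships a seeded generator used as ground truth by every validation
study.

**Population model** (`cell_cycle_mixture`): per-nucleus DNA content in N
units — G1 at `2(1+e)`, G2/M at `4(1+e)` with `e ~ N(0, cv)`; S uniform on
(2, 4) with the same multiplicative spread; debris uniform on (0.5, 1.8);
doublets the sum of two independent G1/G2M-like draws. The default CV of
0.06 is a typical image-cytometry G1 peak CV. The default asynchronous
culture (55% G1, 20% S, 17% G2/M, 6% debris, 2% doublet) is an ordinary
exponentially growing adherent line.

**Optics** (`optics_config`): each nucleus is a truncated 2D Gaussian disk
(truncation at 3 sigma = the nucleus radius) whose total pre-noise signal is
`gain * exposure_ms * sat(content)`, with
`sat(c) = c * K / (c + K)` emulating dye-binding saturation (`K = Inf` is
the linear regime). Per-pixel noise is Poisson shot noise plus Gaussian
read noise/offset; pixels are clipped to `[0, detector_max]` (12-bit
default). Defaults — 5 ms exposure, gain 400 counts/N/ms, background
10 ± 3 counts, 6 ± 0.5 px nuclei, 150 cells per 512×512 field — put the G1
peak near 4000 counts: bright enough that shot noise adds ~2% CV (well below
the biological 6%), dim enough that even 8N doublets stay far from clipping.
Non-clumped nuclei are placed with centers at least `r_i + r_j + 8` px
apart, which guarantees their grown segmentation masks stay disjoint; with
probability `clump_prob` a nucleus is placed tangent to a previous one,
which guarantees the pair merges into one label — the clump phenomenon the
area flag is built to catch.

Dye concentration is not modelled chemically; it maps monotonically to the
saturation constant as `K = 8 * (0.6 / conc)^2` N units. The map's shape is
arbitrary by construction (only its direction is physical); its anchor is
chosen so that 0.6 µg/mL — the strongest concentration at which the 2N/4N
pair remains distinguishable in the emulated system — maps to the strongest
saturation (4N:2N signal ratio 1.67) that still supports peak pairing.
Magnification is emulated jointly by nucleus radius (up) and cells per
field (down).

**What the generator does not emulate:** optical PSF blur, focus drift,
z-structure, photobleaching, uneven illumination, autofluorescence and
cytoplasmic background texture, or irregular nucleus shapes. Passing the
synthetic validation therefore demonstrates the correctness of the
quantification and gating logic under the stated acquisition model, not
robustness to every real-microscope artifact.

## Calibrating a mixture to published gated fractions

Published studies report *gated* percentages, which are not mixture
fractions: an auto-gated S window captures only part of the S population,
debris overlaps the bottom of the G1 band, and G1+G1 doublets land in the
G2/M band. `calibrate_gated_mixture()` inverts this mapping analytically —
Gaussian tail probabilities for G1/G2M, numeric integration over the uniform
S population, interval overlap for debris, and the two-component
convolution for doublets (doublet fraction fixed at 2%) — and solves the
resulting 3×3 linear system iteratively. The inversion involves no
simulation and reports an explicit error when a requested fraction set is
unreachable (e.g. a gated S fraction larger than the residual window can
capture).

## Validation studies and problem sizes

The test suite renders its own data at sizes chosen to keep the full suite
in the low minutes while leaving sampling error well inside the asserted
margins:

* **Phase-fraction recovery**: for each of three published condition sets
  (an untreated glioma culture and two durations of rapamycin-induced G1
  arrest), 3 seeded replicates × 2000 nuclei are rendered and pushed through
  the complete pipeline; recovered mean percentages must land within 2.5
  percentage points of the targets — comparable to the published replicate
  SDs (0.9–2.6). `scripts/acceptance.R` re-runs exactly this study.
* **Exposure neutrality**: the same population rendered at 3, 5, 8 and
  10 ms must pass QC and give per-phase fractions agreeing pairwise within
  2 pp — multiplicative gating makes the analysis scale-free, so exposure
  inside the linear range is a nuisance parameter.
* **Saturation collapse**: a five-concentration sweep (0.2–1.0 µg/mL
  equivalent). This study uses a coarse-resolution acquisition (gain 100,
  4 px nuclei), where the histogram spans a few dozen interval-60 bins, and
  averages the score over three seeds per point. At the default bright/fine
  acquisition the score is nearly flat until collapse, because two
  saturation effects cancel: the S population is squeezed into a narrower
  valley (raising the valley floor) at the same rate as the G2/M peak
  sharpens (raising the reference peak). At coarse bin resolution peak
  sharpening is capped by the bin width while the S squeeze continues, so
  the score degrades monotonically before pairing fails outright at the
  strongest concentration.
* **Cell-number robustness**: at the extremes of 229 and 2032 cells the
  histogram must remain clearly bimodal, and at 2032 the recovered fractions
  must track the truth within 3 pp.
* **Exact oracles**: binning against brute-force bin assignment, gating
  against event-by-event classification, ANOVA against the textbook
  sum-of-squares decomposition, and labelling against a naive flood fill.

## Replicate statistics

Replicates are summarized as mean ± sample SD (n−1); conditions are
compared per phase with classical one-way ANOVA (`F` with k−1, N−k degrees
of freedom). Degenerate inputs are resolved as limits: all-identical values
give F = 0, p = 1; zero within-group variance with distinct means gives
F = Inf, p = 0. No multiple-testing correction is applied across phases —
per-phase p-values are reported directly, matching common reporting practice
in this literature; users comparing many conditions should adjust downstream.

## Known limitations

* Gating is threshold-based; no model-based histogram deconvolution
  (Watson, Dean–Jett–Fox) is attempted, so the S fraction inherits the
  residual-window convention of the gates.
* Very dim sub-G1 debris may fall below the segmentation threshold; its
  loss slightly inflates all gated fractions (≲1 pp at default settings).
* Clumps are excluded, not split, so heavily clumped fields lose cells.
* The detected G2/M peak position is quantized to the bin grid; with a weak
  4N population its placement can wander a few percent, which is the
  dominant error source in strongly arrested conditions.
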