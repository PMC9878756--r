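---
title: "Methods: uncertainty-calibrated ETT placement assessment and classical tube segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-calibrated ETT placement assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ettassess)
```

## The clinical problem

Intubated ICU patients receive routine portable chest radiographs to check
that the endotracheal tube (ETT) tip sits an adequate distance above the
carina, the bifurcation of the trachea. A tip-to-carina distance below
2 cm is the conventional "too low" criterion: the tube risks slipping into
a main bronchus. Reading these films is slow and error-prone, so a
detector (neural or otherwise) that proposes tip and carina locations with
confidence scores is attractive — provided its output is calibrated,
auditable, and visually checkable. `ettassess` implements everything
downstream of such a detector:

1. pairing the per-landmark detections into an ETT–carina distance,
2. converting the detector's confidence into a physical uncertainty (cm),
3. an uncertainty-adjusted placement call with a coupled human/model
   reading,
4. a classical (non-learned) segmentation of the tube for visual review,
5. the evaluation statistics used to characterise such a system, and
6. a synthetic phantom generator that provides exact ground truth for all
   of the above.

The detector itself is deliberately out of scope: any source of
`landmark_detection` records (bounding box + class + confidence) plugs in,
including the phantom module's oracle detector.

## Distance, confidence, and uncertainty

Coordinates are 0-based `(row, col)` pixels, rows increasing downward;
physical conversion uses per-axis pixel spacings in cm/px (DICOM
`PixelSpacing` is mm/px and is divided by 10 on read). Landmark points are
defined as bounding-box centers; clinician point annotations convert to
200 × 200 px training-style boxes, so `box_center(annotation_to_box(p))`
is exactly `p`.

The *level of confidence* of a paired prediction is
`C = min(conf_tip, conf_carina)` — the chain is only as reliable as its
weaker landmark. The uncertainty of the predicted distance is modelled as

$$U(C) = \alpha + \beta\, e^{-\gamma C} \quad [\mathrm{cm}],$$

fitted to binned (confidence, absolute error) pairs: the observed
confidence range is split into 8 equal-width bins (empty bins dropped,
abscissa = mean member confidence, not the bin midpoint — more robust when
confidences are skewed), and the per-bin mean absolute error is fitted by
weighted non-negative least squares (weights = bin counts,
Levenberg–Marquardt with box constraints at zero; starting values
`alpha0 = min bin MAE`, `beta0 = range of bin MAEs`, `gamma0 = 1`).
Whether the original operating point was fitted with equal-width or
equal-count bins, weighted or not, is not documented anywhere we know of;
equal-width weighted is our choice and is flagged in the configuration.

The shipped default model is `U(C) = 0.1 + 4.2 e^{-3.3 C}`; users with a
different detector should refit with `fit_uncertainty()`.

```{r}
predict_uncertainty(default_calibration(), c(0, 0.5, 1, 100))
```

**Identifiability note.** With confidences capped at 1, the asymptote
`alpha` is weakly identified: at `C = 1` the exponential term of the
default curve (0.155 cm) still exceeds `alpha` (0.1 cm), so at realistic
sample sizes (a few thousand pairs) the sampling error of `alpha` is of
the order of `alpha` itself, while the fitted *curve* is stable to a few
percent. Tests therefore assert curve recovery, and parameter-level
recovery only for generating values that are identifiable at the simulated
sample size.

## The placement rule

A film is called `too_low` when the uncertainty-adjusted distance fails to
clear the threshold:

$$\text{good position} \iff D_{pred} - U_{pred} \ge 2\ \mathrm{cm}.$$

The 2-cm threshold is conventional, not sacred, and is a parameter
(`threshold_cm`). Bronchial insertions are classified along with
`too_low`. The *coupled reading* flags `too_low` when either the model or
the clinician does (logical OR); this provably never lowers sensitivity
below either reader and never raises specificity above either — the
trade-off the evaluation module's tests verify on random labelings. A run
whose `U_pred` exceeds a configurable trust ceiling (default 2.0 cm: at
that uncertainty the adjusted rule calls everything `too_low`, so the
numeric answer carries no information) is flagged untrusted in the report
and on the overlay banner.

## Classical tube segmentation

The five steps, all deliberately non-learned so that they are fast,
deterministic and inspectable:

1. **ROI.** A 6-cm-wide band of columns centred on the predicted tip
   column, from the top of the image to 1 cm below the predicted tip
   (half-open pixel intervals; clipping at the frame is recorded). The
   tube enters from the top edge, so this contains all of it.
2. **Ridge detection.** Gaussian smoothing at `scale_px`, then the 2 × 2
   Hessian per pixel; ridge strength is `max(0, -lambda1)` with `lambda1`
   the smaller eigenvalue — bright curves on darker background have
   strongly negative principal curvature across the curve.
3. **Vertical filtering, opening, binarization.** Cross-correlation with
   the 10 × 3 kernel whose rows are `(1, 0, -1)` (absolute value taken):
   vertical structures spanning ten rows accumulate tenfold; horizontal
   ones contribute from a single row. Grayscale opening with a 7 × 1
   vertical line then suppresses speckle while sparing vertical ridges,
   and the brightest 10% of pixels are kept ("first decile" read as the
   *top* decile — the brightest, sharpest elements; the literal bottom
   decile would select background). The on-fraction is exact to one pixel
   when values are distinct.
4. **DBSCAN.** The binary map is a 2-D point cloud; standard DBSCAN
   (grid-bucketed neighbour search, `eps` = 0.15 cm in pixels, `min_pts`
   = 5) separates the tube cluster from scattered noise and blob
   artifacts. Cluster ids are deterministic (first-core-index order;
   border ties to the smallest-index core neighbour).
5. **Cluster thinning.** From the cluster point nearest the predicted
   tip, walk upward one row at a time, keeping the single point whose
   column is nearest the previous one (search window ±3 px, ties to the
   smaller column, up to 5 consecutive empty rows tolerated). Columnar
   continuity makes the walk follow the near-vertical ETT and shed a
   gastric tube diverging at an angle, even when DBSCAN merged both into
   one cluster.

### Numerical choices that matter

* **Ridge scale.** `scale_px` defaults to 0.05 cm (the radiopaque line's
  wall thickness) divided by the column spacing, minimum 1 px. The
  vertical filter is a horizontal derivative, so its response peaks one
  profile-width either side of the ridge crest; smoothing at the full
  tube radius (0.25 cm) widens the profile and displaces the retained
  rails several pixels off the centerline, while the wall-thickness scale
  keeps them within ±2 px at typical portable-film resolutions.
* **Border handling.** Smoothing and morphology use replicate padding, so
  a tube touching the top of the frame is not eroded and a constant map
  filters to exactly zero. Genuine image borders inside the ROI can still
  win the decile cut on strongly tilted films — a known failure mode of
  the method that we reproduce rather than silently fix (an optional
  `exclude_border` mask is off by default).
* **Known limitation: laterally bowed tubes.** When the tube bows
  monotonically sideways, the nearest-column walk hugs the trailing edge
  of the binarized band and can sit 2–3 px behind a strongly curved
  centerline. On phantoms with a realistic 0.4-cm lateral bow the walk
  stays on the tube but its sub-band position is biased; on straight or
  gently tilted tubes it tracks the centerline within ±1 px.
* **Degenerate inputs.** An all-noise ROI yields either a
  `segmentation_failure` condition (no non-noise cluster) or a short
  polyline; both are legitimate outcomes and the run report records them.

## Evaluation statistics

* `mae()` — mean absolute error with n−1 standard deviation; position
  errors are 2-D Euclidean distances in cm.
* `mean_error_cs()` — the mean signed error under a compound-symmetry
  (exchangeable) covariance within clusters, fitted by REML
  (`nlme::gls`), with CI and two-sided p-value on a t reference with
  (number of clusters − 1) degrees of freedom. With singleton clusters
  the correlation is unidentifiable and the procedure *is* the one-sample
  t test, which is returned exactly. The clustering unit is the caller's
  choice (image id by default); with repeated measures per film the
  balanced-design variance matches the closed form
  `sigma^2 (1 + rho) / (2m)`.
* `rater_agreement()` — mean absolute difference per quantity plus the CS
  mean of signed differences. A signed error of a 2-D landmark needs a
  direction: we use the craniocaudal (row-axis) component, the clinically
  meaningful one; the absolute part stays Euclidean.
* `confusion_and_rates()` — positive class `too_low`; Wald 95% intervals
  clipped to [0, 1] (Wilson by flag); undefined rates are reported as
  `NA`, never 0 or 1.

## The phantom generator

`phantom_spec()` defaults describe a portable ICU film at desk scale: a
600 × 500 px frame at 0.05 cm/px (a 30 × 25 cm field), background level
60/255, a tube rendered as an anti-aliased bright curve (~2.5 px wide, 80
levels above background, cubic-polynomial centerline supporting tilt and
lateral bow), a dark inverted-V carina template, optional gastric tube
(overlapping then diverging at 45°), optional horizontal cable, bright
blob artifacts, and additive Gaussian noise (sd 8). All randomness is
fixed by the seed; the truth object records the exact rendered centerline,
tip, carina, distance and placement label.

What the phantom does *not* emulate: anatomy (ribs, mediastinum, lung
opacities), scatter and heel effects, burned-in text, and detector-specific
failure modes. Passing the phantom suites therefore demonstrates that the
geometry, calibration and statistics are implemented correctly — not that
any particular detector performs well on clinical films.

The oracle detector inverts the calibration law: it samples a confidence
`C`, then displaces the tip along the tip→carina axis by a Gaussian amount
whose expected absolute value is `noise_scale * U(C)`, so the absolute
distance error follows the law exactly (`noise_scale = 0` disables noise;
displacement along the axis keeps the relationship exact rather than
first-order). This closes the loop for end-to-end parameter-recovery
tests.

## Problem sizes

The shipped test-suite and reproduction scripts use 600 × 500 phantoms,
2 000 draws for calibration recovery, 2 000 replicates for the type-I
calibration of the mixed model, and 100 random instances (≤ 200 points)
for the DBSCAN/oracle equivalence — sizes chosen so the full suite runs in
well under five minutes on a single core while keeping Monte-Carlo error
far below the asserted tolerances.
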