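---
title: "Estimating LVEF from LV masks by the method of disks"
author: "echoSimpson"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating LVEF from LV masks by the method of disks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The left-ventricular ejection fraction,

$$\mathrm{LVEF} = \frac{\mathrm{EDV} - \mathrm{ESV}}{\mathrm{EDV}} \times 100\,\%,$$

is the fraction of the end-diastolic blood volume ejected per beat and
the workhorse index of systolic function.  Clinically it is computed
from two echocardiographic frames — end-diastole (maximal volume) and
end-systole (minimal volume) — by tracing the left-ventricular (LV)
endocardial border and applying Simpson's method of disks: slice the
chamber into $n$ equal-height disks perpendicular to its long axis and
sum the disk volumes

$$V = \sum_{i=1}^{n} \frac{\pi\, a_i\, b_i\, l}{4},$$

where $a_i$ and $b_i$ are the full disk diameters measured in two
orthogonal apical views (four-chamber, A4C, and two-chamber, A2C) and
$l = L/n$ is the disk height along a major axis of length $L$.  When
only the A4C view is available the monoplane form assumes circular
disks, $b_i = a_i$.  This package consumes binary LV segmentation
masks of the two frames and carries out every intermediate step of
that workflow, so each quantity a cardiologist would inspect —
contour, landmarks, axis, diameters, volumes — is an explicit object.

A note on notation: some texts write $a_i, b_i$ as "semi-axes", but
the $/4$ divisor is only dimensionally consistent with full diameters
(an ellipse with diameters $a$ and $b$ has area $\pi a b / 4$); the
package treats them as full diameters throughout.

## Geometric conventions

All pixel coordinates are $(x, y)$ with $x$ the column index and $y$
the row index, both 0-based, pixel centers at integer coordinates, $y$
increasing downward (image convention).  Physical calibration is a
scalar `spacingMmPerPx`; public EchoNet-style exports carry no
calibration, so the default is 1 mm/px and calibration is explicit
configuration.

**Contour.**  `extractContour()` keeps the largest connected component
of the mask, fills interior holes (segmentation masks are imperfect),
and traces the boundary once with a Moore-neighbor walk.  The returned
polygon starts at the boundary pixel with lexicographically smallest
$(y, x)$, runs counter-clockwise (positive shoelace area in the
$x$-right/$y$-down frame), and contains exactly the foreground pixels
having at least one background 8-neighbor.

**Landmarks.**  The clinical landmarks are the apex and the midpoint
of the mitral annulus; their localization on a bare mask is not
standardized, so the package fixes a testable rule:

1. the long-axis direction is the principal axis of the boundary
   points (second moments);
2. at each axis-extreme end, the candidate endpoint is the *centroid of
   the boundary points within one pixel of the extreme projection* —
   for a flat mitral plane every basal pixel projects equally, and the
   centroid yields the basal midpoint, whereas a raw argmax would pick
   an arbitrary corner and bias the axis length by up to
   $\sqrt{L^2+r^2}/L$;
3. the apex is the end with the smaller local width, measured as the
   maximal perpendicular spread of boundary points within the 10 % of
   the axis length nearest that end — anatomically the apex is pointed
   and the base broad;
4. if the two widths differ by less than 1 % (e.g. a near-circular
   mask) the end nearer the image top is taken as apex, matching the
   apex-up A4C display convention, with a warning.  A contour whose
   points are collinear within one pixel is rejected as degenerate.

**Disks.**  The axis from mitral midpoint to apex is divided into $n$
equal parts (clinical default $n = 20$); disk $k$ is centered at
$\mathrm{base} + (k - \tfrac12)/n \cdot (\mathrm{apex} -
\mathrm{base})$, ordered base → apex.  The region of interest of a
disk is the perpendicular *slab* of thickness $l$ centered at its
position: the foreground pixels whose signed projection onto the axis
falls within $\pm l/2$ of the disk center's projection.  The slabs
partition the chamber, mirroring the volume decomposition, and make
the diameter rule well-posed; a circular region (radius $l/2$) is
available as `roi = "circle"` for comparison.  The diameter $a_i$ is
the maximum Euclidean distance between any two pixels of the region,
computed exactly via the region's convex hull (identical to all-pairs,
much cheaper); an empty region legally yields $a_i = 0$.

## Discretization behaviour of the disk sum

Two systematic effects of the slab rule are worth knowing when
interpreting results on synthetic shapes.

*Wide-edge bias.*  For a chamber whose chord narrows monotonically
toward the apex, the maximum pairwise distance within a slab is
attained at the slab's basal edge, so $a_i$ measures the chord at
$x_k - l/2$ rather than at the disk center $x_k$ (plus a small
diagonal term $\sqrt{1 + (l/c)^2}$ when the chord $c$ is comparable to
$l$).  For a half prolate spheroid the induced volume inflation is
$6/(8n)$ to leading order — about $3.75\,\%$ at $n = 20$ —
*independently of the chamber's size*.  It therefore cancels almost
exactly in the EDV/ESV ratio, which is why end-to-end EF errors
(≈ 0.5 EF points median on noiseless renders) are an order of
magnitude smaller than the individual volume biases.  The residual EF
error is driven by the diagonal term, which is relatively larger for
the smaller ES chamber.

*Near-apex relative error.*  Because the chord of a spheroid varies as
$\sqrt{1 - u^2}$, the half-slab shift exceeds 3 % of the local chord
once the disk center passes $x/L \approx 0.67$.  Property tests that
compare measured diameters against the analytic chord at disk centers
therefore check the basal two-thirds of the disks (1–13 of 20); the
apical disks are correct under the slab rule but are not point samples
of the chord.

*Quantization.*  Diameters are distances between pixel centers, so a
single diameter is reproducible across resolutions only to about one
coarse pixel (slab boundaries shift relative to the pixel grid).  The
package's consistency tests bound the per-diameter change between
0.5 mm/px and 0.25 mm/px renders by two coarse pixels and the summed
volume change by 2 %; the measured volume change for the reference
spheroid is ≈ 1.3 %.

## The synthetic generator

`makeCase()`/`makeDataset()` provide exact ground truth without any
external dataset.  The LV stand-in is a solid of revolution with
radius profile

$$\rho(x) = r\,\bigl(1 - (x/L)^2\bigr)^{p/2},$$

$x$ the distance from the basal plane: widest at the base, pointed at
the apex.  $p = 1$ (the default and the only family used for ground
truth) is a half prolate spheroid with closed-form volume
$V = \tfrac23 \pi r^2 L$; other exponents exercise blunter or more
bullet-like chambers through a high-resolution numerical revolution
integral (`analyticVolume()`, ≥ 10⁴ midpoint slices, stable to well
under $10^{-4}$ relative under slice doubling).

A case solves for the ED pair $(L, r)$ and the ES pair so the
analytic volumes meet the requested EDV and EF exactly: the ES shape
is the ED shape radially contracted, with a randomly drawn 3–10 %
long-axis shortening, mimicking systolic contraction.  Generator
conditions (chosen once, on clinical plausibility):

| parameter | default | rationale |
|---|---|---|
| EF targets | U(20, 75) % | spans severely reduced to hyperdynamic |
| EDV targets | U(70, 180) mL | typical adult range |
| ED axis length | U(70, 95) mm | typical adult A4C LV length |
| ES long-axis shortening | U(3, 10) % | mild physiologic shortening |
| rotation / translation | ±10°, ±8 px | pose variation for equivariance |
| spacing | 0.5 mm/px | sub-millimetre rendering |
| canvas | 256 × 256 px | fits a 95 mm LV at 0.5 mm/px |

`renderMask()` itself defaults to a 112 × 112 canvas, the standard
input size of segmentation networks in this setting; dataset rendering
uses the larger canvas so the full-size shapes fit.  All randomness is
seeded: targets come from the dataset seed, per-case shape and pose
from `seed + i`.  The two streams are deliberately separate — drawing
a case's targets and its internal parameters from the same stream
would correlate, e.g., the EF target with the axis length and leak the
label into a feature.

An optional noise model perturbs the contour with Gaussian radial
jitter (SD in mm, sampled at 64 axial knots, linearly interpolated)
before rasterization; the default is 0 so oracle tests stay exact.
What the generator does **not** emulate: ultrasound speckle and
texture, segmentation-network error structure (boundary
over/under-shoot correlated along the wall, basal-plane ambiguity),
foreshortened views, and any discrepancy between the monoplane
geometric volume and a clinically adjudicated volume — for these
shapes the monoplane circular-disk assumption is *exactly* true.
Passing the synthetic tests therefore validates the geometry,
volumetrics and plumbing; it does not by itself predict accuracy on
real echocardiograms.

That last point has a visible consequence.  On real data, regression
on the extracted features outperforms the direct Simpson computation,
because regression calibrates away systematic segmentation and
cross-method biases.  On noiseless synthetic data there is nothing to
calibrate: the direct computation is near-oracle (cohort MAE well
under 1 EF point), while EF
$= 100\,(1 - r_{es}^2 L_{es} / (r_{ed}^2 L_{ed}))$ is a smooth *ratio*
that no linear function of the diameters and lengths matches to that
accuracy over the full study range.  The acceptance script reports
both numbers (`lr_test_mae`, `simpson_test_mae`) so the relationship
is measured, not asserted.

## Regression on extracted features

The feature vector concatenates the 20 ED diameters (base → apex), the
ED axis length, the 20 ES diameters and the ES axis length — 42
features in a fixed, documented column order (`featureNames()`), with
the reference EF as label.

* **Linear regression** is native: ordinary least squares by QR
  factorization, with a ridge fallback ($\lambda = 10^{-8}$) when the
  design is rank-deficient or has fewer rows than the 43 parameters.
* **SVR / decision tree / random forest** are delegated to the
  standard implementations (e1071, rpart, randomForest) behind the
  package's fixed contract, with hyperparameter grids as
  configuration: SVR kernel ∈ {linear, rbf}, degree 2–6,
  γ ∈ {0.001, 0.01, 0.1, 1}, C ∈ {0.1, 1, 10}, ε ∈ {0.1, 0.01, 0.001};
  tree depth 5–10 and leaf/split minima 5–20; forest size 100–500 with
  depth ∈ {unlimited, 5, 10} and mtry ∈ {all, √p, log₂p}.  Two
  mappings are worth noting: `randomForest` exposes no depth control,
  so `max_depth = d` is implemented as `maxnodes = 2^d`; and the
  leaf/split ranges are searched in steps of 2.
* **RNN / LSTM** consume the features as a 2-step sequence — step 1
  the ED block, step 2 the ES block (`sequenceLayout()`, a lossless
  reshape) — so the recurrence spans the diastole→systole transition.
  They are a compact native implementation (stacked Elman or LSTM
  layers, backpropagation through time, MSE loss), configured by
  default as published for this task: layers 128/32/16 (RNN, Adam) or
  64/32/16 (LSTM, SGD), learning rate 0.001, batch 32, 70/100 epochs,
  tanh activations.  Gradients are verified against central finite
  differences in the test suite.

Model selection is exhaustive grid search with $k$-fold
cross-validation ($k = 5$), minimizing mean squared error — the same
criterion as the network training loss; the full CV table is returned
for audit.  Fold assignment is a pure function of (row count, fold
count, seed).  Feature standardization (z-score with training-set
statistics, exactly invertible) is applied for the kernel and sequence
learners; tree learners see raw features; the regression target is
likewise standardized internally for the networks and inverted at
prediction.  For synthetic experiments the package uses a
200-train/50-test split (matching the ≈ 74/13/13 proportions of the
large public dataset at the scale of a desk-size cohort).

## Evaluation metrics

* Dice similarity $2|A \cap B|/(|A| + |B|)$; two empty masks are
  defined as agreeing (DSC 1) with a warning, avoiding 0/0.
* Hausdorff distance, the maximum of the two directed max–min
  point-set distances, in mm.
* Contour MAE: the symmetric mean nearest-neighbor distance between
  contour point sets.  No pairing between predicted and reference
  points is assumed; this choice is symmetric, pairing-free, and zero
  exactly on identical sets.
* Cohort agreement: MAE, RMSE (always ≥ MAE), Pearson correlation
  (undefined and reported NA with a warning for constant series), and
  Bland–Altman bias with limits of agreement at ±1.96 sample standard
  deviations ($n-1$ denominator) of the paired differences, with
  optional Bland–Altman and correlation scatter plots.

## Numerical choices and degenerate inputs

* Empty disk regions yield a 0 diameter, not an error; a single-pixel
  mask yields a profile of zeros.
* Negative EF (ESV > EDV, e.g. a mislabeled frame pair) warns rather
  than errors; EDV ≤ 0 is an error.
* Biplane sums require equal disk counts and axis lengths within 5 %;
  the primary profile's disk height is used.
* Component ties during mask cleaning resolve to the first label in
  raster-scan order; landmark width ties resolve apex-up with a
  warning.
* Cohort runs never abort on a failing case: the case is logged,
  skipped, and listed in the summary.
* All writers are deterministic (fixed column order and float
  formatting), so re-running a configuration reproduces CSV outputs
  byte-identically.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data at desk scale, the package's chosen study sizes: 50-case cohorts
for end-to-end EF recovery, a 250-case cohort (200 train / 50 test)
for the regression comparison, 256 × 256 px renders at 0.5 mm/px, and
20 disks.  The volume-summation oracle uses analytically sampled
diameters at $n = 20$ and $n = 400$ against the spheroid closed form.

## Known limitations

* The landmark rule assumes a single, roughly convex chamber with a
  pointed apex and broad base; masks violating that (e.g. severe
  segmentation failures) fall back to the apex-up tie-break or fail
  loudly.
* Monoplane volumes inherit the circular-disk assumption; on real
  ventricles with non-circular cross-sections this is a modeling
  error the synthetic suite cannot expose (its shapes satisfy the
  assumption by construction).
* The recurrent regressors are deliberately compact CPU
  implementations for the 2-step sequence; they are not a general
  deep-learning substrate.
* Contour jitter is the only segmentation-noise model; it does not
  reproduce structured segmentation-network errors.
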