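---
title: "Quantifying and normalizing peptide-microarray kinome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and normalizing peptide-microarray kinome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinorm)
```

## The measurement and its failure modes

A kinome-profiling peptide array carries short kinase-substrate peptides —
by default 1024 substrates spotted as three replicate 32 × 32 sets, 560 µm
apart, 250 µm spot diameter — incubated with cell lysate and radiolabelled
ATP. A phosphorimager reads the deposited β-radiation at 50 µm/pixel and
stores square-root-compressed 16-bit values. Three properties make the
downstream statistics unlike expression arrays:

1. there is no housekeeping kinase, and total kinase activity legitimately
   differs between conditions;
2. the chip is small (~1000 features) and typically 50–70% of spots are
   unphosphorylated ("off-spots"), so little buffering mass is available
   for distribution-matching normalizers;
3. enzymatic kinetics turn small spatial differences in sample or peptide
   concentration into smooth intensity gradients across a slide.

Under these conditions global median-centering or quantile normalization
misattribute genuine induction to technical shift and create artificial
repression in the unaffected spots. The pipeline in this package addresses
each failure mode in turn: per-spot quality flagging, triplicate-based
intraslide gradient correction, and an iterative interarray normalization
(RSE) that centers only on substrates showing no significant condition
difference.

## Image analysis and quantification

Raw pixels are first reverse-transformed, `I = I_raw² / TF` with
`TF = 42752`, undoing the scanner's square-root compression; saturation is
defined on this scale (level 95 000, which corresponds to a raw value just
below the 16-bit ceiling). The exact functional form of the scanner
transform is configurable via `transform_spec()`; the quadratic form is the
one consistent with the stated transformation factor and saturation level,
and is the package default.

Gridding and quality control run on an *enhanced* image — 3 × 3 median
filter, negated Laplacian-of-Gaussian with σ = spot radius/√2 (≈ 1.8 px,
matched-filter sizing for a Gaussian spot of 250 µm FWHM), morphological
opening with a 1-px disc (removing objects under 100 µm), final Gaussian
smoothing with σ = 1 px. All four parameters are exposed in
`enhance_image()`. Intensity quantification never reads enhanced pixels;
it always returns to the reverse-transformed image.

Rotation alignment thresholds the enhanced image at its 87th percentile and
scans ±3° in 0.1° steps for the angle maximizing the variance of the
column-sum profile — sharp column peaks indicate vertically aligned spot
columns. The objective is a design choice (the alignment criterion itself is
not fully determined by the procedure's description); the variance of the
marginal profile is the simplest statistic that is maximal exactly when
columns align. Angles at the bound raise a warning.

Within user-supplied bounds the spotted area is partitioned into 8 × 8 pin
blocks (±10% tolerance on the bounds, proportional rescale). Per block,
round objects of the expected size are detected at two thresholds — 96th
percentile (bright) and 85th (weak; objects found only at the weak
threshold are classified weak) — with a floor of 6 robust SDs (MAD) of the
enhanced response so that sparse blocks do not grow objects out of noise.
An ideal grid is then placed by maximizing the summed weight (bright 3,
weak 1) of objects whose centroid falls within 125 µm of a node, searching
translations up to one pitch (0.25 px resolution) and, when at least four
objects anchor it, pitch scalings of ±5%. Two numerical details matter:
a tiny distance penalty (10⁻⁶ × squared centroid–node distance) breaks
ties between placements that catch the same objects, and among placements
within 0.01 of the optimal score the one closest to the nominal grid wins —
whole-pitch translations otherwise tie exactly and would re-index every
spot. A block with no detected objects falls back to the nominal grid with
a warning.

Per spot, the centre is refined within ±2 px (100 µm) of its grid node by
maximizing the 21-pixel disc mean; net intensity is the disc mean minus the
median of the background region (550 µm square minus a 275 µm exclusion
circle, minus any large-artifact pixels), log2-transformed. Net intensities
≤ 0 become missing; we use ≤ rather than strict < so that `log2` is always
defined on unflagged spots.

### Quality flags

Eight binary flags, each 1 = unreliable (`quantify_params()` holds every
constant):

* **artifact** — a connected component of the reverse-transformed image
  above its 90th percentile that is either very large (> 20 spot areas) or
  large and elongated (> 2 spot areas with aspect > 2) covers more than 30%
  of the spot's background window, or fewer than 10 background pixels
  remain. The component-size rule is this package's operationalization of
  "a large artifact shadows the spot": it captures stripes and blemishes
  while leaving even very bright round spots untouched.
* **overshine** — a directly neighbouring bright spot (log2 > 8) shows
  uniformly decreasing intensity along a 5-sample ray into the spot area,
  and the ray still exceeds background median + 3 robust SD where it meets
  the measurement disc. The gate on the ray's final sample (rather than on
  the disc mean against background + 3 SD) is deliberate: radially decaying
  bleed elevates the background window with a spread of the same order as
  the disc elevation, so a disc-mean gate can structurally never fire.
  The robust (MAD) spread stops the bleed from masking itself.
* **ks** — a two-sample Kolmogorov–Smirnov test of the 21 disc pixels
  against the background pixels fails to reject at α = 0.01: the spot is
  indistinguishable from background. This is the off-spot marker; its
  polarity (flagging *indistinguishable* spots) means downstream
  normalization automatically excludes off-spots together with all other
  flagged spots.
* **no-contrast** — all enhanced-image disc pixels are negative, or the net
  intensity is ≤ 0.
* **saturated** — more than 3 of the 21 disc pixels exceed 95 000 on the
  reverse-transformed scale.
* **shape** — the connected above-threshold object at the centre of a
  500 µm window (80th-percentile threshold) has an aspect ratio above 1.6
  for bright spots (log2 > 8) or 2.0 for weak ones. The aspect ratio is the
  square root of the second-moment eigenvalue ratio, regularized by the
  1/12 single-pixel variance so tiny objects do not divide by zero.
* **position** — the intensity-weighted centroid of that object lies more
  than 100 µm (configurable) from the grid node. Restricting both shape and
  position to the *connected central object*, rather than all
  above-threshold window pixels, keeps isolated bright background pixels
  from dragging the centroid.
* **overall** — OR of the seven.

Missing inputs set the corresponding flag conservatively to 1.

## Intraslide gradient correction

Each substrate appears once per replicate set at the same within-set
position. For every spot, deviations against its two replicate counterparts
are computed (only between unflagged spots); a local gradient per
counterpart set is the median deviation over the nearest ≥ 20 unflagged
spots, excluding the spot's own deviation. The neighbourhood is grown as a
circle in steps of one spot pitch (560 µm) until it holds the minimum
count, and every eligible spot inside the final circle participates — ties
at the boundary are all included, which makes the result independent of
enumeration order. The search never crosses set boundaries: a deviation is
a property of a location *within* a set, and a 96 × 32 cross-set
neighbourhood would mix gradient regimes.

The applied correction is `(gradient₁ + gradient₂) / 3`, subtracted from
the observed value. The divisor equal to the number of sets is what makes
the procedure self-consistent: if set 3 is offset by −δ while sets 1 and 2
agree, the corrections are +δ/3, +δ/3 and −2δ/3, and after subtraction all
three sets coincide exactly (the test suite verifies this identity to
machine precision over random offsets and layouts). The subtraction sign is
fixed by that same algebra. Flagged spots pass through uncorrected — they
are excluded downstream anyway, and interpolating values for them would
manufacture data. A single correction pass is applied; the procedure is not
iterated.

## RSE interarray normalization

A control/treatment pair is normalized on substrate triplicate means
(unflagged replicates only):

1. **Local median-centering** over all substrates passing QC in both
   conditions: for each substrate, the median of the between-condition
   differences `d(s)` over its ≥ 20 nearest eligible substrates (the same
   radius-growth rule; here the substrate itself is *included*, since
   unlike the intraslide case its own difference carries no self-referential
   bias) gives an offset `m(s)`, applied symmetrically: +m/2 to the control
   slide, −m/2 to the treatment slide, preserving the pair mean. An option
   to anchor one slide instead is available through the returned offsets.
2. **Exclusion** of condition-affected substrates by a two-sided
   two-sample Student t-test (pooled variance — with three replicates per
   group, Welch degrees of freedom are too unstable) at the quasi-stringent
   α = 0.1 on the centered values. Centering shifts both groups of a
   substrate by constants, so only the mean difference `d(s) − m(s)` moves;
   testing on centered values makes the decision invariant to the overall
   array offset. Substrates with under two usable replicates in either
   condition are treated as unaffected (they cannot be tested, and
   excluding them would only shrink the centering set).
3. Re-centering on the reduced set, re-testing, and so on until the set
   repeats. Each iteration rebuilds the centering from the *original*
   values with the current set, so a substrate excluded early can re-enter
   later. Exact set identity between successive iterations is the
   convergence criterion; a revisited earlier set (a cycle) is resolved
   deterministically by centering on the cycle union, with a warning, and
   recorded as `stabilized_by = "cycle"`. Only exhausting `max_iterations`
   (default 50) counts as non-convergence.

Zero pooled variance is handled explicitly: identical values on both sides
give p = 1, a nonzero difference with zero variance gives p = 0. The
per-substrate t battery is computed vectorized from group summaries for
speed; the test suite pins it against `stats::t.test(var.equal = TRUE)`.

The two baselines used for comparison are global median-centering (all
spots, flags ignored, slides shifted to the common median) and quantile
normalization (rank-wise order-statistic means, ties receiving the mean of
their tied quantile values; spots missing in any slide are left
unnormalized and excluded from quantile estimation).

## The in-silico experiment generator

`simulate_experiment()` builds the virtual study the validation rests on.
Per substrate and patient, each log2 spot value is the sum of:

| component | distribution | default | shared across |
|---|---|---|---|
| basic intensity | N(µ = 10, σ = 1.5) | — | replicates, conditions, patients |
| patient variation | N(0, σ = 0.5) | — | replicates, conditions |
| treatment effect | E (+ variation, below) | E = 0.8 | induced substrates, treatment slide |
| intraslide gradient | smooth field, range *g* | g = 1.0 | slide (per-position value) |
| array effect | U[−2, 0] | — | slide |
| spot error | N(0, σ = 0.4) | — | nothing (per replicate) |

The default effect size E = 0.8 is the effect/spot-error ratio of 2 that
defines the reference design; 197 of 1024 substrates are induced, organized
by `annotation_fixture()` into 2 pathways of 9 kinases each (11 or 10
substrates per kinase), with decoy pathways of comparable size over
uninduced substrates. In pathway mode two further sources are added:
per-patient biological effect-size variation N(0, 0.4) and per-substrate
technical effect-size variation U(−0.2, 0.2) (use ±0.33 E in effect-size
sweeps). Spot error is drawn per replicate — per-substrate error would make
the triplicate t-tests degenerate.

Gradient fields are parametric smooth surfaces over the full 96 × 32 grid
(sums of 1–3 random low-frequency cosine waves and Gaussian bumps),
rescaled to mean zero and max − min equal to the configured strength; the
default strength 1.0 sits mid-way in the 0.4–1.5 range that gradient
correction is designed for, and 15 candidate fields are drawn with one
assigned independently to every slide (a patient's two slides do not share
a field). Off-spots, when requested, are modelled as detection-floor noise
N(0, σ_error) carrying a pre-set KS flag — off-spots do not follow the
slide's systematic effects, and flagged spots are exactly what the
normalization excludes. All components draw from named substreams of the
master seed, so changing one leaves the others bit-identical.

What the generator does **not** emulate: spatially correlated spot error,
replicate-set-specific printing differences, intensity-dependent variance,
partial saturation of real scans, or the composition of real chip
annotation. Passing the in-silico benchmarks therefore demonstrates the
normalization algebra and its selectivity under the stated noise model, not
performance on any particular biological data set.

## Evaluation harness

Per-substrate two-sided pooled t-tests between the normalized triplicates
give p-values; with the induced labels known, calls at α = 0.05 yield
confusion counts, and the ROC curve is swept over all observed p-values
(lower p = more positive). The AUC is computed by the Mann–Whitney rank
statistic with averaged ties, which the trapezoid over the sweep reproduces
exactly (the curve includes the (0, 0) origin so the first segment is
counted). Pathway tests pair each substrate's triplicate mean across
conditions and apply a paired t-test per pathway (< 3 usable substrates:
skipped); constant paired differences short-circuit to p = 1 (zero
difference) or p = 0.

`benchmark_normalizers()` sweeps a grid of simulation configurations ×
normalizers, optionally applying gradient correction first, and reports the
mean AUC over patients and repeats with its SEM.

## Problem sizes and test design

The packaged test suite exercises the full default design (8 patients,
3 × 1024 spots) for the RSE convergence and set-size checks, 50 seeds for
array-effect recovery, five-seed null calibrations, a three-point induced
fraction sweep (5/10/20%) at 8 patients × 5 repeats for the normalizer
comparison, and single-set 32 × 32 slides for the imaging round trip; the
oracle-equivalence properties run on 8 × 8 to 16 × 16 layouts where
brute-force enumeration is cheap. Within-triplicate spread reduction under
gradient correction is asserted on the mean over eight slides per gradient
strength: at the weak end of the range (0.4) the correction's median noise
is of the same order as the gradient it removes, so individual slides can
break even while the average strictly improves.

## Known limitations

* RSE is pairwise by design (control vs treatment per patient); no
  multi-slide generalization is provided.
* The interarray step assumes a large fraction of substrates is unaffected;
  with a majority of induced substrates the converged set loses its meaning
  (the generator lets you probe this regime).
* Flagged spots are excluded, never repaired or imputed.
* Grid fitting assumes an approximately regular print; strongly distorted
  or partially printed slides fall back to nominal geometry per block
  rather than failing loudly.
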