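---
title: "Quantifying corneal vascularization from longitudinal en-face angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corneal vascularization from longitudinal en-face angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctrack)
```

## The problem

In the suture-induced rabbit model of corneal neovascularization, vessels
sprout from the limbus (the vascularized corneal border) and grow
centripetally toward rows of corneal sutures, reaching the central cornea
after about two weeks. Anti-VEGF treatment then drives the vessels to
regress row by row back toward the limbus; depending on the drug and the
delivery route the regression is sustained or followed by regrowth. The
study question is quantitative: what fraction of the cornea is
vascularized at each weekly visit, and how much did the vasculature grow
or regress between visits, measured consistently enough that treatment
arms can be compared and two imaging modalities (OCT angiography and
indocyanine green angiography) can be checked against each other.

`vasctrack` implements the full measurement chain and, because no public
image set accompanies this kind of preclinical study, a ground-truthed
simulator of the whole experiment. The simulator is first-class, tested
code: every downstream claim about the pipeline's accuracy is made
against its known truth.

## The synthetic study

`simulation_config()` defines the study conditions. Vessels are grown as
a biased branching random walk: `n_roots` (18) roots are seeded uniformly
on the limbal circle (radius fraction 0.88 of the half-canvas on a
160×160 px canvas) and advance in steps of `step_len` (4 px) with their
heading pulled halfway toward the centripetal direction plus Gaussian
angular noise (`dir_noise_sd` = 0.35 rad). Each step each tip branches
with probability 0.10. Segment radii start at 1.9 px and decay by a
factor 0.985 per step with a 1 px floor. Growth stops when every active
tip has passed the week's target suture row; the four suture rows sit at
radius fractions 0.80, 0.62, 0.44, 0.26 of the limbal radius (row 4
innermost), with week 1 targeting row 2 and week 2 row 4 — the
"vessels reach the central cornea at two weeks" endpoint of the model.

These defaults were set once so that week-2 (pre-treatment) true
densities land in the 20–35% band that anti-VEGF studies report for the
vascularized state (arm means near 25–32%); across generator seeds they
produce 26–32%. This is not a physiological angiogenesis model — there is
no VEGF field, no anastomosis, no flow — it is a geometry generator with
controllable density and centripetal direction, which is all the
measurement pipeline needs.

Treatment (weeks 3 and 4) is a per-arm/per-route schedule
(`default_schedule()`):

* saline controls keep growing toward virtual inner targets;
* the aflibercept-like arm prunes the latest-born segment fraction at
  both weeks (0.40 then 0.18 injected; 0.50 then 0.35 topical) —
  sustained regression;
* the ranibizumab-like arm prunes at week 3 (0.45 injected, 0.50
  topical) and regrows at week 4 — the rebound pattern.

Pruning is distal-first by birth order (ties by segment index), which
reproduces the row-by-row regression seen clinically, and because
children are always born after their parents it can never orphan a
segment. The prune fractions were chosen once to approximate the
reported arm-mean trajectories (e.g. ~30% → ~19% → ~17% for the injected
aflibercept-like arm).

Rendering turns the rasterized boolean vessel map into modality-specific
frames. OCTA: vessel level 0.88 over background 0.12, multiplicative
speckle (SD 0.18 of the local level), additive noise (SD 0.04), a 0.6 px
PSF, and Poisson(1.5) bright motion-artefact rows (+0.55) along the
fast-scan axis. ICGA: lower contrast (0.75 over 0.22), a wider 0.8 px
PSF, a smooth additive fluorescence gradient (amplitude 0.25, random
orientation) and milder speckle. The ICGA PSF deserves a note: at
substantially larger widths (≳1.3 px at this sampling) blur structurally
biases any area measurement — it dilates sparse vasculature and erodes
dense vasculature by several percentage points — which would contradict
the close OCTA/ICGA agreement (correlation ≈ 0.99, sub-point mean
differences) that motivates using the two modalities interchangeably.
The default keeps ICGA optically worse than OCTA but inside the regime
where vessel area remains recoverable.

Each visit is rendered twice per modality with independent noise
(same vasculature, same pose): these are the same-session replicates used
for repeatability. Between consecutive visits the eye is repositioned by
a random rigid pose (translation up to 3% of the canvas per visit,
rotation up to 2°, so relative inter-visit transforms reach ~6%/4°); the
moving-to-fixed transform of every pair is recorded in the ground truth
together with exact per-visit densities.

What the simulator does **not** emulate: depth-projection artefacts,
vessel-diameter changes under treatment (regression removes whole
segments), non-rigid tissue deformation, defocus or signal-strength
variation between sessions, and ICGA dye-timing effects. Passing tests
therefore demonstrate correctness of the measurement chain under
controlled conditions, not robustness to every failure mode of real
acquisitions.

## Preprocessing

Motion-artefact rows are flagged when the robust z-score of the row mean
(against the median/MAD of all row means) exceeds 3.5 and are replaced by
the average of the nearest clean rows above and below; if more than 30%
of rows are flagged the image is declared unusable rather than silently
repaired. Denoising is a radius-1 median filter. Two ICGA-only steps
exist: rolling-ball background flattening (grayscale opening with a disc
of radius 9 px — an estimate that cannot absorb vasculature, unlike a
plain median, since opening removes all bright structure smaller than
the element) and unsharp masking (σ = 1.3 px, gain 1) to compensate the
modality's excess PSF. Flattening is **off** by default: measured on
dense frames, subtracting any estimated background removed several
percentage points of true vessel area, while the seeded segmentation
below already discards unseeded background components, which neutralizes
the smooth gradient. The step remains available (`flatten = TRUE`) for
data with stronger gradients.

## Registration

The transform family is rigid with unit scale: session-to-session eye
repositioning at this field size is well approximated by a rotation plus
translation, and the optics do not change between visits. Translation is
estimated by phase correlation (FFT cross-power spectrum) with parabolic
sub-pixel refinement; rotation by a coarse 0.5° grid over ±10° followed
by golden-section refinement, re-estimating the translation at every
candidate and scoring by normalized correlation on the overlap.
Registration always runs on preprocessed intensity images, never on
binary masks, so segmentation error cannot propagate into alignment. A
normalized-correlation floor (default 0.2) turns bad alignments into
classed failures; the pipeline logs and excludes the affected interval
instead of aborting the study. On simulated pairs with default noise the
recovery error is ~0.1–0.3 px and ~0.05°, comfortably inside the 0.5 px
/ 0.5° tolerance the tests assert.

## Segmentation

The binarization is vesselness-seeded reconstruction, and the reason is
worth recording. The obvious design — threshold a multiscale Hessian
vesselness response directly — was implemented first and measured: at
the densities this model reaches (25–35% of the cornea), converging
vessels merge into clusters whose interiors are flat, so *every*
curvature-based response is zero exactly where vessels are thickest.
Direct thresholding capped noiseless Dice overlap at ~0.87–0.94 and
biased densities by up to −14 points; no threshold choice fixes a
support that the response does not carry. The shipped default therefore
uses the Hessian line filter (rectified, σ²-normalized negative
principal eigenvalue, maximum over scales 1, 2, 4 px) only for what it
is good at — finding tubular cores with high precision — and recovers
the vessel support from the intensity image: Otsu's threshold within the
ROI proposes candidate support, and 8-connected support components that
contain at least one vesselness seed are kept. Bright blobs without a
tubular core are discarded with the unseeded components. On noiseless
renderings this recovers the true mask essentially exactly (Dice ≈ 1.0);
with default noise, per-frame density errors are a few tenths of a
point.

Remaining knobs: ties at any threshold go to foreground; connectivity is
8-connected everywhere (thin diagonal vessels stay connected; EBImage's
4-connected labeller is deliberately not used); components under
`min_area` (20 px) are removed; morphological closing is available but
defaults to radius 0, since closing radius 1 fills one-pixel gaps
between adjacent vessels and measurably inflates density (~+1 point).
The `local_mean` threshold method remains selectable for strong
background gradients.

## Quantification

Densities are exact integer pixel-count ratios; nothing is interpolated.
The ROI is the disk inside the limbal circle — stated explicitly because
the denominator convention decides the scale of every reported
percentage; `n_roi_px` is recorded with each measurement so any other
convention can be reproduced. The ROI is placed on the first visit and
propagated analytically through the estimated registrations (a rigid
transform maps a disk to a disk, so only the center moves; raster
warping of the ROI was tried first and erodes the boundary). Growth
between consecutive visits warps the later binary mask into the earlier
frame by nearest neighbour — masks are never interpolated, fractional
vessel pixels are undefined — and partitions the common overlay region
into grown / regressed / persistent / empty; the scalar growth density
`100·(grown − regressed)/common` equals the density difference on the
common region identically, and the label map is exported as the
diagnostic change map (green/red/white). Repeatability errors are
*signed* replicate differences (their mean ≈ 0; the absolute summary is
also reported); replicates are same-session scans and are treated as
pre-aligned, with a config flag to force registration for robustness
testing.

## Statistics

Bland–Altman uses the conventional 1.96 multiplier for the limits of
agreement (not a t quantile), with a t-based 95% CI on the bias.
The paired nonparametric test is the Wilcoxon signed-rank test — the
standard paired analogue sometimes loosely called a "paired
Mann-Whitney" — with exact p-values up to 25 nonzero tie-free
differences and the tie-corrected normal approximation beyond; the
unpaired Mann-Whitney U is also provided. Unpaired comparisons default
to Welch's t-test (small, unequal arms; no variance-homogeneity
assumption). Quantiles use linear interpolation between order statistics
(type 7), pinned so IQRs are reproducible. Degenerate-input conventions
are explicit: zero-SD paired differences report p = 1 (zero mean) or
p = 0 (nonzero mean); all-zero differences are a no-information error
for the signed-rank test.

## Problem sizes and numerical choices

The shipped study size is six animals (three arms × two routes, one
animal each) × 4 weeks × 2 modalities × 2 replicates on a 160×160 px
canvas — small enough to regenerate everywhere, large enough that every
arm contributes growth and regression intervals. Under these conditions,
measured per-frame density errors against ground truth have mean ≈ 0.4
points with ~99.6% of frames within 2 points; the rare exceedance
(≈ 2.1 points) occurs on the densest ICGA frames and matches the
replicate-to-replicate spread of identical vasculature, i.e. it is
rendering-noise variance, not pipeline bias. Growth direction matches
truth in effectively all intervals with |true growth| ≥ 3 points;
same-session repeatability error (mean |error| ≈ 0.2 points) sits a
factor ~40 below mean |follow-up change|, reproducing the
repeatability-versus-change contrast that justifies the growth statistic.

Other numerical choices: images are min-max normalized floats in [0, 1]
(thresholds and noise parameters stay modality-comparable; no bit depth
is assumed); pixel coordinates are row-major, origin top-left, 0-based;
physical pixel size is not modeled — densities are pixel fractions, so
no mm² conversion exists anywhere; PNG output is 8-bit, and the
write/read round trip is exact to 1/255.

## Limitations

Cross-modality image registration (OCTA to ICGA) is intentionally
absent: each modality's time series is registered within itself and the
modalities are compared through their measurements, not fused pixelwise.
Scale and deformable alignment are out of scope by design. Vessel
morphometry (lengths, branch points, diameters, fractal measures) is not
computed. The acceptance evidence is simulation-based throughout; on
real scans the segmentation defaults (scales, minimum area, threshold
method) should be revisited against the instrument's resolution and
noise.
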