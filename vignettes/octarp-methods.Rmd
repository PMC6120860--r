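---
title: "Quantifying retinal vascular progression in retinitis pigmentosa from OCT angiography"
author: "octarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal vascular progression in retinitis pigmentosa from OCT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octarp)
```

## The measurement problem

Retinitis pigmentosa (RP) progressively attenuates the retinal vasculature.
En-face OCT angiography (OCT-A) images the perfused capillary beds of the
superficial (SCP) and deep (DCP) plexus and the choriocapillaris without dye,
which makes it attractive for tracking disease progression longitudinally.
`octarp` implements a complete quantification pipeline for such studies:

1. **Binarization** of an 8-bit en-face angiogram into vessel/background.
2. **FAZ delineation** — the foveal avascular zone, whose area grows as
   perifoveal capillaries drop out.
3. **Perfusion density (PD)** — the percentage of analyzed pixels classified
   as vessel, with FAZ pixels excluded from numerator and denominator.
4. **Choriocapillaris mean gray value (MGV)** — the mean level of the raw
   choriocapillaris image, a brightness proxy for choroidal flow.
5. **Ellipsoid-zone (EZ) line width** from horizontal foveal B-scan
   reflectivity profiles (9-mm scans), a structural anchor for surviving
   photoreceptors.
6. A **longitudinal statistics battery**: per-eye change over time, one-sample
   and paired t-tests, and Pearson correlation grids against EZ width and
   best-corrected visual acuity (BCVA, logMAR).

Because clinical OCT-A image sets are rarely shareable, the package pairs the
pipeline with a **synthetic angiogram and cohort generator** with exact,
pixel-level ground truth. Every stage of the pipeline is then validated by
parameter recovery: configure a known truth, render data, measure it back.

## Image model and preprocessing

An angiogram is an 8-bit square grid; the default geometry is 245 × 245
pixels over a 3 × 3 mm fovea-centered field (the A-scan/B-scan count of the
acquiring device), so the pixel pitch is `3/245` ≈ 12.2 µm. RGB exports are
reduced to their **red channel** before analysis; grayscale input passes
through with a note. JPEG input is accepted with a warning that lossy
compression can shift thresholds (test fixtures are lossless PNG).

**Thresholding** reproduces the default dark-background rule of the standard
image-analysis tool: the iterative intermeans (IsoData-variant) algorithm on
the 256-bin histogram,

&nbsp;&nbsp;&nbsp;&nbsp;`t ← floor((mean(pixels ≤ t) + mean(pixels > t)) / 2)`

iterated from the image mean to a fixed point (integer floor at each step;
convergence is an unchanged `t`; a constant image is a degenerate-histogram
error). Under the dark-background convention the vessel class is bright, so
the returned bounds are `(t + 1, 255)`. Both bounds are **inclusive** when a
mask is formed — a pixel exactly at the lower bound is vessel — mirroring the
in-range semantics of the tool the rule emulates. A fixed-bounds mode
(`threshold_bounds(60, 255)`) is available for studies that freeze bounds
derived once from the default tool; the auto rule is the default pipeline
path. No other threshold families (Otsu, Huang, local/adaptive) are in
scope, and no skeletonization is applied: perfusion density is defined on
the binarized mask by pixel counting, so a skeletonization step would change
the measurand.

## FAZ delineation

The reference method is a manual free-hand outline. `octarp` ingests manual
input as a closed polygon of pixel vertices (even-odd fill, pixel-center
inclusion, boundary pixels inside) or as a binary raster. For unattended
runs it provides an automated surrogate, clearly labeled as such in the
`method` field of its result: the vessel mask is morphologically closed with
a disc of radius `r_close = 2` px (≈ 24 µm at the default pitch — wide
enough to seal inter-capillary gaps smaller than a capillary caliber without
bridging the FAZ), then the avascular region is grown by 4-connected flood
fill from a seed at the image center (scans are fovea-centered). If the seed
lands on a closed-vessel pixel a 5 × 5 neighborhood is searched; if the fill
leaks over more than half the field the perifoveal ring is broken and the
call fails rather than returning a silently wrong area. 4-connectivity is
deliberate: it cannot leak through diagonal gaps that an 8-connected fill
would cross. Area is always `pixels × pitch²` (mm²).

## Statistics

Change over time is `(follow-up − baseline) / Δt` in units per year, per eye
(negative = decline); Δt comes from ISO dates as days/365.25 or directly
from a `dt_years` column. Mean rates are tested against zero with a
one-sample Student's t-test; visit means and SCP-vs-DCP contrasts use paired
t-tests; association uses Pearson correlation with the usual
`t = r √((n−2)/(1−r²))` two-sided p. All tests are two-sided at α = 0.05.
No multiple-testing correction is applied across the correlation grid by
default (matching the reference protocol); a Benjamini–Hochberg column is
available behind `fdr = "bh"`. Dispersion is reported as SD for visit means
and SEM for rates, with both always present in the output tables. Two-grader
workflows are supported by `grader_merge()`, which reports the inter-grader
Pearson r and returns the element-wise mean series for downstream use.
Missing values are handled complete-case per analysis with the `n` used
reported per row.

## The synthetic cohort generator

The generator is first-class, tested code — it defines the study conditions
under which the pipeline is validated.

**Single angiograms.** `generate_angiogram()` seeds 16 trunk walkers at the
field edge that perform biased random walks toward the center with direction
persistence, branching with probability 0.10 (stroke widths 1–3 px), carves
an irregular star-convex avascular zone (a disk with smooth random radial
perturbation, so the free-hand-outline code path is exercised by realistic
shapes) of **exactly** the requested pixel count, lays a 1–2 px capillary
ring hugging the FAZ boundary, and then adds or prunes vessel boundary
pixels until the ground-truth perfusion density matches the target exactly
(up to count rounding, well inside the documented 0.5-pp tolerance).
Rendering is bright-vessels-on-dark-background — the raw-export convention;
the black-vessel convention appears only in `render_processed()` — with
per-image brightness jitter (background level U(8, 16), vessel level
N(110, 12) clipped to [75, 160]) and additive Gaussian noise (SD 6 gray
levels). Those levels were chosen so that (a) the automatic intermeans lower
bound varies across scans and brackets 60, the value a fixed-bounds study
would freeze, and (b) the threshold iteration remains stable even on
near-vessel-free images (a heavier background tail makes intermeans collapse
into the noise floor on low-density scans, which is a property of the
algorithm, not of the data model).

**Longitudinal pairs.** `degrade_angiogram()` realizes a follow-up visit
from a baseline truth: the FAZ is grown (or, for negative deltas, shrunk)
shell by shell to the target area, the capillary margin is re-formed as a
tight ring at the new boundary, and vessel pixels are pruned or added to hit
the density delta exactly. The re-formed ring is the one deliberate
exception to strict vessel-mask nesting between visits: without it, a grown
FAZ's boundary would sit in an arbitrary position relative to the remaining
vasculature and the flood-fill surrogate would quantize measured areas to
the surrounding vessel geometry (and a shrinking FAZ would be unmeasurable
entirely), biasing cohort growth rates by double-digit percentages. Apart
from that ≤ 3-px boundary band, a negative density delta only removes vessel
pixels and a non-negative area delta never removes FAZ pixels — both are
property-tested.

**Cohorts.** `cohort_spec()` holds the population: 28 eyes (one per
patient), follow-up N(1.3, 0.46²) years truncated at 0.5, per-metric
baseline means/SDs and yearly-rate means/dispersions, and a 7 × 7 baseline
correlation matrix. Baselines are drawn jointly Gaussian; per-eye rates are
drawn `N(rate_mean, rate_sd²)` independently across metrics (the reference
tables report no rate cross-correlations); visit 2 is `visit1 + rate·Δt`.

Two documented readings deserve emphasis:

* **The ± of a progression rate is a standard error of the mean.** The
  summary convention "mean ± SD" cannot hold for the rate rows: a mean rate
  of −2.42 with P = 0.001 at n = 28 implies t ≈ 3.9, which requires the ±
  value (0.62) to be the SEM. The generator therefore uses between-eye rate
  SD = SEM·√28 — a property of the study population that stays fixed when a
  different cohort size is simulated.
* **The default correlation matrix is completed to positive definiteness.**
  Only the EZ-width and BCVA rows of the visit-1 correlation grid are
  reported; with all unreported pairs set to zero the matrix has a negative
  eigenvalue (−0.27) and no joint Gaussian exists. The unreported pairs are
  filled once with clinically plausible values — plexus densities track each
  other (0.65), FAZ areas track each other (0.60), density opposes FAZ area
  within and across slabs (−0.30…−0.45), EZ width opposes BCVA (−0.45), the
  choriocapillaris is essentially uncorrelated with retinal metrics — giving
  a minimum eigenvalue of 0.19. A non-PSD user matrix is rejected at spec
  validation.

Raw Gaussian draws are kept in `*_v1_raw` columns; the values actually
rendered are clipped to what an image can encode (PD ∈ [2, 95] %, FAZ ≥
0.04 mm², MGV ∈ [2, 253], EZ ∈ [0, 8900] µm). The floors are the generator's
domain of validity: a visit-2 FAZ below ~0.04 mm² (radius ≈ 9 px) is erased
by the closing step of the segmenter, and densities below 2 % cannot support
the sealed perifoveal ring. This clipping censors the extreme tails the
configured Gaussian populations place outside physical range (about 4 % of
DCP visit-2 density draws fall below zero), which biases realized DCP
density decline by about +0.05 %/yr — an inherent cost of using unbounded
Gaussian populations with the reference parameters, quantified by the
distributional-calibration tests.

**Other channels.** Choriocapillaris textures are i.i.d. Gaussian gray
levels about the target MGV (rounded, clipped; `noise_sd = 0` documents the
rounding to the nearest representable 8-bit level). EZ profiles are plateaus
of the requested physical width with Gaussian-smoothed shoulders (symmetric
kernel, so the half-maximum crossings stay at the plateau edges) plus
additive noise; the automatic width estimator smooths with a moving average
(window 5) and takes the widest above-half-maximum run containing the peak.

**What the generator does not emulate:** OCT speckle/decorrelation physics,
projection artifacts, device slab-segmentation errors, motion artifacts, and
vessel-caliber/morphology realism beyond a branching random walk. Passing
recovery tests therefore demonstrate the *pipeline's* correctness under
controlled truth, not the clinical accuracy of OCT-A itself.

## Numerical choices and degenerate inputs

* Intermeans ties break by integer floor; both classes are kept non-empty by
  clamping `t` into `[min, max−1]`.
* Exact pixel-count targets are reached by seeded add/prune passes on
  vessel boundaries; the FAZ ring and a 3-px margin are protected from
  pruning.
* The flood fill runs on a growing bounding box (cost scales with component
  size) and aborts as "unbounded" past 50 % of the field.
* Polygon rasterization rejects self-intersecting outlines
  (O(n²) proper-intersection test) and zero-area (collinear) outlines;
  outlines exiting the raster are clipped with a warning.
* Degenerate statistics (zero variance, all-missing metrics) surface as
  errors or as warnings plus `NA` rows in the tables — never as silent
  numbers.
* Dates are ISO-8601; Δt = days/365.25.

## Validation sizes

The test suite validates recovery with 10 replicate 28-eye image cohorts per
run (the acceptance script uses 80, plus 200 profile cohorts, 400
metadata-only cohorts, and n = 5000 correlation draws); a 25-angiogram FAZ
battery spans 0.1–1.5 mm²; null calibration uses 1000 cohorts and p-value
uniformity 2000. With those sizes the Monte-Carlo SE of a recovered mean
rate is a few percent of its value.

## Known limitations

* Only two visits per eye; rates are linear by construction, as in the
  reference protocol. No mixed-effects or exponential progression models.
* The manual-outline path is validated against constructed polygons, not
  against human graders.
* The automated FAZ surrogate needs an intact perifoveal capillary ring; on
  images with a broken ring it fails loudly and the eye must be outlined
  manually.
* Rate draws are independent across metrics; only baselines carry the
  configured correlation structure.
* The one-sample test's power at the reference SCP-density effect size
  (|mean|/SEM ≈ 3.9, df 27) is 0.86 at α = 0.01 — a design fact worth
  knowing when simulating significance patterns.

## A minimal worked example

```{r example, eval = FALSE}
library(octarp)
sp <- image_spec()                               # 245 px over 3 mm
g1 <- generate_angiogram(sp, target_pd = 33.4,
                         target_faz_mm2 = 0.345, seed = 1)
g2 <- degrade_angiogram(g1$truth, pd_delta_pct = -3.0,
                        faz_delta_mm2 = +0.10, seed = 2)
q1 <- quantify_angiogram(g1$image)               # auto threshold + FAZ
q2 <- quantify_angiogram(g2$image)
change_over_time(q1$pd_pct, q2$pd_pct, dt_years = 1.3)   # ~ -2.3 %/yr

cs <- cohort_spec(n_eyes = 28, rng_seed = 7)
res <- run_pipeline(cs, out_dir = tempfile("cohort"))
res$tables$visits[, c("label", "rate_mean", "rate_sem", "p_rate")]
```
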