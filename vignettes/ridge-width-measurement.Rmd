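---
title: "Measuring alveolar ridge width change from paired CBCT scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring alveolar ridge width change from paired CBCT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgewidth)
```

## The measurement problem

After a tooth is extracted, the alveolar ridge that held it resorbs: the
buccal and oral cortical plates collapse toward the socket center, and the
ridge loses width — most of it crestally and within the first months of
healing. Whether a socket-preservation biomaterial slows this process is
usually judged radiologically, from a CBCT scan taken right after extraction
and a second one taken before implant placement. Most published measurement
schemes read one or two calliper distances off a single slice; `ridgewidth`
implements a denser, semi-automated protocol that measures the ridge at
**15 standardized positions** — five mesio-distal offsets (central, ±1 mm,
±2 mm) on each of three axial planes (crestal, 2.5 mm and 5.0 mm apical) —
so that the spatial pattern of resorption, not just its crestal maximum, is
quantified.

The only manual inputs are (a) a region of interest shared by both
timepoints and (b) one straight line drawn through the socket center,
perpendicular to the ridge, extending beyond it. Everything downstream —
grid expansion, profile extraction, peak detection, width computation,
change tables, agreement statistics — is deterministic code.

## The width measurement

At each grid position a *wide line profile* is sampled: grey values along
the line at steps of one in-plane voxel, each sample the mean of
`sampling_width_px` (default 10) bilinear samples spaced one pixel apart
along the perpendicular. On such a profile the dense cortical rims bounding
the ridge appear as two prominent maxima; the ridge width is

$$ w = x_{\text{right rim}} - x_{\text{left rim}}, $$

the distance between the two **outermost** profile maxima whose topographic
prominence exceeds a threshold (default 10% of the profile's dynamic
range). Longitudinal change at a position is
$\Delta w = w_{t_0} - w_{t_1}$, positive for loss; gains are representable
and do occur in clinical data.

Two QC flags guard the outermost-pair rule: `EXTRA_PEAKS` when more than
two prominent maxima exist (e.g. a root fragment, or a resorption step
within the averaging band splitting a rim into two bumps), and
`BOUNDARY_PEAK` when an outer maximum sits within one sampling step of a
profile end, i.e. the drawn line may not have extended beyond the ridge.
Positions with fewer than two maxima are reported as explicitly
unmeasurable, never dropped.

### Numerical choices

* **Grey standardization.** The 8-bit conversion uses a single whole-stack
  min–max window, rounded half-up. Width depends only on peak *locations*,
  which any global strictly increasing map preserves (a property the suite
  tests); per-slice windows would break inter-slice comparability. A
  constant stack maps to zero rather than erroring, so padded phantom
  corners are harmless. The nominal grey maximum is taken as 255.
* **Peak finding.** Prominence is computed topographically (walk to the
  nearest higher sample on each side; the base is the higher of the two
  intervening minima). Plateaus report their center. The original protocol's
  interactive peak tool requires a user tolerance it does not document; the
  10% default is therefore a package choice, recorded in every `peak_set`
  for audit, and configurable.
* **No sub-sample refinement.** Peak x-coordinates are read off the sample
  grid, as the original plot-reading procedure does; parabolic refinement is
  deliberately omitted so results are bit-reproducible. Widths are
  consequently quantized to the voxel pitch (0.15 mm at the reference
  scanner settings).
* **Depth planes.** The slice offset for a target depth $t$ is
  $k = \operatorname{round}(t/\Delta z)$ (half-up; an exact tie breaks
  toward the more crestal slice, preferring to exclude rather than include
  less-resorbed anatomy), accepted only if $|k\Delta z - t| \le$ 0.25 mm.
  With 0.15 mm slices the achieved depths are 2.55 and 4.95 mm; with 1 mm
  slices the 2.5 mm target is honestly unreachable and errors. A looser
  0.5 mm tolerance can be requested.
* **Offsets.** The duplicated lines sit at 1 and 2 mm mesially and
  distally of the central line, translated exactly perpendicular to it;
  both the offsets and the "at least 10 pixels" averaging width are
  configurable. The 10 is interpreted as pixels (image-tool line-width
  semantics), not millimeters.
* **Alignment.** The follow-up scan reuses the baseline ROI and is refined
  by exhaustive integer-voxel translation search maximizing normalized
  cross-correlation (default radius ±10 in-plane, ±3 axial). The original
  workflow aligns stacks interactively and states only that rotational
  discrepancies were minimal, so rotation is *not* refined; the NCC score is
  reported so users can judge alignment quality. Exhaustive search over
  integer shifts is exactly reproducible, and sub-voxel registration is
  deliberately out of scope. With a nonzero ROI rotation the search runs in
  the rotated reference frame (one rotation of a padded crop, then window
  shifts), which reports translations in reference coordinates.
* **Rotation.** In-plane, about the crop-rect center, bilinear with zero
  fill — matching common image-tool behavior and keeping profiles smooth.
  `cospi`/`sinpi` make quarter turns exact index permutations.
* **Indexing.** All slice/voxel indices in the API are 1-based (native R);
  the mm origin is the center of voxel (1,1,1), so physical coordinates
  match the usual 0-based convention exactly.

## The statistics layer

The package reproduces the statistical toolkit used around the measurement:

* `summarize_positions()` — per-position mean ± SD (n−1) across subjects.
* `anova_tukey()` — one-way ANOVA with Tukey HSD at 95% CI (delegated to
  `stats::aov`/`TukeyHSD`, validated against the studentized-range closed
  form in the suite).
* `icc()` — Shrout–Fleiss forms from two-way ANOVA mean squares:
  ICC(2,1) "single random", ICC(3,1) "single fixed", and the
  average-measures ICC(2,k)/ICC(3,k). For a subjects × raters × repeats
  study the inter-rater forms treat each repeat round as a target by
  default (pairing raters within rounds, matching a consecutive-rounds
  design; averaging repeats first is available). Intra-rater reliability is
  the per-rater two-way consistency ICC across repeats. Whether a published
  analysis paired per-position-per-scan or per-scan means is often
  unstated; the default here is per-target pairing, and the choice is a
  function argument rather than a constant.
* `bland_altman()` — limits of agreement $\bar d \pm 1.96\,s_d$, with
  points strictly outside the limits flagged as outliers and within-epsilon
  boundary cases flagged separately.
* `sample_size_ttest()` — smallest integer $n$ per group with two-sample
  noncentral-t power $\ge$ the request (noncentrality $d\sqrt{n/2}$,
  $2n-2$ df). At $d = 1.019$, $\alpha = 0.05$, power 0.80 it returns 17.

## The synthetic phantom: what it emulates and what it does not

No patient CBCTs ship with the package, so validation rests on
`phantom_spec()`/`generate_phantom()`: paired volumes of a ridge
cross-section with *known* per-position widths. Each axial slice renders
two bright cortical rim bands (Gaussian cross-profile, σ 0.25 mm) on a
trabecular plateau over a darker background, with a low-intensity socket
channel at the center; the follow-up renders the same geometry minus a
programmed loss applied to the buccal rim. An in-plane Gaussian PSF
emulates partial-volume blur, then additive Gaussian noise is applied, and
the volume is stored at 12 bits so the pipeline's 8-bit standardization is
exercised. All randomness flows from one seed; the truth table is
seed-invariant.

Stated-world defaults, chosen once: isotropic 0.15 mm voxels (the reference
scanner's slice thickness); crestal width 8.1 mm flaring ~0.12 mm/mm
apically, both quantized to the voxel grid; intensities
rim 220 > trabecular 100 > socket 40 ≥ background 20; PSF σ 0.1 mm; noise
SD 5 grey levels. The default resorption gradient mirrors the clinical
pattern — maximal centrally and crestally, tapering laterally and
apically: crestal 2.1/1.8/1.5 mm at |offset| 0/1/2 mm, 0.9/0.75/0.6 at
−2.5 mm, 0.45/0.3/0.15 at −5.0 mm, symmetric mesio-distally. Loss is
piecewise constant over 1 mm mesio-distal strips centered on the offsets,
linear in |offset|, so the 10-pixel averaging band (±0.68 mm) mixes
neighbor strips symmetrically and the band-averaged rim peak stays at the
central strip's true position.

Design constraints worth knowing:

* True rim positions and losses are multiples of the voxel pitch. Since
  peak x-values live on the sample grid, off-grid truth would add up to
  half a voxel of representation error per rim before the algorithm even
  runs; on-grid truth separates algorithmic error from quantization.
* The PSF is applied in-plane only. The measurement reads one in-plane
  profile per position, so axial blur would add nothing testable.
* The phantom is *not* an anatomical simulation: no scatter, beam
  hardening, metal artifacts, curved ridges, or oblique sockets. A green
  phantom suite establishes that the geometry pipeline and peak arithmetic
  are correct and noise-robust at realistic contrast — not that the method
  segments difficult clinical anatomy.
* Lateral loss steps much larger than the rim support (≳1 mm between
  adjacent strips) split the band-averaged rim into two prominent bumps;
  the outermost-pair rule then reports the less-resorbed bump and flags
  `EXTRA_PEAKS`. The default gradient (0.3 mm steps) stays well inside the
  merged regime; pathological gradients are exactly what the flag exists
  for.

## Worked example

```{r, eval = FALSE}
spec <- phantom_spec(seed = 42)
fix <- tempfile(); write_fixture(spec, fix)       # DICOM fixture on disk
out <- tempfile()
cfg <- run_config(t0_dir = file.path(fix, "t0"),
                  t1_dir = file.path(fix, "t1"),
                  roi = file.path(fix, "roi.json"),
                  central_line = file.path(fix, "central_line.json"),
                  out_dir = out)
res <- run_pipeline(cfg, scan_id = "phantom42")
summarize_positions(res$change)
```

The change table recovers the programmed gradient (2.1 mm central-crestal
loss, decreasing laterally and apically) to within one voxel per position;
`tests/testthat/test-acceptance.R` asserts this, plus half-voxel recovery
in the noiseless case, on every run.

## Known limitations

* Deformable or rotational refinement between timepoints is out of scope;
  badly rotated follow-ups surface as low NCC scores, not corrections.
* Differing voxel sizes between timepoints are an error, not a resample.
* DICOM support covers uncompressed little-endian single-frame series (the
  export format of the reference workflow); compressed transfer syntaxes
  and multi-frame enhanced DICOM are rejected.
* Grey values are treated as relative (CBCT is not HU-calibrated); no
  density analysis is attempted.
* Crestal-slice and socket-center identification remain the operator's
  task, as in the original semi-automated protocol.
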