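---
title: "Methods: synthesizing structured breast ultrasound reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesizing structured breast ultrasound reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(busrep)
```

## The problem

In routine breast ultrasound screening the operator saves many frames per
patient — grayscale B-mode views, Doppler overlays showing flow, and
elastography frames quantifying tissue stiffness — and burns short
annotations into the pixels: the breast side, the lesion's clock-face
position around the nipple, its distance from the nipple, and often a
caliper size ("LEFT 2:00 5CM", "RIGHT 9 h, 6 CM"). The radiologist later
turns this pile of frames into a findings report, a slow and error-prone
transcription task. `busrep` reconstructs that workflow as a semi-automatic
pipeline: it classifies each frame's scan mode from visual features,
classifies stiffness on shear-wave elastography (SWE) frames, reads and
repairs the burned-in annotations, groups frames that describe the same
lesion, and compiles one templated findings sentence per lesion, leaving
radiologist-only judgments (BI-RADS category) as explicit blanks.

## Scan-mode classification from visual features

Four modes are distinguished by a fixed-order decision procedure:

1. a frame whose every pixel has max channel difference at most
   `grayscale_tol` is **B-mode**;
2. otherwise, if the colored-pixel density of the scan region is below
   `doppler_density_threshold` *and* the largest colored contours are
   irregular (max rectangularity below `rectangularity_threshold`), the
   frame is **Doppler** — flow overlays are small and blob-shaped;
3. otherwise, if the text "kPa" is recognized near the vertical color
   legend bar, the frame is **SWE** — shear-wave elastography displays
   stiffness in kilopascals;
4. otherwise it is **SE** (strain elastography): same large rectangular
   colored overlay and legend bar, but no kilopascal units.

Because the branch order is literal, a hypothetical Doppler frame that also
carried a kPa legend would be labeled Doppler; the source procedure leaves
this case undefined and we implement the stated order.

Tunable parameters (all in `icvf_config()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `grayscale_tol` | 2 | intensity levels | absorbs chroma round-off of lossy exports; the procedure itself says only "grayscale" |
| `doppler_density_threshold` | 0.02 | fraction of scan-region pixels | "low density" is not quantified at source; calibrated once on the synthetic fixtures, where Doppler blobs sit near 0.002–0.004 and elastography overlays above 0.05 |
| `rectangularity_threshold` | 0.75 | area / bbox area | below the rasterized-disc value (π/4 ≈ 0.785), so discs and ragged blobs count as irregular while the axis-aligned elastography boxes (1.0) do not |
| `legend_aspect`, `legend_right_frac` | 5, 0.85 | — | the legend bar is the tallest thin colored component touching the right strip; no source geometry is given |

The colored-pixel density deliberately excludes the bottom-third annotation
band, so colored annotation glyphs can never influence mode evidence.
Legend bars on the left of the frame are out of scope (a config hook
exists via `legend_right_frac`).

## Stiffness classification

For SWE frames the colored overlay (the largest non-legend colored
contour) is cropped and classified as negative / equivocal / positive.
Two backends ship:

* **Color baseline** (`color_baseline()`): the fraction *f* of colored ROI
  pixels in the high-stiffness (red-dominant) band, thresholded at
  (0.3, 0.7) — the midpoints between the synthetic class encodings below.
  Deterministic; used as the default pipeline backend and as the
  independent check on the trainable backend.
* **Trainable backend** (`train_classifier()`): ROIs are zero-padded to
  square and bilinearly resized to 224 × 224 (aspect-preserving — the
  padding choice is ours, the source states only that aspect ratio is
  maintained), summarised by a 4 × 4 patch grid of per-cell mean RGB plus
  high-stiffness fraction (64 features), and fed to a single-hidden-layer
  softmax network (`nnet`, 8 hidden units, weight decay 1e-3, at most
  10 × `epochs` BFGS iterations, seeded). No deep-learning framework is
  assumed: the backend is a documented plug-in point, and any model
  exposing the same predict surface (e.g. a DenseNet-style CNN) can stand
  in. The published workflow's clinical accuracy figures depend on a
  private hospital dataset and are not reproduced here.

Class imbalance is handled by inverse-frequency weights
`w_c = N / (K · n_c)`, so e.g. training counts 48/118/157 give weights
2.243/0.912/0.686 and the minority (negative) class is penalized hardest.
The weight formula is our concrete choice for the stated "higher weights to
the minority class". Exact probability ties break toward the more severe
class (positive > equivocal > negative), the clinically conservative rule;
the source is silent on ties.

## Annotation recognition and confusion correction

Annotations live in the bottom third of the frame: `crop_text_band()`
takes 0-based rows `floor(2H/3) .. H-1`. Recognition is a pluggable
adapter. The shipped template matcher inverts the packaged 5 × 7 bitmap
font exactly (binarizing on the minimum channel so colored overlay pixels
never read as text), which removes OCR-engine nondeterminism from pipeline
tests; a mock recognizer bypasses pixels and replays ground truth with
injected confusions, isolating the correction stage. An adapter for a real
OCR engine plugs in through the same `bus_recognizer` surface.

OCR engines confuse characters systematically; the four documented pairs
are S→5, I→1, Z→2 and b→6, corrected directionally (never 5→S) and only in
context. The shipped confusion matrix ranks S→5 highest (most frequent,
especially with "cm" adjacent). Context predicates:

* `in_numeric_field` — token contains a digit, decimal point, or colon;
* `cm_adjacent` — a ±1 neighbour token equals "cm"/"CM" or the token ends
  in cm;
* `in_clock_token` — a ±1 neighbour is an "h" clock marker.

A digit-or-cm-adjacency predicate alone is insufficient: a fully corrupted
bare clock hour ("RIGHT **Z** h,") contains neither. After substitution
the candidate token must parse as a number, clock time, or size/depth
expression, otherwise the original is kept — this token-grammar guard is
what keeps alphabetic words ("SIZE", "RIGHT") untouched, and makes the
correction idempotent. On the synthetic corpus the round trip
corrupt → recognize → correct achieves a character error rate (Levenshtein
distance over truth length) of exactly 0% at every injection rate up to
1.0; the test suite and `scripts/acceptance.R` recompute this.

Cleaning retains only decimal numbers as size dimensions; integer
distances with a cm unit are depths. Both operator dialects parse
("2:00" and "9 h", including half hours), unparseable fields come back
empty rather than guessed, and the only hard error is an annotation
naming both sides.

## Grouping and report compilation

Scans are grouped by the normalized location key (side, clock hour, clock
minute, depth): qualifiers like "LO" are kept but excluded from the key,
so "LEFT 2:00 5CM" and "LEFT 2:00 5CM LO" share a group, and frames
without annotations (distractors) join no group. Depth equality is exact
after parsing (the workflow groups on identical location text); a
`depth_tol` config exists for near-miss depths but defaults to 0. When
members disagree on size, the maximal-dimension annotation wins with a
warning; per-type classes consolidate by majority vote with severe-side
ties. Groups order by side (LEFT first), clock, then depth; no source
order is stated.

Each annotation-bearing group renders one findings sentence:

```{r}
formulate_sentence(list(
  side = "RIGHT", clock_hour = 9L, clock_minute = 0L, depth_cm = 6,
  size_dims = c(0.41, 1.2), doppler_class = NA,
  swe_class = "positive", se_class = NA
))$rendered
```

Unfillable slots render as `()` and are listed as pending; the BI-RADS
category is always pending by design. Reports compile to a plain-text
findings file plus a JSON sidecar, byte-identical across reruns (the
timestamp is externalized). A generated sentence *matches* ground truth
iff the location key and the set of filled elastography types agree —
class values are deliberately not compared, mirroring the
report-correctness criterion of the emulated evaluation.

## The synthetic data generator

Real clinical frames cannot ship with the package, so every stage is
exercised on `fixture_spec()` studies that realize exactly the visual
attributes the pipeline keys on: grayscale speckle with a dark lesion
ellipse (B-mode); a small ragged diagonal colored stroke, colored fraction
well under the Doppler threshold (Doppler); a vertical rainbow legend bar
in the right strip, a large axis-aligned colored overlay, and a rendered
"kPa" label present (SWE) or absent (SE). The frame defaults to 970 × 1292
pixels, matching the export resolution of the emulated scanner; the test
suite and acceptance script generate at 360 × 480 — the geometry is
proportional and every contract is resolution-independent above the
300-pixel floor, so the smaller frames are purely a problem-size choice.

Synthetic stiffness is encoded as the per-pixel probability of drawing a
high-stiffness (red-family) versus low-stiffness (blue-family) color:
0.1 / 0.5 / 0.9 for negative / equivocal / positive, optionally with
per-ROI Gaussian jitter. The emulated colormap and legend geometry are an
emulation, not a reproduction of any vendor layout, which is the main
caveat on external validity: passing tests show the *pipeline logic* is
correct under the stated visual attributes, not that the thresholds
transfer to a particular scanner. Likewise the packaged bitmap font makes
recognition exactly invertible; performance with a real OCR engine
depends on that engine and enters only through the adapter.

Experiment noise levels were fixed once, before any result was read off:
σ = 0.08 for accuracy experiments (classes separated by ≈ 5σ — visibly
noisy but learnable, the regime a usable clinical encoder should occupy)
and σ = 0.2 for the class-weighting experiment (adjacent classes ≈ 2σ
apart, forcing boundary errors so that weighting has something to
improve). The weighting experiment uses 20/100/100 training ROIs, echoing
the roughly 1:2.5:3.3 clinical imbalance with the negative class rarest.

Determinism is a contract throughout: identical `fixture_spec`s (seed
included) generate byte-identical studies; per-frame seeds derive from the
spec seed plus the frame index.

## Numerical and degenerate-input choices

* Character error rate = Levenshtein distance / truth length (in %);
  the empty-truth case is an error, an empty prediction against truth is
  100%.
* Per-class precision/recall with a zero denominator contribute 0 with a
  warning, never NaN; macro averaging is the default, support-weighted is
  available.
* One-vs-rest AUROC uses the midrank (Wilcoxon) statistic, so ties count
  one half; it is invariant under strictly monotone score transforms.
* Stratified k-fold splitting deals each class's shuffled indices
  round-robin with a fold pointer persisting across classes, making both
  per-class and total fold sizes differ by at most one (543 items at
  k = 5 give folds of 108–109).
* Probability vectors must sum to 1 within 1e-6; the nnet backend
  renormalizes defensively.

## Known limitations

* Single emulated vendor layout; left-side legend bars unhandled.
* Doppler and SE stiffness classification are out of scope (the per-type
  class slots exist and render as blanks), as in the emulated workflow
  where only the SWE submodule was validated.
* DICOM I/O is not provided; frames travel as 8-bit RGB PNG, the format
  the workflow itself converts to before analysis.
* The trainable backend is a compact feature-based network chosen to train
  in minutes on a CPU; it is not a stand-in for a deep CNN's capacity on
  real speckle imagery.
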