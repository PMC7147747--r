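---
title: "Decision policies, curation and metrics for DR screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision policies, curation and metrics for DR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscreen)
```

## The problem

Automated diabetic-retinopathy (DR) screening pipelines end in a classifier
whose softmax layer assigns each fundus photograph a probability vector over
disease grades. The argmax of that vector maximizes accuracy, but a
screening program cares about asymmetric errors: missing referable disease
is far worse than over-referring, and conversely a program that triages
healthy eyes away from human graders needs a negative call to be extremely
safe (high sensitivity for Healthy, high NPV). `drscreen` implements the
*post-classifier* stages of such a pipeline — grade-scheme remapping and
splitting, image preprocessing, quality-based curation, sensitivity-boosting
decision rules, and the screening-metric suite — together with seeded
synthetic generators so that every stage is exercised by fast, deterministic
tests. The trained classifier itself is out of scope; any model that
produces per-image probability vectors can sit in front of this package.

## Grade schemes and remapping

The five-grade fundus labelling (No, Mild, Moderate, Severe, Proliferative
DR) is remapped by the shipped presets to:

* `kaggle5to3`: Healthy / Non-referable DR (mild + moderate) /
  Referable DR (severe + proliferative);
* `kaggle5to2`: Healthy / Diseased.

A `label_map` validates that every source grade maps to exactly one target,
every target class is hit, and that the map preserves severity order. Grade
columns in CSV/TSV tables accept either the printed names or the 0–4
integer encoding used by the public EyePACS distribution.

`make_split()` partitions ids 70/15/15 (train/validation/test) by default.
Two choices here were genuinely open and are the package's own:

* **Stratification defaults to on.** Referable disease is ~4.5% of a
  screening population; an unstratified 15% test fraction would carry a
  noisy class mix, so per-class allocation is the reproducible default.
* **Largest-remainder rounding.** Set sizes are `floor(n·r)` plus one unit
  to the largest fractional remainders, ties broken by (train, validation,
  test) order; within a stratified split the same rule applies per class.
  This makes the partition an exact, testable function of `(ids, labels,
  ratios, seed)`.

## Fundus preprocessing

Preprocessing is crop → resize → enhance:

1. **Crop**: the tight bounding box of pixels whose channel mean exceeds a
   background threshold (default 10/255). Fundus photographs have a
   near-black surround, so this recovers the camera's field of view without
   circle fitting. An image with no qualifying pixel is passed through with
   a warning rather than an error.
2. **Resize**: bilinear, to a square `target_size` (default 600 px), via
   EBImage.
3. **Enhance**: per channel, in real arithmetic,
   `I_c = α·I + β·(G(ρ) ∗ I) + γ`, then round half-up and clip to
   [0, 255]. Defaults `α = 3, β = −3, γ = 128, ρ = 14`.

Because `α + β = 0`, the enhancement is a band-pass: the Gaussian blur
estimates the local illumination field and the subtraction removes it, so
differences in lighting, camera and exposure largely cancel and every image
is recentred on the mid-grey `γ`. A spatially constant image maps exactly
to `γ`, which the tests assert bit-exactly.

Several conventions are not forced by the formula and are fixed here as
documented decisions:

* `ρ` is the Gaussian **standard deviation in pixels on the resized
  image**; the kernel is truncated at `4ρ` and renormalized.
* Boundary handling is **symmetric reflection** (edge pixel repeated).
  Reflection avoids the dark vignette that zero-padding would smear into
  the fundus border, which would otherwise dominate the subtracted field
  near the rim.
* The blur is applied **independently per RGB channel** (not on a luminance
  channel).
* Rounding is **half-up after clipping bounds are applied**, so outputs are
  bit-reproducible across runs and platforms.

The in-package separable convolution exists because these conventions
(truncation radius, reflection, exactness) are part of the function's
contract; the test suite checks it against a literal dense 2-D convolution
written independently in the tests.

## Quality scoring and curation

Real screening sets contain ungradable images — blurred, under-exposed,
truncated. The package fixes the curation *workflow*: every image gets an
adequacy score in [0, 1], a threshold splits the set into curated and
rejected subsets, and the same policies are then evaluated on both
(`run_curation_experiment()`), reporting the exact rejection ratio. The
scorer is a registry entry, so a learned gradability model can replace the
default without touching the workflow.

The shipped `baseline` scorer is a deliberately simple heuristic — a
weighted mean (weights 0.4 / 0.3 / 0.3, configurable) of

* fundus-area fraction (pixels above the background threshold),
* a sharpness proxy: variance of a discrete 4-neighbour Laplacian on the
  green channel, divided by a saturation constant (default 500) and capped
  at 1 — the green channel carries most vessel contrast,
* global contrast: interquartile range of the channel-mean image / 255.

It is *not* a validated gradability model; what the tests assert is the
ordering contract (each degradation — defocus, under-exposure, truncation —
strictly lowers the score) and the workflow invariants (conservation,
monotonicity in the threshold), which are the properties the curation
experiment actually relies on.

## Decision policies

Let `p` be the probability vector over classes ordered least → most severe.

* **Argmax** returns a class attaining `max(p)`; exact ties break toward
  the more severe class — the conservative direction for screening.
* **Cascading thresholds** carries a threshold for every class except the
  designated fallback (written `~`). Classes are scanned most-severe-first;
  the first class whose probability reaches its threshold is returned
  *regardless of the less severe probabilities*; if none fires, the
  fallback is returned. Lowering a severe class's threshold can only add
  predictions of that class, so its sensitivity is non-decreasing as the
  threshold falls — the monotonicity the tests assert.
* **Margin max** takes a margin `m` and a preference order. With
  `m* = max(p)`, it returns the most-preferred class `c` with
  `m* − p[c] ≤ m`. Since the argmax satisfies the condition trivially, the
  rule is total; `m = 0` reduces to argmax (up to exact ties) and `m = 1`
  always returns the most-preferred class.

The margin-max formalization deserves a note. The informal description of
the technique — ignore the maximum rule when the top classes are within a
set margin — is ambiguous about *which* competitor the boosted class is
compared against. This package compares the boosted class against the
**global maximum**, which reproduces the canonical worked example
(`[0.3, 0.45, 0.25]`, margin 0.2, boosting Healthy → Healthy;
`[0.2, 0.45, 0.35]` → the argmax, Non-referable) and extends cleanly to
boosting the diseased direction.

The default preference order puts the boosted class first and the remaining
classes by increasing severity distance from it (ties toward more severe).
Boosting the least severe class therefore yields severity-ascending
preference, and boosting the most severe class severity-descending — the
two cases used in practice. An explicit `preference` argument overrides
this. When the diseased direction of a three-class scheme is boosted, the
preference is (Referable, Non-referable, Healthy).

A useful identity the tests exercise: in a two-class scheme, boosting
Healthy raises Healthy sensitivity and — by the one-vs-rest definitions,
identically — the Diseased specificity.

## Metrics

For class `c` in a K×K confusion matrix (rows true, columns predicted),
the one-vs-rest reduction is `TP = n[c,c]`, `FN = row − TP`,
`FP = column − TP`, `TN = rest`, and

* sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
* `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
* `F1 = 2·PPV·sens/(PPV+sens)`, accuracy = trace/total.

Zero denominators (a class absent from the truth or never predicted, which
happens routinely in small synthetic sets) yield an undefined flag (`NA`),
never an error, and are excluded from aggregates. Reports print at 4
decimal places. Note that specificity and PPV are distinct quantities —
screening reports occasionally conflate the two because both can be read as
"how trustworthy is a positive/negative call" — and this package computes
each strictly from its formula; the binary identities
(`sens(c₀) = spec(c₁)`, `PPV(c₀) = NPV(c₁)`) are asserted on random
matrices, as is equality against a literal per-sample TP/FP/TN/FN
enumeration.

## Synthetic generators

**Probability records.** Conditional on a true class drawn from a
prevalence vector, the probability vector is Dirichlet with class-specific
concentration — the simplest generative model on the simplex with
controllable confusability (concentration mass on the true coordinate sets
discriminability; total magnitude sets decisiveness). The `paperlike`
preset uses prevalence 65,300 : 19,400 : 4,000 (≈ 0.7362 / 0.2187 /
0.0451), the composition of a large public screening set, and
concentrations

```
Healthy          (9.0, 2.2, 0.5)
Non-referable DR (4.0, 5.0, 1.8)
Referable DR     (2.2, 3.6, 4.2)
```

chosen once so that unboosted argmax shows the qualitative profile of a
real screening classifier — high Healthy sensitivity (≈ 0.99), moderate
disease-grade sensitivities (≈ 0.54–0.60), accuracy ≈ 0.88. The pattern is
qualitative by design; no numeric agreement with any published
classifier's table is claimed or tested. The generator does **not** emulate
classifier calibration, inter-image correlation, or any image-level
pathology: tests passing on it demonstrate the correctness of the decision
rules, metrics and workflows, not the performance of any real CNN.

**Fundus images.** A centred bright disc with radial shading on a black
field, vessel-like dark random-walk curves, then exposure scaling, Gaussian
defocus and additive noise — enough geometry and texture for the crop,
enhancement and quality heuristics to respond to, and nothing more. Both
generators are pure functions of their config (a saved-and-restored RNG
stream), so identical configs give bit-identical output.

## Workbench

`run_comparison()` evaluates each policy next to the argmax `Original`
column on one record set; cells are exactly the metrics module's output for
that (records, policy) pair, with no recomputation in between.
`sweep_policy()` walks a parameter grid (margins, or a common cascade
threshold) against an objective such as sensitivity(Referable) ≥ 0.85 and
returns the parameter meeting it while maximizing the same class's
specificity; among ties the least aggressive (first-in-grid) parameter
wins, and an unreachable objective returns the best-achieving parameter
with a not-met flag. Reports carry a reproducibility header (package
version, R version, config hash).

## Numerical choices and problem sizes

* Probability sums are accepted within 1e-6 of 1, renormalized with a
  warning within 1e-3, rejected beyond — tolerant of CSV round-trips,
  strict against real errors.
* Monotonicity and policy-equivalence suites run on 10⁴-record synthetic
  sets and an exhaustive 0.05-step simplex grid (231 vectors for K = 3);
  generator contracts (prevalence and class-conditional means within three
  standard errors) are asserted at n = 10⁵. These sizes make the full
  suite run in well under a minute on one CPU while leaving the
  statistical assertions comfortably powered.

## Known limitations

* The baseline quality scorer is a heuristic stand-in behind the scorer
  interface; its absolute scores are not calibrated to expert gradability
  judgments, only its orderings are tested.
* The enhancement's blur convention (σ definition, truncation, reflection,
  per-channel application) is one reasonable fixed choice among several;
  images enhanced elsewhere with different conventions will differ at the
  border and in overall scale.
* One-vs-rest metrics on heavily imbalanced schemes can be undefined for
  rare classes in small samples; downstream code must handle the `NA`
  flags.
* Synthetic records are i.i.d. given the config; effects that depend on
  per-patient correlation (two eyes per subject) or covariate shift are
  outside what the generators emulate.
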