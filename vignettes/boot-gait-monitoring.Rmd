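---
title: "Monitoring tendon load and walking speed in an immobilizing boot: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring tendon load and walking speed in an immobilizing boot: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootgait)
```

## The monitoring problem and the model

During rehabilitation from an Achilles tendon rupture, patients walk in an
immobilizing boot whose heel wedges are removed in stages (30°, 5°, 0°),
each stage loading the tendon more. The quantity a clinician wants to track
is the **peak Achilles tendon load per stride**, expressed in multiples of
body weight (BW); **walking speed** (m/s) is the companion metric that is
easy to coach. Lab equipment (an instrumented insole and motion capture)
measures both, but only a body-worn IMU is practical for weeks of
monitoring. The pipeline therefore learns a mapping from stride-level IMU
summaries to the two targets.

The mapping is a LASSO: for a stride with feature vector $x \in
\mathbb{R}^p$ (z-scored per feature with training statistics $\mu_j,
\sigma_j$),

$$\hat y = \beta_0 + \sum_j \beta_j \tilde x_j, \qquad
\hat\beta = \arg\min_\beta \tfrac{1}{2n}\lVert y - \beta_0 - \tilde X\beta
\rVert_2^2 + \lambda \lVert \beta \rVert_1 ,$$

with the intercept unpenalized. An L1 penalty suits this feature set:
stride summaries of six channels are strongly collinear (all are driven by
the same gait cycle), and the sparsity both stabilizes the fit and keeps
the model auditable — typically a handful of nonzero weights out of 32.

**Assumptions.** (1) The gait cycle is well defined and detectable from
plantar force; (2) stride-level summary statistics carry enough information
that a *linear* model in those statistics predicts the targets; (3) the
insole-derived targets are trustworthy ("lab truth"); (4) subjects walk at
an approximately constant speed within a trial, checked by requiring
$R^2 \ge 0.98$ for the regression of forward center-of-mass position on
time (sub-threshold trials are flagged, not discarded — the check is a
confirmation, not a filter).

## Pipeline stages and their parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| contact threshold | 50 | N | heel strike / toe-off detection on insole force |
| debounce `min_off_s` | 0.05 | s | minimum sub-threshold interval accepted as swing |
| integrity tolerance | 0.1 | s | max insole-vs-IMU duration mismatch before a trial is rejected |
| inclusion filter `min_bw` | 0.5 | BW | strides with lower peak load are excluded (boundary inclusive) |
| lever ratio | 1.0 | — | stand-in insole-force → tendon-load multiplier |
| penalty grid | 30 points, $[10^{-4}, 10]\times\lambda_{\max}$ | — | inner-CV search space |
| inner CV folds | 5 | — | penalty selection, minimizing MAPE |
| MAPE grades | 10 / 20 | % | "excellent" / "acceptable" thresholds |

Notes on the less obvious choices:

* **"Local minima" as threshold crossings.** With a 50 N floor, the force
  minima that separate steps lie in the sub-threshold (swing) region, so
  contacts are delimited by reproducible threshold crossings rather than by
  noise-sensitive minimum positions. The debounce window absorbs chatter at
  the threshold line; leading/trailing partial contacts are discarded.
* **Toe-off** uses the same 50 N rule (first sustained fall below
  threshold). Whether the original lab implementations used a distinct
  rule is unknowable from the outside; stance/swing times remain
  insole-derived either way.
* **Phase impulses are signed; the absolute impulse is separate.** Since
  "absolute impulse" is listed as its own statistic, the stance/swing
  impulses are plain integrals $\int x\,dt$ — sign symmetry is tested.
  Integration is trapezoidal with $dt = 1/f_s$ (second-order accurate;
  exact for the constant and ramp oracles in the tests).
* **Scaling lives in the modeling step.** Standardization parameters are
  computed from training rows only, so no test-set statistics leak into
  the scaler. Zero-variance features are excluded from scaling and receive
  coefficient 0.
* **Penalty selection.** No selection rule is canonical here; the package
  uses seeded inner 5-fold CV over a log grid anchored at the data-driven
  $\lambda_{\max}$ (the smallest penalty that zeroes all coefficients),
  with MAPE as the selection criterion so that selection optimizes the
  reported metric. Ties prefer the sparser model.
* **The 0.5 BW boundary is inclusive** ("under 0.5 BW" excludes only
  strictly smaller peaks).
* **The tendon-load estimator is a documented stand-in**: load =
  lever_ratio × force / body weight. It is monotone in plantar force and
  replaceable by a full physics-based moment-balance model; with the
  synthetic generator the ground truth is known, so no conclusions depend
  on the stand-in's fidelity.

## Training paradigms

All three paradigms are evaluated per wedge condition and target, and
aggregated as across-subject mean ± SD (each subject weighs equally,
regardless of stride count):

* **generalized** — leave-one-subject-out: the test subject contributes
  nothing to training;
* **hybridized** — training adds the test subject's random half of strides
  to all other subjects' data;
* **personalized** — training uses only that half.

The 50/50 split is random at stride level, seeded, and *shared* between
hybridized and personalized so their test sets coincide and the paradigm
comparison is paired. Sensor ablations (gyroscope off; 50/25 Hz; extra
sensors) re-extract features from the raw recordings per configuration,
because decimation changes the sampled extrema and impulses. Decimation
keeps every $k$-th sample with no anti-alias filter — the point is to
emulate a sensor *natively* sampling slower, and such a sensor applies no
digital pre-filter; the insole and COM streams stay at 100 Hz because the
targets come from lab-grade equipment. IMU stride indices are obtained
from insole-clock events by time-proportional mapping with
round-half-away-from-zero.

## What the synthetic cohort emulates — and what it does not

`sim_config()` defaults describe ten subjects × three wedge conditions ×
four self-selected speeds (pathological 0.60, slow 0.90, medium 1.25, fast
1.60 m/s) × three trials × fourteen strides ≈ 5,000 strides. Ground truth
per stride is

$$\text{load}_{s,i} = \text{base}(c) + 0.8\,(v - 1.1) + u_s +
\varepsilon_i, \qquad u_s \sim N(0, 0.45^2),\ \varepsilon_i \sim N(0,
0.06^2),$$

with base loads 1.3 / 2.1 / 2.9 BW for 30° / 5° / 0° (progressive loading
as wedges are removed), floored at 0.3 BW. Walking speed is the COM slope;
the subject-specific speed offset (SD 0.05 m/s) enters the speed itself and
is therefore *visible* to the kinematic features, whereas the load offset
$u_s$ is not encoded in any feature. That single asymmetry reproduces the
monitoring problem's central structure: generalized speed models succeed,
generalized load models carry an irreducible per-subject error, and
personalized load models absorb it. Signal-level realism is deliberately
minimal but sufficient for the pipeline: a double-bump stance force scaled
so the sampled peak equals the true load × body weight (its 0.45 floor
keeps the whole stance above the 50 N threshold, so each step is exactly
one contact); a stride-locked SI-accelerometer oscillation whose amplitude
is linear in speed ($2 + 4v$ m/s², plus a heel-strike transient); an ML
gyroscope oscillation whose extrema scale with cadence; low-frequency
content throughout so 25 Hz sampling distorts features by under 2 %.

Not emulated: pathological gait asymmetry beyond a speed/loading shift,
3-D kinematics, the insole's 3-region partition, or any subject-specific
*feature-to-speed* idiosyncrasy — consequently the personalized paradigm
shows no advantage for walking speed on synthetic data, and passing tests
say nothing about that effect in real patients. Passing tests demonstrate
that the pipeline recovers structure it is pointed at, not that real boot
gait has that structure.

## Numerical choices and degenerate inputs

* Seeds: one global seed; subjects draw from spaced substreams
  (seed + 100003·index) so subsets reproduce and nearby global seeds give
  disjoint cohorts. Pipeline stages use named substream offsets.
* glmnet is run with our standardization (not its own), `thresh = 1e-8`
  during CV and `1e-9` with the path truncated at the selected penalty for
  the final fit; on nearly collinear designs the last digits at near-zero
  penalties may not settle within the iteration cap, which leaves
  predictions unaffected at these tolerances and is tolerated silently.
* MAPE requires strictly positive truth; the 0.5 BW filter and speed
  positivity guarantee it in the pipeline, and `mape()` refuses otherwise.
* Empty event lists, single contacts, and strides with zero kept rows are
  returned as empty results or per-subject warnings, never silent NA.
* Learning-curve subsets resample pooled training rows (not whole
  subjects) at each fraction, averaged over 5 seeded repetitions.
* Cross-correlation agreement normalizes per lag on the overlapping
  segment (so a pure delay scores 100 %), reports the signed maximum, and
  bounds the lag search at ±1 s to avoid spurious distant maxima.

## Problem sizes used by the test suite

Unit tests run on a 4-subject, 384-stride cohort; the end-to-end paradigm
checks use the full default cohort (≈ 5,000 strides) at three seeds; the
ablation neutrality check uses a noise-free 6-subject cohort; the
acceptance script regenerates the default cohort once. These sizes were
chosen so the statistical claims under test (orderings, recovery rates)
are comfortably powered while the whole suite stays quick to run.

## Known limitations

* The tendon-load estimator is a placeholder scaled force, adequate only
  because the generator supplies ground truth; real deployments need the
  physics-based insole model.
* Paradigm orderings are demonstrated on synthetic cohorts whose
  structure guarantees them in expectation; they are a check of the
  machinery, not evidence about patients.
* `mape_grade()` thresholds (10 %/20 %) are clinical conventions, not
  statistical tests; no hypothesis testing between paradigms is provided.
* Time is represented as sample index + rate after parsing; streams are
  assumed synchronized at $t = 0$, and no timestamp-based realignment is
  attempted.
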