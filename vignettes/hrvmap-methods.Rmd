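---
title: "Methods: normalized N-dimensional return maps for HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized N-dimensional return maps for HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvmap)
```

## The model

An RR record is a sequence of M positive beat-to-beat intervals. Two levels
of filtration remove, respectively, slow (circadian-scale) and local
influences:

1. **Global normalization**: `x_i = X_i / mean(X)`, a dimensionless series
   with mean exactly 1. Every downstream quantity is therefore invariant
   under rescaling of the raw intervals, which removes inter-subject
   differences in mean heart rate and makes the representation unit-free.
2. **Local filtration**: order-N forward moving averages
   `<x>_i = (x_i + ... + x_{i+N-1}) / N`, i = 1..M-N+1.
3. **Deviation field**: `Delta_{i,k} = x_{i+k} - <x>_i`, the residual of the
   orthogonal projection of the window onto the identity line
   `{1, ..., 1} t` — the locus of zero beat-to-beat variability. The locally
   normalized variant is `delta_i = Delta_i / <x>_i`, which expresses each
   window's deviation relative to its own local rate; we compute with
   `Delta` throughout and expose `delta` for exploration.

Each row sums to zero analytically, so the field lies in the zero-sum
hyperplane and only N - 1 components are informative; `truncate_for_graph()`
drops the last component (recoverable as the negative sum of the others).
For N = 5 the four truncated components render as a 3D scatter with the
fourth component hue-coded to 0-1.

Assumptions worth stating: windows are formed over consecutive *recorded*
beats with no gap interpolation. Upstream "NN-only" cleaning (discarding
ectopic-labeled beats) must not be applied: the premature-beat /
compensatory-pause structure is exactly the signal the B-line detectors
measure. `intervals_from_annotations()` therefore keeps all beats by
default.

## Primary variability

The field is centered at the origin by construction, so the displacement of
its center of mass measures uncompensated N-th order structure. Averaged
over all M - N + 1 overlapping windows this displacement is spuriously
small, because each interval re-enters N - 1 consecutive vectors and cancels
against itself. `primary_variability()` therefore averages only the
stride-N subset of windows (starts i = 1, 1 + N, 1 + 2N, ...), in which each
beat appears exactly once, and reports

    Phi_N = scale_factor * || mean_{strided i} Delta_i ||.

`scale_factor` defaults to 100, putting Phi on a percent-like scale. The
norm uses all N components: closure makes the full Euclidean norm well
defined and identical in content to any fixed (N-1)-dimensional
parametrization of the hyperplane; a `truncated = TRUE` flag computes the
first-(N-1)-components variant for sensitivity studies. The strided subset
starts at the first window, with no averaging over the N possible stride
phases — on stochastic records the phase choice is immaterial, and on
stride-locked periodic records the un-averaged statistic is the sharper
diagnostic (`order_scan()` on a period-5 series shows Phi_5 far above
Phi_4, which is the intended behavior of a phase-locked detector).
`order_scan()` computes Phi across orders; ties for the minimum break
toward the smallest order, and orders outside `[2, M/2]` are skipped with a
warning rather than silently renumbered. Records shorter than twice the
order are rejected by name of the minimum length.

## The line catalog

Arrhythmic event types are rays through the origin, represented as
unit-norm direction vectors (`arrhythmia_line`). Matching is
orientation-sensitive: a direction and its negation are distinct
physiological events. A line is *compensated* when its components sum to
zero and *terminated* when its last component vanishes.

- **A1 (ramps)**: the zero-mean arithmetic ramp. `A1+` is the accelerating
  form — intervals shrinking across the window, components running from
  positive to negative, `(2, 1, 0, -1, -2)` at N = 5 — and `A1-` its
  negation. This is the dominant variability mode of healthy sinus rhythm.
- **A2 (respiratory)**: one full period of a sampled sine,
  `sin(2 pi k / N)`, compensated at any phase; a `phase` argument is
  provided because the zero-phase convention is a choice, not a constraint.
- **B1 (compensated ectopic beat)**: -1 then +1 at consecutive positions.
  The canonical member places the pair at interior positions
  (N-3, N-2) — (2, 3) for N = 5 — which both terminates the window and
  matches the position of clear ubiquity in pathological records; the other
  interior positions are available as named variants, and the wrap-around
  "edge" pattern `(1, 0, ..., 0, -1)` is constructible but excluded from the
  default signature because it does not clearly occur.
- **B2 (pause-tachycardia)**: `(m, -1, ..., -1, 0)` at order m + 2 — a pause
  compensated by m proportionally faster beats, then a terminating beat on
  the local average. The canonical member is m = 4, a sixth-order
  structure.
- **B2 fragments**: an order-6 B2 event seen by order-5 windows produces
  `(4, -1, -1, -1, -1)` and `(-1, -1, -1, -1, 4)`. As raw sequences these
  are not compensated (the event completes only at order 6), so they are
  flagged accordingly.
- **B3 (displaced pause)**: the pause moved to an interior position i of the
  compensating run, `(-1, ..., +m at i, ..., -1, 0)`. The component lists
  follow from the defining constraints (compensated, terminated, interior
  pause, pairwise non-parallel across i); this package's constructor is its
  own normative definition of the family.
- **Shadows**: derived constructively as the directions produced when a B2
  event is scanned by windows offset i beats from its onset: (m - i + 1)
  components of -(i + 1) followed by (i + 1) components of (m - i + 1).
  This reproduces the faint companion lines seen alongside B2 and is, again,
  this package's own construction satisfying the family's constraints.
  Shadows and B3 are catalogued for overlay and exploration but excluded
  from the default signature; their quantitative behavior is deliberately
  left uncharacterized.

`default_catalog()` bundles the six signature lines in fixed report order:
A1+, A1-, A2+, A2-, B1, B2. JSON export/import allows alternative
transcriptions of any family to be loaded without code change.

## Presence quantification

For each window the generalized angle to a line is computed on the first
N - 1 components (the truncated line renormalized), orientation preserved.
Windows with truncated norm at or below `quiescence = 1e-6` have no
meaningful direction and are never matched; the threshold is far below any
physiological variability at double precision. A window matches when
`cos(theta) >= tolerance_cos`; the packaged default is 0.98 (about 11.5
degrees), exposed as a parameter since the appropriate tightness depends on
noise level. An optional amplitude floor (default off) can reject
noise-level alignments.

The presence of a line is `100 * m * (N-1) / (M-N)` percent. The factor
N - 1 converts a count of matched windows into beat coverage, which implies
m should count *events*: a single isolated event produces several
near-matching overlapping windows. Overlap suppression (default on)
therefore makes windows i+1..i+N-1 ineligible after a match at i, greedily
left to right. The literal every-window count is available with
`suppress_overlap = FALSE`. Suppression preserves monotonicity of presence
in the tolerance: loosening the tolerance enlarges the candidate set, and
greedy matching with a fixed blocking length never selects fewer matches
from a superset.

`signature()` assembles the six presences plus Phi_N. B2 is evaluated at
its native order 6 on a second field built from the same record (the
default), because the compensated form is a sixth-order structure even when
the rest of the signature uses N = 5; presences from the two orders are
reported side by side without rescaling. The alternative
`b2_order = "fragments"` policy evaluates the two order-5 fragments as one
joint detector at N = 5. `M_cap` restricts analysis to the first M_cap
beats (e.g. 4200) so records of different lengths are compared on equal
footing — Phi in particular depends on record length.

## The synthetic generator

`generate_rr()` emulates: a unit-mean baseline at `mean_rr`; stationary
AR(1) multiplicative noise (`noise_sd`, `ar_coefficient`) — the simplest
model with tunable short-range correlation resembling sinus variability; a
respiratory sinusoid of amplitude `resp_amplitude` and period 5.1 beats,
chosen incommensurate with the order-5 window so the strided phase drifts
rather than artificially inflating Phi_5; and injected events that
*overwrite* their beats with exact zero-sum templates scaled by an
amplitude. Overwriting keeps an aligned window's deviation vector exactly
on its catalog line when noise is zero, so recovery tests are exact rather
than statistical, and zero-sum templates leave the record mean untouched.

Three presets fix the study conditions (3000 beats per record): `nsr_like`
(12 ramp+, 8 ramp-, 8 sinus bursts, 2 ectopic pairs; noise 0.02, AR 0.5,
respiratory amplitude 0.02), `hf_like` (40 ectopic pairs, 10
pause-tachycardia runs, 1 ramp of each sign; noise 0.03, AR 0.6),
`sd_like` (4 ectopic pairs, 2 ramps; noise 0.08, AR 0.9 — high variability
with little structured ectopy). Event rates were chosen once to mirror the
qualitative orderings of the corresponding clinical regimes — ramp-dominated
health, ectopy-dominated heart failure, noise-dominated post-arrest — at
presences of a few percent; positions are drawn with spacing of at least 12
beats (twice the largest analysis order) so injected events remain isolated.

What the generator does **not** emulate: circadian nonstationarity, beat
detection error, missed or duplicated annotations, heavy-tailed noise,
coupling between events and the surrounding rate, and drug- or
activity-induced regime changes. Passing tests on these fixtures therefore
demonstrate correctness of the geometry, the catalog and the counting
procedure under controlled conditions — not clinical performance on Holter
databases, which additionally depends on acquisition choices outside this
package.

## Numerical choices

- Moving averages are computed by direct convolution with unit weights and
  a single division by N, so each window mean is a fresh N-term sum;
  rounding stays at a few machine epsilon per row instead of accumulating
  along a running sum, keeping closure residuals below 1e-12 even on long
  records. Closure is then asserted post hoc, not enforced by
  re-projection: the formula guarantees it analytically and the assertion
  catches implementation drift.
- Unit handling: a median interval above 10 is taken as milliseconds at
  ingest; a declared unit always overrides detection. Normalization cancels
  units, but the raw series is stored canonically in seconds.
- Indexing is 0-based in the line-position arguments (matching the
  component index k = 0..N-1) and 1-based in all window/beat reports.
- Degenerate inputs: series shorter than 2 beats, non-positive intervals
  (reported by index), orders outside [2, M], records too short for a
  stride subset or a signature — all rejected with the minimum requirement
  named. Constant records produce all-zero fields, zero presences and zero
  Phi rather than errors.
- Output files serialize floats at 12 significant digits, so identical
  inputs and configuration give byte-identical CSV/JSON.
- The view rotation of `hf_view_projection()` solves an orthogonal
  Procrustes problem mapping the three canonical B1-family spatial
  directions to 120-degree-separated directions in the viewing plane, with
  the reflection corrected to determinant +1 — a reproducible construction
  in place of an unspecified camera angle; user-supplied Euler angles
  override it.

## Problem sizes used in the test suite

Property tests run on 1000 random series of 10-5000 beats at orders 2-10
(closure and projection-oracle equivalence), 200 random 120-beat records
(tolerance monotonicity), cohorts of 20 + 20 records of 3000 beats
(signature-space separation), and exact-recovery fixtures of 300-600 beats.
These sizes exercise every code path at full numerical strictness while
keeping the default suite around ten seconds.

## Limitations

The locally normalized delta field is computed and exposed but its
discrete-mode structure is not further analyzed here. Only RR intervals are
handled, not other QRS components. Presence percentages are descriptive
statistics, not diagnostic classifiers: no decision thresholds are provided,
and the synthetic regimes are calibrated for ordering, not for reproducing
clinical presence magnitudes from any particular database.
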