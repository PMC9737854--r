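---
title: "The PLUS hierarchical fuzzy model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PLUS hierarchical fuzzy model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluscore)
```

## The problem

Life satisfaction is routinely measured with several complementary
clinimetric questionnaires at once — perceived stress (PSS10, 0–40, higher =
worse), satisfaction with life (SWLS, 5–35, higher = better), musculoskeletal
complaints (NMQ count, 0–40, higher = worse) and the three Maslach Burnout
Inventory subscales: emotional exhaustion (EE, 0–54), depersonalization (DP,
0–30) and personal accomplishment (PA, 0–48, the only MBI subscale where
higher is better). Each instrument has its own range, direction and
linguistic interpretation ("low stress", "moderate exhaustion"), which makes
a simple weighted sum a poor aggregate. The PLUS (personal living usual
satisfaction) composite instead treats the aggregation as fuzzy inference:
the instruments' linguistic interpretations become fuzzy partitions, and
their combination becomes a small, auditable rule base. The result is a
single score in $[0, 1]$, "the higher, the better", suitable for repeated
remote monitoring and for flagging deterioration between assessments.

## The inference machinery

All systems in the hierarchy are Mamdani systems with one fixed operator
configuration:

* premise aggregation: **product** of the antecedent membership degrees,
* implication: **min** (each consequent set is clipped at its rule's
  activation),
* accumulation: **max** (the pointwise upper envelope of the clipped sets),
* defuzzification: **centre of gravity** (COG),
  $e = \int x\,\mu(x)\,dx \,/\, \int \mu(x)\,dx$.

Membership functions are trapezoids $T = (l, k_1, k_2, r)$: zero outside the
support $[l, r]$, one on the kernel $[k_1, k_2]$, linear on the shoulders.
Degenerate shoulders are allowed and the kernel wins at the shared point, so
$(0,0,0,14)$ has membership 1 at exactly 0 — this convention is required for
the boundary behaviour below.

Because every membership curve in the pipeline is piecewise linear, the
accumulated envelope is represented exactly: its breakpoints are the clipped
trapezoids' corners plus every crossing between clipped sets, and the COG is
accumulated per linear segment in closed form (area
$\tfrac{\Delta x}{2}(y_1+y_2)$, first moment
$\tfrac{\Delta x}{6}\,(x_1(2y_1+y_2) + x_2(y_1+2y_2))$). A dense-grid
numeric integration exists in the test suite as an independent oracle (step
$10^{-4}$, agreement within $10^{-6}$ over 1,000 random envelopes), but the
shipped path is the closed form: exactness at the boundaries is a stated
property of the model, not a numerical accident.

## The three-tier hierarchy

**Tier 1 — normalization.** Each of the six raw scores is mapped to $[0,1]$
by a single-input system. The input partitions are the published
low/medium/high trapezoids, for example for PSS10
$X^L = (0,0,0,14)$, $X^M = (0,14,26,40)$, $X^H = (26,40,40,40)$ — all six
partitions are Ruspini partitions (label memberships sum to 1 everywhere).
The output variable has three sets $Y_1 = (0,0,0,0.5)$,
$Y_2 = (0,0.5,0.5,1)$, $Y_3 = (0.5,1,1,1)$; for defuzzification the
boundary sets are extended to $(-0.5,0,0,0.5)$ and $(0.5,1,1,1.5)$ so the
centroid can reach exactly 0 and exactly 1. Scales where higher raw scores
are better (SWLS, PA) use the identity rule assignment
(low→$Y_1$, medium→$Y_2$, high→$Y_3$); the rest use the reversed one, so
every normalized value means "the higher, the better".

**Tier 2 — context modules.** Mental state aggregates normalized PSS10 and
SWLS; physical condition has the single NMQ input and passes it through
unchanged; burnout aggregates the three normalized MBI subscales. Module
inputs are split into two complementary ramps $I^L = (0,0,0,1)$,
$I^H = (0,1,1,1)$. The three-input burnout module uses the published
eight-rule base — the output level $O_{k+1}$ is simply the number $k$ of
inputs at $H$ — over the four-set partition $O_1,\dots,O_4$ with kernels at
$0, \tfrac13, \tfrac23, 1$. We use exact thirds rather than the printed
roundings $0.333/0.667$: the roundings are evident decimal truncations, and
exact thirds preserve both the Ruspini property and the mirror symmetry
below.

**Tier 3 — final aggregation.** The final system is structurally identical
to the three-input module and combines the mental, physical and burnout
outputs with equal importance.

```{r}
res <- plus_evaluate(c(pss10 = 20, swls = 19.5, nmq = 20,
                       mbi_ee = 21.5, mbi_dp = 11, mbi_pa = 35))
res
```

Every raw value above is its scale's kernel midpoint, so all tiers sit at
the neutral 0.5 — a useful fixed point for checking a deployment.

### Design choices that were genuinely open

* **The two-input rule base is reconstructed.** The source description
  states that multi-input modules split their inputs into two-valued
  variables and prints the three-input base, but not the two-input one. We
  use the unique minimal analogue — LL→low, LH and HL→mid, HH→high over the
  three-set $Y$ partition with extended boundary sets. Any other
  mirror-symmetric choice on these partitions would have to introduce
  asymmetric mid levels the description gives no grounds for.
* **The defuzzification interval.** The COG integration domain is nowhere
  stated; we integrate over $[-0.5, 1.5]$ at tier 1 and
  $[-\tfrac13, \tfrac43]$ at the module/final tiers, i.e. exactly the span
  of the extended boundary sets, which is the only reading under which the
  stated purpose of those sets ("reach exactly 0 and exactly 1") holds.
* **Extended boundary sets at every tier.** The extension is printed only
  for the tier-1 output variable, but the final tier is stated to share the
  three-input module's structure and the same boundary argument applies, so
  we extend $O_1/O_4$ the same way.
* **The PA partition keeps the printed 49s.** The personal-accomplishment
  subscale tops out at 48, yet its printed sets use 49 as the upper support
  and kernel bound. We keep the printed parameters and the $[0, 48]$ legal
  range; the visible consequence — a perfect PA score normalizes to about
  0.93, so the best achievable PLUS score is about 0.985 rather than 1 — is
  documented rather than silently "fixed".
* **Raw scores are accepted as reals** within the closed legal intervals
  (integers are the documented norm, but half-point conventions exist in
  practice), and validation failures name the scale, the offending value
  and the legal interval.

### Properties the implementation maintains

These are enforced by the test suite, not merely asserted:

* all printed partitions are Ruspini partitions on dense grids;
* the analytic COG agrees with an independent numeric oracle;
* three-input modules satisfy $f(1-a, 1-b, 1-c) = 1 - f(a, b, c)$;
* the PLUS score is monotone along every single score axis (the other five
  held at their kernel midpoints) and stays in $[0, 1]$ over an exhaustive
  $5^6$ grid spanning every scale's full range;
* the physical module output is bit-identical to the normalized NMQ value;
* a model serialized to JSON (17 significant digits) and reloaded produces
  bit-identical outputs.

## Longitudinal monitoring

`compute_deltas` takes consecutive differences of the PLUS score (and raw
scores) across a subject's assessments. `detect_deterioration` flags a
subject when some consecutive drop reaches a threshold — default **0.05**
on the PLUS scale, a value chosen because it separates the two reference
cohorts' mean trajectories (consecutive mean changes of −0.060/−0.113 in
the deteriorating group versus −0.044/+0.035 in the stable one); no formal
decision rule was published, so the threshold is configurable and the flag
is deliberately conservative: a zero step never counts as a decline, even
at threshold 0. Trends are classified as deteriorating (all steps down),
improving (all steps up), stable (all steps within the threshold band) or
mixed.

`summarize_group` uses quartiles by linear interpolation at position
$(n-1)p$ (R's default type 7) and the sample ($n-1$) standard deviation.
These conventions were not stated in the source; they are pinned by the
published group summaries, which they reproduce exactly at the printed
precision (e.g. Q1 0.2045 → printed 0.204, Q3 0.25475 → printed 0.255 for
the deteriorating group's final assessment). The published summary rows for
the *earlier* two assessments do not all reconcile with the published
per-subject values themselves (differences beyond 3-decimal rounding), so
only the final-assessment rows serve as an exact fixture.

`change_correlation` computes Spearman's $\rho$ on average ranks, with a
two-sided p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (matching common statistical-package
output at these small $n$) and an optional exact permutation p; results are
marked non-significant at $p \ge 0.05$.

## The synthetic cohort generator

No subject-level questionnaire data were ever released, so the package
generates cohorts with the study's structure: two occupational groups
(physiotherapists-like "group1", IT-professionals-like "group2"), three
timepoints, $n = 20$ by default. Each subject's score on each scale is
drawn from a truncated normal around the per-timepoint preset mean, with a
persistent subject-level offset (SD = half the cross-sectional SD, the
remainder independent per timepoint, so the total cross-sectional SD is
preserved), then rounded to integer scores and clamped to the legal range.

Preset provenance, number by number:

* Group-1 PSS10 (29.20/30.85/33.20, SD 2.71/2.25/2.19), SWLS
  (16.30/14.90/10.95, SD 3.57/3.42/2.26) and MBI aggregate
  (48.75/56.75/63.50, SD 15.50/12.67/8.99) are the published per-timepoint
  summaries.
* The published tables print only an MBI *aggregate*; the presets decompose
  it as a burnout load $EE + DP + (48 - PA)$ split 57/18/25 — proportional
  to the subscale ranges, emotional exhaustion largest, personal
  accomplishment drifting opposite to the other two. This decomposition is
  a reconstruction, not data.
* The published group-2 table prints its MBI and SWLS columns swapped
  relative to the scales' legal ranges (an SWLS mean of 53.55 exceeds the
  scale maximum of 35); values are assigned to the scale whose range they
  fit.
* Where a published per-timepoint mean contradicts the study's own summary
  of significant drift directions (group-1 NMQ is printed flat-then-down
  yet summarized as "more problems"; group-2 PSS10/MBI are printed
  non-monotone yet summarized as improving), the presets follow the drift
  direction, since reproducing those directions in expectation is the
  generator's contract: group-1 NMQ rises 0.70/0.85/1.05; group-2 PSS10
  eases 18.55/17.50/16.00, SWLS rises 17.25/19.50/21.00, and the burnout
  load peaks at the middle assessment (53.55/62.50/48.00) — the peak is
  what produces the published dip-then-recovery pattern in group 2's PLUS
  trajectory while the net change still improves.

All preset values were fixed from this reasoning before the end-to-end
expectations were run, and are not tuning knobs. What the generator
emulates is the *location, spread and drift* of the published cohorts; what
it does not emulate is item-level response behaviour, floor/ceiling
clustering, or the exact per-subject outcomes (under-determined without the
raw data), so passing end-to-end tests demonstrate that the pipeline
recovers the intended group-level patterns from realistically noisy input —
not that the model reproduces the original cohort subject by subject.

```{r}
rec <- generate_cohort(preset_cohort_spec("group1-like", n = 20), seed = 1)
mon <- plus_monitor(rec)
mon$summaries[, c("group", "timepoint", "median", "mean", "sd")]
table(mon$reports$trend)
```

## Problem sizes and numerical notes

The grid-extrema sweep uses 5 levels per axis ($5^6 = 15{,}625$
evaluations, with tier-wise memoization of repeated sub-inferences); the
end-to-end cohort checks use $n = 200$ subjects per group, at which every
preset drift direction is statistically overwhelming. Property suites use
10,001-point grids for partition sums, 1,000 random envelopes for the COG
oracle and 500 random triples for mirror symmetry, all under fixed seeds.
Envelope crossings are located by exact linear interpolation between
candidate breakpoints; rules with activation exactly 0 are dropped before
accumulation, and an all-zero activation vector raises a degenerate-
inference error rather than returning an arbitrary value (for in-domain
inputs it cannot occur, because every input partition is Ruspini).

## Known limitations

* The best achievable PLUS score is ≈0.985, a direct consequence of the
  printed PA partition (see above).
* The two-input rule base and the MBI preset decomposition are documented
  reconstructions.
* Tier-1 normalization is insensitive within a scale's medium kernel (any
  PSS10 between 14 and 26 normalizes to exactly 0.5); this is inherent to
  the published partitions and explains the many identical scores a
  healthy cohort produces.
* `detect_deterioration`'s threshold is a monitoring convention, not a
  clinically validated cut-off.
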