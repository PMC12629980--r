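---
title: "Methods: crossdating, error localization and sapwood dating in dendrodate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossdating, error localization and sapwood dating in dendrodate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodate)
```

This vignette explains the statistical machinery of the package, the
assumptions behind it, the choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## Ring series and calendar conventions

A `ring_series` is a dated sequence of strictly positive annual ring widths
in mm, anchored by the calendar year of its outermost ring. Calendar years
are plain CE integers; all supported material is 2nd millennium CE, so no
year-zero handling exists. Widths of zero (the "missing ring" placeholder
some archive files carry) are rejected at parse time rather than imputed:
every downstream statistic assumes complete measured sequences, and a
silent zero would corrupt both the log-ratio transform and the sign series.

The Tucson reader accepts both circulating dialects — the `999` stop marker
(0.01 mm storage) and `-9999` (0.001 mm) — and infers the unit from the
sentinel, with an explicit `unit` argument as override; a file with neither
sentinel is refused with instructions rather than guessed. Unit conversion
uses integer division by 100 or 1000 rather than multiplication by 0.01, so
a write/read round trip reproduces widths bit-identically at storage
precision.

## Crossdating statistics

**Baillie–Pilcher transform.** Index `x_i = ln(w_i / m_i)` with `m_i` the
mean of the centred 5-year window. The two boundary years at each end are
dropped rather than computed from a shrunken window, so every index is a
true 5-year ratio. The window mean is computed as an explicit 5-term sum,
which makes a constant series transform to exact zeros (a useful degeneracy
check) instead of accumulating convolution rounding.

**TBP.** `t = r · sqrt(n − 2) / sqrt(1 − r²)` over the `n` overlapping
transformed values. Two overlap counts are carried everywhere: `overlap`
(raw overlapping rings, the Ol users expect to see printed) and `overlap_t`
(transformed-value overlap, 4 less when one series is nested in the other),
because conflating them is a classic off-by-four confusion. When `r` is
numerically 1 — self-matches, duplicate detection — the formula diverges;
`t` is reported as a fixed cap of 9999, and the cap also bounds `|t|` from
below 1, so every ranking is total and finite. Zero variance in an overlap
segment (possible for constant stretches) is an error in the scalar
functions and a silently skipped offset in the scan.

**%PV and its significance.** Per interval the score is `|s_a + s_b| / 2`
on the ternary signs of first differences: 1 for agreement in a nonzero
direction, 1/2 when exactly one series shows no change, 0 otherwise. Ties
contribute ½ but the interval count `n` is not reduced, following the
classic treatment. Significance uses the one-sided normal approximation
with null mean ½ and standard deviation `1/(2·sqrt(n))`. This approximation
ignores the serial correlation of sign agreements; it is the form the
field's software prints, and the thresholds (63 %, p < 0.05) are calibrated
to it.

**Scan and ranking.** Every end year giving at least `min_overlap_scan`
(default 50) raw overlapping rings is evaluated. Results are ranked by `t`
descending, ties broken by %PV, then overlap, then the earlier end year —
a deterministic total order. Classification: *accepted* needs `t ≥ 5`,
`%PV ≥ 63` and p ≤ 0.05; *potential* needs `t ≥ 3.5` over ≥ 100 rings;
everything else is *no match*. The thresholds are a `match_policy` object,
not constants, because laboratories differ.

**Same-tree assessment.** Two boards from one trunk share not only the
regional signal but the tree's own growth noise, so their match is
dramatically stronger than any between-tree match. The verdict
`same_tree_candidate` requires `t ≥ 10` (a configuration default of this
package — the literature gives no canonical number) *and* %PV significant
at p < 0.001. A `disregard` window excludes a stated span of calendar years
from both statistics, the standard device when a known measurement problem
contaminates part of a series.

## Localizing missing and doubled rings

Given a trusted reference of the same ring sequence, a single-ring slip in
the suspect shows as a step in the local alignment: rings before the slip
match the reference at one lag, rings after it at a lag one ring away.
The procedure:

1. **Lag profile.** Sliding 30-ring windows (step 5) over the
   Baillie–Pilcher indices, each assigned the lag in ±3 maximizing windowed
   correlation. Short runs (≤ 2 windows) whose lag differs from both
   neighbours are absorbed into the nearer-lag neighbour: windows
   straddling a duplicate pair carry distorted values and can prefer an
   arbitrary lag, and treating such blips as boundaries fabricates events.
2. **Boundaries.** Each lag step, plus a leading (trailing) region when the
   first (last) window is off the lag expected there, becomes a boundary
   region with known flanking lags. The step direction determines the event
   kind: the reference gaining a ring across the step means a ring is
   missing in the suspect; losing one means a ring was measured twice.
3. **Position.** Within a boundary, candidate positions are scored on raw
   ring widths under the split alignment (head rings at the incoming lag,
   tail at the outgoing lag; for a doubled hypothesis the two duplicate
   measurements are replaced by their sum, matched against the one
   reference ring). Raw widths are the right scale because measurement
   noise is additive in mm, making the residual sum of squares the Gaussian
   likelihood statistic. The reported position maximizes the posterior mass
   of its ±1-ring neighbourhood rather than the point posterior: over a
   complacent (low-variance) growth stretch one-ring misalignments are
   nearly free and the likelihood plateaus, and the window rule targets
   exactly the quantity that matters — the year "or the year next to it",
   the form in which the field itself reports such slips. The ambiguity
   flag (`year_uncertainty = 1`) is raised when the central candidate
   carries less than ¾ of that window mass.
4. **Acceptance.** A candidate correction is applied and judged on the
   realized whole-series TBP *re-anchored* over a global shift of up to
   `max_events` rings — what a dendrochronologist does after an edit is
   re-crossdate. Re-anchoring is essential: when one missing and one
   doubled ring offset each other (the classic configuration), correcting
   either one alone moves the stated end year off the reference, and at a
   fixed anchor no single edit improves the match. Corrections are accepted
   greedily, earliest boundary first (so an accepted edit sits where the
   suspect's calendar still agrees with the reference and its year is a
   calendar estimate), each requiring an improvement of at least `min_gain`
   (default 0.25 t-units) — the guard that keeps the false-event rate on
   clean pairs low.
5. **Joint corrections.** If no single edit clears the bar but two adjacent
   boundaries exist, they are corrected jointly; and when the two slips sit
   closer together than one profile window they never produce a lag step at
   all, only a dip in the windowed correlation — detected as a contiguous
   run of windows at least 0.15 below the typical correlation level — and a
   joint two-event search runs across the dip in both orders. A joint
   correction has twice the freedom to overfit and must clear twice
   `min_gain`; its TBP improvement is attributed to the pair, halved onto
   each reported event, so `delta_t` stays non-negative for every event and
   every accepted correction step strictly increases the re-anchored
   whole-series TBP.

Corrections use the start-anchored calendar convention (first ring fixed,
end year shifts by ±1 per event), the exact inverse of the generator's
error injection. A doubled ring is corrected by summing the two implicated
widths — the exact inverse of splitting a ring in two — and a missing ring
by inserting a placeholder with the local 5-ring median width, flagged in
the `reconstructed_years` attribute. The placeholder's width is a
convention, which is precisely why the position search never lets it vote:
positions are chosen on real rings only.

Limitations: events must be at least roughly `2 × window` rings from each
other for the profile to separate them into distinct boundaries (closer
pairs go through the valley search); block errors spanning several rings
and corrections against a mean chronology (rather than a single trusted
series) are out of scope; and the position of a slip inside a long
complacent stretch is inherently ambiguous — no estimator can do better
than the ±1 report when the rings around it carry no variation to align.

## Sapwood dating

The estimates are exact interval arithmetic on the regional sapwood
statistic (shipped default: oaks grown in Poland, 9–24 rings, median 15,
90 % confidence interval):

- heartwood/sapwood border dated `y`: felling in `[y + 9, y + 24]`,
  median `y + 15`;
- heartwood only: terminus post quem `y + 9`;
- `k` sapwood rings preserved: the border is `y − k`, giving
  `[y − k + 9, y − k + 24]` with the lower bound clamped to `y + 1` — a
  tree cannot have been felled before its last existing ring grew. The
  published arithmetic has no partial-sapwood case; the clamp generalizes
  it conservatively;
- bark edge present: felling is exactly `y`.

Production windows add the seasoning allowance `(s_min, s_max)`: earliest
possible production `[L + s_min, L + s_max]` from the felling lower bound
`L`, likely production `[L + s_min, U + s_max]` (open above for a terminus
post quem). Presets: `klein_1990s` (2, 2) and `replication` (2, 5).
The confidence attached to the interval is carried through from the
statistic verbatim; whether it attaches to the whole interval or to each
tail is not re-interpreted here. No new sapwood distributions are fitted;
statistics for other regions are constructed with `sapwood_stats()`, not
shipped.

## The synthetic generator

`synthetic_scenario()` emulates the data structure the analysis assumes:

- **Master signal**: standardized AR(1) with persistence `ar1_phi`
  (default 0.3, the moderate year-to-year carryover typical of ring-width
  series).
- **Trees**: log growth mixes the master with tree-level AR(1) noise,
  `sqrt(share)·master + sqrt(1 − share)·tree`, so `tree_signal_share` *is*
  the expected log-width correlation between trees, and its square root the
  correlation with the master. Default 0.45, putting a board's correlation
  with the master near 0.67 — the range in which a good series-to-chronology
  match lives — while two unrelated trees (r ≈ 0.45) stay safely below the
  same-tree threshold.
- **Age trend**: negative-exponential width trend (2.5 mm initial, decay
  0.02/yr, 1.0 mm asymptote), realistic for slow-grown oak.
- **Scale**: `master_sd` (default 0.25) is the log-scale standard deviation
  of the growth signal; noise is multiplicative, so widths stay positive
  and the log-ratio transform is the natural analysis scale.
- **Boards**: tree widths over the board's span plus additive measurement
  noise (`measurement_sd`, default 0.05 mm — between the ~0.01–0.02 mm of
  on-screen measurement from calibrated photographs and the 0.1 mm of a
  hand lens); negative draws are resampled. Sapwood counts stated as `NA`
  are drawn uniformly over the statistic's range — only the range and
  median are published, so no finer shape is assumed.
- **Errors**: a `missing` event deletes the stated ring (end year −1), a
  `doubled` event splits it into two half-width rings (end year +1, total
  width conserved, making the summation merge its exact inverse).

The default board table mirrors a three-panel study setting: a 210-ring
board ending 1606 at the heartwood/sapwood border, a 231-ring board from
the same tree with 8 sapwood rings ending 1614, and a 99-ring board from a
second tree ending 1601, under a 1100–1650 master.

What the generator does *not* emulate: climate signatures and their spatial
decay (so it cannot validate provenance inference), ring-width
heteroscedasticity tied to age, juvenile-wood effects, locally absent rings
of biological origin, or measurement error that is correlated along the
radius. Passing tests therefore show that the statistics and search
procedures behave as designed under the assumed signal/noise structure —
not that any particular real pair of panels will reach a given t-value.

## Numerical choices and test scale

Determinism: every stochastic routine draws from R's generator after
`set.seed(scenario$seed)` in a fixed order, so outputs are reproducible
across platforms at floating-point tolerance. The scan is pure slice
arithmetic (no per-offset allocation beyond the slices), keeping a
210-ring-vs-550-year scan in the tens of milliseconds.

The test suite validates the statistics against brute-force oracles (direct
Pearson sums, explicit sign-agreement counting) to 10⁻¹², and calibrates
the Monte-Carlo claims at the study's own scale: 200 seeded crossdating
scenarios (550-year master, 210-ring samples), 1000 independent pairs at
overlap 100 for the null exceedance of t = 3.5, 200 same-tree pairs with
one injected deletion plus one duplication for error recovery, and 200
different-tree pairs for the same-tree false-positive rate. These sizes
give binomial standard errors of 1–2 percentage points on the rates being
bounded, which is sufficient for the pass/fail margins involved and keeps
the whole suite under a minute on one CPU.
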