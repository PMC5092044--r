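---
title: "Processing model and validation of RFID home-cage sociability measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing model and validation of RFID home-cage sociability measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecohab)
```

## The measurement problem

A cohort of up to twelve transponder-tagged mice lives in a ring of four
housing compartments connected by four tube corridors, each corridor
carrying an RFID antenna at both ends. The raw data are antenna
detections: timestamped, millisecond-resolution reads of a 14-digit
transponder code. Nothing in the stream says directly where a mouse *is*
— only which coil it just passed. Everything downstream (occupancy,
co-residence, odor preference) therefore rests on reconstructing visits
("sessions") from pairs of detections, and all the subtlety of the
pipeline lives in the rules that decide which pairs bracket a genuine
stay.

## Session reconstruction

For each mouse, detections are taken in chronological order and
classified pairwise with a sliding window — (e1, e2), then (e2, e3) — so
a single detection may both close one visit and open the next, exactly as
a mouse leaving one compartment enters another. For each pair, in order:

1. **Gap below the threshold** (default 2 s): skipped. Bursts of re-reads
   under one coil and dashes straight through a compartment both produce
   sub-second to second-scale gaps; treating the threshold rule first
   means a read burst can never manufacture a visit.
2. **Same antenna** twice: a visit to that antenna's nearest compartment
   (entered and left through the same corridor).
3. **Two antennas of one corridor**: a corridor pass; skipped (corridor
   time is deliberately not assigned to any compartment).
4. **Antennas of two different corridors with the same nearest
   compartment**: a visit to that shared compartment.
5. **Anything else**: ambiguous; skipped, and tallied in the diagnostics,
   because such a pair can only arise when at least two crossings went
   undetected.

Two readings of rule 4 are defensible: corridor granularity (the two
corridors are adjacent) or antenna granularity (the two specific antennas
face the same compartment). The package uses the antenna-level rule. Two
antennas of adjacent corridors that do *not* face a common compartment
already prove a missed detection, and assigning a compartment on provably
incomplete evidence would contaminate the downstream duration measures;
those pairs go to the ambiguous bin instead. A consequence worth knowing:
of the 64 ordered antenna pairs in the standard ring, 8 are same-antenna,
8 same-corridor, 8 face a shared compartment, and 40 are ambiguous.

Sessions record a `consecutive` flag: `TRUE` for two-antenna visits (rule
4), `FALSE` for same-antenna visits (rule 2). The first and last
detections of a recording simply end the pair chain; no synthetic
boundary visits are invented, so the final dwell of every mouse — which
no exit event ever closes — is invisible to the measures. This is an
irreducible censoring of the method, not of this implementation.

Timestamps are handled as half-open intervals `[start, end)` everywhere,
so abutting phases and abutting visits never double-count an instant.
Simultaneous reads of one mouse are processed in log order; their gap of
zero falls under rule 1 and is harmless. Internally times are POSIXct
(UTC); raw-file writing reconstructs the integer millisecond by rounding,
so a write → read round trip preserves every field bit-for-bit.

## Masking and phases

Experiments are divided into named phases declared in an INI-style
`config.txt`. Two masking modes restrict a session table to a window:

* `clip` (default for every duration-bearing measure): keep overlapping
  sessions and truncate them to the window. Clipping conserves time — a
  partition of a span into consecutive windows sums back to the whole —
  which is the property occupancy and sociability need.
* `start_based`: keep, unmodified, sessions *starting* in the window.
  This reproduces the behavior of the original field scripts and is kept
  for comparability; it drops or over-counts boundary-straddling time.

Corrupted recording segments have no reliable automatic signature, so
they are declared by the experimenter as exclusion intervals and
subtracted from analysis windows (`subtract_exclusions()`).

## The measures

**Occupancy** of compartment *i* by mouse *a* is the clipped session time
divided by the window length, `t_ai ∈ [0, 1]`; the per-mouse total falls
short of 1 by corridor and unassigned time. **Activity** is the count of
sessions starting in the window.

**In-cohort sociability** of a pair is `t_ab − Σ_i t_ai · t_bi`: observed
normalized time together minus the time expected were the two mice
exploring independently. Three exact scenarios pin down its behavior and
are asserted to 1e-12 in the tests: two mice sharing one compartment for
the whole window score 0 (their co-residence is fully explained by
occupancy); perfectly synchronized mice splitting the window between two
compartments score +0.5; perfectly anti-synchronized mice score −0.5.
The first scenario is a genuine degeneracy worth remembering: the score
measures co-residence *beyond what occupancy predicts*, so a cohort
compressed into one compartment scores zero no matter how literally
"together" it is.

**Approach to social odor** is the ratio of stimulus-bin preference to
baseline-bin preference, `(T_S/T_nS) / (t_S/t_nS)`. Any zero denominator
makes the ratio undefined; undefined ratios propagate as `NA` with a
`defined = FALSE` flag rather than infinities, mirroring the
quality-control rule that excludes animals too inactive to have visited
the stimulus compartments. The baseline bin is conventionally drawn from
the last dark phase before stimulus presentation at the same clock offset
and duration as the stimulus bin, controlling for circadian activity; the
bins are fully caller-specified, so any other convention is available.
Log-scale presentation of ratios is left to plotting; statistics are
always computed on raw ratios.

**Group comparisons** use the Mann-Whitney U test and Pearson correlation
through thin wrappers over `stats::wilcox.test()` and
`stats::cor.test()`; these scores are typically non-normal.

## The simulator

The generator is a test harness, not a behavioral model: it is the
simplest continuous-time process that produces data with the structure
the pipeline must handle. Each mouse alternates exponential compartment
dwells (mean 60 s by default — a realistic home-cage visit scale that
yields roughly one antenna crossing per 30 s of active exploration) with
fixed corridor transits (2.5 s by default, deliberately above the 2 s
threshold so corridor passes are classified by geometry rather than
discarded by the gap rule). Corridor choice is symmetric, so single-mouse
long-run occupancy is uniform across compartments — a property the tests
check by Monte-Carlo.

Two couplings create recoverable effects:

* **Affinity** multiplies a mouse's expected dwell by `(1 + α)` for each
  co-resident affiliated partner, acting on the *leaving rate* rather
  than on destination choice so that it directly inflates co-residence
  time, the quantity the sociability score measures. Rate changes are
  handled by the memorylessness of the exponential: whenever a partner
  arrives or departs, the remaining dwell is redrawn at the new rate.
  Affinity structure matters. Uniform all-pairs coupling at large α makes
  group dwell multipliers compound (four co-residents at α = 3 already
  multiply dwell by 4³), and the cohort collapses into a single immobile
  clump — a regime where the chance-corrected score degenerates toward 0
  and where visits stop closing because nobody crosses an antenna again.
  Validation cohorts therefore use disjoint affiliated *partner pairs*
  (`partner_affinity()`), which raise pair co-residence strongly without
  freezing the cohort.
* **Odor effect** multiplies expected dwell in one designated compartment
  by `k` from an onset time, emulating an attractive olfactory stimulus;
  since visit rates to all compartments stay symmetric, the stationary
  occupancy ratio — and hence the approach score — recovers `k` itself.

Detection is modeled per antenna crossing: a read with probability
`1 − p_miss` (default 0; video-validated installations read essentially
every passage), plus `Poisson(burst_mean)` extra reads spaced 0.25–0.6 s
apart — wider than the 210 ms merge window of the acquisition hardware,
so they appear as separate log lines, and narrower than the 2 s
threshold, so the sessionizer absorbs them. Read-out durations are
uniform in 20–200 ms. All randomness in a simulation flows from one
`set.seed()` stream, which makes cohorts exactly reproducible from a
single integer seed; per-mouse counter-based streams were considered and
rejected as R provides no efficient primitive for them, and the
single-stream design already delivers the reproducibility that matters.

What the simulator does *not* emulate: circadian rhythm, aggression and
dominance dynamics, scent marking, individual variation in movement
speed, and antenna cross-talk. Passing recovery tests on simulated data
therefore demonstrates the correctness of the *computation* — that the
pipeline recovers what the generator planted — not the biological
validity of any particular threshold for a given mouse strain.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:

* the sessionizer against a brute-force re-implementation of the five
  rules, written naively from the rule list, over 1000 random event logs
  of up to 50 events with gaps straddling the threshold;
* every duration computation against a 1-ms discretized-timeline count,
  anchored near the epoch where millisecond values are exactly
  representable, to below 1e-9 relative error;
* end-to-end occupancy against ground truth on 8 simulated mice for 2 h
  with perfect detection, where reconstruction error (corridor transits,
  sub-threshold visits, the uncloseable final dwell) stays below 5% of
  the window;
* sociability null calibration on 20 independent 2-mouse cohorts (mean
  within 2 standard errors of 0) and effect recovery on 10 affiliated
  vs 10 null 8-mouse cohorts of one simulated hour (rank-sum p < 0.05);
* odor recovery on 50 single-mouse simulations per condition with 8 h
  baseline and stimulus bins. The ratio-of-ratios estimator is consistent
  but finitely biased upward (roughly `k · (1 + CV²)` of the baseline
  preference ratio), and both bias and variance shrink as 1/T; 8 h bins
  put the population mean within half a percent of the planted `k` and
  the standard error of a 50-mouse mean near 4%, comfortably inside the
  10% acceptance band. Shorter bins (30 min – 4 h) remain available for
  time-course analyses, at proportionally higher estimator noise.

`scripts/acceptance.R` recomputes all of these quantities from scratch at
any seed; no number reported there or in the README is asserted anywhere
— each is produced by running the pipeline.

## Known limitations

* A mouse's final visit in any recording (or analysis window) is censored
  until its next antenna crossing; measures on windows comparable to a
  single dwell are accordingly biased low.
* The sessionizer discards corridor time by design; total per-mouse
  occupancy fractions sum to less than 1 and the deficit grows with
  crossing frequency.
* The in-cohort sociability score cannot distinguish a cohort compressed
  into one compartment from independent exploration (both score ~0); it
  is a measure of *excess* co-residence, not of proximity per se.
* The exact on-disk date format of a given acquisition installation must
  be known; the reader's dialect is configurable but not auto-detected.
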