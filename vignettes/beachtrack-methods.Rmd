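---
title: "Estimating nesting-beach track counts from camera traps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nesting-beach track counts from camera traps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beachtrack)
```

## The problem

Sea turtle nesting beaches are indexed by counting the tracks females leave
when they emerge to nest. Counting on foot is labour-intensive and, at
remote rookeries, often impossible for most of the season. Fixed time-lapse
cameras photograph a stretch of beach every morning and can run unattended
for weeks, but each camera only sees a small alongshore window (5–30 m in
practice), so raw camera counts must be scaled up to the whole beach, and
the reliability of that scaled estimate depends on how much of the beach
the cameras cover. `beachtrack` implements the full chain of methods needed
to design and analyse such a survey:

1. a **per-metre binomial deposition model** and Monte-Carlo simulator that
   quantify how the precision of the whole-beach estimate varies with
   camera coverage;
2. a **power-law fit** of estimate SD against coverage, the designer's
   summary of that simulation;
3. **whole-beach extrapolation** of raw camera counts under day-varying
   coverage, with camera-range calibration;
4. **tidal-phase classification and stale-track back-allocation** for foot
   patrol data with gaps;
5. **track-longevity estimation** under the field censoring rules; and
6. **camera duty-cycle and storage arithmetic**.

A seeded synthetic-season generator reproduces the statistical structure of
the field data so every stage runs, and is tested, without any field data.

## The deposition model and the coverage simulation

The beach is a line of $L$ one-metre sections. On each day, each metre
independently receives a track with probability

$$ q = \frac{\mu}{L}, \qquad p = 1 - q, $$

where $\mu$ is the expected whole-beach track count per day. At the study
scale ($L = 2800$ m, $\mu = 6$/day) this gives $q = 0.0021428$ (reported
truncated to seven decimals). The model allows at most one track per metre
per day — a reasonable idealisation given track widths near 1 m and daily
counts far below saturation.

Cameras observe $m$ of the $L$ metres (coverage fraction $f = m/L$). The
day's covered count $N$ is extrapolated to the whole beach as
$\hat{X} = N L / m$, and a season estimate is the mean of $\hat{X}$ over
$D$ days. `run_coverage_simulation()` repeats this for $R$ replicate
seasons, re-drawing the covered metres each replicate, and reports the mean
and sample SD (denominator $R-1$) of the replicate means. Because
deposition is i.i.d. across metres, the covered count is exactly
$\mathrm{Binomial}(m, q)$; the simulator draws it directly instead of
materialising all $L$ indicators, which is an exact thinning, not an
approximation — a test cross-checks it against the explicit per-metre path.

The analytic counterpart (`coverage_sd_closed_form()`) is

$$ \mathrm{SD}\left(\bar{\hat{X}}\right)
   = \sqrt{\frac{\mu (1-q)}{D f}}, $$

since $\mathrm{Var}(\hat{X}) = (L/m)^2 \, m q (1-q) = \mu (1-q)/f$. Every
simulated SD is tested against this oracle within the Monte-Carlo sampling
error of an SD estimated from $R$ replicates, approximately
$\mathrm{SD}/\sqrt{2(R-1)}$.

### Problem sizes

The simulation defaults are the study scale: 90-day seasons, 100
replicates per coverage level, and the six-level grid
$\{2, 5, 10, 20, 30, 40\}\%$ — the grid spans the stated 2–40 % range, and
six points are what a single-numerator-degree-of-freedom fit over that
sweep implies. Tests that only exercise the machinery use smaller beaches
and shorter seasons; the statistical checks (rate recovery, oracle
agreement, unbiasedness) run at 3000 simulated days or 100+ replicates and
use 3-standard-error bands.

## The power-law fit

The SD falls in coverage as $\mathrm{SD} = a / C^{\,b}$ with $C$ in
percent. `fit_power_law()` estimates $a$ and $b$ by ordinary least squares
of $\log \mathrm{SD}$ on $\log C$ ($b$ the negated slope, $a$ the
back-transformed intercept, i.e. the SD at 1 % coverage). Natural logs are
used internally; the result is invariant to the log base, and a test
verifies this against an independent base-10 route. On the closed-form SDs
the exponent is exactly $1/2$ — the fitted exponent on simulated SDs
scatters around $0.5$ and the coefficient around
$\sqrt{100\,\mu(1-q)/D} \approx 2.58$ at the study scale. No weighting or
nonlinear least squares is used: the fit is a straight line on log scales
by construction.

`cameras_needed()` turns a target coverage into a camera count. At 20 %
of 2800 m (560 m) with 30-m camera ranges the exact quotient is 18.6. The
default recommendation is the ceiling (19); because field planning
typically rounds to a margin, `round_up_to = 10` gives the planning figure
of 20. The choice is exposed rather than hard-coded because the quotient,
not the rounding, is the defensible quantity.

## Extrapolation under day-varying coverage

Real coverage changes daily as cameras fog, fall, or fill their cards.
`daily_coverage()` collapses a station-day log to per-day covered metres
and failure counts by cause; `extrapolate_daily_count()` scales a day's raw
count by $L/\text{covered}_m$. Two conventions matter and are fixed here:

* **Per-day extrapolation, then averaging** — not a pooled ratio — so
  season totals are non-integer, exactly as day-wise construction implies.
* **Days with zero working cameras are undefined**, excluded from every
  mean and reported in an `n_undefined_days` diagnostic. Treating them as
  zero-track days would bias the season mean downward.

Station intervals are half-open `[start, end)` in metres from the beach's
southern end, required disjoint; a track belongs to the interval containing
its metre index. `calibrate_station_range()` converts counts of 5-m-spaced
marker tracks into observed ranges.

The simulated camera log carries two counts per station-day: all tracks
visible in frame (`track_count`, the direct content of an image) and
tracks seen at that station for the first time that day
(`new_track_count`). Whole-beach *emergence* estimates use the latter —
an analyst comparing consecutive images counts new tracks — while the
former measures track-days and would overcount emergences by roughly one
plus the mean persistence. `extrapolate_camera_log()` defaults to new
tracks when the column is present.

## Tidal structure

The tidal calendar is a repeating 15-day cycle indexed 0–14 from spring
tide. Days 0–3 and 12–14 are spring-phase, days 4–11 neap-phase. Patrol
tables carry a `gap_days` column equal to the calendar-day difference to
the previous survey; tracks older than 24 h found at a survey are spread
over the `gap_days - 1` unsurveyed days by `allocate_stale_tracks()`:
every gap day receives `floor(stale/gap)` and the remainder goes one per
day to the days nearest the survey, so the allocation vector is
non-increasing with distance and always conserves the total. Daily surveys
(`gap_days = 1`) have no unsurveyed days, so a nonzero stale count there is
rejected as inconsistent rather than silently absorbed.

Bin means follow the two-day convention: (0,1), (2,3), …, (12,13), with
day 14 reported as its own singleton bin — fifteen labels cannot pair
evenly, and folding day 14 into any pair would blur the spring peak. Empty
bins are reported as missing, never zero. Tidal-day labels above 14 (a
cycle running a day long) are clamped to 14 with a warning; the calendar
itself is an input, not something the package predicts.

## Track longevity and censoring

Longevity is **last visible day minus first visible day**: a track seen on
one morning only has longevity 0, which is why the natural range starts at
zero. A record yields no value (is censored) when

* the track was already present when the camera started recording,
* the camera stopped for good while the track was still visible
  (including persistence past the end of the record), or
* the vegetation line is out of frame, so the track's landward end — and
  hence its disappearance — cannot be judged.

A single invisible day between sightings (fog) is **bridged**: a foggy
lens does not erase a track, so only the first and last sightings matter.
A camera that goes down and never operates again while the track persists
censors the record; summaries (`longevity_summary()`) cover uncensored
records only and report the censored count alongside. On synthetic data
the uncensored records measure true persistence exactly (a property test
compares each against the brute-force max-minus-min oracle); censoring at
the season end removes disproportionately long-lived late tracks, a small
selection effect the recovery test absorbs within its Monte-Carlo band.

## The synthetic-season generator

The generator is the package's stand-in for a field campaign and defines
the conditions every statistical test runs under:

* **Daily counts**: per-metre Bernoulli with day-specific probability
  `mean_day / L` — the same family as the coverage simulation — with
  `mean_day` = 5.0 tracks/day on neap days and 2.4 on spring days, the
  observed phase means. An optional hotspot profile reweights metres (the
  field arrays record strongly nonuniform alongshore density); the profile
  must not push any per-metre probability above 1.
* **Persistence**: truncated geometric on $\{0,\dots,9\}$ days with its
  mean solved numerically to equal 2.8 days — the simplest single-parameter
  discrete distribution with the right support given that only the mean,
  SD and range of persistence are known. Its implied SD (≈2.6 d) is close
  to, but not fitted to, the observed ≈2.2 d.
* **Failures**: fog is independent per camera-day (0.3/13 ≈ 0.023);
  falling is absorbing until a service day (rate 0.6/13 ≈ 0.046, weekly
  service by default); in high-frequency mode the card fills
  deterministically after `capacity_days` operating days.
* **Tidal calendar**: the repeating 15-day cycle anchored at
  `spring_tide_day0`.

What the generator does **not** emulate: weather-driven persistence
(monsoon wash-outs), species mixtures, day-to-day rate variation beyond
the two-phase tidal modulation, spatial autocorrelation of emergences, and
drift in a camera's observed distance over time. Passing tests therefore
demonstrate that the estimators are correct *under the stated model*, not
that the model captures every feature of real beaches; in particular the
real camera-count SDs are heavier-tailed than the binomial model predicts.

## Numerical and interface choices

* All randomness flows from explicit integer seeds; sweeps draw one
  substream seed per coverage level so levels are independent and
  reproducible bit-for-bit.
* Covered metres are re-drawn each replicate (not each day); under i.i.d.
  deposition the estimator's distribution is the same either way.
* `m` rounds to the nearest metre with a floor of 1.
* Probabilities print truncated, not rounded (`format_probability()`), to
  match how the per-metre pair $p, q$ is conventionally reported; the
  printed $p$ is the complement of the truncated $q$.
* Duty-cycle image counts expose the endpoint convention explicitly
  (`exclude_end` floor-counts intervals and reproduces 180 images/day at
  30 s over 0700–0830; `include_both` adds the final fence post and gives
  3 images at 30 min over 0700–0800) because deployed cameras exhibit
  both behaviours.
* CSV files use ISO-8601 dates or integer day indices, metres as the only
  length unit, and coverage in percent in user-facing tables (fractions
  internally). Readers validate eagerly and name offending rows.

## Limitations

The extrapolation assumes track density on covered metres reflects the
whole beach; with hotspots and few cameras this only holds on average over
placements, and the whole-beach SD at the observed ~5 % coverage is large
(the power law predicts roughly 1.1–1.2 tracks/day at 5 % versus 0.58 at
20 % for the study-scale beach). Longevity estimation treats persistence
as an intrinsic property; it does not model weather covariates. The
camera-count recommendation is deterministic arithmetic, not an optimal
design under a cost function.
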