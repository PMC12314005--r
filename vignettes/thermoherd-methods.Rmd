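---
title: "Thermal exposure and grazing-cattle behaviour: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal exposure and grazing-cattle behaviour: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thermoherd` turns four multimodal sensor streams from collared grazing
cattle — 5-second ethogram labels, 1 Hz GNSS fixes, 10-minute weather
records, and weekly weigh-scale records — into an exposure–response
analysis: how does behaviour (grazing, walking, ruminating, resting,
drinking, shade use, travel distance) co-vary with thermal load, and how do
weight gain and *Bos indicus* ancestry enter the picture? This vignette
documents the models, the conventions, the tunable parameters, and the
synthetic-data generator that the test suite uses in place of (on-request
only) trial data.

## The thermal index

Thermal load is summarised by the Comprehensive Climate Index (CCI) of
Mader, Johnson and Gaughan (2010): an apparent temperature

$$\mathrm{CCI} = T_a + \mathrm{adj}_{RH}(T_a, RH) + \mathrm{adj}_{WS}(WS) +
\mathrm{adj}_{RAD}(T_a, RAD),$$

where $T_a$ is air temperature (°C), $RH$ relative humidity (%), $WS$ wind
speed (m/s) and $RAD$ solar radiation (W/m²). Unlike heat-only indices such
as THI, the CCI is defined across both cold- and heat-stress ranges, which
matters for subtropical late-spring conditions where nights are mild. The
three adjustment equations are transcribed into a single constants table in
`R/cci.R` (version tag `mader-2010`) rather than scattered through the
code, so the index is auditable and replaceable. Structural anchors of the
equations that the tests pin down:

* the humidity adjustment carries an $(RH - 30)$ factor, so it vanishes
  identically at 30% relative humidity;
* at zero radiation the radiation adjustment reduces to the pure
  temperature term $0.1\,T_a - 2$;
* the index is increasing in $T_a$, increasing in $RH$ at warm $T_a$,
  decreasing in $WS$, increasing in $RAD$;
* the decomposition `cci = ta + rh_adj + ws_adj + rad_adj` is exact to
  numerical tolerance, and spot values are checked against an independent
  hand evaluation of the published equations.

Wind speed is held internally in m/s (the convention of the source
equations); weather files recorded in km/h are converted on read
(`wind_unit = "km/h"`, ÷3.6), and group summaries report wind back in km/h.
The published equations have a finite validity envelope (roughly
$T_a \in [-30, 45]$ °C, $WS \le 30$ m/s, $RAD \le 1500$ W/m²); inputs
outside it are computed with a warning by default, with `"clamp"` and
`"reject"` alternatives (`cci_envelope` in `herd_config()`). Humidity
outside $[0, 100]$ and negative radiation are always hard errors.

Each calendar date is reduced to its **maximum** CCI — peak thermal load —
and that single per-date value is attached to the full-day, daytime, and
nighttime summaries of the date alike.

## Trajectories, shade use, distance

Raw fixes are reduced to one position per animal per 10-minute interval by
taking the median of each coordinate independently (even counts: mean of
the two middle values). The median is what makes single-fix outliers
harmless, which a property test verifies.

Shade use is a binary per-interval classification against a digitised
canopy map: a position is *open* iff it lies inside the paddock polygon and
inside no canopy polygon. Point-in-polygon is even-odd ray casting; a point
exactly on a canopy boundary counts as canopy, deliberately conservative
for shade estimates. An independent winding-number implementation serves as
the test oracle on random simple polygons. Daytime time in the open is
1/6 h per open interval; it is undefined at night and therefore appears
only in daytime analyses.

Travel distance is exactly the estimator the collar data supports: the sum
of haversine great-circle segments (sphere radius 6371.0 km) between
*consecutive 10-minute medians*. This underestimates true path length —
within-interval movement is averaged away — and the package implements the
estimator as-is rather than attempting resampling corrections. Two
conventions are ours where the field is silent: no segment is accumulated
across a gap of more than 60 min of missing medians (prevents spurious
jumps), and each segment is attributed to the daypart of its starting
interval, so day + night distance partitions the full-day distance exactly.
Animal-days whose full-day distance falls outside $[0, 10]$ km are flagged
implausible and excluded, the filter being applied to the full day and
propagated to both dayparts.

## Behaviour budgets and dayparts

Each 5-second label contributes $5/3600$ h to its class, aggregated per
(animal, hour) and then per (animal, date, daypart). Daytime is the
half-open interval $[05{:}00, 18{:}00)$ local time — 13 h day, 11 h night —
matching sunrise/sunset at the trial site. All timestamps are interpreted
at a fixed UTC+10 offset (no daylight saving in the region); the timezone
is configurable. A date's night is that date's evening plus that same
date's pre-dawn hours; the alternative (night spans midnight into the next
date) is one configuration flag (`night_same_date = FALSE`), provided for
sensitivity analysis.

Mondays are weighing days: mustering induces atypical activity, so Monday
rows are removed from all behavioural tables (idempotently). Weight records
themselves, and the climate ranking below, keep all days.

Labelled time need not cover the day: observed class-hours in the source
setting sum to roughly 13 h per day, not 24. Coverage is therefore
measured as the fraction of a daypart's *hours containing at least one
record*; dayparts below the threshold (default 80%) are flagged incomplete
and dropped from correlations. Missing data is always explicit (`NA`),
never a silent zero, and correlations use pairwise-complete deletion.

Weekly behaviour tables report median ± MAD per trial week; the MAD is raw
(no 1.4826 normal-consistency scaling), and that convention is stated in
the function documentation.

## Exposure ranking

Correlating behaviour against raw CCI can understate cumulative stress, so
days from both trials are pooled and ranked by daily maximum CCI (rank 1 =
coldest; ties get midranks, making the ranking permutation-invariant and
invariant to any strictly monotone transform of the index). Weekly means of
day ranks order the eight trial weeks; consecutive pairs of that ordering
form four exposure groups, group 1 the coolest pair, group 4 the warmest.
Weeks are the trials' calendar weeks (consecutive 7-day blocks from each
trial start). "High CCI" analyses are group 4; "low CCI" analyses group 1.

## Correlation layer

Within each group × daypart stratum, each anchor variable — daily maximum
CCI, *Bos indicus* proportion, initial weight, weekly weight gain — is
correlated with each behavioural variable (six class-hours plus distance;
time in the open daytime only), plus weight gain against CCI and against
*Bos indicus*. The coefficient is plain Pearson $r$; the 95% interval is
the Fisher $z$ closed form $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$,
the convention behind forest plots (no CI method is specified in the
source presentation; Fisher is the standard choice). Spearman coefficients
are emitted alongside as a linearity check. No multiple-testing correction
is applied, matching the source presentation; "significant" language is
restricted to "CI excludes 0".

The unit of analysis is the **animal-day pooled within the group** (two
weeks × all animals), the main reproduction assumption since the source
does not state its pooling; per-animal means within group are available as
`unit = "animal_mean"`. Pooled animal-days are not independent — animals
repeat across days and day-level CCI is shared across animals — so for
animal-level anchors (Bos indicus, initial weight) the nominal Fisher
intervals are anti-conservative under animal-level heterogeneity. This
pseudo-replication caveat is inherent to the reproduced design; the
package surfaces it here rather than silently switching to a mixed model,
which would be a different analysis.

Weekly weight gain is the difference of consecutive Monday weighings,
attributed to the week ending at the later weighing; gaps other than
exactly 7 days are flagged and excluded from weekly correlations.

## The synthetic-data generator

No public accession exists for the trial data, so `simulate_trials()`
emulates the full five-stream study at its stated scale: two 28-day trials
(starting on the Mondays 2022-11-21 and 2023-11-20, so that weigh dates
are Mondays) of 60 animals each. Its defaults *are* the study conditions:

* **Weather**: 10-minute series with a diurnal temperature sinusoid
  (peak 15:00) on an AR(1) day-to-day drift, humidity anti-correlated with
  temperature, a solar half-sine that is exactly zero at night scaled by a
  daily cloud factor, log-normal wind (~4.8 km/h mean), sparse rain.
  Parameters are calibrated so daily maximum CCI spans roughly 36–52, the
  reported range of the trials.
* **Behaviour**: per animal-day class-hour targets centred on the observed
  weekly medians (grazing ≈ 7 h, ruminating ≈ 2.9 h, resting ≈ 2.1 h,
  walking ≈ 0.75 h, drinking ≈ 0.1 h) with animal-level random effects,
  allocated to hours via diurnal templates, capped at 1 h/hour, quantised
  to the 5-s grid.
* **Planted effects**, all linear in (daily max CCI − 44): `graze_shift`
  (default 0.12 h per CCI unit) moves grazing from day to night;
  `rest_gain` (0.06) adds daytime resting; `shade_affinity` (0.12 logits
  per CCI unit) raises daytime canopy occupancy; a small positive
  walking × *Bos indicus* × CCI interaction. The daytime-resting effect is
  planted positive (resting increases with CCI), following the results
  narrative of the source study (its abstract prints the opposite sign for
  the same coefficient; the inconsistency is noted, not resolved).
  Effects are planted at the *daily-budget* level so their theoretical
  signs and magnitudes are available in closed form for recovery tests.
* **Movement**: per 10-minute block the animal is under canopy with the
  planted probability (night occupancy fixed at 0.15, independent of CCI);
  canopy blocks sample uniformly inside an animal-day home canopy, open
  blocks scatter (σ = 10 m) around an anchor near it, which keeps daily
  distances in the observed 2.5–3.9 km envelope and below the 10 km
  plausibility bound. GNSS receiver noise is isotropic Gaussian (~3 m);
  no error model is published for the collars.
* **Animals**: initial weights with median 259 kg and spread 39 kg; *Bos
  indicus* uniform on [0.47, 0.95]; weekly gains = baseline + small
  coefficients on mean grazing hours and distance + noise, totalling
  ≈ 25 kg median over four weeks (259 → 284 kg).
* **Rain** has no behavioural effect by default (the analysis is CCI-only);
  the config leaves a hook for future covariates.

The generator is a pure function of its configuration: one seed, one byte
stream. Two emission resolutions share identical planted truth and RNG
draws: `"full"` writes 5-second labels and raw fixes (the on-disk fixture
dialect, used at small scale), `"hourly"` emits hourly budgets and
10-minute medians directly (the trial-scale route; emitting 5-s/1 Hz
streams for 120 animal-months — hundreds of millions of rows — would be
pointless for analyses that begin by aggregating to exactly these levels).
A test verifies the two routes agree exactly on the shared truth and that
budgets reconstructed from the 5-s labels equal the realized truth.

What the generator does *not* emulate: spatially realistic movement
(attractor scatter, not a biomechanical walk), weather fronts or
rain-driven behaviour, collar dropout and fix-quality variation,
between-trial differences beyond a weather offset, and any nonlinear or
lagged exposure response. Passing recovery tests therefore demonstrate
that the *pipeline* recovers what was planted under the stated noise — not
that real cattle behave linearly.

## Numerical and design choices

* Intervals are half-open everywhere (5 s, 10 min, 1 h, 1 day), making
  aggregation partitions exact; conservation tests assert exact equality.
* Tie-breaking: midranks in day ranking; week pairing breaks exact
  avg-rank ties by week index for stable output.
* `n = 3` correlation cells get the degenerate full-range CI $[-1, 1]$;
  zero-variance cells are reported as missing, never as $r = 0$.
* The null configuration for CI-coverage checks sets planted slopes *and*
  animal random effects to zero: Fisher coverage is only expected under
  exchangeable observations (see the pseudo-replication caveat above). The
  "≈95%" expectation is operationalised as [92%, 98%] pooled over cells,
  slightly wider than the iid band because weekly-gain × CCI cells are
  cross-clustered even under the null.
* Problem sizes in the test suite: full-scale runs (2 × 28 days × 60
  animals) use the hourly emission route; 40 seeds for sign recovery, 10
  for null coverage, 1000 replicates for Fisher-CI calibration at
  $\rho = 0.3$, $n = 100$; fixture round-trips use 2 animals × 7 days at
  full resolution. These sizes were chosen to make the Monte-Carlo bands
  sharp at interactive runtimes.

## Worked example

```{r, eval = FALSE}
library(thermoherd)

sim <- simulate_trials(sim_config(seed = 1))
an  <- herd_analysis(sim$streams)
an$groups                 # week pairs, coolest to warmest
summary(an)               # headline correlations
plot(an)                  # daytime forest plots, warmest group
write_analysis(an, "out") # CSV tables
```

Known limitations, beyond those noted above: the median-to-median distance
estimator's downward bias is documented, not corrected; canopy maps are
treated as static truth (real shade moves with sun angle); and the
correlation layer intentionally stops at bivariate associations — no
mixed-effects modelling, no causal claims.
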