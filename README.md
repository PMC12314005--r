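# thermoherd

Exposure–response analysis for collar-based grazing-cattle studies:
quantify how cattle behaviour shifts with thermal load from multimodal
sensor streams, without direct observation.

The package is written for precision-livestock researchers who have (or
want to simulate) four synchronized data streams from a grazing trial:

* **behaviour labels** — a collar classifier's 5-second ethogram calls
  (grazing, walking, ruminating, resting, drinking, other);
* **GNSS fixes** — nominal 1 Hz positions per animal;
* **weather** — 10-minute station records (temperature, humidity, wind,
  solar radiation, rain);
* **animal records** — initial weight, weekly Monday weighings, and
  genomically estimated *Bos indicus* proportion;

plus a digitised canopy map (paddock boundary and tree-canopy polygons,
GeoJSON).

## The method

Thermal load is the **Comprehensive Climate Index** (CCI; Mader, Johnson &
Gaughan 2010), an apparent temperature valid across cold- and heat-stress
ranges:

    CCI = Ta + adj_RH(Ta, RH) + adj_WS(WS) + adj_RAD(Ta, RAD)

reduced to a daily maximum per calendar date. GNSS fixes become 10-minute
median positions, classified open vs canopy against the map (shade-seeking
proxy), and chained into haversine travel distances (R = 6371 km, 0–10 km
daily plausibility filter). Behaviour labels become hourly budgets and
daily day/night time budgets (daytime 05:00–18:00 local), with weighing
days (Mondays) excluded.

Because single hot days matter less than runs of them, days from both
trials are pooled and **ranked** by daily maximum CCI (rank 1 = coldest);
weekly mean ranks order the eight trial weeks into four **paired-week
exposure groups**, coolest pair to warmest pair. Within each group and
daypart the package reports Pearson correlations with Fisher-z 95%
confidence intervals (Spearman cross-check included) between the daily
maximum CCI, behaviour hours, time in the open, distance travelled, weekly
weight gain, initial weight and *Bos indicus* proportion, plus forest
plots per anchor variable.

A deterministic **synthetic-trial generator** (`simulate_trials()`)
emulates the full five-stream study — two 4-week trials of 60 animals,
daily max CCI spanning ~36–52 — with planted, parameterised CCI effects
(shade affinity, day-to-night grazing shift, daytime resting gain), so
the entire pipeline is testable end to end without any data download.

## Worked example

```r
library(thermoherd)

sim <- simulate_trials(sim_config(seed = 1))  # two synthetic 28-day trials
an  <- herd_analysis(sim$streams)             # the full pipeline
an
summary(an)
```

```
thermal-exposure herd analysis
  2880 animal-day summaries (120 animals), 56 trial days
  daily max CCI: 38.1 to 49.5
week-pair climate-exposure groups (1 = coolest)
  group 1: weeks 1, 7 (avg day rank 16.86, 19.71)
  group 2: weeks 4, 2 (avg day rank 21.29, 29.00)
  group 3: weeks 3, 8 (avg day rank 30.57, 33.29)
  group 4: weeks 6, 5 (avg day rank 34.86, 42.43)
correlation suite: 752 cells over 4 group(s), methods: pearson, spearman
  pearson cells: 376, of which 58 have a 95% CI excluding 0
headline correlations (Pearson):
                                    quantity  value
 r(CCI, daytime time in open), warmest group -0.483
      r(CCI, daytime grazing), warmest group -0.293
        r(CCI, night grazing), warmest group  0.549
      r(CCI, daytime resting), warmest group  0.164
```

Reading the output: the 56 pooled trial days rank into four exposure
groups; in the warmest pair of weeks, hotter days see cattle spend less
daytime in the open (r = −0.48), graze less by day (−0.29) and more by
night (+0.55), and rest more by day — the planted heat-avoidance pattern,
recovered by the pipeline. `plot(an)` draws the forest plots for any
group/daypart; `write_analysis(an, "out/")` writes the correlation,
summary and group tables as CSV. Real data enters the same way through
`read_streams()` + `herd_analysis()`.

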