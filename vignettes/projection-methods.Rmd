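---
title: "Projecting ALS case numbers: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting ALS case numbers: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alscast)
```

## The model

Amyotrophic lateral sclerosis (ALS) is an adult-onset motor neuron
disease with a median survival of roughly 2–4 years and an incidence
that peaks between ages 60 and 79.  Because survival is short and ALS
incidence is empirically stable over calendar time, point prevalence in
an age/sex stratum is well approximated by the stationary relation

$$P(s, b) \;=\; \frac{I(s, b)}{100{,}000} \times N(s, b, t) \times D,$$

where $I(s,b)$ is the incidence rate (new cases per 100,000
person-years) for sex $s$ in 5-year age band $b$, $N(s,b,t)$ is the
projected population of that stratum in calendar year $t$, and $D$ is
the region's median disease duration in years.  Summing over strata
gives the expected number of people living with ALS in a region-year;
holding $I$ and $D$ fixed while $N$ ages forward isolates the
demographic component of growth in case numbers.  `project_cases()`
implements exactly this product, with no rounding anywhere in the
engine.

Three assumptions are built in and should be kept in mind:

* **Stationarity.** Incidence schedules are applied unchanged to every
  projected year, and prevalence is incidence × *median* duration (not
  mean).  Improving survival over time is out of scope and would make
  these projections underestimates.
* **Within-band closure.** A case diagnosed in band $b$ is counted in
  band $b$; ageing across a band boundary during the disease course is
  ignored.  This is what the band-wise product does, and the
  microsimulation below exists to quantify (not correct) the
  approximation.
* **Binary sex stratification.** Schedules are strictly male/female;
  combined-sex inputs are rejected rather than split, because the whole
  pipeline is sex-specific.

## Age-band harmonization

Study age bands rarely match the demographic 5-year grid (0–4, …,
95–99, 100+; bands are closed integer-year intervals, so 15–19 has
width 5 and the open 100+ band is treated as 100–104 where a width is
needed).  `harmonize()` maps a study schedule onto the grid:

* a grid band fully inside one study band inherits that band's rate;
* a partially overlapped grid band gets `rate × overlapping years / 5`,
  assuming ages are uniform within the band (so study band 18–24 at
  rate $r$ gives 15–19 the rate $2r/5$ and 20–24 the rate $r$);
* an open-ended study band (e.g. 75+) covers every older grid band
  through 100+;
* grid bands with no overlap get rate 0 — in particular ages younger
  than the youngest study band contribute no cases, which matches
  restricting the at-risk population to adults when schedules start at
  age 20.

Two switches matter:

* `overlap = "full"` carries the whole study rate into any straddled
  grid band (the study band covering most of the band wins, ties to the
  younger band).  The proportional default conserves expected case
  mass under a uniform-within-band age structure; the full-rate variant
  exists for sensitivity checks against the cruder convention.
* `extend_oldest = TRUE` carries a bounded terminal rate upward to
  100+.  Registry incidence above age 80 is plausibly under-ascertained,
  so the default (rate 0 above a bounded oldest band) is conservative;
  the switch quantifies the other extreme.

## Pooling and global extrapolation

Where several studies represent one continent, `pool_schedules()`
combines them as a convex mixture weighted by study catchment
population: $w_i = \text{pop}_i / \sum_j \text{pop}_j$, pooled band
rate $\sum_i w_i r_i(b)$, pooled duration $\sum_i w_i D_i$ (the same
weights for incidence and duration).  Consequences used as tests:
every pooled rate lies between the component extremes, and rescaling
all catchments by a constant changes nothing.  "Catchment population"
(the persons covered by the study) is used as the weight rather than
person-years of observation, which published studies report too
inconsistently to use.

`extrapolate_global()` applies one rate source per continent — a single
study region's schedule or a pool — to continent-level pyramids and
sums to world totals.  The bundled default tables
(`default_continent_table()`) use the standard mapping: United States →
North America, Uruguay → South America, Libya → Africa, New Zealand →
Oceania, the EU28 pooled schedule alone → Europe, and Asia pooled from
China, Japan, Taiwan and Iran.  Serbia is carried in the ten-region
analysis but deliberately excluded from the Europe extrapolation (the
EU28 pooled analysis already represents the continent); Central America
and the Caribbean ride with North America.  Both choices live in
user-editable CSVs, not code.

## Rounding and reporting

All computation is unrounded; only the report layer rounds, half away
from zero (`round_half_away()`), to integer cases and integer percents.
This is why the bundled published reference table's per-cell sums can
differ from its reported totals by a couple of cases — a pure display
artifact that the engine must not inherit, and the reason the
machine-readable outputs (`cases.csv`, `summary.json`) carry full
precision while `case_table.txt` carries the human formatting.

Reports embed provenance: MD5 digests of every input, the engine
switches and their hash, the package version, and the population data
vintage.  Vintage is known only when pyramids come through the
`fetch_idb()` cache (each cached payload records URL, timestamp and
vintage); plain CSV inputs report `"unknown"`.  Census International
Data Base vintages are revised, so two runs against different vintages
legitimately differ — the vintage line is how a reader tells.

## The synthetic world

`generate_world()` draws, deterministically under one integer seed,
everything the pipeline consumes, with the structure the analysis
assumes:

* **Pyramids** for a baseline and a horizon epoch.  Baseline band
  weights decay exponentially with age (scale drawn per region from
  25–45 years); the horizon tilts weights by
  $\exp(\text{ageing index} \times a_i \times \text{age}/100)$ and
  grows totals by $1 + \text{ageing index} \times g_i$, so an ageing
  index of 0 yields an exactly stationary world and any positive index
  yields horizon pyramids with median age at least the baseline's.
  Region totals are lognormal around 50 million (σ = 0.5 on the log
  scale); the female share rises gently with age.
* **Incidence schedules** on 5-year study bands from age 20 with an
  open 80+ band: a plateau at the peak rate over ages 60–79 with
  exponential decay per decade on both sides, a region level factor
  (U(0.6, 1.4)) and sex factors giving a male:female ratio of about
  1.4.  The default peak of 6 per 100,000 person-years is the order
  observed at the ALS incidence peak.
* **Durations** uniform on 2–4 years (the ALS median-survival range)
  and **catchments** a uniform fraction (0.05–1) of the region
  population, so pooling weights are non-trivial.

Alongside the data the generator returns closed-form expected case
counts computed by direct band-wise arithmetic that never touches
`harmonize()` or `project_cases()`.  Recovery tests require the
pipeline to match this embedded truth to 1e-9 relative — a strong
end-to-end check on I/O, harmonization and projection together.

What the generator does **not** emulate: cohort and period effects in
incidence, migration, diagnostic ascertainment differences between
registries (the ALS vs broader motor-neuron-disease case definitions
are carried as metadata but do not alter synthetic rates), correlation
between ageing and incidence, or time-varying survival.  Passing
recovery tests therefore demonstrates that the software computes its
model correctly, not that the model captures every feature of real
surveillance data.

## The illness–death microsimulation

`microsim_prevalence()` is an independent stochastic oracle for the
product approximation.  Per grid band, onsets arise as a Poisson
process with intensity $\lambda = I/10^5 \times N$ per year in a
stationary regime; each case persists for a duration and point
prevalence is counted at a census instant.  Two duration laws:

* **fixed at the median** (default): every onset within the last $D$
  years is alive at census, so band occupancy is exactly
  Poisson($\lambda D$) — the distributional sharpening of $I \times D$.
  This is the default because the projection multiplies by the median.
* **exponential with that median**: rate $\log 2 / D$, simulated over
  an onset window of $12\times$ the mean (residual survivor mass below
  1e-5; a truncation, not an approximation worth refining at these
  Monte-Carlo errors).  Mean duration is then $D/\log 2 \approx 1.44 D$,
  and simulated prevalence rises by the same factor — a concrete
  demonstration that for skewed duration distributions the
  median-based product understates prevalence.

Tests require the simulation mean to bracket $I \times D$ within 3
Monte-Carlo standard errors across five seeded scenarios at 200
replicates each, and to double when duration doubles.

## Numerical choices and degenerate inputs

* Bands are closed integer intervals; overlap fractions count integer
  years of age, so a "2/5 of the band" statement is exact, not a
  floating-point convention.
* Zero-rate and zero-population strata are valid and produce zero
  cases; an entirely empty pyramid is a domain error for median age.
* `percent_change()` requires a strictly positive baseline; shares are
  computed from unrounded totals and must sum to 1 within 1e-9 per
  year.
* Every malformed input raises a typed condition
  (`alscast_format_error`, `alscast_validation_error`,
  `alscast_config_error`, `alscast_domain_error`,
  `alscast_retrieval_error`); nothing is silently repaired, including
  missing pyramid bands, overlapping study bands and combined-sex rows.
* Pearson's correlation (`ageing_correlation()`) demands at least three
  regions and non-zero variance on both axes.

## Problem sizes

The shipped test suite and acceptance script run entirely from
generated or bundled plain-text inputs: synthetic worlds of 3–6 regions
(42 strata per region-year), five microsimulation scenarios at 200
replicates, and the ten-region published reference table.  These sizes
were chosen to exercise every code path — misaligned bands, open bands,
pooling with unequal weights, both epochs — while keeping a full run in
the order of seconds; the generator scales to larger worlds by changing
`n_regions` alone.

## Known limitations

* No uncertainty intervals: the method propagates none, and inventing
  them would misrepresent it.
* Constant incidence and duration across calendar time; improving
  survival would raise prevalence beyond these projections.
* The stationary product ignores within-duration ageing across band
  boundaries; the microsimulation quantifies the (small, at ALS
  durations) discrepancy rather than correcting it.
* Case-definition heterogeneity between source studies (ALS vs broader
  motor neuron disease) is surfaced as metadata, not adjusted for.
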