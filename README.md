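# alscast

Projection of amyotrophic lateral sclerosis (ALS) case numbers from
age/sex-specific incidence, population structure and median disease
duration.

## The problem

ALS is rare but fatal, with median survival of 2–4 years and incidence
peaking at ages 60–79.  As populations age, the number of people
living with ALS grows even where incidence is flat — and the growth is
fastest in developing countries, whose age pyramids are shifting most.
Health-system planners need expected case counts by region, year and
sex; epidemiologists need the machinery to be reproducible and
auditable.  `alscast` provides that machinery as a tested R pipeline.

## The model

Under stationarity, point prevalence in an age/sex stratum is
incidence × median duration, so the expected case count for sex *s* in
5-year age band *b* of a region in year *t* is

    cases(s, b, t) = I(s, b) / 100,000 × N(s, b, t) × D

with `I` the incidence rate (per 100,000 person-years), `N` the
projected stratum population and `D` the region's median disease
duration in years.  Around this product the package supplies:

* **I/O** for incidence schedules, duration tables and International
  Data Base (IDB) style population pyramids, with strict validation
  and exact round-trips (`read_incidence_table()`, `read_idb_csv()`,
  `fetch_idb()` with an offline-replayable cache);
* **harmonization** of arbitrary study age bands onto the 5-year grid,
  prorating straddled bands by integer years of age (`harmonize()`);
* **projection and analytics**: `project_cases()`,
  `aggregate_cases()` (continent / developed-vs-developing rollups
  with shares), `percent_change()`, `median_population_age()`,
  `ageing_correlation()`;
* **pooling and global extrapolation**: study-size-weighted convex
  pooling of schedules to continents (`pool_schedules()`) and world
  totals (`extrapolate_global()`), with the standard rate-source
  assignment shipped as editable CSVs;
* **a synthetic-world generator** with embedded closed-form truth and
  an **illness–death microsimulation** oracle
  (`generate_world()`, `microsim_prevalence()`);
* **report commands** (`cmd_project()`, `cmd_global()`, `cmd_synth()`,
  `cmd_validate()`) writing full-precision machine output plus rounded
  human tables, with provenance (input digests, data vintage, config
  hash); `scripts/alscast` wraps them for the shell.

See `vignettes/projection-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

The package bundles published reference estimates of projected ALS
cases for ten study regions in 2015 and 2040, plus the matching
continent and development classification:

```r
library(alscast)
tab <- reference_case_table()
dev <- aggregate_cases(tab, reference_hierarchy(), by = "development")
dev
#>       group year cases     share
#>   developed 2015 57174 0.7132485
#>  developing 2015 22986 0.2867515
#>   developed 2040 71152 0.6731823
#>  developing 2040 34543 0.3268177

pc <- percent_change(dev$cases[dev$year == 2015],
                     dev$cases[dev$year == 2040])
setNames(round_half_away(pc), dev$group[dev$year == 2015])
#>  developed developing
#>         24         50
```

Developed countries hold 71% of cases in 2015, falling to 67% by 2040;
over the same horizon their case load grows 24% while the developing
group's grows 50% — the burden is shifting toward developing
countries, driven by population ageing.  From the reported world
totals:

```r
glob <- subset(reference_totals(), scope == "global")
round_half_away(percent_change(glob$cases[1], glob$cases[2]))
#> [1] 69
```

A fully synthetic end-to-end run (every input generated, truth known
in closed form):

```r
w <- generate_world(synthetic_world_spec(n_regions = 3, seed = 42))
head(w$truth, 4)
#>     region year    sex    cases
#> 1 region01 2015   male 1515.817
#> 2 region01 2040   male 2226.559
#> 3 region01 2015 female 1239.301
#> 4 region01 2040 female 1831.189
```

or from the shell:

```sh
Rscript scripts/alscast synth --seed 3 --out-dir world
Rscript scripts/alscast project --incidence world/incidence.csv \
    --durations world/durations.csv --population world/population.csv \
    --hierarchy world/hierarchy.csv --out-dir out
cat out/case_table.txt
```

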