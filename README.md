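# feasquery

Count-only cohort **feasibility queries** over FHIR R4 data, at desk
scale. Before a multi-center study starts, researchers ask each hospital:
*how many of your patients satisfy this criteria combination?* Only an
obfuscated count ever leaves a site. feasquery implements the full query
path of such a platform as an R package: the query model, both
translations a hospital FHIR server may need, a local FHIR Search
evaluator, set-algebra result combination, privacy obfuscation, a
pull-based multi-site broker simulation, and a deterministic generator for
benchmark data sets with exactly predictable answers.

It is aimed at clinical research informaticians who want to study, test,
or extend feasibility-query semantics without standing up FHIR servers and
middleware.

## The model

A Structured Query holds inclusion criteria in conjunctive normal form and
exclusion criteria in disjunctive normal form. A patient matches iff

```
(AND over inclusion groups: OR within group)  AND NOT  (OR over exclusion groups: AND within group)
```

Each criterion is a term code `(system, code)` — e.g. an ICD-10-GM
diagnosis — expanded through a terminology tree to all its subtypes, and
optionally restricted by a value filter (coded value, quantity comparator
`gt/ge/lt/le/eq`, or quantity range, with UCUM units) and a calendar-date
window. The query translates two ways:

* **FHIR Search**: one bundle of atomic searches per criterion
  (`Condition?code=sys|E11,sys|E11.0,...`), recombined by set algebra over
  patient IDs — union within groups and bundles, intersection across
  inclusion groups, set difference for exclusions;
* **CQL**: a single library text with one `define` per criterion and an
  `InInitialPopulation` combining them (text generation only; the boolean
  skeleton is verified equivalent to the reference semantics by
  truth-table enumeration).

Counts are obfuscated by rounding to the nearest 10 before they leave a
site; zero stays zero.

## Worked example

Generate the `small` benchmark data set at 1/100 scale — three planted
cohorts whose members each carry one matching Condition, Procedure and
Observation plus a cohort-specific gender — and run the four-criterion AND
query of the 100,000 cohort:

```r
library(feasquery)
profile <- dataset_profile("small", scale = 1/100)
ds <- generate_dataset(profile, seed = 7)
ds
#> <benchmark data set> profile 'small', scale 0.01, 3 cohort(s)
#> <FHIR resource store>
#>   Patient      1,110
#>   Condition    1,110
#>   Procedure    1,110
#>   Observation  1,110
#>   Total        4,440

qs <- benchmark_queries(profile)
plan_urls(build_plan(qs[["100000-all"]], ds$tree, ds$mapping))
#> Patient?gender=female
#> Condition?code=http%3A%2F%2Ffhir.de%2FCodeSystem%2Fbfarm%2Ficd-10-gm|C50.1
#> Procedure?code=http%3A%2F%2Ffhir.de%2FCodeSystem%2Fbfarm%2Fops|5-787
#> Observation?code=http%3A%2F%2Floinc.org|55782-7

res <- count_query(qs[["100000-all"]], ds$store, ds$tree, ds$mapping)
res
#> <execution result> 1,000 patient(s), 4,000 resource(s) processed
```

The cohort planted with 100,000 patients at full scale holds 1,000 at
scale 1/100; the AND of its four criteria returns exactly those 1,000
patients, touching 4 resources per patient (no short-circuiting — the
worst-case accounting is deterministic). Broadcasting the same query to a
two-site network returns only obfuscated per-site counts and their total:

```r
sites <- list(feas_site("uk-a", ds$store, ds$tree, ds$mapping),
              feas_site("uk-b", generate_dataset(profile, seed = 8)$store,
                        ds$tree, ds$mapping))
env <- query_envelope(qs[["100000-all"]], ds$tree, ds$mapping)
summarize_results(broadcast(env, sites, timeout = 300))
#> <feasibility report>
#>   uk-a         ok       1000
#>   uk-b         ok       1000
#>   total: 2000
```

A thin command-line wrapper over the same functions ships at
`inst/cli/feasquery.R` (`gen | translate | run` subcommands; JSON on
stdout, logs on stderr, exit codes 0/1/2).

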