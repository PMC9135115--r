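---
title: "Feasibility queries over FHIR: model, translation, and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feasibility queries over FHIR: model, translation, and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feasquery)
```

## The problem

Before a clinical study starts, researchers need to know whether enough
eligible patients exist across the hospitals of a research network. A
*feasibility query* asks exactly that: given a combination of inclusion and
exclusion criteria — diagnoses, procedures, laboratory values, demographic
attributes — how many patients at each site satisfy it? Only a count ever
leaves a hospital, never patient-level data.

feasquery implements a desk-scale version of such a platform for FHIR R4
data: a formal query model, translation of a query into the two query
languages a hospital FHIR server may speak (FHIR Search and CQL), a local
FHIR Search evaluator, set-algebra recombination of partial results, count
obfuscation, a pull-based broker simulation, and a synthetic-data generator
that produces benchmark data sets with exactly predictable answers.

## The query model

A Structured Query has inclusion criteria in **conjunctive normal form**
(an AND over groups, OR within a group) and exclusion criteria in
**disjunctive normal form** (an OR over groups, AND within a group). A
patient matches iff

$$
\Big(\bigwedge_{g \in \text{incl}} \bigvee_{c \in g} \text{sat}(c)\Big)
\;\wedge\;
\neg \Big(\bigvee_{g \in \text{excl}} \bigwedge_{c \in g} \text{sat}(c)\Big).
$$

CNF for inclusion and DNF for exclusion mirror how criteria lists are built
in practice: researchers stack required criteria (AND) with alternatives
inside each (OR), and enumerate disqualifying combinations. Each criterion
is a term code — a `(code system, code)` pair such as an ICD-10-GM
diagnosis — optionally restricted by a value filter (coded value, quantity
comparator, or quantity range with UCUM units) and a calendar-date window.
Two deliberate restrictions:

* Comparators are `gt, ge, lt, le, eq` only. A `ne`/NOT criterion is not
  offered because FHIR Search cannot express "patients *without* code X"
  efficiently (a `:not` search returns everything else); negation enters
  only through the exclusion side of the query, which is evaluated as a set
  difference over patient IDs.
* Parsing is strict: unknown JSON fields anywhere in a document are
  rejected with the offending path. A silently ignored restriction would
  *inflate* cohort counts, which is the worst failure mode for feasibility.

`evaluate_reference()` evaluates the contract per patient from precomputed
truth assignments. It is deliberately naive — no set algebra, no store —
and serves as the oracle the executor is tested against.

## Terminology expansion and mapping

Researchers select concepts in a hierarchy; selecting *Diabetes mellitus,
Type 2* (ICD-10 `E11`) must find patients coded with any subtype
(`E11.0` … `E11.9`) as well as at the parent itself — real data is coded at
both levels, so `expand_code()` returns the code *plus* all descendants in
depth-first pre-order. A code absent from the tree expands to itself alone:
the tree adds subtypes, it does not gate which codes may be queried.

The mapping file carries, per concept, the FHIR resource type and the
search parameters for code, value, and date. A missing mapping entry is a
hard error at translation time (never a dropped criterion). Patient-level
concepts such as administrative gender have no code parameter; they are
addressed purely through their value parameter (`Patient?gender=female`).

## The two translation paths

**FHIR Search.** FHIR Search cannot express a multi-criterion feasibility
query in one request, so `build_plan()` mirrors the query into bundles of
atomic searches — one bundle per criterion, several searches per bundle
when the expanded code list exceeds `chunk_size` (default 200 codes per
URL, a URL-length safety margin; results of chunks are unioned, so the
choice is semantically invisible and is verified to be). The executor
unions patient-ID sets within groups, intersects across inclusion groups,
and subtracts the union of exclusion-group intersections. All atomic
queries are always executed — no short-circuiting — so the
`resourcesProcessed` accounting (the sum of result-set sizes over all
atomic searches) is deterministic and reflects the worst case.

Token values are rendered system-qualified (`system|code`) to avoid
cross-system code collisions; the single exception is the administrative
gender value, rendered bare (`gender=female`) following the universal FHIR
convention for that parameter. Atomic pieces of values are percent-encoded;
the structural separators `| , & = ?` are literal, so every rendered URL
parses back losslessly.

**CQL.** A whole query fits into a single CQL library: one retrieve-based
`define` per criterion and one `InInitialPopulation` define combining them
with `and`/`or`/`not`. Only text generation is implemented; execution
belongs to a CQL-capable server, which this package does not ship. The
generated boolean skeleton is instead verified against the reference
evaluator by truth-table enumeration — the two translation paths are thus
held to the same semantic contract even though only one is executable here.

## The local FHIR store

`resource_store()` holds the four resource types of the benchmark design
(Patient, Condition, Procedure, Observation) column-oriented, one row per
coding, and evaluates the exact FHIR Search subset the translator emits:
token parameters with comma-OR, quantity prefixes `gt/ge/lt/le/eq`, and
date prefixes `ge/le`. Numerical choices, chosen for determinism:

* Dates compare at day precision; both bounds inclusive.
* Quantity `eq` is exact decimal equality, a documented divergence from
  FHIR's significant-figure rules; unit and unit-system must match when the
  token carries them.
* Unsupported parameters raise an error naming the parameter. Condition
  dates are searched via `recorded-date`.

## Privacy by aggregation

A site returns its count rounded to the nearest 10 (`obfuscate()`); zero is
returned as zero. Ties round up — half-away-from-zero, fixed so the
operation is deterministic and monotone. Counts 1–4 consequently round to
0; this small-count behaviour is a disclosure trade-off, accepted because a
floor would distort small sites' contributions more than it protects them.
The broadcast layer guarantees the exact count never crosses the site
boundary: only the obfuscated value is placed in a site result, and the
single-site command-line path withholds `resourcesProcessed` unless an
explicit `--exact` debug flag is set (for a single-criterion query it would
equal the exact count).

## The broker simulation

`broadcast()` models a pull transport: the broker parks an envelope holding
*both* representations (Structured Query JSON and CQL text) and each site
pulls, executes through its configured path, and answers with an obfuscated
count — so no hospital needs to accept inbound connections. The simulation
is in-process; the envelope/result interface is the contract a real
transport would implement. Site failures are isolated, results are ordered
by site id and idempotent per query, and a total over sites is flagged as a
lower bound whenever any site timed out or errored. The `cql` execution
path is rejected at configuration time (no engine ships); this keeps the
envelope contract honest without pretending to execute CQL.

## The synthetic benchmark data sets

The generator plants cohorts of exact sizes: each member of a cohort
carries the cohort's patient-level attribute plus exactly one matching
Condition, Procedure, and Observation, and nothing that matches any other
cohort's criteria. The built-in profiles:

| profile  | cohorts                          | background | total resources |
|----------|----------------------------------|------------|-----------------|
| small    | 1,000 / 10,000 / 100,000         | none       | 444,000         |
| bg-small | same                             | yes        | 6,035,480       |
| bg-large | + 1,000,000                      | yes        | 10,035,480      |

The background component — 413,375 conditions over 8,593 unique codes,
270,505 procedures over 6,429, and 4,907,600 observations over 1,798 —
emulates a hospital-scale server load without matching any benchmark
query. Design choices where the design was genuinely open:

* **Patient-level criterion.** Administrative gender, one distinct value
  per cohort, with `female` fixed to the 100,000 cohort (whose criterion
  combination is female + ICD-10 `C50.1` + OPS `5-787` + LOINC `55782-7`).
  Distinctness makes the patient criterion match exactly its cohort, which
  the 4-resources-per-patient accounting of the `-all` queries requires.
  Only four gender values exist, so with more than four cohorts the
  generator switches every cohort to a distinct birth-year range instead.
* **Background distribution.** Resources are spread over the unique codes
  and over patients round-robin (sizes as equal as possible). Only totals
  and unique-code counts are fixed by the design; the real hospital code
  frequency distribution is not available, and the balanced assignment
  reproduces every fixed count deterministically.
* **Background dates and values** are uniform over a fixed five-year
  window (2019–2023) and (0, 100] `mg/dL` respectively, drawn from the
  seeded RNG — present only so date and value filters have something to
  bite on. Everything else in generation is RNG-free, so
  `benchmark_queries()` works from the profile alone.
* **Scaling.** A `scale` factor shrinks every cohort and background
  resource count proportionally (each scaled count must stay an integer;
  unique-code counts are left unscaled). Labels keep the unscaled sizes, so
  the query labeled `1000-1` returns 1 patient at scale 1/1000. The test
  suite runs mostly at scales 1/100–1/1000 and exercises the full-scale
  `small` and `bg-small` profiles once each to confirm the realized counts.

The no-match benchmark query uses codes absent from all data and a
birth-year window (1900) predating every generated patient, so it returns
0 patients after processing 0 resources regardless of profile.

### What the generator does and does not emulate

Planted cohorts make correctness exactly checkable: every benchmark query
has a provable answer, and the executor is additionally verified against a
brute-force per-patient oracle on hundreds of randomized store/query
instances. What the synthetic data does *not* have: realistic code
co-occurrence, multi-coded resources at scale, missing or malformed fields,
multiple resources per patient per planted criterion, or clinical
plausibility of values. Passing tests therefore demonstrate the query
semantics and accounting, not robustness to the messiness of real hospital
FHIR exports.

## Degenerate inputs and edge cases

Empty exclusion lists are valid (pure CNF); empty inclusion lists are not.
An empty resource store is valid and yields zero counts. Criteria whose
term codes map to different resource types are rejected. Duplicate codes
across a criterion's expansions are deduplicated before chunking, keeping
first occurrence. Equality of queries ignores display strings everywhere.

## Known limitations

* FHIR Search support is the emitted subset only — no `_has`, chaining,
  `:not` modifiers, paging, or `_count`.
* CQL is generated, never executed or compiled to ELM.
* Patients are identified by resource id; no cross-site record linkage.
* Only four resource types; the store performs no FHIR profile validation.
* Wall-clock performance of a real server is out of scope; the benchmark
  data sets reproduce counts and query-load structure, not timings.
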