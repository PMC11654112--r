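---
title: "Redistributing garbage-coded external-cause deaths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redistributing garbage-coded external-cause deaths: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcredist)
```

## The problem

Death registries code the underlying cause of each death to ICD-10, but a
substantial share of external-cause certificates carry *garbage codes* —
codes too unspecific (or implausible) to serve as a true underlying cause,
such as "event of undetermined intent" (Y34) or "accidental exposure to
unspecified factor" (X59). Counting only well-specified causes undercounts
homicides, suicides, falls and transport injuries, and does so unevenly
across regions and over time, distorting both levels and trends of violence
statistics.

`gcredist` implements a transparent correction pipeline for registry
microdata: every death keeps its identity as a (possibly fractional-weight)
record, and four stages transform raw records into corrected, comparable
counts:

1. **Cause mapping.** Every ICD-10 code is classified into one of six
   external target subgroups (transport injuries, falls, suicides,
   homicides, other transport, other external), a pneumonia target, one of
   three garbage classes, an excluded class, or out-of-universe.
2. **Missing-demographics redistribution.** Records lacking sex, age or
   year are split into fractional copies over the observed distribution of
   the missing field among complete records in the same stratum.
3. **Garbage redistribution.** Each garbage record's weight is split across
   target causes by one of two criteria (below).
4. **Under-registration correction.** Weights are inflated by externally
   supplied completeness factors per state/sex/age stratum.

Directly age-standardized rates per 100,000, loess trends, percent
variations, corrected-to-registered rate ratios and state rankings summarise
the results.

## The cause taxonomy

The shipped cause map reproduces the published range lists for the six
target subgroups, the small group of natural codes (radiation/sunlight
injuries, L55x/L56x/L58x) counted as other external causes, the
external-garbage naturals G443/G913/R58, the exclusions (alcohol and other
chronic-poisoning codes X45/X65/Y15 reclassified as noncommunicable disease,
and neonatal pulmonary aspiration W75–W84 subsets), and the
investigation-criterion garbage X59/Y34. Any remaining chapter-XX code
(V010–Y899) is residual garbage redistributed proportionally; codes outside
chapter XX are out of the study universe unless listed (pneumonia J12–J18,
septicemia A40–A41, ill-defined R00–R99).

Design choices a user should know:

* **Granularity.** Classification happens at the 4-character level; a
  3-character record code inherits the class of its unspecified (".9")
  child. This matches registries that mix coding granularities. Range
  endpoints are inclusive; where ranges nest, the narrowest wins (so R58
  stays external garbage inside the ill-defined R00–R99 block), and partial
  overlaps with conflicting categories are a configuration error.
* **The V89 block.** The published transport list names "V89" with no
  fourth digit; the shipped map reads it as the whole block V890–V899,
  which is registry practice for unspecified-vehicle deaths. Users who
  prefer the literal single-code reading can edit one row of the config
  CSV.
* **Literal list reading.** Isolated entries such as "W97.9" are mapped
  exactly as printed (the single code W979), not silently widened into
  ranges; the neighbouring codes then fall to residual garbage, which is
  the conservative reading.
* **Unspecified transport garbage** is pre-assigned to the transport-injury
  target at the mapping stage rather than carried as a garbage class,
  because it can only be redistributed within transport injuries and the
  package does not estimate vehicle-type detail.

## The two weighting criteria

For a garbage stratum with total weight $m$, redistribution assigns weight
$m \cdot w_c$ to target cause $c$, with $\sum_c w_c = 1$.

**Proportional criterion.** $w_c$ is cause $c$'s share of target-cause
deaths in the narrowest non-empty stratum (state, year, sex, age group by
default; municipality can be added). When a stratum holds no target deaths
the pool coarsens stepwise — drop age, then sex, then state, then year — a
declared convention, since registry practice varies. This criterion assumes
garbage arises from true causes *at random within the stratum*; it is exact
(unbiased) when the chance a death's code degrades into garbage does not
depend on its true cause.

**Investigated-death criterion.** $w_c$ comes from a reclassification table:
the empirical fractions observed when field investigation replaced a
garbage code with a specific cause. Destinations may include natural causes
(`NATURAL_RESIDUAL`, deaths leaving the external universe). The shipped
table is a clearly-labelled synthetic stand-in with plausible magnitudes
(including the literature's figure that roughly 39% of undetermined-intent
deaths are homicides); users analysing real data must supply their own
fractions.

The default policy mirrors the study design: X59/Y34, the pneumonia class
and natural garbage use investigation fractions; all other external garbage
is proportional. `choose_criterion()` reports the diagnostics that inform
this choice — class size and the total-variation distance between the two
candidate plans.

Two structural decisions:

* **Frozen targets.** All plans are computed on the target distribution
  *before* any garbage is added, in a single pass. An iterative scheme
  (letting redistributed weight update subsequent plans) would make results
  depend on processing order; the frozen single pass is order-independent
  and reproducible.
* **Pneumonia.** Pneumonia-coded deaths are both a source (their
  investigation fractions send part of their weight to external causes)
  and a destination (the residual fraction remains pneumonia, which is kept
  as a target because investigation leaves a considerable share in place).
  When the reclassification table carries no pneumonia rows the class
  passes through untouched.
* **Natural garbage (septicemia, ill-defined).** The published method cites
  empirical migration from these codes into external causes but not its
  criterion; the package uses reclassification rows when present (the
  shipped default, with a dominant `NATURAL_RESIDUAL` share so only the
  external sliver enters this universe) and errors towards an explicit
  choice otherwise.

## Missing-demographics redistribution

Fields are completed in the order sex, age group, year, each by fractional
splitting over the weight-weighted distribution of complete records in the
narrowest non-empty stratum; records missing several fields are split
sequentially on the successive marginals. The stratum conditions on
location, year *and cause category* by default — the published description
conditions only on place and year, but conditioning on cause prevents, say,
garbage deaths borrowing the age structure of transport injuries; the flag
`condition_on_cause = FALSE` restores the literal reading. Fractional
(deterministic) weights were chosen over stochastic integer allocation for
exact reproducibility; rounding to integers is a report-time concern only.
The operation conserves total weight to numerical precision and is
idempotent.

## Rates, trends, ratios, ranks

* **Standardization** is direct: $\text{rate} = \sum_a (d_a/n_a)\, w_a
  \times 10^5$ with $w_a$ the standard population's age shares. The
  standard defaults to the first year of the series (2010 in the study
  design), by age only; sex-specific standardization is available by
  grouping. Deaths in an age bin with no population are an error, not a
  silent zero.
* **Loess trends** use span 0.75, local degree 1, tricube weights, no
  robustness iterations, evaluated exactly (`surface = "direct"`). The
  published analysis names loess without parameters; these are the
  conventional defaults and are exposed as arguments.
* **Percent variation** is $100 (r_{end} - r_{start})/r_{start}$;
  the **rate ratio** is $r = \text{corrected}/\text{registered}$. Both are
  computed unrounded and reported with half-away-from-zero rounding (one
  decimal for rates and variations, two for ratios), matching the apparent
  convention of the published tables.
* **Rankings** are descending by rate with alphabetical tie-break on the
  state code; rank deltas between two methods sum to zero by construction.

## The synthetic registry generator

`scenario_config()` / `simulate_deaths()` emulate the structure the method
assumes: within each (state, year) stratum, deaths draw a true cause from a
six-cause mixture, then with probability $g$ the code is overwritten by a
garbage code; sex/age can be masked and records thinned by an
under-registration factor. The generator's defaults define the validation
conditions used throughout the test suite: all 27 states, 2,000 deaths per
stratum, a 20% garbage fraction, and a cause mixture dominated by homicides
and transport injuries — magnitudes a vital-statistics analyst would
recognise for Brazilian external-cause data, fixed once and not tuned.

Two relabeling regimes matter:

* **Cause-independent** ($g$ scalar): proportional redistribution is
  unbiased, and the suite's Monte-Carlo check (200 replicates) verifies
  per-cause recovery within two standard errors.
* **Cause-conditional** ($g$ per cause, e.g. concentrated on homicides):
  proportional redistribution is provably biased *against* the
  over-contaminated cause — it receives back only its share of the
  surviving distribution, which its own losses depressed. The suite asserts
  this sign, and shows that the investigated-death criterion with the
  scenario's true Bayes fractions ($P(\text{cause} \mid \text{garbage})
  \propto g_c \pi_c$, from `true_reclass_fractions()`) removes the bias.
  This is precisely why the investigation criterion exists.

What the generator does **not** emulate: realistic Brazilian demography
(populations are uniform across strata), spatial correlation, secular
trends, municipality structure, or code-specific garbage palettes per
cause. Passing tests therefore demonstrate the *algorithmic* correctness
and statistical behaviour of the estimator under its stated assumptions,
not the accuracy of any particular reclassification table on real data —
the shipped fractions are synthetic stand-ins.

## Numerical conventions and degenerate inputs

* Weight conservation is asserted at $10^{-9}$ relative through every
  stage before correction; the under-registration stage is the only one
  allowed to change total mass.
* Plans are validated before any record is mutated: a garbage class
  present in the data without a computable plan aborts the run.
* Empty strata fall back as described; a field with *no* complete records
  anywhere, a zero starting rate (percent variation), a zero registered
  rate (ratio), a missing state in a ranking, and a degenerate all-zero
  cause mixture are all explicit errors or flagged `NA`s, never silent.
* Problem sizes in the validation suite — $10^4$-record property fixtures,
  $\le 100$-record brute-force oracle comparisons, and the Monte-Carlo
  design above — were chosen as the smallest sizes at which the checked
  statistics are stable.

## Worked example

```{r example, eval = FALSE}
library(gcredist)

map <- build_cause_map()
cfg <- scenario_config(p_missing_sex = 0.03, p_missing_age = 0.03)
sim <- simulate_deaths(cfg, seed = 42)

bundle <- compare_methods(
  sim$records, sim$population, map = map,
  reclass = read_reclass_table(system.file(
    "extdata", "reclass_fractions_synthetic.csv", package = "gcredist")),
  factors = read_correction_factors(system.file(
    "extdata", "correction_factors_synthetic.csv", package = "gcredist"))
)
bundle$corrected$audit
bundle$ratios
```

## Known limitations

* The reclassification fractions and completeness factors are inputs, not
  estimates; the package deliberately contains no machinery to derive them
  from dual-coded investigation data.
* Municipality-level strata are supported in the schema but the fallback
  chain beyond state level is a convention, not an empirical finding.
* Multiple-cause (line A–D) certificate processing, ICD-9/11, and
  cause–age coherence checks are out of scope.
* The two pipeline arms share the proportional engine; differences between
  them isolate the treatment of X59/Y34, pneumonia-class and natural
  garbage plus the completeness correction, which is what the comparison
  tables are designed to show.
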