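---
title: "Methods: harmonizing and unifying food composition databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing and unifying food composition databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdbkit)
```

## The problem

National food composition tables and databases (FCT/FCDB) report the
content of energy, nutrients and bioactive compounds per 100 g (or 100 mL)
of edible food. No single national table is complete: components are
missing, foods differ across countries, and the same nutrient is reported
under different names, units and zero conventions. Building a usable
cross-country database therefore means (i) harmonizing every source to a
common component vocabulary, unit system and food coding scheme, (ii)
unifying the foods that several sources describe, (iii) validating the
result, and (iv) supporting downstream recipe computation. fcdbkit
implements that pipeline as composable functions plus a thin command-line
wrapper (`inst/cli/fcdb.R`).

## Harmonization model

**Component vocabulary.** Every measured quantity resolves to exactly one
entry of a *component registry*: an INFOODS-style tagname (e.g. `PROCNT`,
`VITC`, `NA` for sodium) with a standard unit from the closed set
{g, mg, ug, kcal, kJ} and a component class (proximate, energy, mineral,
vitamin, fatty_acid, sterol, polyphenol, other). Individual polyphenols
mostly lack standard tagnames; they carry compiler-assigned tags (prefix
`PP_`), flagged as such in the registry. Re-registering an identical
definition is a no-op; the same tagname with a different unit is a hard
conflict.

**Units.** Mass conversions are exact powers of ten. Plain floating-point
multiplication by `10^k` is *not* exactly invertible (and is not even
injective across binades), so `convert_value()` shifts the decimal
exponent of the value's 15-significant-digit representation instead. For
any value that entered the system as decimal text — which is every value
read from a delimited source table — this is an exact decimal operation
and the g/mg/ug round trip is bit-for-bit. Energy converts with
1 kcal = 4.184 kJ (thermochemical calorie, stated once in the factor
configuration so it is auditable). The per-100 g and per-100 mL bases are
never interconverted: that would require a density model no source
provides, so foods unify only within their own basis.

**Food coding.** Foods are keyed by their FoodEx2 classification code,
treated as an opaque validated token (letter + 4 alphanumerics,
case-insensitive). No catalogue download is required or attempted. Rows
whose code does not parse are rejected to the ingestion log with a reason
— the unifier cannot key them — and never silently dropped.

**Zeros.** A literal `0` in a source table is ambiguous: it may be a true
absence (fiber in oil — a *logical zero*) or a missing value miscoded as
zero. Each source mapping declares its convention (`zero_is_logical`).
Both kinds are removed from the unification pool, because a
missing-coded-as-zero would drag the consensus down; logical zeros are
additionally reinstated as a chosen value of 0 when *no* source measured
the component, so true absences survive unification. `trace` amounts
compute as 0 but keep their distinct status in storage.

**Exclusions.** Branded products, fortified foods, dietary supplements and
recipes/prepared dishes are excluded from database construction (their
composition is country- and product-specific); cooked foods and generic
unbranded processed foods are kept. Unknown classes are kept and logged.
Kept + excluded always partitions the input.

## Unification model

Harmonized records are grouped by (FoodEx2 code, basis). For each
component, the pool of contributing values (post zero-cleaning, all in the
standard unit) yields `n`, mean, sample SD (n−1 denominator, 0 when
n = 1), and the sample median — the midpoint of the central pair when n is
even. **The median is the chosen value**: across heterogeneous national
sources the empirical distribution of a component routinely contains one
discordant value (different analytical method, different cultivar, a
unit slip in the original compilation), and the median is robust to
exactly that contamination while the mean is not. The mean and SD are kept
as diagnostics, and full contributor provenance (source, verbatim original
food id, original value and unit) is attached to every unified value.

Chosen values are rounded half-up, deterministically: proximates and
energy to 1 decimal, everything else to 3 significant figures. These digit
rules are this package's fixed reading of the usual compilation
convention; half-up (not banker's) rounding matches how published tables
are rounded.

A unified food's display name and food group come from the contributing
record with the most non-missing components, with ties broken by
lexicographic source id — a deterministic rule, so unification is
invariant to input order.

**Outlier screen.** With at least 3 contributors, a value is flagged when
its robust z-score |v − median| / (1.4826 · MAD) exceeds 3.5, and a whole
component is flagged for review when CV = sd/mean exceeds 2.0. The
thresholds are configurable: the screening idea ("locate the values of the
outer layers") is standard, but no canonical cutoffs exist for this
setting, so 3.5 (the conventional robust-z cutoff) and 2.0 (a CV that for
small n is only reachable when one value dwarfs the rest) are defaults,
not dogma. Flags never alter chosen values — correction is a human,
traceability-driven step. Note that with 3–5 noisy contributors the MAD is
estimated from very few points and the screen flags liberally; that is the
intended behavior of a review queue, not an error rate.

## Energy

Energy is recalculated from macronutrients with general Atwater factors:
kcal = 4·protein + 9·fat + 4·carbohydrate + 7·alcohol, optionally
+ 2·fiber (disabled by default — compilations differ on whether fiber
contributes, so it is a switch, not an assumption). Which carbohydrate
feeds the formula is likewise a switch: available carbohydrate (`CHOAVL`,
default) or total by difference (`CHOCDF`). The recomputed value replaces
the chosen `ENERC` only via `update_energy()`, which retains the reported
value alongside — source energy is never overwritten silently.

## Recipe computation (EuroFIR mixed method)

For ingredient *i* with raw weight `raw_i` and edible portion `EP_i`:

* edible weight `w_i = raw_i · EP_i`;
* component amount `(w_i / 100) · c_{i,k}`, multiplied by the retention
  factor `RF(k, group_i, method)` — most-specific match wins: (tagname,
  group, method) ≻ (tagname, ANY, method) ≻ (class, group, method) ≻
  (class, ANY, method) ≻ default 1; RF may exceed 1 (cooking gains);
* totals sum over ingredients; the yield factor applies **once at recipe
  level**: `cooked = YF · Σ w_i`, `per100_k = 100 · total_k / cooked`.

Water is not separately rebalanced beyond the yield factor — the mixed
method models the weight change, not the water flux. A component missing
from some (but not all) ingredients contributes 0 and the total is marked
partial, because dropping it would bias intake estimates down; a component
missing from every ingredient stays missing. Every computation attaches a
factor audit (EP, RF and matched rule, YF per ingredient and component).
Yield factors are keyed at recipe level by cooking method with group
`ANY` by default; `yf_override` lets a recipe carry its own measured
yield. Polyphenol retention uses the same RF table mechanism — retention
rows for phenolic compounds are just more table rows.

The built-in factor tables cover the common methods with plausible
magnitudes (water-soluble vitamin losses on boiling, water uptake of
boiled cereals/legumes, fat uptake ~10% gain on frying). They make the
engine usable out of the box but are not a reference compilation; supply
curated tables for production work.

## Quality control

The check suite is staged like the compilation process itself
(harmonization → unification → management → recipes) and is pure: it
reports, never edits.

* harmonization: every tagname resolves; every food code matches the
  FoodEx2 pattern; foods have usable names;
* unification: the proximate sum water + protein + fat + total
  carbohydrate + alcohol + ash must lie in the **closed** interval
  [95, 105] g per 100 g (the bounds pass: an interval check on rounded
  published values should not fail on its own endpoints); implausibility
  rules (a) fat = 0 while a fatty acid or cholesterol is positive,
  (b) fat > 1 g with no fatty-acid/cholesterol detail at all,
  (c) fiber > 0 in a fish-group food — the compound sentence behind these
  rules is ambiguous, so each is a separately toggleable rule; outlier and
  extreme-CV flags;
* management: `check_transfer()` verifies that two identically keyed
  exports (e.g. before/after a round trip through the relational store)
  agree bit-exactly in row count, key set and every value;
* recipes: `verify_recipe_model()` compares the engine against an
  independent straight-line implementation.

Range and transfer violations are errors (they are objectively wrong);
implausibilities and outliers are warnings, because their resolution
requires human review against the original source. Fish foods are
identified by a configurable food-group label list — there is no coded
taxonomy to consult.

## Relational store

The unified database persists as eight interrelated tables — sources,
foods, components, component_values, yield_factors, retention_factors,
recipes, recipe_ingredients — as a directory of CSV files with a portable
SQL DDL (`inst/extdata/fcdb_schema.sql`) documenting the same schema for
any SQL engine. A file-backed store keeps the artifact dependency-free and
diffable at desk scale; the DDL makes the server deployment a load script,
not a redesign. Contributor provenance lives inside component_values (one
row per contributor carrying the unified statistics), which keeps the
table count at eight and makes `trace_value()` — from any unified value
back to (source, verbatim original id, original value, original unit) — a
single filter. Values are written with 17 significant digits, so the
flat → store → flat round trip is bit-identical; referential integrity is
validated on read and violations are schema errors naming the keys.

## The synthetic-data generator

No licensed source database ships with the package, so every stage is
exercised against generated fixtures with known ground truth
(`generate_sources()`). The generator emulates the multi-source
compilation setting:

* a food catalog cycling through nine food groups, each with a
  realistic macronutrient profile; water is defined by difference so true
  proximate sums are exactly 100 g; fatty-acid classes are fractions of
  total fat; energy satisfies the Atwater identity; true absences
  (cholesterol in plants, fiber in animal foods, polyphenols in animal
  foods) are genuine logical zeros;
* per-source values are truth × lognormal noise (default CV 0.15 —
  multiplicative noise keeps values positive and matches how composition
  varies across compilations); defaults plant 5% zeros and 5% ×10
  outliers, every planted cell recorded in an exhaustive label set;
* alternating sources emit minerals in discordant units (declared in the
  mapping) and alternate their zero-coding convention, so both cleaning
  paths run;
* everything is deterministic under the spec's seed, byte-for-byte.

What the generator does **not** emulate: correlated errors between
sources, name/translation noise, per-source component coverage gaps,
non-lognormal heavy tails, or the marginal distributions of any specific
national table. Tests passing on these fixtures show the pipeline's logic
is correct under controlled corruption; they do not certify accuracy on
any particular real source.

Two deliberate fixture choices: parameter-recovery comparisons of median
vs mean are evaluated on components that actually contain a planted
outlier (with a 5% planting rate and 7 sources, ~30% of components do;
on clean components the two estimators differ by a coin flip, which is
uninformative), and quality-control scoring plants defects into a
noiseless fixture — under multiplicative noise an honest source's
proximate sum drifts outside [95, 105] by chance, which would contaminate
a labelled-corruption score with unlabelled true positives.

## Numerical choices and problem sizes

* Half-up rounding implemented as `floor(x·10^d + 0.5)/10^d`; ties at
  representable halves go up, deterministically.
* Sample median of an even pool is the midpoint of the central pair.
* The robust z-score denominator uses the consistency constant 1.4826;
  when MAD = 0 no z-flag is assignable (the CV screen still applies).
* Store and fixture files carry 17-significant-digit numbers — the
  shortest length guaranteeing double round trips.
* Test and verification runs use fixtures up to 10 sources × 200 foods ×
  50 components (the oracle-equivalence sweep runs 50 random
  configurations in that envelope), 100 generated recipes, and
  recovery simulations of ~750 outlier-bearing components; these sizes
  were chosen to exercise every code path at desk scale in minutes.

## Known limitations

* Matching is exact FoodEx2 code equality; no probabilistic linkage or
  name similarity. Miscoded foods unify wrongly and only the outlier and
  plausibility screens will hint at it.
* Per-100 mL sources never merge with per-100 g sources.
* IU and % units are unsupported; sources using them need pre-conversion
  with an explicit registry override.
* The eight-table store is single-writer, file-based; concurrent
  multi-user service is out of scope (the DDL ports the schema to a
  server when needed).
* Within-source duplicate foods are not merged — deduplication is logged
  and left to the compiler.
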