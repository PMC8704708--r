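# fcdbkit

Tools for building a **unified food composition database (FCDB)** from
heterogeneous source tables, for nutrition scientists, database compilers
and epidemiologists who need comparable nutrient data across countries.

National food composition tables disagree in component naming, units,
zero conventions and coverage. fcdbkit implements the full compilation
pipeline:

1. **Harmonization** — each source table is ingested under a mapping
   configuration that resolves every column to an INFOODS-style component
   tagname with a standard unit (g / mg / µg / kcal / kJ, per 100 g or
   100 mL), keeps original identifiers verbatim for traceability, and
   rejects unkeyable rows to a log. Branded, fortified, supplement and
   recipe/dish records are excluded; generic (including cooked) foods are
   kept.
2. **Unification** — foods are matched across sources by their FoodEx2
   classification code. Zeros are eliminated from each component pool
   (a `0` is too often a missing value in disguise; true "logical zeros"
   are reinstated when nothing was measured), statistics are computed per
   component, and the **sample median** is the chosen consensus value:

   `chosen(k) = round( median{ v₁ₖ, …, vₙₖ } )`

   with mean and SD kept as diagnostics, half-up rounding (1 decimal for
   proximates/energy, 3 significant figures otherwise), robust outlier
   screening (|v − median| / (1.4826·MAD) > 3.5, CV > 2 for review), and
   full per-value provenance.
3. **Validation** — a staged, HACCP-style check suite: tagname/code
   integrity, the proximate-sum range
   `water + protein + fat + carbohydrate + alcohol + ash ∈ [95, 105] g`,
   fat/fatty-acid/cholesterol plausibility rules, fiber-in-fish, outlier
   flags, and bit-exact transfer checks between exports.
4. **Energy** — Atwater recalculation
   `kcal = 4·P + 9·F + 4·C + 7·A (+ 2·fiber, optional)`, kJ = 4.184·kcal,
   never silently overwriting reported energy.
5. **Recipes** — the EuroFIR mixed method: edible-portion correction and
   retention factors per ingredient, one yield factor at recipe level,
   results per 100 g and per total with a complete factor audit.
6. **Storage** — an eight-table relational store (CSV directory plus
   portable SQL DDL) with referential integrity and value-identical round
   trips, and `trace_value()` from any unified value back to the original
   source records.

Because the real source databases are licensed, the package ships a
**synthetic fixture generator** (`generate_sources()`) producing
multi-source tables with known ground truth, lognormal per-source noise,
discordant units, and exhaustively labelled planted zeros/outliers — every
stage is testable without any external data.

## Worked example

```r
library(fcdbkit)
reg <- default_registry()

# seven synthetic sources, 40 foods, CV 15%, planted zeros and outliers
fx <- generate_sources(fixture_spec(seed = 2026))
records <- harmonize_fixture(fx, reg)
records
#> <fcdb_records> 184 records from 7 source(s), 9752 values (7651 measured)

db <- unify_database(apply_exclusion_filter(records)$kept, reg)
db
#> <fcdb_unified> 40 foods (24 matched across sources, 16 singletons), 2040 unified values
#>   outlier screen: 572 flagged contributor values, 0 components for review

# consensus for one food's protein, with provenance
subset(db$values, foodex2 == "A0001" & tagname == "PROCNT",
       select = c(n_sources, mean, median, sd, chosen))
#>   n_sources  mean median    sd chosen
#> 1         7  2.80   2.78 0.301    2.8

run_suite(db, reg)
#> <fcdb_qc_report> 40 foods checked: 19 error(s), 451 warning(s)
#>   proximate_sum              19
#>   implausible_fat_zero       1
#>   outlier_value              450

head(recalc_energy(db)[, c("foodex2", "kcal", "kJ", "reported_kcal")], 3)
#>   foodex2  kcal    kJ reported_kcal
#> 1 A0001    29.2  122.          30
#> 2 A0002    63.1  264.          63.9
#> 3 A0003   361.  1510.         298.

rec <- recipe("R001", "Boiled greens", "boiled",
              data.frame(foodex2 = "A0001", raw_weight = 200,
                         edible_portion = 0.8))
compute_recipe(rec, db)
#> <fcdb_recipe_result> R001 (boiled): 200.0 g raw -> 152.0 g cooked (YF 0.95), 53 components
```

Reading the numbers: protein for food `A0001` was reported by all 7
sources (2.35–3.14 g/100 g); the median 2.78 rounds to the chosen 2.8 g.
The QC report is a review queue, not a verdict — with 15% noise, some
proximate sums drift outside 95–105 g and the robust screen flags
discordant contributors for exactly the kind of manual review a compiler
performs. The recipe result applies the edible portion (200 g → 160 g),
per-ingredient retention (e.g. vitamin C × 0.55 for boiled vegetables)
and the recipe-level yield factor (× 0.95 → 152 g cooked).

The same pipeline is scriptable from a shell via `inst/cli/fcdb.R`
(`ingest`, `unify`, `qc`, `energy`, `recipe`, `fixtures`, `export`).

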