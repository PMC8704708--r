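Package: fcdbkit
Title: Harmonization, Unification and Quality Control of Food Composition Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for constructing a unified food composition database
    (FCDB) from heterogeneous source tables. Source tables are harmonized to
    INFOODS-style component tagnames with standard units on a per-100 g (or
    per-100 mL) basis, foods are matched across sources by their FoodEx2
    classification code and unified by the per-component median with full
    contributor provenance, energy is recalculated from macronutrients with
    Atwater factors, and recipes are computed with the EuroFIR mixed method
    (yield factor at recipe level, retention factors per ingredient).
    Includes an automated HACCP-style data-quality check suite, a
    synthetic multi-source fixture generator with known ground truth and
    labelled planted defects, and a file-backed eight-table relational store
    with traceability back to the original source records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
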