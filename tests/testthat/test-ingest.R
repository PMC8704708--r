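reg <- default_registry()

simple_mapping <- function(...) {
  source_mapping(
    source_id = "T1",
    columns = data.frame(
      column = c("vitc_mg", "ca_g", "water"),
      tagname = c("VITC", "CA", "WATER"),
      unit = c("mg", "g", "g")
    ),
    id_column = "id", foodex2_column = "code", name_column = "name",
    record_class_column = "class",
    ...
  )
}

simple_table <- function() {
  data.frame(
    id = c("f1", "f2", "f3"),
    name = c("Apple", "Spinach", "Oddity"),
    code = c("A0001", "A00MH", "spinach"),
    class = "generic",
    vitc_mg = c("12.0", "", "3"),
    ca_g = c("0.12", "0", "0.2"),
    water = c("85", "91", "80"),
    stringsAsFactors = FALSE
  )
}

test_that("ingestion converts to standard units and keeps originals", {
  rec <- ingest_source(simple_table(), simple_mapping(), reg)
  expect_identical(nrow(rec$foods), 2L)  # "spinach" code rejected
  v <- rec$values
  vitc <- v[v$tagname == "VITC" & v$original_food_id == "f1", ]
  expect_identical(vitc$value, 12)       # mg -> mg identity
  expect_identical(vitc$status, "measured")
  ca <- v[v$tagname == "CA" & v$original_food_id == "f1", ]
  expect_identical(ca$value, 120)        # 0.12 g -> 120 mg
  expect_identical(ca$raw_value, 0.12)   # verbatim original retained
  expect_identical(ca$raw_unit, "g")
  # rejected row is in the log with its reason, never silently dropped
  expect_identical(rec$log$reason[rec$log$original_food_id == "f3"],
                   "invalid_code")
})

test_that("blank cells become missing, zeros follow the source convention", {
  rec <- ingest_source(simple_table(), simple_mapping(), reg)
  v <- rec$values
  expect_identical(v$status[v$tagname == "VITC" & v$original_food_id == "f2"],
                   "missing")
  expect_identical(v$status[v$tagname == "CA" & v$original_food_id == "f2"],
                   "zero")
  rec2 <- ingest_source(simple_table(), simple_mapping(zero_is_logical = TRUE),
                        reg)
  v2 <- rec2$values
  expect_identical(v2$status[v2$tagname == "CA" & v2$original_food_id == "f2"],
                   "logical_zero")
  expect_identical(v2$value[v2$tagname == "CA" & v2$original_food_id == "f2"], 0)
})

test_that("trace markers and decimal commas are parsed", {
  tab <- simple_table()
  tab$vitc_mg <- c("tr", "1,5", "2")
  rec <- ingest_source(tab, simple_mapping(decimal_mark = ","), reg)
  v <- rec$values[rec$values$tagname == "VITC", ]
  expect_identical(v$status[v$original_food_id == "f1"], "trace")
  expect_identical(v$value[v$original_food_id == "f1"], 0)
  expect_identical(v$value[v$original_food_id == "f2"], 1.5)
})

test_that("negative values reject the row to the log", {
  tab <- simple_table()
  tab$water[1] <- "-5"
  rec <- ingest_source(tab, simple_mapping(), reg)
  expect_false("f1" %in% rec$foods$original_food_id)
  expect_identical(rec$log$reason[rec$log$original_food_id == "f1"],
                   "negative_value")
  # partition: kept + rejected = input
  expect_identical(nrow(rec$foods) +
                     sum(rec$log$action == "rejected"), 3L)
})

test_that("missing mandatory columns are a mapping error", {
  tab <- simple_table()
  tab$code <- NULL
  expect_error(ingest_source(tab, simple_mapping(), reg),
               class = "fcdb_mapping_error")
  # mapped tagname whose unit cannot feed the standard unit
  bad <- source_mapping("T1",
                        columns = data.frame(column = "water",
                                             tagname = "WATER",
                                             unit = "kcal"),
                        id_column = "id", foodex2_column = "code")
  expect_error(ingest_source(simple_table(), bad, reg),
               class = "fcdb_mapping_error")
})

test_that("mapping configurations round-trip through YAML and JSON", {
  mp <- simple_mapping(zero_is_logical = TRUE)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_source_mapping(mp, f)
    got <- read_source_mapping(f)
    expect_identical(got$source_id, mp$source_id)
    expect_identical(got$zero_is_logical, TRUE)
    expect_equal(as.data.frame(got$columns), as.data.frame(mp$columns))
  }
})

test_that("exclusion filter partitions records by class with reasons", {
  tab <- data.frame(
    id = sprintf("f%d", 1:6),
    name = "x", code = sprintf("A000%d", 1:6),
    class = c("generic", "branded", "fortified", "supplement",
              "recipe_or_dish", "mystery"),
    vitc_mg = "1", ca_g = "0.1", water = "80",
    stringsAsFactors = FALSE
  )
  rec <- ingest_source(tab, simple_mapping(), reg)
  part <- apply_exclusion_filter(rec)
  expect_identical(nrow(part$kept$foods) + nrow(part$excluded), nrow(rec$foods))
  expect_setequal(part$excluded$reason,
                  c("branded", "fortified", "supplement", "recipe_or_dish"))
  # unknown class is kept and logged
  expect_true("f6" %in% part$kept$foods$original_food_id)
  expect_true(any(part$log$action == "kept_unknown_class" &
                    part$log$original_food_id == "f6"))
  # cooked generic foods are kept
  expect_true("f1" %in% part$kept$foods$original_food_id)
})

test_that("exclusion of empty input yields empty partitions", {
  rec <- ingest_source(simple_table()[0, ], simple_mapping(), reg)
  part <- apply_exclusion_filter(rec)
  expect_identical(nrow(part$kept$foods), 0L)
  expect_identical(nrow(part$excluded), 0L)
})

test_that("re-harmonizing an already-harmonized table is the identity", {
  fx <- generate_sources(fixture_spec(n_sources = 2, n_foods = 10, seed = 11))
  sid <- names(fx$tables)[2]  # scrambled-unit source
  rec1 <- ingest_source(fx$tables[[sid]], fx$mappings[[sid]], reg)
  # rebuild a wide table from the standardized values and re-ingest with an
  # identity mapping (all units already standard)
  wide <- tidyr::pivot_wider(
    rec1$values[, c("original_food_id", "foodex2", "tagname", "value")],
    names_from = "tagname", values_from = "value")
  tags <- setdiff(names(wide), c("original_food_id", "foodex2"))
  mp <- source_mapping(
    source_id = sid,
    columns = data.frame(column = tags, tagname = tags,
                         unit = resolve_component(reg, tags)$standard_unit),
    id_column = "original_food_id", foodex2_column = "foodex2"
  )
  rec2 <- ingest_source(as.data.frame(wide), mp, reg)
  m1 <- rec1$values[rec1$values$status %in% c("measured", "trace"),
                    c("original_food_id", "tagname", "value")]
  m2 <- rec2$values[!is.na(rec2$values$value) & rec2$values$value != 0,
                    c("original_food_id", "tagname", "value")]
  j <- merge(m1[m1$value != 0, ], m2, by = c("original_food_id", "tagname"))
  expect_gt(nrow(j), 0)
  expect_identical(j$value.x, j$value.y)
})
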