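reg <- default_registry()

test_that("identical seeds give identical fixtures, on disk byte-for-byte", {
  s <- fixture_spec(n_sources = 3, n_foods = 10, seed = 99)
  fx1 <- generate_sources(s)
  fx2 <- generate_sources(s)
  expect_identical(fx1$tables, fx2$tables)
  expect_identical(fx1$ground_truth, fx2$ground_truth)
  expect_identical(fx1$defect_labels, fx2$defect_labels)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(fx1, d1)
  write_fixture(fx2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the data
  fx3 <- generate_sources(fixture_spec(n_sources = 3, n_foods = 10, seed = 100))
  expect_false(identical(fx1$tables, fx3$tables))
})

test_that("the noiseless limit recovers ground truth exactly", {
  fx <- generate_sources(fixture_spec(n_sources = 5, n_foods = 15,
                                      noise_cv = 0, zero_rate = 0,
                                      outlier_rate = 0, seed = 51))
  db <- unify_database(harmonize_fixture(fx, reg), reg)
  j <- dplyr::inner_join(db$values, fx$ground_truth,
                         by = c("foodex2", "tagname"))
  expect_gt(nrow(j), 0)
  expect_identical(j$chosen, round_standard(j$value, j$component_class))
  # true absences come through as reinstated logical zeros
  lz <- j[j$logical_zero.y, ]
  expect_true(all(lz$chosen == 0))
})

test_that("defect labels exhaustively and exclusively mark corruptions", {
  # noiseless fixture with planted zeros and outliers: a cell differs from
  # truth if and only if a label names it
  fx <- generate_sources(fixture_spec(n_sources = 4, n_foods = 20,
                                      noise_cv = 0, zero_rate = 0.08,
                                      outlier_rate = 0.08, outlier_k = 10,
                                      unit_scramble = FALSE, seed = 53))
  rec <- harmonize_fixture(fx, reg)
  truth <- fx$ground_truth
  v <- dplyr::left_join(rec$values, truth, by = c("foodex2", "tagname"))
  lab_key <- paste(fx$defect_labels$source_id,
                   fx$defect_labels$original_food_id,
                   fx$defect_labels$tagname)
  v$key <- paste(v$source_id, v$original_food_id, v$tagname)
  corrupted <- v$raw_value != v$value.y
  expect_setequal(v$key[corrupted], lab_key)
  # labels carry the right type
  z <- fx$defect_labels[fx$defect_labels$type == "planted_zero", ]
  zk <- paste(z$source_id, z$original_food_id, z$tagname)
  expect_true(all(v$raw_value[v$key %in% zk] == 0))
  o <- fx$defect_labels[fx$defect_labels$type == "planted_outlier", ]
  ok <- paste(o$source_id, o$original_food_id, o$tagname)
  expect_identical(v$raw_value[v$key %in% ok], 10 * v$value.y[v$key %in% ok])
})

test_that("overlap controls matching; zero overlap gives singletons only", {
  fx0 <- generate_sources(fixture_spec(n_sources = 4, n_foods = 12,
                                       overlap_fraction = 0, seed = 57))
  db0 <- unify_database(harmonize_fixture(fx0, reg), reg)
  expect_false(any(db0$foods$matched))
  fx1 <- generate_sources(fixture_spec(n_sources = 4, n_foods = 12,
                                       overlap_fraction = 1, seed = 57))
  db1 <- unify_database(harmonize_fixture(fx1, reg), reg)
  expect_true(all(db1$foods$matched))
  expect_true(all(db1$foods$n_source_dbs == 4))
})

test_that("scrambled units are declared in mappings and undone on ingest", {
  fx <- generate_sources(fixture_spec(n_sources = 2, n_foods = 8,
                                      noise_cv = 0, zero_rate = 0,
                                      outlier_rate = 0, unit_scramble = TRUE,
                                      seed = 61))
  # source 2 emits calcium in grams
  mp2 <- fx$mappings[[2]]
  expect_identical(mp2$columns$unit[mp2$columns$tagname == "CA"], "g")
  rec <- harmonize_fixture(fx, reg)
  ca <- rec$values[rec$values$tagname == "CA" & rec$values$source_id == "S02", ]
  expect_identical(unique(ca$raw_unit), "g")
  truth <- fx$ground_truth[fx$ground_truth$tagname == "CA", ]
  j <- dplyr::inner_join(ca, truth, by = "foodex2")
  expect_equal(j$value.x, j$value.y, tolerance = 1e-12)  # back in mg
  expect_equal(j$raw_value, j$value.y / 1000, tolerance = 1e-12)
})

test_that("fixture proximates are internally consistent", {
  fx <- generate_sources(fixture_spec(n_sources = 2, n_foods = 18,
                                      noise_cv = 0, zero_rate = 0,
                                      outlier_rate = 0, seed = 63))
  tr <- tidyr::pivot_wider(fx$ground_truth[, c("foodex2", "tagname", "value")],
                           names_from = "tagname", values_from = "value")
  s <- tr$WATER + tr$PROCNT + tr$FAT + tr$CHOCDF + tr$ALC + tr$ASH
  expect_equal(s, rep(100, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$CHOCDF, tr$CHOAVL + tr$FIBTG, tolerance = 1e-12)
  expect_true(all(tr$FASAT + tr$FAMS + tr$FAPU <= tr$FAT | tr$FAT == 0))
  expect_identical(tr$ENERC,
                   4 * tr$PROCNT + 9 * tr$FAT + 4 * tr$CHOAVL + 7 * tr$ALC)
})

test_that("generated recipes carry reproducible closed-form expectations", {
  db <- unify_database(harmonize_fixture(
    generate_sources(fixture_spec(n_sources = 3, n_foods = 9, seed = 67)), reg),
    reg)
  g1 <- generate_recipes(db, 4, seed = 5)
  g2 <- generate_recipes(db, 4, seed = 5)
  expect_identical(g1$expected, g2$expected)
  expect_identical(lapply(g1$recipes, `[[`, "ingredients"),
                   lapply(g2$recipes, `[[`, "ingredients"))
})
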