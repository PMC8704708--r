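reg <- default_registry()

potato_db <- function(vitc = 20) {
  mini <- make_records(list(S1 = c(VITC = vitc, WATER = 80)),
                       foodex2 = "A0100", group = "vegetables")
  unify_database(mini, reg)
}

test_that("single-ingredient mixed-method computation is exact", {
  db <- potato_db()
  rf <- retention_factors(data.frame(
    component = "VITC", level = "tagname", food_group = "vegetables",
    cooking_method = "boiled", rf = 0.7))
  rec <- recipe("R1", "Boiled potato", "boiled",
                data.frame(foodex2 = "A0100", raw_weight = 200,
                           edible_portion = 0.8),
                yf_override = 0.9)
  res <- compute_recipe(rec, db, rf_table = rf)
  expect_identical(res$total_edible_weight, 160)      # 200 * 0.8
  expect_identical(res$total_cooked_weight, 144)      # YF 0.9 * 160
  vitc <- res$totals[res$totals$tagname == "VITC", ]
  expect_identical(vitc$per_total, (160 / 100) * 20 * 0.7)  # 22.4 mg
  expect_equal(vitc$per_100g, 15.5556, tolerance = 1e-4)
  # audit records the factors used
  aud <- res$factor_audit[res$factor_audit$tagname == "VITC", ]
  expect_identical(aud$rf, 0.7)
  expect_identical(aud$yf, 0.9)
  expect_identical(aud$edible_portion, 0.8)
})

test_that("retention lookup precedence: tagname beats class, group beats ANY", {
  rf <- retention_factors(tibble::tribble(
    ~component, ~level, ~food_group, ~cooking_method, ~rf,
    "VITC", "tagname", "vegetables", "boiled", 0.55,
    "VITC", "tagname", "ANY", "boiled", 0.60,
    "vitamin", "class", "vegetables", "boiled", 0.70,
    "vitamin", "class", "ANY", "boiled", 0.75
  ))
  expect_identical(
    lookup_rf("VITC", "vitamin", "vegetables", "boiled", rf)$rf, 0.55)
  expect_identical(
    lookup_rf("VITC", "vitamin", "fruits", "boiled", rf)$rf, 0.60)
  expect_identical(
    lookup_rf("THIA", "vitamin", "vegetables", "boiled", rf)$rf, 0.70)
  expect_identical(
    lookup_rf("THIA", "vitamin", "fruits", "boiled", rf)$rf, 0.75)
  # no match at all: default 1 with an explicit audit rule
  miss <- lookup_rf("CA", "mineral", "fruits", "boiled", rf)
  expect_identical(miss$rf, 1)
  expect_identical(miss$rule, "default")
  # yield factor: group-specific beats ANY; raw is 1
  expect_identical(lookup_yf("boiled", "vegetables"), 0.90)
  expect_identical(lookup_yf("boiled"), 0.95)
  expect_identical(lookup_yf("raw"), 1)
  expect_true(is.na(lookup_yf("sous_vide")))
})

test_that("identity limit reproduces the mass-weighted mean", {
  fx <- generate_sources(fixture_spec(n_sources = 3, n_foods = 8,
                                      noise_cv = 0, zero_rate = 0,
                                      outlier_rate = 0, seed = 31))
  db <- unify_database(harmonize_fixture(fx, reg), reg)
  db$foods$edible_portion <- 1
  ident_rf <- default_retention_factors()[0, ]
  rec <- recipe("R2", "identity", "raw",
                data.frame(foodex2 = db$foods$foodex2[1:3],
                           raw_weight = c(100, 50, 150)),
                yf_override = 1)
  res <- compute_recipe(rec, db, rf_table = ident_rf)
  expect_identical(res$total_cooked_weight, 300)
  # per 100 g equals the weighted mean of ingredient compositions
  w <- c(100, 50, 150)
  for (tag in c("PROCNT", "CA", "VITC")) {
    comp <- vapply(1:3, function(i) {
      v <- db$values$chosen[db$values$foodex2 == db$foods$foodex2[i] &
                              db$values$tagname == tag]
      if (length(v)) v else 0
    }, 0)
    got <- res$totals$per_100g[res$totals$tagname == tag]
    expect_equal(got, sum(w * comp) / sum(w), tolerance = 1e-12)
  }
})

test_that("doubling raw weights doubles totals, leaves per-100 g unchanged", {
  db <- unify_database(harmonize_fixture(
    generate_sources(fixture_spec(n_sources = 2, n_foods = 6, seed = 37)), reg),
    reg)
  ing <- data.frame(foodex2 = db$foods$foodex2[1:2], raw_weight = c(80, 120))
  r1 <- compute_recipe(recipe("a", "a", "boiled", ing), db)
  ing2 <- ing
  ing2$raw_weight <- ing$raw_weight * 2
  r2 <- compute_recipe(recipe("b", "b", "boiled", ing2), db)
  expect_equal(r2$totals$per_total, 2 * r1$totals$per_total, tolerance = 1e-12)
  expect_equal(r2$totals$per_100g, r1$totals$per_100g, tolerance = 1e-12)
  # mass bookkeeping is exact
  ep <- ifelse(is.na(db$foods$edible_portion[1:2]), 1,
               db$foods$edible_portion[1:2])
  expect_identical(r1$total_cooked_weight, r1$yf * sum(ing$raw_weight * ep))
})

test_that("retention above 1 models cooking gains and is monotone", {
  db <- potato_db()
  mk_rf <- function(r) retention_factors(data.frame(
    component = "VITC", level = "tagname", food_group = "ANY",
    cooking_method = "fried", rf = r))
  ing <- data.frame(foodex2 = "A0100", raw_weight = 100)
  vals <- vapply(c(0.5, 1, 1.5), function(r) {
    res <- compute_recipe(recipe("m", "m", "fried", ing), db,
                          rf_table = mk_rf(r))
    res$totals$per_100g[res$totals$tagname == "VITC"]
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("per-100 g and per-total representations are mutually consistent", {
  db <- unify_database(harmonize_fixture(
    generate_sources(fixture_spec(n_sources = 4, n_foods = 10, seed = 41)), reg),
    reg)
  gr <- generate_recipes(db, 5, seed = 2)
  for (r in gr$recipes) {
    res <- compute_recipe(r, db)
    expect_identical(res$totals$per_100g,
                     100 * res$totals$per_total / res$total_cooked_weight)
  }
})

test_that("engine matches the straight-line oracle on generated recipes", {
  db <- unify_database(harmonize_fixture(
    generate_sources(fixture_spec(n_sources = 5, n_foods = 15, seed = 43)), reg),
    reg)
  gr <- generate_recipes(db, 20, seed = 11)
  cmp <- verify_recipe_model(gr$recipes, db, reference = gr$expected)
  expect_true(all(is.finite(cmp$rel_diff)))
  expect_lt(max(cmp$rel_diff), 1e-9)
  # sensitivity: a wrong factor in the reference localizes the difference
  ref <- gr$expected
  k <- which(ref[[1]]$per_total > 0)[1]  # perturb a nonzero component
  ref[[1]]$per_total[k] <- ref[[1]]$per_total[k] * 1.1
  cmp2 <- verify_recipe_model(gr$recipes, db, reference = ref)
  bad <- cmp2[cmp2$rel_diff > 1e-9, ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$recipe_id, gr$recipes[[1]]$recipe_id)
  # empty recipe list: empty report
  expect_identical(nrow(verify_recipe_model(list(), db, reference = list())), 0L)
})

test_that("unresolvable ingredients and methods raise reference errors", {
  db <- potato_db()
  expect_error(
    compute_recipe(recipe("x", "x", "boiled",
                          data.frame(foodex2 = "Z9999", raw_weight = 50)), db),
    class = "fcdb_reference_error")
  expect_error(
    compute_recipe(recipe("x", "x", "sous_vide",
                          data.frame(foodex2 = "A0100", raw_weight = 50)), db),
    class = "fcdb_reference_error")
  expect_error(recipe("x", "x", "boiled",
                      data.frame(foodex2 = "A0100", raw_weight = -1)))
})

test_that("recipes round-trip through JSON", {
  r <- list(
    recipe("R1", "Stew", "stewed",
           data.frame(foodex2 = c("A0001", "A0002"), raw_weight = c(100, 60),
                      edible_portion = c(0.9, NA)), yf_override = 0.95),
    recipe("R2", "Salad", "raw",
           data.frame(foodex2 = "A0003", raw_weight = 80))
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_recipes(r, f)
  got <- read_recipes(f)
  expect_identical(got[[1]]$recipe_id, "R1")
  expect_identical(got[[1]]$yf_override, 0.95)
  expect_equal(as.data.frame(got[[1]]$ingredients),
               as.data.frame(r[[1]]$ingredients))
  expect_identical(got[[2]]$cooking_method, "raw")
})
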