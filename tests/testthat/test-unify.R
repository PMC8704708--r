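reg <- default_registry()

test_that("zero cleaning eliminates zeros from the pool as missing", {
  vals <- tibble::tibble(
    status = c("measured", "zero", "measured", "logical_zero", "trace"),
    value = c(2, 0, 4, 0, 0)
  )
  out <- clean_zeros(vals)
  expect_identical(out$status,
                   c("measured", "missing", "measured", "logical_zero", "trace"))
  expect_true(is.na(out$value[2]))
  # no zeros: identity
  novals <- tibble::tibble(status = c("measured", "missing"), value = c(1, NA))
  expect_identical(clean_zeros(novals), novals)
  # all-zero input leaves an empty measured pool
  az <- clean_zeros(tibble::tibble(status = rep("zero", 3), value = rep(0, 3)))
  expect_identical(sum(az$status == "measured"), 0L)
})

test_that("component unification takes the sample median as final value", {
  mk <- function(v) data.frame(source_id = paste0("s", seq_along(v)),
                               original_food_id = "1", value = v)
  expect_identical(unify_component(mk(c(2.8, 3.1, 3.5)))$median, 3.1)
  expect_identical(unify_component(mk(c(2.0, 4.0)))$median, 3.0)
  u <- unify_component(mk(c(1.0, 1.2, 1.1, 9.0)))
  expect_identical(u$median, 1.15)  # near the dense cluster
  expect_identical(u$mean, 3.075)   # dragged by the outlier
  expect_identical(u$n_sources, 4L)
  expect_identical(unify_component(mk(5))$sd, 0)  # single value: sd 0
  empty <- data.frame(source_id = character(),
                      original_food_id = character(), value = numeric())
  expect_null(unify_component(empty))
})

test_that("standard rounding is half-up, by component class", {
  expect_identical(round_standard(3.1416, "proximate"), 3.1)
  expect_identical(round_standard(0.012345, "mineral"), 0.0123)
  expect_identical(round_standard(0, "vitamin"), 0)
  expect_identical(round_standard(165.26, "energy"), 165.3)
  # half-up, not banker's rounding
  expect_identical(round_half_up(2.5, 0), 3)
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(signif_half_up(0.001235, 3), 0.00124)
})

test_that("unification groups foods by code across sources", {
  rec <- make_records(list(
    S1 = c(PROCNT = 2.8), S2 = c(PROCNT = 3.1), S3 = c(PROCNT = 3.5)
  ))
  db <- unify_database(rec, reg)
  expect_identical(nrow(db$foods), 1L)
  expect_true(db$foods$matched)
  expect_identical(db$values$n_sources, 3L)
  expect_identical(db$values$chosen, 3.1)
  expect_identical(nrow(db$contributors), 3L)
  # bounds: chosen within [min, max] of contributors
  expect_gte(db$values$median, min(db$contributors$value))
  expect_lte(db$values$median, max(db$contributors$value))
})

test_that("disjoint codes give all-singleton output; empty input is empty", {
  fx <- generate_sources(fixture_spec(n_sources = 3, n_foods = 9,
                                      overlap_fraction = 0, seed = 2))
  db <- unify_database(harmonize_fixture(fx, reg), reg)
  expect_identical(nrow(db$foods), 9L)
  expect_false(any(db$foods$matched))
  empty <- make_records(list(S1 = c(PROCNT = 1)))
  empty$foods <- empty$foods[0, ]
  empty$values <- empty$values[0, ]
  dbe <- unify_database(empty, reg)
  expect_identical(nrow(dbe$foods), 0L)
  expect_identical(nrow(dbe$values), 0L)
})

test_that("logical zeros are reinstated only when nothing was measured", {
  # all sources code fiber as a true absence -> chosen 0 survives
  rec <- make_records(list(S1 = c(FIBTG = 0), S2 = c(FIBTG = 0)),
                      zero_is_logical = TRUE)
  db <- unify_database(rec, reg)
  expect_identical(db$values$chosen, 0)
  expect_true(db$values$logical_zero)
  expect_identical(db$values$n_sources, 0L)
  # one source measured a value -> the zero is not pooled, value wins
  rec2 <- bind_records(
    make_records(list(S1 = c(FIBTG = 0)), zero_is_logical = TRUE),
    make_records(list(S2 = c(FIBTG = 2.4)))
  )
  db2 <- unify_database(rec2, reg)
  expect_identical(db2$values$chosen, 2.4)
  expect_identical(db2$values$n_sources, 1L)
  # plain zeros (not logical) vanish entirely
  rec3 <- make_records(list(S1 = c(FIBTG = 0), S2 = c(FIBTG = 0)),
                       zero_is_logical = FALSE)
  db3 <- unify_database(rec3, reg)
  expect_identical(nrow(db3$values), 0L)
})

test_that("robust z-score flags gross outliers, never small pools", {
  rec <- make_records(list(S1 = c(CA = 10), S2 = c(CA = 11),
                           S3 = c(CA = 10.5), S4 = c(CA = 95)))
  db <- unify_database(rec, reg)
  flagged <- db$contributors[db$contributors$outlier_flag, ]
  expect_identical(flagged$value, 95)
  expect_identical(flagged$source_id, "S4")
  expect_true(db$values$outlier_flag)
  # zero dispersion: no flags
  rec0 <- make_records(list(S1 = c(CA = 10), S2 = c(CA = 10), S3 = c(CA = 10)))
  expect_false(any(unify_database(rec0, reg)$contributors$outlier_flag))
  # n = 2: no flags regardless of spread
  rec2 <- make_records(list(S1 = c(CA = 1), S2 = c(CA = 1000)))
  expect_false(any(unify_database(rec2, reg)$contributors$outlier_flag))
  # flags never alter chosen values
  expect_identical(db$values$chosen, 10.8)  # median(10,10.5,11,95) = 10.75 -> 10.8
})

test_that("extreme coefficient of variation flags a component for review", {
  rec <- make_records(list(S1 = c(CA = 0.1), S2 = c(CA = 0.1),
                           S3 = c(CA = 0.1), S4 = c(CA = 0.1),
                           S5 = c(CA = 500)))
  db <- unify_database(rec, reg)
  expect_true(db$values$review_flag)
  calm <- make_records(list(S1 = c(CA = 10), S2 = c(CA = 11), S3 = c(CA = 12)))
  expect_false(unify_database(calm, reg)$values$review_flag)
})

test_that("unification is invariant to input record order", {
  fx <- generate_sources(fixture_spec(n_sources = 4, n_foods = 15, seed = 9))
  rec <- harmonize_fixture(fx, reg)
  db1 <- unify_database(rec, reg)
  perm <- withr::with_seed(1, sample(nrow(rec$values)))
  rec2 <- rec
  rec2$values <- rec$values[perm, ]
  rec2$foods <- rec$foods[withr::with_seed(2, sample(nrow(rec$foods))), ]
  db2 <- unify_database(rec2, reg)
  expect_identical(db1$values$chosen, db2$values$chosen)
  expect_identical(db1$foods$name, db2$foods$name)
})

test_that("unification matches the brute-force oracle on random fixtures", {
  for (seed in 1:5) {
    fx <- generate_sources(fixture_spec(
      n_sources = 2 + seed, n_foods = 10 + 3 * seed, n_components = 12,
      overlap_fraction = 0.5, seed = seed))
    expect_true(unify_matches_oracle(fx, reg))
  }
})

test_that("chosen values stay within contributor bounds before rounding", {
  fx <- generate_sources(fixture_spec(n_sources = 6, n_foods = 20, seed = 33))
  db <- unify_database(harmonize_fixture(fx, reg), reg)
  rng <- db$contributors |>
    dplyr::group_by(foodex2, basis, tagname) |>
    dplyr::summarise(lo = min(value), hi = max(value), .groups = "drop")
  j <- dplyr::inner_join(db$values, rng, by = c("foodex2", "basis", "tagname"))
  expect_true(all(j$median >= j$lo & j$median <= j$hi))
})

test_that("unified food names come from the richest contributing record", {
  r1 <- make_records(list(S2 = c(PROCNT = 1, CA = 2, FE = 1)))
  r1$foods$english_name <- "rich name"
  r2 <- make_records(list(S1 = c(PROCNT = 1)))
  r2$foods$english_name <- "poor name"
  db <- unify_database(bind_records(r1, r2), reg)
  expect_identical(db$foods$name, "rich name")
})
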