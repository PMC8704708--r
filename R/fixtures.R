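# Synthetic multi-source fixtures with known ground truth. The generator
# emulates the multi-source compilation setting: several national-style
# source tables carrying overlapping FoodEx2-coded foods, per-source
# multiplicative noise, discordant units, zeros planted in place of
# missing values, and gross outliers — every planted corruption is
# recorded in an exhaustive label set so quality control can be scored
# exactly.

.fixture_groups <- c("vegetables", "fruits", "cereals", "legumes", "meat",
                     "fish", "dairy", "fats_oils", "beverages")
.animal_groups <- c("meat", "fish", "dairy", "fats_oils")

#' Fixture specification
#'
#' Defaults describe the study conditions the package is exercised under:
#' seven contributing sources, 15% per-source coefficient of variation
#' (multiplicative lognormal noise, keeping values positive), 5% of values
#' planted as zeros, 5% planted as x10 outliers, and discordant units in
#' alternating sources.
#'
#' @param n_sources,n_foods Counts (>= 1).
#' @param n_components Number of components drawn from the registry menu
#'   (proximates and energy first); `NULL` for the full menu.
#' @param overlap_fraction Fraction of foods present in every source; the
#'   remainder are singletons split across sources.
#' @param noise_cv Per-source multiplicative noise CV.
#' @param zero_rate Fraction of values planted as 0.
#' @param outlier_rate Fraction planted as `outlier_k` x the true value.
#' @param outlier_k Outlier multiplier.
#' @param unit_scramble Emit minerals/selenium of alternating sources in
#'   non-standard units (with the mapping declaring the emitted unit).
#' @param seed Integer; identical seeds give identical fixtures.
#' @return A `fcdb_fixture_spec` list.
#' @export
fixture_spec <- function(n_sources = 7, n_foods = 40, n_components = NULL,
                         overlap_fraction = 0.6, noise_cv = 0.15,
                         zero_rate = 0.05, outlier_rate = 0.05,
                         outlier_k = 10, unit_scramble = TRUE, seed = 1) {
  stopifnot(n_sources >= 1, n_foods >= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            noise_cv >= 0, zero_rate >= 0, zero_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1, outlier_k > 0)
  structure(list(n_sources = n_sources, n_foods = n_foods,
                 n_components = n_components,
                 overlap_fraction = overlap_fraction, noise_cv = noise_cv,
                 zero_rate = zero_rate, outlier_rate = outlier_rate,
                 outlier_k = outlier_k, unit_scramble = isTRUE(unit_scramble),
                 seed = as.integer(seed)),
            class = "fcdb_fixture_spec")
}

# Per-group macronutrient profile (g/100 g) and which components are true
# absences (logical zeros) for that group.
group_profile <- function(group) {
  macro <- switch(group,
    vegetables = c(PROCNT = 2.5, FAT = 0.4, CHOAVL = 4.0, FIBTG = 2.5, ASH = 1.0),
    fruits     = c(PROCNT = 0.8, FAT = 0.3, CHOAVL = 12.0, FIBTG = 2.2, ASH = 0.5),
    cereals    = c(PROCNT = 10, FAT = 2.0, CHOAVL = 65, FIBTG = 7.0, ASH = 1.5),
    legumes    = c(PROCNT = 21, FAT = 3.0, CHOAVL = 45, FIBTG = 15, ASH = 3.0),
    meat       = c(PROCNT = 21, FAT = 8.0, CHOAVL = 0.5, FIBTG = 0, ASH = 1.0),
    fish       = c(PROCNT = 19, FAT = 5.0, CHOAVL = 0.3, FIBTG = 0, ASH = 1.2),
    dairy      = c(PROCNT = 3.5, FAT = 3.6, CHOAVL = 4.8, FIBTG = 0, ASH = 0.7),
    fats_oils  = c(PROCNT = 0.2, FAT = 82, CHOAVL = 0.5, FIBTG = 0, ASH = 0.1),
    beverages  = c(PROCNT = 0.3, FAT = 0.1, CHOAVL = 6.0, FIBTG = 0.2, ASH = 0.2)
  )
  micro <- c(CA = 40, FE = 1.5, MG = 25, P = 120, K = 250, "NA" = 60,
             ZN = 1.2, CU = 0.15, MN = 0.5, CLD = 80, SE = 8, ID = 5,
             VITC = 2, THIA = 0.1, RIBF = 0.15, NIA = 2, VITB6A = 0.2,
             PANTAC = 0.5, VITE = 1, FOL = 40, VITB12 = 1, VITA_RAE = 50,
             VITD = 0.5, VITK = 20, BIOT = 3, CHOLE = 50)
  micro_over <- switch(group,
    vegetables = c(VITC = 35, VITK = 80, FOL = 80),
    fruits = c(VITC = 30, K = 200),
    meat = c(VITB12 = 1.5, ZN = 3, FE = 2, CHOLE = 70),
    fish = c(VITB12 = 3, VITD = 5, SE = 30, CHOLE = 55, ID = 30),
    dairy = c(CA = 120, VITB12 = 0.8, CHOLE = 12),
    fats_oils = c(VITE = 15, CHOLE = 25),
    NULL
  )
  micro[names(micro_over)] <- micro_over
  pp_base <- if (group %in% .animal_groups) 0 else if (group == "beverages") 10 else 2
  lz <- c("ALC",
          if (group %in% .animal_groups) "FIBTG",
          if (group %in% .animal_groups) character() else c("CHOLE", "VITB12", "VITD"))
  list(macro = macro, micro = micro, pp_base = pp_base, lz = lz,
       pp_logical_zero = group %in% .animal_groups)
}

# Ground-truth composition for one food (named vector over `tags`), with
# an attribute naming the logical-zero components. Proximates close to a
# sum of exactly 100 g by defining water by difference.
food_truth <- function(group, tags) {
  pr <- group_profile(group)
  jit <- function(x) x * stats::runif(length(x), 0.85, 1.15)
  macro <- jit(pr$macro)
  macro[pr$macro == 0] <- 0
  out <- stats::setNames(numeric(length(tags)), tags)
  lz <- intersect(pr$lz, tags)
  set <- function(tag, v) if (tag %in% tags) out[[tag]] <<- v
  for (t in names(macro)) set(t, macro[[t]])
  chocdf <- macro[["CHOAVL"]] + macro[["FIBTG"]]
  set("CHOCDF", chocdf)
  set("ALC", 0)
  water <- 100 - (macro[["PROCNT"]] + macro[["FAT"]] + chocdf + macro[["ASH"]])
  set("WATER", water)
  set("ENERC", energy_kcal(macro[["PROCNT"]], macro[["FAT"]],
                           macro[["CHOAVL"]], 0))
  micro <- pr$micro * stats::runif(length(pr$micro), 0.6, 1.6)
  for (t in names(micro)) set(t, micro[[t]])
  # fatty-acid classes as fractions of total fat
  fr <- c(0.35, 0.40, 0.18) * stats::runif(3, 0.8, 1.2)
  fr <- fr / sum(fr) * stats::runif(1, 0.85, 0.95)
  set("FASAT", fr[1] * macro[["FAT"]])
  set("FAMS", fr[2] * macro[["FAT"]])
  set("FAPU", fr[3] * macro[["FAT"]])
  pp_tags <- grep("^PP_", tags, value = TRUE)
  for (t in pp_tags) {
    out[[t]] <- pr$pp_base * stats::runif(1, 0.2, 2)
  }
  if (pr$pp_logical_zero) lz <- c(lz, pp_tags)
  out[lz] <- 0
  attr(out, "logical_zero") <- lz
  out
}

#' Generate multi-source fixture tables
#'
#' Builds a food catalog with ground-truth compositions, then emits one
#' table per source: values are truth times lognormal noise with the
#' spec's CV, planted zeros and x`outlier_k` outliers are recorded with
#' exact positions in `defect_labels`, and (when `unit_scramble` is on)
#' alternating sources report minerals in g and selenium/iodine in mg,
#' with the mapping declaring the emitted unit. Sources alternate their
#' zero convention (`zero_is_logical`), so both zero-cleaning paths occur.
#' Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param registry Component registry supplying the component menu.
#' @return A `fcdb_fixture`: list with `tables` (one data frame per
#'   source), `mappings`, `sources` (source metadata), `foods` (catalog),
#'   `ground_truth` (long: foodex2, tagname, value, logical_zero),
#'   `defect_labels` and `components`.
#' @export
generate_sources <- function(spec, registry = default_registry()) {
  stopifnot(inherits(spec, "fcdb_fixture_spec"))
  tags <- registry$tagname
  if (!is.null(spec$n_components)) {
    tags <- tags[seq_len(min(spec$n_components, length(tags)))]
  }
  withr::with_seed(spec$seed, {
    n <- spec$n_foods
    foods <- tibble::tibble(
      foodex2 = sprintf("A%04d", seq_len(n)),
      name = sprintf("Synthetic %s %03d",
                     .fixture_groups[(seq_len(n) - 1L) %% length(.fixture_groups) + 1L],
                     seq_len(n)),
      food_group = .fixture_groups[(seq_len(n) - 1L) %% length(.fixture_groups) + 1L],
      cooking_method = "raw",
      edible_portion = ifelse(stats::runif(n) < 0.3, 0.8, 1)
    )
    truth_list <- lapply(foods$food_group, food_truth, tags = tags)
    truth_mat <- do.call(rbind, truth_list)
    rownames(truth_mat) <- foods$foodex2
    lz_list <- lapply(truth_list, attr, "logical_zero")
    ground_truth <- tibble::tibble(
      foodex2 = rep(foods$foodex2, each = length(tags)),
      tagname = rep(tags, n),
      value = as.vector(t(truth_mat)),
      logical_zero = unlist(lapply(lz_list, function(l) tags %in% l))
    )

    n_shared <- round(spec$overlap_fraction * n)
    shared_idx <- seq_len(n_shared)
    rest <- setdiff(seq_len(n), shared_idx)
    rest_owner <- if (length(rest)) ((seq_along(rest) - 1L) %% spec$n_sources) + 1L else integer()

    std_unit <- resolve_component(registry, tags)$standard_unit
    cls <- resolve_component(registry, tags)$component_class
    tables <- list()
    mappings <- list()
    labels <- list()
    for (s in seq_len(spec$n_sources)) {
      sid <- sprintf("S%02d", s)
      idx <- sort(c(shared_idx, rest[rest_owner == s]))
      m <- length(idx)
      tr <- truth_mat[idx, , drop = FALSE]
      lzm <- do.call(rbind, lapply(lz_list[idx], function(l) tags %in% l))
      vals <- tr
      if (spec$noise_cv > 0) {
        sdlog <- sqrt(log(1 + spec$noise_cv^2))
        noise <- matrix(stats::rlnorm(m * length(tags), -sdlog^2 / 2, sdlog),
                        nrow = m)
        vals <- tr * noise
      }
      vals[lzm] <- 0
      eligible <- tr > 0 & !lzm
      u <- matrix(stats::runif(m * length(tags)), nrow = m)
      plant_zero <- eligible & u < spec$zero_rate
      plant_out <- eligible & !plant_zero &
        u < spec$zero_rate + spec$outlier_rate
      vals[plant_zero] <- 0
      vals[plant_out] <- vals[plant_out] * spec$outlier_k

      food_ids <- sprintf("%s_%04d", sid, idx)
      lab <- function(mask, type) {
        w <- which(mask, arr.ind = TRUE)
        if (nrow(w) == 0L) return(NULL)
        tibble::tibble(source_id = sid, original_food_id = food_ids[w[, 1]],
                       foodex2 = foods$foodex2[idx][w[, 1]],
                       tagname = tags[w[, 2]], type = type)
      }
      labels <- c(labels, list(lab(plant_zero, "planted_zero"),
                               lab(plant_out, "planted_outlier")))

      emit_unit <- std_unit
      scramble <- spec$unit_scramble && s %% 2 == 0
      if (scramble) {
        emit_unit[cls == "mineral" & std_unit == "mg"] <- "g"
        emit_unit[cls == "mineral" & std_unit == "ug"] <- "mg"
      }
      for (j in seq_along(tags)) {
        if (emit_unit[j] != std_unit[j]) {
          vals[, j] <- convert_value(vals[, j], std_unit[j], emit_unit[j])
        }
      }
      tab <- data.frame(
        food_id = food_ids,
        name = foods$name[idx],
        foodex2 = foods$foodex2[idx],
        food_group = foods$food_group[idx],
        cooking_method = foods$cooking_method[idx],
        edible_portion = foods$edible_portion[idx],
        record_class = "generic",
        stringsAsFactors = FALSE,
        check.names = FALSE
      )
      valdf <- as.data.frame(vals)
      names(valdf) <- tolower(tags)
      tab <- cbind(tab, valdf)
      tables[[sid]] <- tab
      mappings[[sid]] <- source_mapping(
        source_id = sid,
        columns = tibble::tibble(column = tolower(tags), tagname = tags,
                                 unit = emit_unit),
        id_column = "food_id", foodex2_column = "foodex2",
        name_column = "name", group_column = "food_group",
        cooking_method_column = "cooking_method",
        edible_portion_column = "edible_portion",
        record_class_column = "record_class",
        basis = "per_100g",
        zero_is_logical = s %% 2 == 1
      )
    }
    sources <- tibble::tibble(
      source_id = names(tables),
      name = sprintf("Synthetic source %s", names(tables)),
      country_or_org = "synthetic",
      version_date = "2026-01-01",
      notes = sprintf("generated fixture, seed %d", spec$seed)
    )
    structure(list(spec = spec, components = tags, foods = foods,
                   ground_truth = ground_truth, tables = tables,
                   mappings = mappings, sources = sources,
                   defect_labels = dplyr::bind_rows(labels)),
              class = "fcdb_fixture")
  })
}

#' Harmonize all sources of a fixture
#'
#' Convenience wrapper: ingests every source table with its mapping and
#' binds the harmonized records.
#'
#' @param fx A `fcdb_fixture`.
#' @param registry Component registry.
#' @return A `fcdb_records`.
#' @export
harmonize_fixture <- function(fx, registry = default_registry()) {
  stopifnot(inherits(fx, "fcdb_fixture"))
  bind_records(lapply(names(fx$tables), function(sid) {
    ingest_source(fx$tables[[sid]], fx$mappings[[sid]], registry)
  }))
}

#' Write a fixture to disk
#'
#' Emits one CSV per source (full numeric precision), one YAML mapping per
#' source, and the ground truth / defect labels as JSON.
#'
#' @param fx A `fcdb_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(fx$tables)) {
    tab <- fx$tables[[sid]]
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
    utils::write.csv(tab, file.path(dir, paste0(sid, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
    write_source_mapping(fx$mappings[[sid]],
                         file.path(dir, paste0(sid, ".yaml")))
  }
  jsonlite::write_json(fx$ground_truth,
                       file.path(dir, "ground_truth.json"), digits = NA)
  jsonlite::write_json(fx$defect_labels,
                       file.path(dir, "defect_labels.json"), digits = NA)
  jsonlite::write_json(fx$sources, file.path(dir, "sources.json"),
                       digits = NA)
  invisible(dir)
}

# Independent straight-line recipe oracle: plain scalar loops over
# ingredients and components, with its own factor-precedence scan. Used to
# compute the expected results attached to generated recipes.
straight_line_recipe <- function(recipe, db, yf_table, rf_table) {
  ing <- recipe$ingredients
  yf <- recipe$yf_override
  if (is.null(yf)) {
    yf <- NA_real_
    for (g in c("ANY")) {
      rowsel <- yf_table$food_group == g &
        yf_table$cooking_method == recipe$cooking_method
      if (any(rowsel)) { yf <- yf_table$yf[which(rowsel)[1]]; break }
    }
  }
  totals <- list()
  n_present <- list()
  sum_w <- 0
  for (i in seq_len(nrow(ing))) {
    fi <- which(db$foods$foodex2 == toupper(ing$foodex2[i]))[1]
    ep <- ing$edible_portion[i]
    if (is.na(ep)) ep <- db$foods$edible_portion[fi]
    if (is.na(ep)) ep <- 1
    w <- ing$raw_weight[i] * ep
    sum_w <- sum_w + w
    vals <- db$values[db$values$foodex2 == db$foods$foodex2[fi] &
                        db$values$basis == db$foods$basis[fi], ]
    for (j in seq_len(nrow(vals))) {
      tag <- vals$tagname[j]
      klass <- vals$component_class[j]
      grp <- db$foods$food_group[fi]
      rf <- 1
      for (cand in list(c(tag, "tagname", grp), c(tag, "tagname", "ANY"),
                        c(klass, "class", grp), c(klass, "class", "ANY"))) {
        sel <- rf_table$component == cand[1] & rf_table$level == cand[2] &
          rf_table$food_group == cand[3] &
          rf_table$cooking_method == recipe$cooking_method
        if (any(sel)) { rf <- rf_table$rf[which(sel)[1]]; break }
      }
      add <- (w / 100) * vals$chosen[j] * rf
      totals[[tag]] <- (totals[[tag]] %||% 0) + add
      n_present[[tag]] <- (n_present[[tag]] %||% 0L) + 1L
    }
  }
  cooked <- yf * sum_w
  tagnames <- sort(names(totals))
  tibble::tibble(
    tagname = tagnames,
    per_total = unlist(totals[tagnames], use.names = FALSE),
    per_100g = 100 * unlist(totals[tagnames], use.names = FALSE) / cooked,
    total_cooked_weight = cooked,
    n_ingredients_present = unlist(n_present[tagnames], use.names = FALSE)
  )
}

#' Generate random recipes with closed-form expected results
#'
#' Draws recipes (1-6 ingredients, raw weights 20-300 g, a cooking method
#' from the yield-factor table, edible-portion overrides for half the
#' ingredients) against a unified database, and attaches the expected
#' result of each computed by an independent straight-line implementation
#' of the mixed-method formula — the test oracle for the recipe engine.
#'
#' @param db A `fcdb_unified`.
#' @param n Number of recipes.
#' @param seed Integer seed (deterministic output).
#' @param yf_table,rf_table Factor tables.
#' @return List with `recipes` (list of [recipe()]) and `expected`
#'   (parallel list of expectation tables).
#' @export
generate_recipes <- function(db, n, seed = 1,
                             yf_table = default_yield_factors(),
                             rf_table = default_retention_factors()) {
  stopifnot(inherits(db, "fcdb_unified"), nrow(db$foods) > 0)
  methods <- unique(yf_table$cooking_method[yf_table$food_group == "ANY"])
  withr::with_seed(as.integer(seed), {
    recipes <- vector("list", n)
    expected <- vector("list", n)
    for (r in seq_len(n)) {
      k <- sample(seq_len(min(6L, nrow(db$foods))), 1L)
      pick <- sample(nrow(db$foods), k)
      ing <- tibble::tibble(
        foodex2 = db$foods$foodex2[pick],
        raw_weight = stats::runif(k, 20, 300),
        edible_portion = ifelse(stats::runif(k) < 0.5, NA_real_,
                                stats::runif(k, 0.6, 1))
      )
      rec <- recipe(sprintf("R%03d", r), sprintf("Synthetic recipe %03d", r),
                    cooking_method = sample(methods, 1L), ingredients = ing)
      recipes[[r]] <- rec
      expected[[r]] <- straight_line_recipe(rec, db, yf_table, rf_table)
    }
    list(recipes = recipes, expected = expected)
  })
}

#' Plant labelled quality-control defects into a clean database
#'
#' Corrupts a unified database with violations of each rule-based check,
#' returning the corrupted database and an exhaustive label set (check_id,
#' foodex2, tagname). Plants are constructed not to trip other checks:
#' when fat is altered, water absorbs the difference so the proximate sum
#' stays put.
#'
#' @param db A clean `fcdb_unified` (no findings under [run_suite()]).
#' @param n_per_check Plants per check.
#' @param seed Integer seed.
#' @return List with `db` (corrupted) and `labels`.
#' @export
plant_defects <- function(db, n_per_check = 2, seed = 1) {
  stopifnot(inherits(db, "fcdb_unified"))
  get_chosen <- function(code, tag) {
    i <- which(db$values$foodex2 == code & db$values$tagname == tag)
    if (length(i)) db$values$chosen[i[1]] else NA_real_
  }
  set_chosen <- function(code, tag, value) {
    i <- which(db$values$foodex2 == code & db$values$tagname == tag)
    stopifnot(length(i) >= 1L)
    db$values$chosen[i[1]] <<- value
  }
  drop_component <- function(code, tag) {
    keep <- !(db$values$foodex2 == code & db$values$tagname == tag)
    db$values <<- db$values[keep, ]
    keepc <- !(db$contributors$foodex2 == code &
                 db$contributors$tagname == tag)
    db$contributors <<- db$contributors[keepc, ]
  }
  withr::with_seed(as.integer(seed), {
    labels <- list()
    used <- character()
    pick_foods <- function(candidates, k) {
      candidates <- setdiff(candidates, used)
      stopifnot(length(candidates) >= k)
      out <- sample(candidates, k)
      used <<- c(used, out)
      out
    }
    has_tag <- function(tag, positive = TRUE) {
      v <- db$values[db$values$tagname == tag, ]
      if (positive) v <- v[v$chosen > 0, ]
      unique(v$foodex2)
    }

    # proximate sum pushed above 105 g
    for (code in pick_foods(has_tag("WATER"), n_per_check)) {
      set_chosen(code, "WATER", get_chosen(code, "WATER") + 12)
      labels <- c(labels, list(tibble::tibble(
        check_id = "proximate_sum", foodex2 = code, tagname = NA_character_)))
    }
    # (a) fat zeroed while fatty acids remain positive
    cand_a <- intersect(has_tag("FAT"), has_tag("FASAT"))
    for (code in pick_foods(cand_a, n_per_check)) {
      fat <- get_chosen(code, "FAT")
      set_chosen(code, "FAT", 0)
      set_chosen(code, "WATER", get_chosen(code, "WATER") + fat)
      labels <- c(labels, list(tibble::tibble(
        check_id = "implausible_fat_zero", foodex2 = code, tagname = "FAT")))
    }
    # (b) fat > 1 g with all fatty-acid / cholesterol detail removed;
    # restrict to foods whose cholesterol is a true zero so only the
    # fatty-acid rows need dropping
    chole0 <- unique(db$values$foodex2[db$values$tagname == "CHOLE" &
                                         db$values$chosen == 0])
    cand_b <- intersect(has_tag("FAT"), chole0)
    for (code in pick_foods(cand_b, n_per_check)) {
      fat <- get_chosen(code, "FAT")
      new_fat <- max(fat, 2)
      set_chosen(code, "FAT", new_fat)
      set_chosen(code, "WATER", get_chosen(code, "WATER") - (new_fat - fat))
      for (tag in c("FASAT", "FAMS", "FAPU")) drop_component(code, tag)
      labels <- c(labels, list(tibble::tibble(
        check_id = "implausible_fat_no_detail", foodex2 = code,
        tagname = "FAT")))
    }
    # (c) fiber planted into fish
    fish <- db$foods$foodex2[tolower(db$foods$food_group) == "fish"]
    fish <- intersect(fish, unique(db$values$foodex2[db$values$tagname == "FIBTG"]))
    for (code in pick_foods(fish, n_per_check)) {
      set_chosen(code, "FIBTG", 1.5)
      labels <- c(labels, list(tibble::tibble(
        check_id = "fiber_in_fish", foodex2 = code, tagname = "FIBTG")))
    }
    list(db = db, labels = dplyr::bind_rows(labels))
  })
}

#' Perturb a flat export
#'
#' Adds a small offset to randomly chosen numeric cells of a flat export
#' and returns the exact positions, for scoring [check_transfer()]'s
#' localization.
#'
#' @param flat A flat export (see [export_flat()]).
#' @param n Number of cells to perturb.
#' @param delta Offset added.
#' @param seed Integer seed.
#' @return List with `flat` (perturbed) and `labels` (foodex2, column).
#' @export
perturb_export <- function(flat, n = 1, delta = 0.001, seed = 1) {
  num_cols <- names(flat)[vapply(flat, is.numeric, TRUE)]
  withr::with_seed(as.integer(seed), {
    cells <- list()
    tries <- 0
    while (length(cells) < n && tries < 1000) {
      tries <- tries + 1
      i <- sample(nrow(flat), 1L)
      cl <- sample(num_cols, 1L)
      if (!is.na(flat[[cl]][i]) &&
            !any(vapply(cells, function(c) c$i == i && c$cl == cl, TRUE))) {
        cells <- c(cells, list(list(i = i, cl = cl)))
      }
    }
    labels <- list()
    for (c in cells) {
      flat[[c$cl]][c$i] <- flat[[c$cl]][c$i] + delta
      labels <- c(labels, list(tibble::tibble(
        foodex2 = flat$foodex2[c$i], column = c$cl)))
    }
    list(flat = flat, labels = dplyr::bind_rows(labels))
  })
}
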