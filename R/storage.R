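# File-backed relational store: eight interrelated tables persisted as a
# directory of delimited files with full numeric precision, referential
# integrity validated on read, and traceability from every unified value
# back to the contributing original source records. The schema is
# documented as portable SQL DDL in inst/extdata/fcdb_schema.sql.

.store_tables <- c("sources", "foods", "components", "component_values",
                   "yield_factors", "retention_factors", "recipes",
                   "recipe_ingredients")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_store_table <- function(df, path) {
  df <- as.data.frame(df)
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) {
      df[[cl]] <- fmt_num(df[[cl]])
    } else if (is.logical(df[[cl]])) {
      df[[cl]] <- ifelse(is.na(df[[cl]]), "", ifelse(df[[cl]], "TRUE", "FALSE"))
    } else {
      df[[cl]] <- ifelse(is.na(df[[cl]]), "", as.character(df[[cl]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
}

read_store_table <- function(path, numeric_cols = character(),
                             logical_cols = character()) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(), check.names = FALSE,
                        fileEncoding = "UTF-8")
  df <- tibble::as_tibble(df)
  for (cl in intersect(numeric_cols, names(df))) {
    x <- df[[cl]]
    x[!nzchar(x)] <- NA
    df[[cl]] <- as.numeric(x)
  }
  for (cl in intersect(logical_cols, names(df))) {
    x <- df[[cl]]
    df[[cl]] <- ifelse(nzchar(x), x == "TRUE", NA)
  }
  for (cl in setdiff(names(df), c(numeric_cols, logical_cols))) {
    x <- df[[cl]]
    x[!nzchar(x)] <- NA
    df[[cl]] <- x
  }
  df
}

#' Write the relational store
#'
#' Persists a unified database (plus factor tables and recipes, when
#' given) into an eight-table relational layout under `path`:
#' sources, foods, components, component_values (one row per contributing
#' source value, carrying both the provenance and the unified statistics),
#' yield_factors, retention_factors, recipes and recipe_ingredients.
#' Numeric values are written with 17 significant digits so the round trip
#' is value-identical (verify with [check_transfer()]).
#'
#' @param db A `fcdb_unified`.
#' @param path Directory (created if needed).
#' @param registry Component registry (becomes the components table).
#' @param sources Optional source-metadata table (source_id, name,
#'   country_or_org, version_date, notes); derived from provenance when
#'   absent.
#' @param yf_table,rf_table Optional factor tables.
#' @param recipes Optional list of [recipe()] objects.
#' @return `path`, invisibly.
#' @export
store_write <- function(db, path, registry = default_registry(),
                        sources = NULL, yf_table = NULL, rf_table = NULL,
                        recipes = NULL) {
  stopifnot(inherits(db, "fcdb_unified"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sources)) {
    sids <- sort(unique(db$contributors$source_id))
    sources <- tibble::tibble(source_id = sids, name = sids,
                              country_or_org = NA_character_,
                              version_date = NA_character_,
                              notes = NA_character_)
  }
  used_tags <- unique(db$values$tagname)
  components <- registry[registry$tagname %in% used_tags, ]
  dangling <- setdiff(used_tags, components$tagname)
  if (length(dangling) > 0L) {
    rlang::abort(paste0("values reference unregistered tagname(s): ",
                        paste(dangling, collapse = ", ")),
                 class = "fcdb_schema_error")
  }

  stats_cols <- c("foodex2", "basis", "tagname", "n_sources", "mean",
                  "median", "sd", "chosen", "logical_zero", "outlier_flag",
                  "review_flag")
  vals <- db$values[, intersect(stats_cols, names(db$values))]
  contrib <- db$contributors
  cv <- dplyr::left_join(
    contrib[, c("foodex2", "basis", "tagname", "source_id",
                "original_food_id", "raw_value", "raw_unit", "value",
                "outlier_flag")],
    vals[, setdiff(names(vals), "outlier_flag")],
    by = c("foodex2", "basis", "tagname")
  )
  names(cv)[names(cv) == "value"] <- "value_std"
  names(cv)[names(cv) == "outlier_flag"] <- "contributor_outlier_flag"
  # unified rows without contributors (reinstated logical zeros,
  # recalculated energy) keep their statistics with empty provenance
  no_contrib <- dplyr::anti_join(vals, contrib,
                                 by = c("foodex2", "basis", "tagname"))
  if (nrow(no_contrib) > 0L) {
    no_contrib$source_id <- NA_character_
    no_contrib$original_food_id <- NA_character_
    no_contrib$raw_value <- NA_real_
    no_contrib$raw_unit <- NA_character_
    no_contrib$value_std <- NA_real_
    no_contrib$contributor_outlier_flag <- NA
    no_contrib$outlier_flag <- NULL
    cv <- dplyr::bind_rows(cv, no_contrib)
  }
  cv <- dplyr::arrange(cv, .data$foodex2, .data$basis, .data$tagname,
                       .data$source_id, .data$original_food_id)

  rec_tbl <- tibble::tibble(recipe_id = character(), name = character(),
                            cooking_method = character(),
                            yf_override = numeric())
  ing_tbl <- tibble::tibble(recipe_id = character(), foodex2 = character(),
                            raw_weight = numeric(),
                            edible_portion = numeric())
  if (!is.null(recipes)) {
    rec_tbl <- dplyr::bind_rows(lapply(recipes, function(r) {
      tibble::tibble(recipe_id = r$recipe_id, name = r$name,
                     cooking_method = r$cooking_method,
                     yf_override = r$yf_override %||% NA_real_)
    }))
    ing_tbl <- dplyr::bind_rows(lapply(recipes, function(r) {
      tibble::tibble(recipe_id = r$recipe_id,
                     foodex2 = r$ingredients$foodex2,
                     raw_weight = r$ingredients$raw_weight,
                     edible_portion = r$ingredients$edible_portion)
    }))
  }
  tabs <- list(
    sources = sources,
    foods = dplyr::arrange(db$foods, .data$foodex2, .data$basis),
    components = components,
    component_values = cv,
    yield_factors = yf_table %||% default_yield_factors()[0, ],
    retention_factors = rf_table %||% default_retention_factors()[0, ],
    recipes = rec_tbl,
    recipe_ingredients = ing_tbl
  )
  for (nm in .store_tables) {
    write_store_table(tabs[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  ddl <- system.file("extdata", "fcdb_schema.sql", package = "fcdbkit")
  if (nzchar(ddl)) file.copy(ddl, file.path(path, "schema.sql"),
                             overwrite = TRUE)
  invisible(path)
}

#' Read the relational store back
#'
#' Reads the eight tables, validates referential integrity (every
#' component_values row must reference an existing food and component, and
#' a registered source unless it is a provenance-free reinstated value),
#' and reconstructs the `fcdb_unified` object. Integrity violations are
#' schema errors naming the offending keys.
#'
#' @param path Store directory.
#' @return List with `db` (`fcdb_unified`), and the raw `tables`.
#' @export
store_read <- function(path) {
  files <- file.path(path, paste0(.store_tables, ".csv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    rlang::abort(paste0("store is missing table(s): ",
                        paste(.store_tables[missing], collapse = ", ")),
                 class = "fcdb_io_error")
  }
  tabs <- list(
    sources = read_store_table(files[1]),
    foods = read_store_table(files[2],
                             numeric_cols = c("edible_portion", "n_records",
                                              "n_source_dbs"),
                             logical_cols = "matched"),
    components = read_store_table(files[3]),
    component_values = read_store_table(
      files[4],
      numeric_cols = c("raw_value", "value_std", "n_sources", "mean",
                       "median", "sd", "chosen"),
      logical_cols = c("contributor_outlier_flag", "logical_zero",
                       "review_flag")
    ),
    yield_factors = read_store_table(files[5], numeric_cols = "yf"),
    retention_factors = read_store_table(files[6], numeric_cols = "rf"),
    recipes = read_store_table(files[7], numeric_cols = "yf_override"),
    recipe_ingredients = read_store_table(
      files[8], numeric_cols = c("raw_weight", "edible_portion"))
  )
  cv <- tabs$component_values
  food_key <- paste(tabs$foods$foodex2, tabs$foods$basis)
  bad <- !paste(cv$foodex2, cv$basis) %in% food_key
  if (any(bad)) {
    rlang::abort(paste0("component_values references unknown food(s): ",
                        paste(unique(cv$foodex2[bad]), collapse = ", ")),
                 class = "fcdb_schema_error")
  }
  bad <- !cv$tagname %in% tabs$components$tagname
  if (any(bad)) {
    rlang::abort(paste0("component_values references unknown component(s): ",
                        paste(unique(cv$tagname[bad]), collapse = ", ")),
                 class = "fcdb_schema_error")
  }
  has_src <- !is.na(cv$source_id)
  bad <- has_src & !cv$source_id %in% tabs$sources$source_id
  if (any(bad)) {
    rlang::abort(paste0("component_values references unknown source(s): ",
                        paste(unique(cv$source_id[bad]), collapse = ", ")),
                 class = "fcdb_schema_error")
  }
  if (nrow(tabs$recipe_ingredients) > 0L) {
    bad <- !tabs$recipe_ingredients$recipe_id %in% tabs$recipes$recipe_id
    if (any(bad)) {
      rlang::abort("recipe_ingredients references unknown recipe(s)",
                   class = "fcdb_schema_error")
    }
  }

  cls <- tabs$components$component_class[match(cv$tagname,
                                               tabs$components$tagname)]
  cv$component_class <- cls
  stats_cols <- c("foodex2", "basis", "tagname", "component_class",
                  "n_sources", "mean", "median", "sd", "chosen",
                  "logical_zero", "review_flag")
  values <- dplyr::distinct(cv[, stats_cols])
  contrib <- cv[has_src, c("foodex2", "basis", "tagname", "source_id",
                           "original_food_id", "value_std", "raw_value",
                           "raw_unit", "contributor_outlier_flag")]
  names(contrib)[names(contrib) == "value_std"] <- "value"
  names(contrib)[names(contrib) == "contributor_outlier_flag"] <- "outlier_flag"
  flagged <- contrib |>
    dplyr::group_by(.data$foodex2, .data$basis, .data$tagname) |>
    dplyr::summarise(outlier_flag = any(.data$outlier_flag), .groups = "drop")
  values <- dplyr::left_join(values, flagged,
                             by = c("foodex2", "basis", "tagname"))
  values$outlier_flag[is.na(values$outlier_flag)] <- FALSE
  values$n_sources <- as.integer(values$n_sources)
  db <- structure(
    list(foods = tabs$foods,
         values = dplyr::arrange(values, .data$foodex2, .data$basis,
                                 .data$tagname),
         contributors = dplyr::arrange(contrib, .data$foodex2, .data$basis,
                                       .data$tagname, .data$source_id,
                                       .data$original_food_id),
         report = NULL),
    class = "fcdb_unified"
  )
  db$report <- list(
    n_foods = nrow(db$foods), n_matched = sum(db$foods$matched),
    n_singleton = sum(!db$foods$matched), n_values = nrow(db$values),
    n_flagged_contributors = sum(db$contributors$outlier_flag),
    n_review_components = sum(db$values$review_flag)
  )
  list(db = db, tables = tabs)
}

#' Flat (wide) export of a unified database
#'
#' One row per food, one column per tagname holding the chosen value —
#' the spreadsheet-shaped view used for transfer checking and for
#' downstream consumers.
#'
#' @param db A `fcdb_unified`.
#' @return A tibble.
#' @export
export_flat <- function(db) {
  stopifnot(inherits(db, "fcdb_unified"))
  wide <- db$values |>
    dplyr::select("foodex2", "basis", "tagname", "chosen") |>
    dplyr::arrange(.data$tagname) |>
    tidyr::pivot_wider(names_from = "tagname", values_from = "chosen")
  out <- dplyr::left_join(
    db$foods[, c("foodex2", "basis", "name", "food_group", "matched",
                 "edible_portion")],
    wide, by = c("foodex2", "basis")
  )
  dplyr::arrange(out, .data$foodex2, .data$basis)
}

#' Write / read a flat export at full precision
#'
#' @param flat A flat export table.
#' @param path CSV path.
#' @return `read_flat()` returns the tibble with numeric columns restored
#'   bit-exactly.
#' @export
write_flat <- function(flat, path) {
  write_store_table(flat, path)
  invisible(path)
}

#' @rdname write_flat
#' @export
read_flat <- function(path) {
  df <- read_store_table(path, logical_cols = "matched")
  meta <- c("foodex2", "basis", "name", "food_group", "matched")
  for (cl in setdiff(names(df), meta)) {
    x <- df[[cl]]
    x[is.na(x)] <- ""
    x[!nzchar(x)] <- NA
    df[[cl]] <- as.numeric(x)
  }
  df
}

#' Trace a unified value to its sources
#'
#' Returns, for a food (optionally one component), the contributing
#' original records: source, verbatim original food id, the value in the
#' source's original unit, and the standardized value that entered the
#' unification pool.
#'
#' @param db A `fcdb_unified`.
#' @param foodex2 FoodEx2 code.
#' @param tagname Optional tagname filter.
#' @param sources Optional source-metadata table to attach source names.
#' @return Provenance tibble (one row per contributing value).
#' @export
trace_value <- function(db, foodex2, tagname = NULL, sources = NULL) {
  stopifnot(inherits(db, "fcdb_unified"))
  code <- canonical_foodex2(foodex2)
  out <- db$contributors[db$contributors$foodex2 == code, ]
  if (!is.null(tagname)) out <- out[out$tagname %in% tagname, ]
  if (nrow(out) == 0L) {
    known <- code %in% db$values$foodex2
    if (!known) {
      rlang::abort(sprintf("no such food/value in database: %s", code),
                   class = "fcdb_not_found")
    }
  }
  if (!is.null(sources)) {
    out <- dplyr::left_join(out,
                            sources[, c("source_id", "name")],
                            by = "source_id")
    names(out)[names(out) == "name"] <- "source_name"
  }
  dplyr::arrange(out, .data$tagname, .data$source_id)
}
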