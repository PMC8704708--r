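# Ingestion: read one source table with its mapping configuration, apply
# unit conversion to each mapped component, and emit harmonized records.
# Original identifiers are kept verbatim for traceability; rows that cannot
# be keyed (unparseable FoodEx2 code) are rejected to the log, never
# silently dropped.

.record_classes <- c("generic", "branded", "fortified", "supplement",
                     "recipe_or_dish")
.excluded_classes <- c("branded", "fortified", "supplement", "recipe_or_dish")
.value_statuses <- c("measured", "zero", "logical_zero", "trace", "missing")

#' Source mapping configuration
#'
#' Describes how one source table maps onto the harmonized model: which
#' column holds the source's own food identifier (kept verbatim), which
#' holds the FoodEx2 code, and how each component column maps to a
#' registered tagname and the unit the source reports it in.
#'
#' @param source_id Token identifying the source database.
#' @param columns Data frame with columns `column`, `tagname`, `unit`: one
#'   row per component column of the source table.
#' @param id_column,foodex2_column Mandatory metadata columns.
#' @param name_column,english_name_column,group_column,cooking_method_column,
#'   edible_portion_column,record_class_column Optional metadata columns.
#' @param basis `"per_100g"` or `"per_100mL"`; bases are never
#'   interconverted.
#' @param zero_is_logical If `TRUE`, a literal 0 in this source is a
#'   compiler-reviewed logical zero (true absence) rather than a
#'   missing-coded-as-zero.
#' @param decimal_mark `"."` or `","` (sources from different countries
#'   realistically differ).
#' @return A `fcdb_mapping` object.
#' @export
source_mapping <- function(source_id, columns, id_column, foodex2_column,
                           name_column = NULL, english_name_column = NULL,
                           group_column = NULL, cooking_method_column = NULL,
                           edible_portion_column = NULL,
                           record_class_column = NULL,
                           basis = c("per_100g", "per_100mL"),
                           zero_is_logical = FALSE, decimal_mark = ".") {
  basis <- match.arg(basis)
  stopifnot(is.character(source_id), length(source_id) == 1L, nzchar(source_id))
  if (missing(id_column) || missing(foodex2_column)) {
    rlang::abort("id_column and foodex2_column are mandatory",
                 class = "fcdb_mapping_error")
  }
  columns <- tibble::as_tibble(columns)
  stopifnot(all(c("column", "tagname", "unit") %in% names(columns)))
  columns$unit <- normalize_unit(columns$unit)
  if (anyDuplicated(columns$column)) {
    rlang::abort("duplicate source columns in mapping",
                 class = "fcdb_mapping_error")
  }
  structure(
    list(source_id = source_id, columns = columns,
         id_column = id_column, foodex2_column = foodex2_column,
         name_column = name_column, english_name_column = english_name_column,
         group_column = group_column,
         cooking_method_column = cooking_method_column,
         edible_portion_column = edible_portion_column,
         record_class_column = record_class_column,
         basis = basis, zero_is_logical = isTRUE(zero_is_logical),
         decimal_mark = decimal_mark),
    class = "fcdb_mapping"
  )
}

#' Read / write a source mapping as YAML or JSON
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param mapping A `fcdb_mapping`.
#' @return `read_source_mapping()` returns a `fcdb_mapping`.
#' @export
read_source_mapping <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  cols <- raw$columns
  if (!is.data.frame(cols)) {
    cols <- dplyr::bind_rows(lapply(cols, tibble::as_tibble))
  }
  source_mapping(
    source_id = raw$source_id, columns = cols,
    id_column = raw$id_column, foodex2_column = raw$foodex2_column,
    name_column = raw$name_column,
    english_name_column = raw$english_name_column,
    group_column = raw$group_column,
    cooking_method_column = raw$cooking_method_column,
    edible_portion_column = raw$edible_portion_column,
    record_class_column = raw$record_class_column,
    basis = raw$basis %||% "per_100g",
    zero_is_logical = isTRUE(raw$zero_is_logical),
    decimal_mark = raw$decimal_mark %||% "."
  )
}

#' @rdname read_source_mapping
#' @export
write_source_mapping <- function(mapping, path) {
  obj <- unclass(mapping)
  obj$columns <- lapply(seq_len(nrow(mapping$columns)), function(i) {
    as.list(mapping$columns[i, ])
  })
  obj <- obj[!vapply(obj, is.null, TRUE)]
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Read a delimited source table
#'
#' Reads CSV/TSV with all columns as character so that original identifiers
#' and number formats are preserved verbatim for parsing under the mapping's
#' decimal-mark convention. Empty strings are kept (never promoted to NA):
#' the sodium tagname is literally `NA`, so missing markers are handled
#' explicitly downstream.
#'
#' @param path File path; `.tsv`/`.tab` read as tab-separated, else CSV.
#' @return A character data frame.
#' @export
read_source_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::read.csv(path, sep = sep, colClasses = "character",
                  na.strings = character(), check.names = FALSE,
                  fileEncoding = "UTF-8")
}

# Parse one component column. Character cells honour the source's decimal
# mark; "tr"/"trace" mark trace amounts (computed as 0, stored distinctly).
parse_value_column <- function(x, decimal_mark) {
  if (is.numeric(x)) {
    return(list(value = as.numeric(x), trace = rep(FALSE, length(x)),
                unparseable = rep(FALSE, length(x))))
  }
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  trace <- tolower(x) %in% c("tr", "trace")
  y <- x
  if (decimal_mark == ",") {
    y <- gsub(".", "", y, fixed = TRUE)  # thousands separator
    y <- gsub(",", ".", y, fixed = TRUE)
  }
  val <- suppressWarnings(as.numeric(y))
  val[trace] <- 0
  unparseable <- !trace & is.na(val) & nzchar(x)
  list(value = val, trace = trace, unparseable = unparseable)
}

#' Ingest a source table into harmonized records
#'
#' Applies the source mapping: every component value is converted to its
#' tagname's standard unit with [convert_value()]; blank cells become
#' `missing`, literal zeros become `zero` (or `logical_zero` when the
#' mapping declares `zero_is_logical`); rows whose FoodEx2 code does not
#' parse, or that contain a negative value, are rejected to the ingestion
#' log with a reason — never silently dropped.
#'
#' @param table Data frame, or path to a delimited file (see
#'   [read_source_table()]).
#' @param mapping A [source_mapping()].
#' @param registry A component registry; every mapped tagname must resolve
#'   and its unit must be dimensionally compatible with the source unit.
#' @return A `fcdb_records` object: list with
#'   * `foods`: one row per kept record (source_id, original_food_id,
#'     original_name, english_name, foodex2, food_group, cooking_method,
#'     basis, edible_portion, record_class);
#'   * `values`: long table of component values (standard units, with the
#'     verbatim raw value and unit retained for traceability);
#'   * `log`: ingestion log (source_id, original_food_id, action, reason).
#' @export
ingest_source <- function(table, mapping, registry) {
  stopifnot(inherits(mapping, "fcdb_mapping"))
  if (is.character(table) && length(table) == 1L) {
    table <- read_source_table(table)
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)

  mandatory <- c(mapping$id_column, mapping$foodex2_column, mapping$columns$column)
  missing_cols <- setdiff(mandatory, names(table))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("source table is missing mapped column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "fcdb_mapping_error")
  }
  # mapped tagnames must resolve; units must be convertible to the standard
  defs <- resolve_component(registry, mapping$columns$tagname)
  comp <- units_compatible(mapping$columns$unit, defs$standard_unit)
  if (!all(comp)) {
    rlang::abort(paste0("mapping declares incompatible unit(s) for: ",
                        paste(mapping$columns$tagname[!comp], collapse = ", ")),
                 class = "fcdb_mapping_error")
  }

  n <- nrow(table)
  get_col <- function(colname, default = NA_character_) {
    if (is.null(colname) || !colname %in% names(table)) {
      rep(default, n)
    } else {
      as.character(table[[colname]])
    }
  }
  original_food_id <- as.character(table[[mapping$id_column]])
  foodex2_raw <- as.character(table[[mapping$foodex2_column]])
  code_ok <- is_foodex2_code(foodex2_raw)

  ep_raw <- get_col(mapping$edible_portion_column)
  ep <- suppressWarnings(as.numeric(gsub(",", ".", ep_raw, fixed = TRUE)))
  ep[is.na(ep_raw) | !nzchar(trimws(ep_raw))] <- 1
  if (is.null(mapping$edible_portion_column)) ep <- rep(1, n)
  ep_ok <- !is.na(ep) & ep > 0 & ep <= 1

  # parse all component columns up front so negative values can reject rows
  parsed <- lapply(seq_len(nrow(mapping$columns)), function(i) {
    parse_value_column(table[[mapping$columns$column[i]]], mapping$decimal_mark)
  })
  neg_row <- rep(FALSE, n)
  for (p in parsed) neg_row <- neg_row | (!is.na(p$value) & p$value < 0)

  keep <- code_ok & ep_ok & !neg_row
  reason <- dplyr::case_when(
    !code_ok ~ "invalid_code",
    neg_row ~ "negative_value",
    !ep_ok ~ "invalid_edible_portion",
    TRUE ~ NA_character_
  )
  log <- tibble::tibble(
    source_id = mapping$source_id,
    original_food_id = original_food_id[!keep],
    action = "rejected",
    reason = reason[!keep]
  )

  record_class <- get_col(mapping$record_class_column, "generic")
  record_class[is.na(record_class) | !nzchar(record_class)] <- "generic"
  cooking <- get_col(mapping$cooking_method_column)
  name <- get_col(mapping$name_column)
  name[is.na(name)] <- original_food_id[is.na(name)]
  english <- get_col(mapping$english_name_column)
  english[is.na(english)] <- name[is.na(english)]

  foods <- tibble::tibble(
    source_id = mapping$source_id,
    original_food_id = original_food_id,
    original_name = name,
    english_name = english,
    foodex2 = canonical_foodex2(foodex2_raw),
    food_group = get_col(mapping$group_column, ""),
    cooking_method = cooking,
    basis = mapping$basis,
    edible_portion = ep,
    record_class = record_class
  )[keep, ]
  if (anyDuplicated(foods[c("source_id", "original_food_id")])) {
    rlang::abort(sprintf("duplicate original_food_id within source '%s'",
                         mapping$source_id),
                 class = "fcdb_duplicate_id")
  }

  vals <- lapply(seq_len(nrow(mapping$columns)), function(i) {
    p <- parsed[[i]]
    tag <- mapping$columns$tagname[i]
    from_unit <- mapping$columns$unit[i]
    std_unit <- defs$standard_unit[i]
    raw_value <- p$value[keep]
    trace <- p$trace[keep]
    unp <- p$unparseable[keep]
    status <- rep("measured", sum(keep))
    status[is.na(raw_value) | unp] <- "missing"
    status[trace] <- "trace"
    zero <- !is.na(raw_value) & raw_value == 0 & !trace
    status[zero] <- if (mapping$zero_is_logical) "logical_zero" else "zero"
    value <- convert_value(raw_value, from_unit, std_unit)
    value[status == "missing"] <- NA_real_
    tibble::tibble(
      source_id = mapping$source_id,
      original_food_id = original_food_id[keep],
      foodex2 = canonical_foodex2(foodex2_raw[keep]),
      basis = mapping$basis,
      tagname = tag,
      status = status,
      value = value,
      raw_value = raw_value,
      raw_unit = from_unit
    )
  })
  values <- dplyr::bind_rows(vals)
  n_unp <- sum(vapply(parsed, function(p) sum(p$unparseable[keep]), 0L))
  if (n_unp > 0L) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      source_id = mapping$source_id, original_food_id = NA_character_,
      action = "values_dropped",
      reason = sprintf("unparseable_cells:%d", n_unp)
    ))
  }
  new_fcdb_records(foods, values, log)
}

new_fcdb_records <- function(foods, values, log) {
  structure(list(foods = foods, values = values, log = log),
            class = "fcdb_records")
}

#' Combine harmonized record sets from several sources
#'
#' @param ... `fcdb_records` objects (or a single list of them).
#' @return A single `fcdb_records`.
#' @export
bind_records <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "fcdb_records")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, TRUE, "fcdb_records")))
  new_fcdb_records(
    foods = dplyr::bind_rows(lapply(parts, `[[`, "foods")),
    values = dplyr::bind_rows(lapply(parts, `[[`, "values")),
    log = dplyr::bind_rows(lapply(parts, `[[`, "log"))
  )
}

#' Write / read harmonized records as JSON
#'
#' Full-precision JSON serialization of a `fcdb_records` (foods, values,
#' ingestion log), the exchange format between the `ingest` and `unify`
#' pipeline stages.
#'
#' @param records A `fcdb_records`.
#' @param path JSON path.
#' @return `read_records()` returns a `fcdb_records`.
#' @export
write_records <- function(records, path) {
  stopifnot(inherits(records, "fcdb_records"))
  jsonlite::write_json(list(foods = records$foods, values = records$values,
                            log = records$log),
                       path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  raw <- jsonlite::fromJSON(path)
  as_chr <- function(df, cols) {
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.character(df[[cl]])
    df
  }
  foods <- tibble::as_tibble(raw$foods)
  values <- tibble::as_tibble(raw$values)
  log <- tibble::as_tibble(raw$log)
  if (nrow(log) == 0L) {
    log <- tibble::tibble(source_id = character(),
                          original_food_id = character(),
                          action = character(), reason = character())
  }
  new_fcdb_records(foods, values, log)
}

#' Exclude non-generic records
#'
#' Fortified foods, dietary supplements, branded commercial products and
#' recipes/prepared dishes are excluded from database construction; generic
#' records — including cooked foods and generic unbranded processed foods —
#' are kept. Unknown record classes are kept and logged. Kept and excluded
#' partition the input exactly.
#'
#' @param records A `fcdb_records`.
#' @return List with `kept` (`fcdb_records`), `excluded` (food rows with a
#'   `reason` column naming the class), and `log`.
#' @export
apply_exclusion_filter <- function(records) {
  stopifnot(inherits(records, "fcdb_records"))
  foods <- records$foods
  excl <- foods$record_class %in% .excluded_classes
  unknown <- !foods$record_class %in% .record_classes
  log <- records$log
  if (any(unknown)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      source_id = foods$source_id[unknown],
      original_food_id = foods$original_food_id[unknown],
      action = "kept_unknown_class",
      reason = foods$record_class[unknown]
    ))
  }
  excluded <- foods[excl, ]
  excluded$reason <- excluded$record_class
  kept_foods <- foods[!excl, ]
  key <- function(df) paste(df$source_id, df$original_food_id, sep = "\r")
  kept_values <- records$values[key(records$values) %in% key(kept_foods), ]
  if (nrow(excluded) > 0L) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      source_id = excluded$source_id,
      original_food_id = excluded$original_food_id,
      action = "excluded",
      reason = excluded$reason
    ))
  }
  list(kept = new_fcdb_records(kept_foods, kept_values, log),
       excluded = excluded, log = log)
}

#' @export
print.fcdb_records <- function(x, ...) {
  cat(sprintf("<fcdb_records> %d records from %d source(s), %d values (%d measured)\n",
              nrow(x$foods), length(unique(x$foods$source_id)),
              nrow(x$values), sum(x$values$status == "measured")))
  invisible(x)
}
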