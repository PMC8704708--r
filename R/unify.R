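# Unification: match harmonized records across sources by FoodEx2 code,
# remove zeros from the pool, compute per-component statistics, and take
# the median as the consensus value. Zeros coded as logical zeros (true
# absence) are removed from the pool like any zero but reinstated as a
# chosen value of 0 when no source measured the component.

#' Deterministic half-up rounding
#'
#' `round_half_up()` rounds to `digits` decimals with ties away from zero;
#' `signif_half_up()` rounds to `sig` significant figures the same way.
#' Unlike [round()], which ties to even, these are the compilation
#' conventions used for published food composition values.
#'
#' @param x Numeric vector.
#' @param digits,sig Integer scalars.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @export
signif_half_up <- function(x, sig = 3) {
  out <- x
  ok <- is.finite(x) & x != 0
  d <- sig - 1L - floor(log10(abs(x[ok])))
  out[ok] <- round_half_up(x[ok], d)
  out
}

#' Standard rounding of a chosen value
#'
#' Proximates and energy are rounded to 1 decimal; minerals, vitamins,
#' fatty acids, sterols, polyphenols and other components to 3 significant
#' figures. Rounding is half-up and deterministic.
#'
#' @param value Non-negative numeric vector.
#' @param component_class Character vector of component classes (recycled).
#' @return Rounded numeric vector.
#' @examples
#' round_standard(3.1416, "proximate")   # 3.1
#' round_standard(0.012345, "mineral")   # 0.0123
#' @export
round_standard <- function(value, component_class) {
  coarse <- component_class %in% c("proximate", "energy")
  out <- value
  out[coarse] <- round_half_up(value[coarse], 1)
  out[!coarse] <- signif_half_up(value[!coarse], 3)
  out
}

#' Clean zeros before unification
#'
#' Zeros are eliminated from the unification pool and treated as missing,
#' so that a missing value miscoded as 0 cannot drag the consensus down.
#' `status = "zero"` becomes `"missing"`; `status = "logical_zero"` rows are
#' kept distinct (they are excluded from the pool too, but reinstated as a
#' chosen 0 when all contributing sources coded the component as a logical
#' zero).
#'
#' @param values Component-value table with a `status` column (and `value`).
#' @return The table with zero statuses recoded to missing (value NA).
#' @export
clean_zeros <- function(values) {
  z <- values$status == "zero"
  values$status[z] <- "missing"
  values$value[z] <- NA_real_
  values
}

#' Unify one component pool
#'
#' Computes the consensus for one (food, component) pool of contributing
#' values (already zero-cleaned, all in the standard unit): sample median
#' (midpoint of the central pair when n is even) as the final value, with
#' mean and sample SD (n-1 denominator; 0 when n = 1) kept as diagnostics.
#'
#' @param pool Data frame with columns `source_id`, `original_food_id`,
#'   `value`; one row per contributing value.
#' @param component_class Class used by [round_standard()] for the chosen
#'   value.
#' @return `NULL` for an empty pool (the component stays missing);
#'   otherwise a list with `n_sources`, `mean`, `median`, `sd`, `chosen`
#'   and the `contributors` data frame.
#' @examples
#' pool <- data.frame(source_id = c("a", "b", "c"),
#'                    original_food_id = "1", value = c(2.8, 3.1, 3.5))
#' unify_component(pool, "proximate")$median  # 3.1
#' @export
unify_component <- function(pool, component_class = "other") {
  if (is.null(pool) || nrow(pool) == 0L) return(NULL)
  v <- pool$value
  stopifnot(!anyNA(v))
  med <- stats::median(v)
  list(
    n_sources = length(v),
    mean = mean(v),
    median = med,
    sd = if (length(v) > 1L) stats::sd(v) else 0,
    chosen = round_standard(med, component_class),
    contributors = pool[order(pool$source_id, pool$original_food_id), ,
                        drop = FALSE]
  )
}

#' Unify harmonized records into a consensus database
#'
#' Groups records by (FoodEx2 code, basis), zero-cleans each component
#' pool, computes mean/median/SD per component, and selects the rounded
#' median as the chosen value. Foods present in a single source pass
#' through with their own values; foods matched across >= 2 sources carry
#' `matched = TRUE`. The display name and food group of a unified food come
#' from the contributing record with the most non-missing components (ties
#' broken by lexicographic source id). Contributor provenance is retained
#' for every unified value. Robust outlier screening is applied via
#' [flag_outliers()].
#'
#' @param records A `fcdb_records` (typically after
#'   [apply_exclusion_filter()]).
#' @param registry Component registry used for rounding classes.
#' @param z_threshold,cv_threshold Outlier-screen thresholds, see
#'   [flag_outliers()].
#' @return A `fcdb_unified` object: list with `foods`, `values` (one row
#'   per unified component value), `contributors` (provenance), and a
#'   `report` (matched vs singleton counts, flag tallies).
#' @export
unify_database <- function(records, registry, z_threshold = 3.5,
                           cv_threshold = 2.0) {
  stopifnot(inherits(records, "fcdb_records"))
  vals <- clean_zeros(records$values)
  defs <- registry[, c("tagname", "component_class")]
  vals <- dplyr::left_join(vals, defs, by = "tagname")
  if (anyNA(vals$component_class)) {
    rlang::abort(paste0(
      "values reference unregistered tagname(s): ",
      paste(unique(vals$tagname[is.na(vals$component_class)]), collapse = ", ")
    ), class = "fcdb_unknown_tagname")
  }

  pool <- vals[vals$status %in% c("measured", "trace"), ]
  pool$value[pool$status == "trace"] <- 0  # trace computes as zero
  pool <- dplyr::arrange(pool, .data$foodex2, .data$basis, .data$tagname,
                         .data$source_id, .data$original_food_id)

  stats_tbl <- pool |>
    dplyr::group_by(.data$foodex2, .data$basis, .data$tagname,
                    .data$component_class) |>
    dplyr::summarise(
      n_sources = dplyr::n(),
      mean = mean(.data$value),
      median = stats::median(.data$value),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data$value), 0),
      .groups = "drop"
    )
  stats_tbl$chosen <- round_standard(stats_tbl$median, stats_tbl$component_class)
  stats_tbl$logical_zero <- FALSE

  # reinstate logical zeros where no source measured the component
  lz <- vals[vals$status == "logical_zero", ] |>
    dplyr::distinct(.data$foodex2, .data$basis, .data$tagname,
                    .data$component_class) |>
    dplyr::anti_join(stats_tbl, by = c("foodex2", "basis", "tagname"))
  if (nrow(lz) > 0L) {
    lz <- dplyr::mutate(lz, n_sources = 0L, mean = 0, median = 0, sd = 0,
                        chosen = 0, logical_zero = TRUE)
    stats_tbl <- dplyr::bind_rows(stats_tbl, lz)
  }
  stats_tbl <- dplyr::arrange(stats_tbl, .data$foodex2, .data$basis,
                              .data$tagname)

  # food-level metadata: name from the record with most non-missing values
  richness <- vals |>
    dplyr::group_by(.data$source_id, .data$original_food_id) |>
    dplyr::summarise(n_present = sum(.data$status != "missing"),
                     .groups = "drop")
  meta <- dplyr::left_join(records$foods, richness,
                           by = c("source_id", "original_food_id"))
  meta$n_present[is.na(meta$n_present)] <- 0L
  foods <- meta |>
    dplyr::group_by(.data$foodex2, .data$basis) |>
    dplyr::arrange(dplyr::desc(.data$n_present), .data$source_id,
                   .data$original_food_id, .by_group = TRUE) |>
    dplyr::summarise(
      name = dplyr::first(.data$english_name),
      food_group = dplyr::first(.data$food_group),
      cooking_method = dplyr::first(.data$cooking_method),
      edible_portion = stats::median(.data$edible_portion),
      n_records = dplyr::n(),
      n_source_dbs = dplyr::n_distinct(.data$source_id),
      matched = dplyr::n_distinct(.data$source_id) >= 2L,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$foodex2, .data$basis)

  contributors <- pool[, c("foodex2", "basis", "tagname", "source_id",
                           "original_food_id", "value", "raw_value",
                           "raw_unit")]

  db <- structure(
    list(foods = foods, values = stats_tbl, contributors = contributors,
         report = NULL),
    class = "fcdb_unified"
  )
  db <- flag_outliers(db, z_threshold = z_threshold,
                      cv_threshold = cv_threshold)
  db$report <- list(
    n_foods = nrow(foods),
    n_matched = sum(foods$matched),
    n_singleton = sum(!foods$matched),
    n_values = nrow(stats_tbl),
    n_flagged_contributors = sum(db$contributors$outlier_flag),
    n_review_components = sum(db$values$review_flag)
  )
  db
}

#' Robust outlier screening of unified values
#'
#' A contributor value is flagged when its robust z-score
#' `|v - median| / (1.4826 * MAD)` exceeds `z_threshold`; when the
#' coefficient of variation `sd / mean` exceeds `cv_threshold` the whole
#' component is flagged for review. Flags require at least 3 contributing
#' values and never alter chosen values — review and correction are a
#' separate, human step.
#'
#' @param db A `fcdb_unified`.
#' @param z_threshold Robust z-score cutoff (default 3.5).
#' @param cv_threshold Extreme-CV cutoff (default 2.0).
#' @return `db` with `outlier_flag` on contributors and `outlier_flag` /
#'   `review_flag` on values.
#' @examples
#' # contributors {10, 11, 10.5, 95}: 95 is flagged, the rest are not
#' @export
flag_outliers <- function(db, z_threshold = 3.5, cv_threshold = 2.0) {
  stopifnot(inherits(db, "fcdb_unified"))
  contrib <- dplyr::left_join(
    db$contributors,
    db$values[, c("foodex2", "basis", "tagname", "n_sources", "median")],
    by = c("foodex2", "basis", "tagname")
  )
  contrib <- contrib |>
    dplyr::group_by(.data$foodex2, .data$basis, .data$tagname) |>
    dplyr::mutate(
      .mad = stats::median(abs(.data$value - .data$median)),
      outlier_flag = .data$n_sources >= 3L & .data$.mad > 0 &
        abs(.data$value - .data$median) / (1.4826 * .data$.mad) > z_threshold
    ) |>
    dplyr::ungroup()
  db$contributors <- contrib[, setdiff(names(contrib),
                                       c(".mad", "n_sources", "median"))]
  vals <- db$values
  cv <- ifelse(vals$mean > 0, vals$sd / vals$mean, 0)
  vals$review_flag <- vals$n_sources >= 3L & cv > cv_threshold
  flagged <- db$contributors |>
    dplyr::group_by(.data$foodex2, .data$basis, .data$tagname) |>
    dplyr::summarise(outlier_flag = any(.data$outlier_flag), .groups = "drop")
  vals$outlier_flag <- NULL
  vals <- dplyr::left_join(vals, flagged, by = c("foodex2", "basis", "tagname"))
  vals$outlier_flag[is.na(vals$outlier_flag)] <- FALSE
  db$values <- vals
  db
}

#' @export
print.fcdb_unified <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<fcdb_unified> %d foods (%d matched across sources, ",
                     "%d singletons), %d unified values\n"),
              r$n_foods, r$n_matched, r$n_singleton, r$n_values))
  if (r$n_flagged_contributors > 0 || r$n_review_components > 0) {
    cat(sprintf("  outlier screen: %d flagged contributor values, %d components for review\n",
                r$n_flagged_contributors, r$n_review_components))
  }
  invisible(x)
}
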