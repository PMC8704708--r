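# Energy recalculation from macronutrients with Atwater factors.

#' Atwater conversion factors
#'
#' General Atwater factors in kcal per gram of macronutrient. The fiber
#' term is optional and disabled by default (`fiber = 0`); enable it with
#' `fiber = 2`. The kcal-to-kJ constant is the thermochemical 4.184.
#'
#' @param protein,fat,carbohydrate,alcohol,fiber kcal/g factors.
#' @param kJ_per_kcal Conversion constant.
#' @return A `fcdb_atwater` list.
#' @export
atwater_factors <- function(protein = 4, fat = 9, carbohydrate = 4,
                            alcohol = 7, fiber = 0, kJ_per_kcal = 4.184) {
  f <- list(protein = protein, fat = fat, carbohydrate = carbohydrate,
            alcohol = alcohol, fiber = fiber, kJ_per_kcal = kJ_per_kcal)
  stopifnot(all(unlist(f) >= 0))
  structure(f, class = "fcdb_atwater")
}

#' Energy from macronutrient amounts
#'
#' `kcal = 4 p + 9 f + 4 c + 7 a (+ 2 fib when enabled)` with the factor
#' set supplied; missing (NA) terms contribute 0.
#'
#' @param protein,fat,carbohydrate,alcohol,fiber Amounts in g per 100 g.
#' @param factors An [atwater_factors()] set.
#' @return Numeric vector of kcal per 100 g.
#' @examples
#' energy_kcal(10, 5, 20, 0)  # 165
#' @export
energy_kcal <- function(protein, fat, carbohydrate, alcohol = 0, fiber = 0,
                        factors = atwater_factors()) {
  z <- function(x) ifelse(is.na(x), 0, x)
  factors$protein * z(protein) + factors$fat * z(fat) +
    factors$carbohydrate * z(carbohydrate) + factors$alcohol * z(alcohol) +
    factors$fiber * z(fiber)
}

#' Recalculate energy for a unified database
#'
#' Computes energy per food from its chosen macronutrient values. The
#' reported source energy (tagname `ENERC`), when present, is returned
#' alongside for comparison — it is never overwritten silently. Which
#' carbohydrate feeds the formula (available vs by difference) is a config
#' switch; the default is available carbohydrate (`CHOAVL`).
#'
#' @param db A `fcdb_unified`.
#' @param factors An [atwater_factors()] set; set `fiber = 2` there to
#'   enable the fiber term.
#' @param carbohydrate Tagname feeding the carbohydrate term.
#' @return Tibble with one row per food: `kcal`, `kJ`, the reported
#'   `ENERC` chosen value (`reported_kcal`, NA when absent) and
#'   `missing_terms` (comma-separated macronutrients that contributed 0).
#' @export
recalc_energy <- function(db, factors = atwater_factors(),
                          carbohydrate = "CHOAVL") {
  stopifnot(inherits(db, "fcdb_unified"))
  tags <- c(protein = "PROCNT", fat = "FAT", carbohydrate = carbohydrate,
            alcohol = "ALC", fiber = "FIBTG")
  wide <- db$values |>
    dplyr::filter(.data$tagname %in% c(tags, "ENERC")) |>
    dplyr::select("foodex2", "basis", "tagname", "chosen") |>
    tidyr::pivot_wider(names_from = "tagname", values_from = "chosen")
  for (t in c(tags, "ENERC")) {
    if (!t %in% names(wide)) wide[[t]] <- NA_real_
  }
  out <- db$foods[, c("foodex2", "basis")]
  out <- dplyr::left_join(out, wide, by = c("foodex2", "basis"))
  used <- tags[c(TRUE, TRUE, TRUE, TRUE, factors$fiber > 0)]
  miss <- vapply(seq_len(nrow(out)), function(i) {
    paste(used[is.na(unlist(out[i, used]))], collapse = ",")
  }, "")
  kcal <- energy_kcal(out[[tags[["protein"]]]], out[[tags[["fat"]]]],
                      out[[tags[["carbohydrate"]]]], out[[tags[["alcohol"]]]],
                      if (factors$fiber > 0) out[[tags[["fiber"]]]] else 0,
                      factors = factors)
  tibble::tibble(
    foodex2 = out$foodex2, basis = out$basis,
    kcal = kcal, kJ = kcal * factors$kJ_per_kcal,
    reported_kcal = out$ENERC, missing_terms = miss
  )
}

#' Write recalculated energy back into a database
#'
#' Replaces the chosen `ENERC` value with the Atwater recomputation
#' (rounded by the energy rule) while keeping the previous chosen value in
#' a `chosen_reported` column. Foods without an `ENERC` row gain one with
#' `n_sources = 0`.
#'
#' @inheritParams recalc_energy
#' @return The updated `fcdb_unified`.
#' @export
update_energy <- function(db, factors = atwater_factors(),
                          carbohydrate = "CHOAVL") {
  en <- recalc_energy(db, factors, carbohydrate)
  en$recalc <- round_standard(en$kcal, "energy")
  vals <- db$values
  if (!"chosen_reported" %in% names(vals)) {
    vals$chosen_reported <- NA_real_
  }
  is_en <- vals$tagname == "ENERC"
  key <- paste(vals$foodex2, vals$basis)
  ekey <- paste(en$foodex2, en$basis)
  idx <- match(key[is_en], ekey)
  vals$chosen_reported[is_en] <- vals$chosen[is_en]
  vals$chosen[is_en] <- en$recalc[idx]
  new <- en[!ekey %in% key[is_en], ]
  if (nrow(new) > 0L) {
    vals <- dplyr::bind_rows(vals, tibble::tibble(
      foodex2 = new$foodex2, basis = new$basis, tagname = "ENERC",
      component_class = "energy", n_sources = 0L,
      mean = new$recalc, median = new$recalc, sd = 0, chosen = new$recalc,
      logical_zero = FALSE, review_flag = FALSE, outlier_flag = FALSE,
      chosen_reported = NA_real_
    ))
  }
  db$values <- dplyr::arrange(vals, .data$foodex2, .data$basis, .data$tagname)
  db
}
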