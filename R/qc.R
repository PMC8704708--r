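# HACCP-style quality control: staged validation checks producing a pure
# findings report. Checks never mutate data; corrections are a separate,
# traceability-driven human step.

.qc_checks <- c("tagname_resolution", "foodex2_pattern", "name_missing",
                "proximate_sum", "implausible_fat_zero",
                "implausible_fat_no_detail", "fiber_in_fish",
                "outlier_value", "extreme_cv", "transfer_mismatch")

qc_finding <- function(check_id, severity, foodex2, tagname, detail, stage) {
  tibble::tibble(check_id = check_id, severity = severity,
                 foodex2 = foodex2, tagname = tagname, detail = detail,
                 stage = stage)
}

empty_findings <- function() {
  qc_finding(character(), character(), character(), character(),
             character(), character())
}

#' Quality-control configuration
#'
#' @param proximate_range Closed interval (g per 100 g) the proximate sum
#'   must fall in.
#' @param carbohydrate Tagname used as "total carbohydrates" in the
#'   proximate sum (total by difference, `CHOCDF`, by default).
#' @param fish_groups Food-group labels (matched case-insensitively)
#'   identifying fish, for the fiber-in-fish implausibility rule.
#' @param z_threshold,cv_threshold Outlier-screen thresholds (see
#'   [flag_outliers()]).
#' @param checks Which checks [run_suite()] executes; each implausibility
#'   rule is individually toggleable.
#' @return A `fcdb_qc_config` list.
#' @export
qc_config <- function(proximate_range = c(95, 105),
                      carbohydrate = "CHOCDF",
                      fish_groups = c("fish", "fish and seafood",
                                      "fish, seafood, amphibians, reptiles and invertebrates"),
                      z_threshold = 3.5, cv_threshold = 2.0,
                      checks = .qc_checks) {
  stopifnot(length(proximate_range) == 2L,
            proximate_range[1] < proximate_range[2])
  structure(list(proximate_range = proximate_range,
                 carbohydrate = carbohydrate,
                 fish_groups = tolower(fish_groups),
                 z_threshold = z_threshold, cv_threshold = cv_threshold,
                 checks = match.arg(checks, .qc_checks, several.ok = TRUE)),
            class = "fcdb_qc_config")
}

chosen_wide <- function(db, tagnames) {
  wide <- db$values |>
    dplyr::filter(.data$tagname %in% tagnames) |>
    dplyr::select("foodex2", "basis", "tagname", "chosen") |>
    tidyr::pivot_wider(names_from = "tagname", values_from = "chosen")
  for (t in tagnames) if (!t %in% names(wide)) wide[[t]] <- NA_real_
  dplyr::left_join(db$foods[, c("foodex2", "basis", "food_group")], wide,
                   by = c("foodex2", "basis"))
}

#' Proximate-sum range check
#'
#' For each food on a per-100 g basis, the sum of water + protein + fat +
#' total carbohydrates + alcohol + ash must lie in the closed interval
#' 95-105 g. Missing terms contribute 0 but are named in the finding
#' detail. Violations are error-severity findings at the unification stage.
#'
#' @param db A `fcdb_unified`.
#' @param config A [qc_config()].
#' @return A findings tibble (zero rows when all foods pass).
#' @export
check_proximate_sum <- function(db, config = qc_config()) {
  terms <- c("WATER", "PROCNT", "FAT", config$carbohydrate, "ALC", "ASH")
  wide <- chosen_wide(db, terms)
  wide <- wide[wide$basis == "per_100g", ]
  if (nrow(wide) == 0L) return(empty_findings())
  m <- as.matrix(wide[, terms])
  s <- rowSums(m, na.rm = TRUE)
  missing_terms <- apply(m, 1L, function(r) paste(terms[is.na(r)], collapse = ","))
  bad <- s < config$proximate_range[1] | s > config$proximate_range[2]
  if (!any(bad)) return(empty_findings())
  qc_finding(
    check_id = "proximate_sum", severity = "error",
    foodex2 = wide$foodex2[bad], tagname = NA_character_,
    detail = sprintf("proximate sum %.6g g outside [%g, %g]%s", s[bad],
                     config$proximate_range[1], config$proximate_range[2],
                     ifelse(nzchar(missing_terms[bad]),
                            paste0("; missing terms: ", missing_terms[bad]), "")),
    stage = "unification"
  )
}

#' Implausible-value checks
#'
#' Three individually toggleable rules, each a warning requiring review
#' (never an automatic edit):
#' * (a) `implausible_fat_zero` — total fat is 0 while an individual fatty
#'   acid or cholesterol value is > 0;
#' * (b) `implausible_fat_no_detail` — total fat exceeds 1 g while fatty
#'   acids and cholesterol are all zero or missing;
#' * (c) `fiber_in_fish` — dietary fiber > 0 in a food whose group is fish.
#'
#' @inheritParams check_proximate_sum
#' @return A findings tibble.
#' @export
check_implausible <- function(db, config = qc_config()) {
  fa_tags <- unique(db$values$tagname[db$values$component_class == "fatty_acid"])
  tags <- unique(c("FAT", "FIBTG", "CHOLE", fa_tags))
  wide <- chosen_wide(db, tags)
  fat <- wide$FAT
  fam <- as.matrix(wide[, intersect(c(fa_tags, "CHOLE"), names(wide)), drop = FALSE])
  any_fa_pos <- if (ncol(fam) > 0) {
    apply(fam, 1L, function(r) any(!is.na(r) & r > 0))
  } else rep(FALSE, nrow(wide))
  all_fa_absent <- if (ncol(fam) > 0) {
    apply(fam, 1L, function(r) all(is.na(r) | r == 0))
  } else rep(TRUE, nrow(wide))

  out <- list()
  if ("implausible_fat_zero" %in% config$checks) {
    a <- !is.na(fat) & fat == 0 & any_fa_pos
    if (any(a)) {
      out <- c(out, list(qc_finding(
        "implausible_fat_zero", "warning", wide$foodex2[a], "FAT",
        "total fat is 0 while a fatty acid or cholesterol value is positive",
        "unification")))
    }
  }
  if ("implausible_fat_no_detail" %in% config$checks) {
    b <- !is.na(fat) & fat > 1 & all_fa_absent
    if (any(b)) {
      out <- c(out, list(qc_finding(
        "implausible_fat_no_detail", "warning", wide$foodex2[b], "FAT",
        sprintf("total fat %.6g g with all fatty acids and cholesterol zero/missing",
                fat[b]),
        "unification")))
    }
  }
  if ("fiber_in_fish" %in% config$checks) {
    cc <- tolower(wide$food_group) %in% config$fish_groups &
      !is.na(wide$FIBTG) & wide$FIBTG > 0
    if (any(cc)) {
      out <- c(out, list(qc_finding(
        "fiber_in_fish", "warning", wide$foodex2[cc], "FIBTG",
        sprintf("fiber %.6g g in fish food", wide$FIBTG[cc]),
        "unification")))
    }
  }
  if (length(out) == 0L) return(empty_findings())
  dplyr::bind_rows(out)
}

#' Flat-export transfer check
#'
#' Verifies that two identically keyed exports (e.g. the flat spreadsheet
#' export before and after a round trip through the relational store) agree
#' exactly: same row count, same key set, and bit-exact equality of every
#' value. Any mismatch is an error finding naming the keys involved.
#'
#' @param export_a,export_b Data frames keyed by `key` columns.
#' @param key Character vector of key column names.
#' @return A findings tibble (zero rows when the exports are identical).
#' @export
check_transfer <- function(export_a, export_b, key = c("foodex2", "basis")) {
  stopifnot(all(key %in% names(export_a)), all(key %in% names(export_b)))
  ka <- do.call(paste, c(export_a[key], sep = "\r"))
  kb <- do.call(paste, c(export_b[key], sep = "\r"))
  out <- list()
  only_a <- setdiff(ka, kb)
  only_b <- setdiff(kb, ka)
  if (nrow(export_a) != nrow(export_b) || length(only_a) || length(only_b)) {
    out <- c(out, list(qc_finding(
      "transfer_mismatch", "error", NA_character_, NA_character_,
      sprintf("row/key mismatch: %d vs %d rows; keys only in A: %s; only in B: %s",
              nrow(export_a), nrow(export_b),
              paste(gsub("\r", "/", only_a), collapse = ","),
              paste(gsub("\r", "/", only_b), collapse = ",")),
      "management")))
  }
  common <- intersect(ka, kb)
  cols <- intersect(setdiff(names(export_a), key),
                    setdiff(names(export_b), key))
  a <- export_a[match(common, ka), cols, drop = FALSE]
  b <- export_b[match(common, kb), cols, drop = FALSE]
  for (cl in cols) {
    same <- (is.na(a[[cl]]) & is.na(b[[cl]])) |
      (!is.na(a[[cl]]) & !is.na(b[[cl]]) & a[[cl]] == b[[cl]])
    if (!all(same)) {
      keys <- export_a[match(common[!same], ka), key, drop = FALSE]
      out <- c(out, list(qc_finding(
        "transfer_mismatch", "error",
        foodex2 = as.character(keys[[1]]), tagname = cl,
        detail = sprintf("value mismatch in column '%s'", cl),
        stage = "management")))
    }
  }
  if (length(out) == 0L) return(empty_findings())
  dplyr::bind_rows(out)
}

check_harmonization <- function(db, registry) {
  out <- list()
  bad_tag <- setdiff(unique(db$values$tagname), registry$tagname)
  if (length(bad_tag) > 0L) {
    out <- c(out, list(qc_finding(
      "tagname_resolution", "error", NA_character_, bad_tag,
      "tagname does not resolve in the component registry",
      "harmonization")))
  }
  bad_code <- !is_foodex2_code(db$foods$foodex2)
  if (any(bad_code)) {
    out <- c(out, list(qc_finding(
      "foodex2_pattern", "error", db$foods$foodex2[bad_code], NA_character_,
      "food code does not match the FoodEx2 token pattern",
      "harmonization")))
  }
  noname <- is.na(db$foods$name) | !nzchar(trimws(db$foods$name))
  if (any(noname)) {
    out <- c(out, list(qc_finding(
      "name_missing", "warning", db$foods$foodex2[noname], NA_character_,
      "food has no usable display name", "harmonization")))
  }
  if (length(out) == 0L) return(empty_findings())
  dplyr::bind_rows(out)
}

check_outlier_flags <- function(db, config) {
  vals <- db$values
  out <- list()
  oo <- vals$outlier_flag
  if (any(oo)) {
    flagged <- db$contributors[db$contributors$outlier_flag, ]
    agg <- flagged |>
      dplyr::group_by(.data$foodex2, .data$basis, .data$tagname) |>
      dplyr::summarise(detail = paste0("outlying contributor(s): ",
                                       paste(.data$source_id, collapse = ",")),
                       .groups = "drop")
    out <- c(out, list(qc_finding(
      "outlier_value", "warning", agg$foodex2, agg$tagname, agg$detail,
      "unification")))
  }
  rv <- vals$review_flag
  if (any(rv)) {
    out <- c(out, list(qc_finding(
      "extreme_cv", "warning", vals$foodex2[rv], vals$tagname[rv],
      sprintf("coefficient of variation %.3g exceeds %.3g",
              ifelse(vals$mean[rv] > 0, vals$sd[rv] / vals$mean[rv], 0),
              config$cv_threshold),
      "unification")))
  }
  if (length(out) == 0L) return(empty_findings())
  dplyr::bind_rows(out)
}

#' Run the validation suite
#'
#' Executes the staged checks on a unified database: tagname resolution,
#' FoodEx2 pattern and name checks (harmonization stage), the
#' proximate-sum range, implausible-value and outlier checks (unification
#' stage). The report is deterministic for a given input and the checks
#' never mutate the database.
#'
#' @param db A `fcdb_unified`.
#' @param registry Component registry.
#' @param config A [qc_config()]; toggles individual checks.
#' @return A `fcdb_qc_report`: list with `findings`, `summary` (named
#'   counts per check), and `n_foods_checked`.
#' @export
run_suite <- function(db, registry, config = qc_config()) {
  stopifnot(inherits(db, "fcdb_unified"))
  parts <- list()
  if (any(c("tagname_resolution", "foodex2_pattern", "name_missing")
          %in% config$checks)) {
    h <- check_harmonization(db, registry)
    parts <- c(parts, list(h[h$check_id %in% config$checks, ]))
  }
  if ("proximate_sum" %in% config$checks) {
    parts <- c(parts, list(check_proximate_sum(db, config)))
  }
  parts <- c(parts, list(check_implausible(db, config)))
  if (any(c("outlier_value", "extreme_cv") %in% config$checks)) {
    o <- check_outlier_flags(db, config)
    parts <- c(parts, list(o[o$check_id %in% config$checks, ]))
  }
  findings <- dplyr::bind_rows(parts)
  findings <- dplyr::arrange(findings, .data$check_id, .data$foodex2,
                             .data$tagname)
  summary <- table(factor(findings$check_id, levels = .qc_checks))
  structure(list(findings = findings,
                 summary = stats::setNames(as.integer(summary), names(summary)),
                 n_foods_checked = nrow(db$foods)),
            class = "fcdb_qc_report")
}

#' @export
print.fcdb_qc_report <- function(x, ...) {
  n_err <- sum(x$findings$severity == "error")
  n_warn <- sum(x$findings$severity == "warning")
  cat(sprintf("<fcdb_qc_report> %d foods checked: %d error(s), %d warning(s)\n",
              x$n_foods_checked, n_err, n_warn))
  nz <- x$summary[x$summary > 0]
  for (nm in names(nz)) cat(sprintf("  %-26s %d\n", nm, nz[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.fcdb_qc_report <- function(x, ...) as.data.frame(x$findings)
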