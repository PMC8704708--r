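# Closed unit vocabulary and exact unit conversion.
#
# The unit set is deliberately closed: g / mg / ug for mass, kcal / kJ for
# energy. IU and % are not part of the vocabulary; per-100 g and per-100 mL
# bases are carried on the record, never interconverted (no density model).

#' Supported units
#'
#' The closed set of units a component value may carry: mass per 100 g (or
#' 100 mL) of food in `g`, `mg` or `ug`, and energy in `kcal` or `kJ`.
#'
#' @return Character vector of unit tokens.
#' @export
fcdb_units <- function() c("g", "mg", "ug", "kcal", "kJ")

.mass_exponent <- c(g = 0L, mg = -3L, ug = -6L)
.kj_per_kcal <- 4.184

#' Normalize a unit token
#'
#' Maps common spellings onto the canonical tokens: `µg`/`mcg` become `ug`,
#' case variants of `g`/`mg`/`kcal`/`kJ` are canonicalized. Unknown tokens
#' raise an error.
#'
#' @param unit Character vector of unit tokens.
#' @return Character vector of canonical unit tokens.
#' @export
normalize_unit <- function(unit) {
  u <- trimws(as.character(unit))
  low <- tolower(u)
  out <- character(length(u))
  out[low %in% c("g", "gram", "grams")] <- "g"
  out[low %in% c("mg", "milligram", "milligrams")] <- "mg"
  out[low %in% c("ug", "µg", "μg", "mcg", "microgram", "micrograms")] <- "ug"
  out[low %in% c("kcal", "cal")] <- "kcal"
  out[low %in% c("kj", "kjoule", "kilojoule")] <- "kJ"
  bad <- out == ""
  if (any(bad)) {
    rlang::abort(
      paste0("unknown unit token(s): ", paste(unique(u[bad]), collapse = ", "),
             " (supported: ", paste(fcdb_units(), collapse = ", "), ")"),
      class = "fcdb_unknown_unit"
    )
  }
  out
}

# Exact power-of-ten scaling by shifting the decimal exponent of the
# 15-significant-digit representation. For values that entered the system as
# decimal text (every value read from a delimited source table), this is an
# exact decimal operation and round trips bit-for-bit; plain floating-point
# multiplication by 10^k does not (it is not even injective across binades).
decimal_shift <- function(x, e) {
  out <- x
  ok <- is.finite(x) & x != 0
  if (!any(ok)) return(out)
  s <- sprintf("%.14e", x[ok])
  mant <- sub("e.*$", "", s)
  ex <- as.integer(sub("^.*e", "", s))
  out[ok] <- as.numeric(paste0(mant, "e", ex + e))
  out
}

#' Convert a component value between units
#'
#' Mass units convert by the exact power-of-ten ratio (an exact decimal
#' scaling, so `convert_value(convert_value(v, "g", "mg"), "mg", "g")`
#' recovers `v` bit-for-bit for decimal-entered values); energy converts with
#' 1 kcal = 4.184 kJ. Mixing a mass unit with an energy unit is a
#' dimensional error.
#'
#' @param value Numeric vector of values (NA passes through).
#' @param from,to Unit tokens (see [fcdb_units()]; `µg`/`mcg` accepted).
#' @return Numeric vector in the target unit.
#' @examples
#' convert_value(0.5, "g", "mg")   # 500
#' convert_value(250, "ug", "mg")  # 0.25
#' convert_value(100, "kcal", "kJ") # 418.4
#' @export
convert_value <- function(value, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  stopifnot(length(from) == 1L, length(to) == 1L)
  if (from == to) return(value)
  mass <- names(.mass_exponent)
  if (from %in% mass && to %in% mass) {
    return(decimal_shift(value, .mass_exponent[[from]] - .mass_exponent[[to]]))
  }
  if (from == "kcal" && to == "kJ") return(value * .kj_per_kcal)
  if (from == "kJ" && to == "kcal") return(value / .kj_per_kcal)
  rlang::abort(
    sprintf("incompatible units: cannot convert %s to %s", from, to),
    class = "fcdb_incompatible_unit"
  )
}

# TRUE when two units are interconvertible (both mass or both energy).
units_compatible <- function(a, b) {
  a <- normalize_unit(a)
  b <- normalize_unit(b)
  mass <- names(.mass_exponent)
  (a %in% mass & b %in% mass) | (a %in% c("kcal", "kJ") & b %in% c("kcal", "kJ"))
}
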