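# FoodEx2 classification codes are treated as opaque validated tokens:
# one letter followed by four alphanumerics (e.g. A00MH). No catalogue
# lookup is performed; the code is the matching key for unification.

#' Validate FoodEx2 codes
#'
#' A valid code is a 5-character token: a letter followed by four
#' alphanumerics. Comparison is case-insensitive; [canonical_foodex2()]
#' upper-cases for storage and matching.
#'
#' @param code Character vector.
#' @return Logical vector.
#' @examples
#' is_foodex2_code(c("A00MH", "spinach", "A00"))
#' @export
is_foodex2_code <- function(code) {
  !is.na(code) & grepl("^[A-Za-z][A-Za-z0-9]{4}$", code)
}

#' @rdname is_foodex2_code
#' @export
canonical_foodex2 <- function(code) toupper(trimws(code))
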