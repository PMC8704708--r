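# The component registry is the controlled vocabulary of everything
# measured: one row per INFOODS-style tagname with its standard unit and
# component class. Every value in every record must resolve here.

.component_classes <- c("proximate", "energy", "mineral", "vitamin",
                        "fatty_acid", "sterol", "polyphenol", "other")
.tagname_origins <- c("infoods_standard", "compiler_assigned")

#' Create a component registry
#'
#' @param components Optional data frame with columns `tagname`,
#'   `display_name`, `standard_unit`, `component_class`, `tagname_origin`;
#'   rows are registered one by one so all invariants are enforced.
#' @return A `fcdb_registry` tibble.
#' @seealso [register_component()], [default_registry()]
#' @export
component_registry <- function(components = NULL) {
  reg <- tibble::tibble(
    tagname = character(), display_name = character(),
    standard_unit = character(), component_class = character(),
    tagname_origin = character()
  )
  class(reg) <- c("fcdb_registry", class(reg))
  if (!is.null(components)) {
    for (i in seq_len(nrow(components))) {
      reg <- register_component(
        reg,
        tagname = components$tagname[i],
        display_name = components$display_name[i],
        standard_unit = components$standard_unit[i],
        component_class = components$component_class[i],
        tagname_origin = components$tagname_origin[i]
      )
    }
  }
  reg
}

#' Register a component definition
#'
#' Re-registering an identical definition is a no-op; registering the same
#' tagname with a different unit (or class) is a registration conflict.
#' Components without an INFOODS standard tagname (most individual
#' polyphenols) are registered with `tagname_origin = "compiler_assigned"`.
#'
#' @param registry A component registry.
#' @param tagname Token of uppercase letters, digits and underscores.
#' @param display_name Human-readable component name.
#' @param standard_unit One of `g`, `mg`, `ug`, `kcal`, `kJ` (per 100 g or
#'   100 mL of food). Energy components must use `kcal` or `kJ`.
#' @param component_class One of proximate, energy, mineral, vitamin,
#'   fatty_acid, sterol, polyphenol, other.
#' @param tagname_origin `"infoods_standard"` or `"compiler_assigned"`.
#' @return The updated registry.
#' @examples
#' reg <- component_registry()
#' reg <- register_component(reg, "PROT", "Protein", "g", "proximate")
#' @export
register_component <- function(registry, tagname, display_name = tagname,
                               standard_unit, component_class,
                               tagname_origin = "infoods_standard") {
  stopifnot(inherits(registry, "fcdb_registry"))
  if (!grepl("^[A-Z][A-Z0-9_]*$", tagname)) {
    rlang::abort(sprintf("invalid tagname token: '%s'", tagname),
                 class = "fcdb_invalid_tagname")
  }
  standard_unit <- normalize_unit(standard_unit)
  component_class <- match.arg(component_class, .component_classes)
  tagname_origin <- match.arg(tagname_origin, .tagname_origins)
  if (component_class == "energy" && !standard_unit %in% c("kcal", "kJ")) {
    rlang::abort("energy components must use kcal or kJ",
                 class = "fcdb_invalid_unit")
  }
  if (component_class != "energy" && standard_unit %in% c("kcal", "kJ")) {
    rlang::abort("kcal/kJ are reserved for energy components",
                 class = "fcdb_invalid_unit")
  }
  existing <- registry[registry$tagname == tagname, ]
  if (nrow(existing) > 0L) {
    same <- existing$standard_unit == standard_unit &&
      existing$component_class == component_class &&
      existing$display_name == display_name &&
      existing$tagname_origin == tagname_origin
    if (same) return(registry)  # idempotent re-registration
    rlang::abort(
      sprintf("tagname '%s' already registered with unit '%s' (got '%s')",
              tagname, existing$standard_unit, standard_unit),
      class = "fcdb_registration_conflict"
    )
  }
  out <- dplyr::bind_rows(registry, tibble::tibble(
    tagname = tagname, display_name = display_name,
    standard_unit = standard_unit, component_class = component_class,
    tagname_origin = tagname_origin
  ))
  class(out) <- c("fcdb_registry", setdiff(class(out), "fcdb_registry"))
  out
}

#' Resolve a tagname
#'
#' @param registry A component registry.
#' @param tagname Tagname token(s).
#' @return One registry row per tagname; unknown tagnames are an error.
#' @export
resolve_component <- function(registry, tagname) {
  idx <- match(tagname, registry$tagname)
  if (anyNA(idx)) {
    rlang::abort(
      paste0("unregistered tagname(s): ",
             paste(unique(tagname[is.na(idx)]), collapse = ", ")),
      class = "fcdb_unknown_tagname"
    )
  }
  registry[idx, ]
}

#' Built-in component registry
#'
#' The default controlled vocabulary: proximates (g), energy (kcal),
#' minerals and vitamins (mg/ug), fatty-acid classes (g), cholesterol (mg)
#' and a set of individual polyphenols. Polyphenols carry compiler-assigned
#' tagnames (prefixed `PP_`), reflecting that most individual phenolic
#' compounds have no INFOODS standard tagname.
#'
#' @return A `fcdb_registry` tibble.
#' @export
default_registry <- function() {
  cached <- .fcdb_cache$default_registry
  if (!is.null(cached)) return(cached)
  def <- function(tag, name, unit, cls, origin = "infoods_standard") {
    list(tag, name, unit, cls, origin)
  }
  rows <- list(
    # proximates, g per 100 g
    def("WATER",  "Water",                       "g", "proximate"),
    def("PROCNT", "Protein, total",              "g", "proximate"),
    def("FAT",    "Fat, total",                  "g", "proximate"),
    def("CHOAVL", "Carbohydrate, available",     "g", "proximate"),
    def("CHOCDF", "Carbohydrate, total (by difference)", "g", "proximate"),
    def("FIBTG",  "Fibre, total dietary",        "g", "proximate"),
    def("ALC",    "Alcohol",                     "g", "proximate"),
    def("ASH",    "Ash",                         "g", "proximate"),
    # energy
    def("ENERC",  "Energy, metabolizable",       "kcal", "energy"),
    # minerals
    def("CA",  "Calcium",    "mg", "mineral"),
    def("FE",  "Iron",       "mg", "mineral"),
    def("MG",  "Magnesium",  "mg", "mineral"),
    def("P",   "Phosphorus", "mg", "mineral"),
    def("K",   "Potassium",  "mg", "mineral"),
    def("NA",  "Sodium",     "mg", "mineral"),
    def("ZN",  "Zinc",       "mg", "mineral"),
    def("CU",  "Copper",     "mg", "mineral"),
    def("MN",  "Manganese",  "mg", "mineral"),
    def("CLD", "Chloride",   "mg", "mineral"),
    def("SE",  "Selenium",   "ug", "mineral"),
    def("ID",  "Iodine",     "ug", "mineral"),
    # vitamins
    def("VITC",     "Vitamin C",        "mg", "vitamin"),
    def("THIA",     "Thiamin",          "mg", "vitamin"),
    def("RIBF",     "Riboflavin",       "mg", "vitamin"),
    def("NIA",      "Niacin",           "mg", "vitamin"),
    def("VITB6A",   "Vitamin B6",       "mg", "vitamin"),
    def("PANTAC",   "Pantothenic acid", "mg", "vitamin"),
    def("VITE",     "Vitamin E (alpha-tocopherol)", "mg", "vitamin"),
    def("FOL",      "Folate, total",    "ug", "vitamin"),
    def("VITB12",   "Vitamin B12",      "ug", "vitamin"),
    def("VITA_RAE", "Vitamin A (retinol activity equivalents)", "ug", "vitamin"),
    def("VITD",     "Vitamin D",        "ug", "vitamin"),
    def("VITK",     "Vitamin K",        "ug", "vitamin"),
    def("BIOT",     "Biotin",           "ug", "vitamin"),
    # fatty acids and sterols
    def("FASAT", "Fatty acids, saturated",       "g", "fatty_acid"),
    def("FAMS",  "Fatty acids, monounsaturated", "g", "fatty_acid"),
    def("FAPU",  "Fatty acids, polyunsaturated", "g", "fatty_acid"),
    def("CHOLE", "Cholesterol",                  "mg", "sterol"),
    # individual polyphenols: compiler-assigned tagnames
    def("PP_CATECHIN",         "(+)-Catechin",      "mg", "polyphenol", "compiler_assigned"),
    def("PP_EPICATECHIN",      "(-)-Epicatechin",   "mg", "polyphenol", "compiler_assigned"),
    def("PP_QUERCETIN",        "Quercetin",         "mg", "polyphenol", "compiler_assigned"),
    def("PP_KAEMPFEROL",       "Kaempferol",        "mg", "polyphenol", "compiler_assigned"),
    def("PP_MALVIDIN",         "Malvidin",          "mg", "polyphenol", "compiler_assigned"),
    def("PP_CYANIDIN",         "Cyanidin",          "mg", "polyphenol", "compiler_assigned"),
    def("PP_HESPERIDIN",       "Hesperidin",        "mg", "polyphenol", "compiler_assigned"),
    def("PP_NARINGENIN",       "Naringenin",        "mg", "polyphenol", "compiler_assigned"),
    def("PP_RESVERATROL",      "Resveratrol",       "mg", "polyphenol", "compiler_assigned"),
    def("PP_GALLIC_ACID",      "Gallic acid",       "mg", "polyphenol", "compiler_assigned"),
    def("PP_FERULIC_ACID",     "Ferulic acid",      "mg", "polyphenol", "compiler_assigned"),
    def("PP_CAFFEIC_ACID",     "Caffeic acid",      "mg", "polyphenol", "compiler_assigned"),
    def("PP_CHLOROGENIC_ACID", "Chlorogenic acid",  "mg", "polyphenol", "compiler_assigned"),
    def("PP_TYROSOL",          "Tyrosol",           "mg", "polyphenol", "compiler_assigned"),
    def("PP_OLEUROPEIN",       "Oleuropein",        "mg", "polyphenol", "compiler_assigned")
  )
  df <- tibble::tibble(
    tagname = vapply(rows, `[[`, "", 1L),
    display_name = vapply(rows, `[[`, "", 2L),
    standard_unit = vapply(rows, `[[`, "", 3L),
    component_class = vapply(rows, `[[`, "", 4L),
    tagname_origin = vapply(rows, `[[`, "", 5L)
  )
  reg <- component_registry(df)
  .fcdb_cache$default_registry <- reg
  reg
}

.fcdb_cache <- new.env(parent = emptyenv())

#' Read / write a component registry
#'
#' The on-disk format mirrors the compiler's "labels and units" sheet: one
#' row per tagname with display name, standard unit, class and origin.
#' `.csv`/`.tsv` and `.json` are supported by extension.
#'
#' @param path File path.
#' @param registry A component registry.
#' @return `read_component_registry()` returns a `fcdb_registry`;
#'   `write_component_registry()` returns `path` invisibly.
#' @export
read_component_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    tsv = utils::read.delim(path, colClasses = "character",
                            na.strings = "", fileEncoding = "UTF-8"),
    utils::read.csv(path, colClasses = "character",
                    na.strings = "", fileEncoding = "UTF-8")
  )
  component_registry(df)
}

#' @rdname read_component_registry
#' @export
write_component_registry <- function(registry, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(as.data.frame(registry), path,
                         auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  }
  invisible(path)
}
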