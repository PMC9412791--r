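# Impact-category registry: the 16 Product Environmental Footprint (PEF)
# midpoint categories, their LCIA method names and units, plus the PEF
# toxicity-exclusion set used when normalizing.

#' Default registry of the 16 PEF impact categories
#'
#' Returns the registry of midpoint impact categories used throughout the
#' package: climate change, acidification, the three eutrophication
#' categories, the three toxicity categories, ionising radiation,
#' respiratory inorganics, photochemical ozone formation, ozone depletion,
#' land use, fossil and mineral resource use, and dissipated water. Category
#' ids are the standard abbreviations (CC, EAC, ECF, EUF, EUM, EUT, HCE,
#' HIR, HNC, HRI, HOF, RLU, HOD, RFF, RMM, RDW).
#'
#' @return A data frame of class `impact_registry` with columns `id`,
#'   `name`, `method` (LCIA method name) and `unit`, one row per category.
#' @examples
#' reg <- default_impact_categories()
#' nrow(reg)           # 16
#' category_unit(reg, "CC")
#' @export
default_impact_categories <- function() {
  reg <- data.frame(
    id = c("CC", "EAC", "ECF", "EUF", "EUM", "EUT", "HCE", "HIR",
           "HNC", "HRI", "HOF", "RLU", "HOD", "RFF", "RMM", "RDW"),
    name = c(
      "Climate change",
      "Freshwater and terrestrial acidification",
      "Ecotoxicity freshwater",
      "Eutrophication freshwater",
      "Eutrophication marine",
      "Eutrophication terrestrial",
      "Cancer effects",
      "Ionising radiation",
      "Non-cancer effects",
      "Respiratory inorganics",
      "Photochemical ozone formation",
      "Land use",
      "Ozone depletion",
      "Resource use, fossils",
      "Resource use, minerals and metals",
      "Dissipated water"),
    method = c(
      "IPCC 2013 GWP 100a",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "ILCD 2011 Midpoint+",
      "PM method",
      "ILCD 2011 Midpoint+",
      "Soil quality index based on LANCA",
      "ILCD 2011 Midpoint+",
      "CML-IA baseline",
      "CML-IA baseline",
      "AWARE"),
    unit = c(
      "kg CO2 eq", "Mol H+ eq", "CTUe", "kg P eq", "kg N eq", "Molc N eq",
      "CTUh", "kBq U-235 eq", "CTUh", "Disease inc.", "kg NMVOC eq", "Pt",
      "kg CFC11 eq", "MJ", "kg Sb eq", "m3 depriv"),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("impact_registry", "data.frame")
  validate_impact_registry(reg)
}

#' Validate an impact-category registry
#'
#' Checks id uniqueness and non-empty unit strings.
#'
#' @param reg data frame with columns `id`, `name`, `method`, `unit`.
#' @return `reg`, invisibly classed as `impact_registry`.
#' @export
validate_impact_registry <- function(reg) {
  required <- c("id", "name", "method", "unit")
  missing <- setdiff(required, names(reg))
  if (length(missing))
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(reg$id))
    stop("duplicate category id in registry: ",
         paste(unique(reg$id[duplicated(reg$id)]), collapse = ", "))
  if (any(!nzchar(reg$unit)))
    stop("every category must carry a non-empty unit string")
  if (!inherits(reg, "impact_registry"))
    class(reg) <- c("impact_registry", "data.frame")
  reg
}

#' Add a category to a registry
#'
#' @param reg an `impact_registry`.
#' @param id,name,method,unit fields of the new category.
#' @return The extended registry. Registering an id that already exists is
#'   an error.
#' @export
register_category <- function(reg, id, name, method, unit) {
  if (id %in% reg$id)
    stop("duplicate category id in registry: ", id)
  out <- rbind(as.data.frame(reg),
               data.frame(id = id, name = name, method = method, unit = unit,
                          stringsAsFactors = FALSE))
  validate_impact_registry(out)
}

lookup_category <- function(reg, id) {
  i <- match(id, reg$id)
  if (is.na(i)) stop("unknown impact category: ", id)
  reg[i, , drop = FALSE]
}

#' Unit string of a registered category
#'
#' @param reg an `impact_registry`.
#' @param id category id, e.g. `"CC"`.
#' @return The unit string; unknown ids are an error.
#' @export
category_unit <- function(reg, id) lookup_category(reg, id)$unit

#' PEF toxicity exclusions
#'
#' The three toxicity-related categories (freshwater ecotoxicity and the
#' cancer and non-cancer human-health effects) are excluded from normalized
#' reporting while the robustness of their characterization models is under
#' review, following PEF practice.
#'
#' @return Character vector of the three excluded category ids.
#' @export
pef_excluded_toxicity_ids <- function() c("ECF", "HCE", "HNC")

#' Default normalization references
#'
#' Per-person-per-year reference values used to normalize midpoint scores.
#' The real per-capita reference set is user-supplied data; the default of
#' 1.0 per category is a documented synthetic placeholder that keeps the
#' normalization step runnable and testable without asserting external
#' reference values.
#'
#' @param reg an `impact_registry`.
#' @param value reference value applied to every category (default 1).
#' @return Data frame with columns `category_id`, `reference_value`.
#' @export
default_normalization_refs <- function(reg = default_impact_categories(),
                                       value = 1) {
  stopifnot(value > 0)
  data.frame(category_id = reg$id, reference_value = value,
             stringsAsFactors = FALSE)
}

#' Read / write an impact registry as CSV
#'
#' The file schema is `(id, name, method, unit)`. Round-trips losslessly.
#'
#' @param path file path.
#' @return `read_impact_registry` returns an `impact_registry`.
#' @export
read_impact_registry <- function(path) {
  df <- read_checked_csv(path, c("id", "name", "method", "unit"))
  validate_impact_registry(df)
}

#' @rdname read_impact_registry
#' @param reg registry to write.
#' @export
write_impact_registry <- function(reg, path) {
  utils::write.csv(as.data.frame(reg), path, row.names = FALSE)
  invisible(path)
}

#' Read / write normalization references as CSV
#'
#' Schema `(category_id, reference_value)`; reference values must be
#' strictly positive.
#'
#' @param path file path.
#' @return `read_normalization_refs` returns the reference data frame.
#' @export
read_normalization_refs <- function(path) {
  df <- read_checked_csv(path, c("category_id", "reference_value"),
                         numeric_cols = "reference_value")
  if (any(df$reference_value <= 0))
    stop("normalization reference values must be > 0 (row ",
         which(df$reference_value <= 0)[1], ")")
  df
}

#' @rdname read_normalization_refs
#' @param refs reference table to write.
#' @export
write_normalization_refs <- function(refs, path) {
  utils::write.csv(refs, path, row.names = FALSE)
  invisible(path)
}
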