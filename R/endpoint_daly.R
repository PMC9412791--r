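# Human-health endpoint conversion: disability-adjusted life years (DALYs).
#
# Midpoint scores in the human-health-relevant categories are converted to
# DALY contributions with endpoint damage factors, summed, and expressed
# also as DALY-seconds (total x seconds in a 365-day year), the unit in
# which sub-second health burdens per child-year are easiest to read.

#' Seconds in a 365-day year
#'
#' The constant used to convert total DALYs into DALY-seconds
#' (365 x 24 x 3600 = 31,536,000).
#' @return 31536000.
#' @export
seconds_per_year <- function() 31536000

#' Endpoint human-health damage categories
#'
#' The eight damage pathways tracked in the DALY conversion: global
#' warming, stratospheric ozone depletion, ionising radiation, particulate
#' matter formation, photochemical ozone formation, cancer effects,
#' non-cancer effects and water consumption.
#'
#' @return Character vector of the eight category names.
#' @export
endpoint_categories <- function() {
  c("global_warming", "stratospheric_ozone_depletion", "ionising_radiation",
    "particulate_matter_formation", "photochemical_ozone_formation",
    "cancer_effects", "non_cancer_effects", "water_consumption")
}

#' Default endpoint damage factors
#'
#' DALYs per unit of the corresponding midpoint score. Real
#' hierarchist-perspective endpoint factors are licensed method data and
#' are not bundled; these synthetic defaults have realistic orders of
#' magnitude and exist so the pipeline runs end to end. Supply your own
#' table for substantive endpoint work.
#'
#' @return Data frame `(category, source_category, factor, unit)`, where
#'   `source_category` is the midpoint category id feeding each damage
#'   pathway.
#' @export
default_endpoint_factors <- function() {
  data.frame(
    category = endpoint_categories(),
    source_category = c("CC", "HOD", "HIR", "HRI", "HOF",
                        "HCE", "HNC", "RDW"),
    factor = c(9.3e-7, 5.3e-4, 8.5e-9, 6.3e-1, 9.1e-7,
               3.3e-6, 6.7e-9, 2.2e-7),
    unit = "DALY per midpoint unit",
    stringsAsFactors = FALSE)
}

#' Convert midpoint scores to per-category DALYs
#'
#' Elementwise product of the relevant midpoint scores with the endpoint
#' damage factors; linear in its inputs. A missing factor for any of the
#' eight pathways is an error (an explicit zero is required instead).
#'
#' @param scores named numeric vector of midpoint scores (must cover every
#'   `source_category` of `factors`), or an `lcia_result`.
#' @param factors endpoint factor table, see [default_endpoint_factors()].
#' @return Named numeric vector of DALYs per endpoint category.
#' @export
endpoint_convert <- function(scores, factors = default_endpoint_factors()) {
  if (inherits(scores, "lcia_result")) scores <- scores$scores
  missing_cat <- setdiff(endpoint_categories(), factors$category)
  if (length(missing_cat))
    stop("missing endpoint factor for: ",
         paste(missing_cat, collapse = ", "))
  if (any(!is.finite(factors$factor)) || any(factors$factor < 0))
    stop("endpoint factors must be finite and nonnegative")
  src <- factors$source_category
  absent <- setdiff(src, names(scores))
  if (length(absent))
    stop("scores do not cover midpoint category: ",
         paste(absent, collapse = ", "))
  stats::setNames(factors$factor * scores[src], factors$category)
}

#' Total DALYs over the eight endpoint categories
#'
#' @param per_category named numeric vector of per-category DALYs; all
#'   eight endpoint categories must be present (explicit zeros allowed) and
#'   finite.
#' @return The arithmetic total.
#' @export
total_dalys <- function(per_category) {
  missing_cat <- setdiff(endpoint_categories(), names(per_category))
  if (length(missing_cat))
    stop("missing DALY value for category: ",
         paste(missing_cat, collapse = ", "))
  v <- per_category[endpoint_categories()]
  if (any(!is.finite(v))) stop("DALY values must be finite")
  sum(v)
}

#' DALY-seconds from total DALYs
#'
#' @param total total DALYs (>= 0).
#' @return `total * seconds_per_year()`.
#' @export
daly_seconds <- function(total) {
  if (total < 0) stop("total DALYs must be nonnegative")
  total * seconds_per_year()
}

#' Assemble a DALY result
#'
#' @param per_category named per-category DALYs covering all eight
#'   endpoint categories.
#' @param programme metadata label.
#' @return A `daly_result`: list with `per_category`, `total` and
#'   `seconds`.
#' @export
daly_result <- function(per_category, programme = NA_character_) {
  total <- total_dalys(per_category)
  structure(list(programme = programme,
                 per_category = per_category[endpoint_categories()],
                 total = total,
                 seconds = daly_seconds(total)),
            class = "daly_result")
}

#' @export
print.daly_result <- function(x, ...) {
  cat(sprintf("DALY result (%s)\n", x$programme))
  print(data.frame(category = names(x$per_category),
                   DALYs = signif(x$per_category, 6)), row.names = FALSE)
  cat(sprintf("total: %.6g DALYs = %.4f DALY-seconds\n", x$total, x$seconds))
  invisible(x)
}

#' Bundled reference DALY breakdown for the two programmes
#'
#' Per-category human-health DALY values for the supervised and provision
#' programmes as reported for the original full-database assessment,
#' bundled as a plain-text fixture. Used by the tests and the acceptance
#' analysis to check the summation and DALY-second arithmetic; it is input
#' data, not something this package recomputes (the absolute values depend
#' on a proprietary background database).
#'
#' @return Data frame `(category, supervised, provision)`.
#' @export
reference_daly_table <- function() {
  path <- system.file("extdata", "daly_reference.csv", package = "brushLCA",
                      mustWork = TRUE)
  read_checked_csv(path, c("category", "supervised", "provision"),
                   numeric_cols = c("supervised", "provision"))
}
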