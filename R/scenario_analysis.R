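# Sensitivity scenarios: per-category percent changes against the baseline
# and comparison tables shaped like published LCIA sensitivity tables
# (rows = impact categories, columns = baseline + scenario scores).

#' Signed percent change of a variant against a baseline
#'
#' `(variant - baseline) / baseline * 100`; negative values are reductions.
#' Scale-invariant in its two arguments. Percent changes are always taken
#' relative to the baseline column.
#'
#' @param baseline baseline score (nonzero).
#' @param variant variant score.
#' @return Signed percent change (vectorised).
#' @examples
#' percent_change(1.95, 1.66)   # -14.87..., a 15% reduction
#' report_percent(percent_change(1.95, 1.66))  # -15
#' @export
percent_change <- function(baseline, variant) {
  if (any(baseline == 0))
    stop("percent change undefined for zero baseline")
  (variant - baseline) / baseline * 100
}

#' Round a percent change for narrative reporting
#'
#' Integer rounding, half away from zero, matching the way sensitivity
#' percentages are usually quoted ("reduced by 15%"). The unrounded signed
#' values are always retained in the data model; this helper only formats.
#'
#' @param pct signed percent change(s).
#' @return Integer percent(s), half rounded away from zero.
#' @export
report_percent <- function(pct) {
  sign(pct) * floor(abs(pct) + 0.5)
}

#' Run a programme's sensitivity scenarios
#'
#' Builds the baseline system and one variant per scenario, assesses each
#' against the same characterization table and background, and collects
#' per-category scores and percent changes.
#'
#' @param programme `"supervised"` or `"provision"`.
#' @param cf characterization table used for every run.
#' @param background list of background processes (or a
#'   `synthetic_background_spec`).
#' @param scenarios named list of `scenario` objects; defaults to the
#'   programme's published sensitivity set
#'   (see [default_scenarios()]).
#' @param params baseline parameters (defaults to the programme defaults).
#' @param registry impact registry.
#' @return A `scenario_comparison`: list with `programme`, `baseline`
#'   (`lcia_result`), `scenarios` (list of `lcia_result`), and `table`
#'   (data frame: `category_id`, `unit`, `baseline`, one score column and
#'   one `pct_change_*` column per scenario).
#' @export
run_scenarios <- function(programme = c("supervised", "provision"),
                          cf, background,
                          scenarios = default_scenarios(programme),
                          params = NULL,
                          registry = default_impact_categories()) {
  programme <- match.arg(programme)
  if (inherits(background, "synthetic_background_spec"))
    background <- generate_background_processes(background)
  params <- params %||% (if (programme == "supervised")
    supervised_parameters() else provision_parameters())

  run_one <- function(p, label) {
    sys <- attach_background(build_programme_system(programme, p), background)
    assess_system(sys, cf, registry = registry,
                  programme = programme, scenario = label)
  }
  baseline <- run_one(params, "baseline")
  variants <- lapply(names(scenarios), function(nm) {
    run_one(apply_scenario(params, scenarios[[nm]]), scenarios[[nm]]$name)
  })
  names(variants) <- names(scenarios)

  tab <- data.frame(category_id = registry$id, unit = registry$unit,
                    baseline = unname(baseline$scores),
                    stringsAsFactors = FALSE)
  for (nm in names(variants)) {
    tab[[nm]] <- unname(variants[[nm]]$scores)
    tab[[paste0("pct_change_", nm)]] <-
      percent_change(tab$baseline, tab[[nm]])
  }
  structure(list(programme = programme, baseline = baseline,
                 scenarios = variants, table = tab),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison: %s (baseline + %d scenario%s)\n",
              x$programme, length(x$scenarios),
              if (length(x$scenarios) == 1) "" else "s"))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare two assessments category by category
#'
#' @param baseline,variant two `lcia_result` objects over the same
#'   category registry.
#' @return Data frame `(category_id, baseline, variant, difference,
#'   ratio)`, with `ratio = variant / baseline` (`NA` where the baseline
#'   is zero).
#' @export
compare_programmes <- function(baseline, variant) {
  if (!identical(names(baseline$scores), names(variant$scores)))
    stop("results use different category registries")
  ratio <- ifelse(baseline$scores == 0, NA_real_,
                  variant$scores / baseline$scores)
  data.frame(category_id = names(baseline$scores),
             baseline = unname(baseline$scores),
             variant = unname(variant$scores),
             difference = unname(variant$scores - baseline$scores),
             ratio = unname(ratio),
             stringsAsFactors = FALSE)
}

#' Bundled reference LCIA sensitivity tables
#'
#' The published midpoint scores for the two programmes and their
#' sensitivity columns, bundled as plain-text fixtures (supervised:
#' baseline, bamboo toothbrush, doubled toothpaste; provision: baseline,
#' bamboo toothbrush, paper bag, bamboo + paper bag, excluding water use).
#' Those absolute scores rest on a proprietary background database; this
#' package treats them as input data for percent-change reporting and
#' cross-checks, never as something it recomputes.
#'
#' @param programme `"supervised"` or `"provision"`.
#' @return Data frame with `category_id` plus one numeric column per
#'   published result column.
#' @export
reference_lcia_table <- function(programme = c("supervised", "provision")) {
  programme <- match.arg(programme)
  file <- sprintf("lcia_reference_%s.csv", programme)
  path <- system.file("extdata", file, package = "brushLCA", mustWork = TRUE)
  cols <- if (programme == "supervised")
    c("category_id", "baseline", "bamboo", "double_paste")
  else
    c("category_id", "baseline", "bamboo", "paper_bag", "bamboo_paper_bag",
      "exclude_water")
  read_checked_csv(path, cols, numeric_cols = setdiff(cols, "category_id"))
}
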