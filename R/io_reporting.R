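# CSV readers/writers for every table the pipeline consumes or produces,
# config loading, and the end-to-end pipeline runner.

# Read a CSV and validate its schema; report offending line numbers.
read_checked_csv <- function(path, required_cols, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    if (length(bad))
      stop("file ", path, ", column '", col, "': non-numeric value at line ",
           bad[1] + 1)
    if (anyNA(v))
      stop("file ", path, ", column '", col, "': missing value at line ",
           which(is.na(v))[1] + 1)
    df[[col]] <- v
  }
  df
}

#' Read / write a characterization table
#'
#' Schema `(category_id, flow_id, factor, unit)`. Values round-trip at
#' full double precision; scientific notation (e.g. `5.30E-04`) is
#' accepted on input.
#'
#' @param path file path.
#' @return `read_cf_table` returns the validated table.
#' @export
read_cf_table <- function(path) {
  df <- read_checked_csv(path, c("category_id", "flow_id", "factor", "unit"),
                         numeric_cols = "factor")
  validate_cf_table(df)
  df
}

#' @rdname read_cf_table
#' @param cf table to write.
#' @export
write_cf_table <- function(cf, path) {
  validate_cf_table(cf)
  write_full_precision(cf, path)
  invisible(path)
}

# Full-precision CSV write (so numeric round trips are lossless).
write_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) {
    s <- formatC(v, digits = 17, format = "g")
    trimws(s)
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Serialize / read a product system as two CSVs
#'
#' `processes.csv` holds `(id, name, ref_flow, ref_amount)`;
#' `exchanges.csv` holds `(process_id, flow_id, kind, amount)` with
#' `kind` either `product` (an input) or `elementary`.
#'
#' @param sys a `foreground_system`.
#' @param dir directory to write into (created if needed).
#' @return `write_system` returns the two file paths; `read_system`
#'   rebuilds the `foreground_system` (demand and labels are not part of
#'   the process serialization and must be supplied).
#' @export
write_system <- function(sys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  procs <- do.call(rbind, lapply(sys$processes, function(p) {
    data.frame(id = p$id, name = p$name, ref_flow = p$ref_flow,
               ref_amount = p$ref_amount, stringsAsFactors = FALSE)
  }))
  exch <- do.call(rbind, lapply(sys$processes, function(p) {
    rbind(
      if (length(p$inputs))
        data.frame(process_id = p$id, flow_id = names(p$inputs),
                   kind = "product", amount = unname(p$inputs),
                   stringsAsFactors = FALSE),
      if (length(p$elementary))
        data.frame(process_id = p$id, flow_id = names(p$elementary),
                   kind = "elementary", amount = unname(p$elementary),
                   stringsAsFactors = FALSE))
  }))
  paths <- file.path(dir, c("processes.csv", "exchanges.csv"))
  write_full_precision(procs, paths[1])
  write_full_precision(exch, paths[2])
  invisible(paths)
}

#' @rdname write_system
#' @param demand demand vector for the rebuilt system.
#' @param labels optional contribution labels.
#' @export
read_system <- function(dir, demand, labels = NULL) {
  procs <- read_checked_csv(file.path(dir, "processes.csv"),
                            c("id", "name", "ref_flow", "ref_amount"),
                            numeric_cols = "ref_amount")
  exch <- read_checked_csv(file.path(dir, "exchanges.csv"),
                           c("process_id", "flow_id", "kind", "amount"),
                           numeric_cols = "amount")
  bad <- which(!exch$kind %in% c("product", "elementary"))
  if (length(bad))
    stop("exchanges.csv: invalid kind at line ", bad[1] + 1)
  plist <- lapply(seq_len(nrow(procs)), function(i) {
    rows <- exch[exch$process_id == procs$id[i], , drop = FALSE]
    prod <- rows[rows$kind == "product", , drop = FALSE]
    elem <- rows[rows$kind == "elementary", , drop = FALSE]
    process(procs$id[i], procs$name[i], procs$ref_flow[i],
            procs$ref_amount[i],
            inputs = stats::setNames(prod$amount, prod$flow_id),
            elementary = stats::setNames(elem$amount, elem$flow_id))
  })
  foreground_system(plist, demand, labels)
}

#' Read / write programme parameters and scenarios as YAML
#'
#' Parameters serialize as a flat key/value map; a scenario file holds
#' `name` plus an `overrides` map.
#'
#' @param path file path.
#' @return The parsed object.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(programme_parameters, vals)
}

#' @rdname read_parameters
#' @param params a `programme_parameters` object.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname read_parameters
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$name)) stop("scenario file must contain a 'name'")
  scenario(vals$name, vals$overrides %||% list())
}

#' Pipeline run configuration
#'
#' @param programme `"supervised"` or `"provision"`.
#' @param out_dir output directory.
#' @param seed integer seed driving all synthetic generation.
#' @param overrides named list of parameter overrides applied to the
#'   programme's default parameters.
#' @param scenarios named list of scenarios (default: the programme's
#'   published sensitivity set).
#' @param cf_path optional path to a characterization-table CSV; if `NULL`
#'   a synthetic table is generated from `seed`. Exactly one
#'   characterization source is used.
#' @param normalization_path optional path to a normalization-reference
#'   CSV; default references of 1.0 are used otherwise.
#' @param endpoint_path optional path to an endpoint-factor CSV; synthetic
#'   defaults otherwise.
#' @return A classed `run_config`.
#' @export
run_config <- function(programme, out_dir, seed = 1L,
                       overrides = list(), scenarios = NULL,
                       cf_path = NULL, normalization_path = NULL,
                       endpoint_path = NULL) {
  if (!programme %in% c("supervised", "provision"))
    stop("unknown programme: ", programme)
  structure(list(programme = programme, out_dir = out_dir,
                 seed = as.integer(seed), overrides = overrides,
                 scenarios = scenarios, cf_path = cf_path,
                 normalization_path = normalization_path,
                 endpoint_path = endpoint_path),
            class = "run_config")
}

#' Run the full assessment pipeline
#'
#' End to end for one programme: build the foreground, attach the (read or
#' synthetic) background, run the baseline and sensitivity scenarios,
#' normalize the baseline with the PEF toxicity exclusions, decompose it
#' into component contributions, convert the human-health pathways to
#' DALYs, and write everything to the output directory:
#'
#' * `scenario_comparison.csv` — categories x (baseline + scenarios +
#'   percent changes);
#' * `normalized.csv` — normalized baseline scores with exclusion flags;
#' * `contributions.csv` — per-category component scores and shares;
#' * `daly.csv` — per-pathway DALYs, total and DALY-seconds;
#' * `manifest.json` — seed, config hash, package and R versions, files.
#'
#' Deterministic: the same config produces byte-identical outputs.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the in-memory results bundle
#'   (`comparison`, `normalized`, `contributions`, `daly`, `files`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- default_impact_categories()

  params <- if (config$programme == "supervised") supervised_parameters()
            else provision_parameters()
  if (length(config$overrides))
    params <- apply_scenario(params, scenario("overrides", config$overrides))
  scenarios <- config$scenarios %||% default_scenarios(config$programme)

  spec <- synthetic_background_spec(seed = config$seed)
  cf <- if (is.null(config$cf_path)) generate_cf_table(spec)
        else read_cf_table(config$cf_path)
  background <- generate_background_processes(spec)

  comparison <- run_scenarios(config$programme, cf, background,
                              scenarios = scenarios, params = params,
                              registry = registry)

  refs <- if (is.null(config$normalization_path)) default_normalization_refs(registry)
          else read_normalization_refs(config$normalization_path)
  normalized <- normalize_scores(comparison$baseline, refs)

  sys <- attach_background(build_programme_system(config$programme, params),
                           background)
  contributions <- contribution_by_group(sys, cf, registry = registry)

  epf <- if (is.null(config$endpoint_path)) default_endpoint_factors()
         else read_checked_csv(config$endpoint_path,
                               c("category", "source_category", "factor",
                                 "unit"),
                               numeric_cols = "factor")
  daly <- daly_result(endpoint_convert(comparison$baseline, epf),
                      programme = config$programme)
  daly_df <- rbind(
    data.frame(category = names(daly$per_category),
               dalys = unname(daly$per_category), stringsAsFactors = FALSE),
    data.frame(category = "total", dalys = daly$total),
    data.frame(category = "daly_seconds", dalys = daly$seconds))

  files <- file.path(config$out_dir,
                     c("scenario_comparison.csv", "normalized.csv",
                       "contributions.csv", "daly.csv"))
  write_full_precision(comparison$table, files[1])
  write_full_precision(normalized, files[2])
  write_full_precision(as.data.frame(contributions), files[3])
  write_full_precision(daly_df, files[4])

  manifest <- list(programme = config$programme, seed = config$seed,
                   config_hash = config_hash(config),
                   package = "brushLCA",
                   package_version = as.character(
                     utils::packageVersion("brushLCA")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   files = basename(files))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(comparison = comparison, normalized = normalized,
                 contributions = contributions, daly = daly,
                 files = c(files, manifest_path)))
}

# md5 of the canonical JSON form of the scientific configuration; the output
# location is excluded so identical analyses hash identically wherever they
# are written.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
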