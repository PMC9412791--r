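# Seeded synthetic background: stand-in characterization factors and
# background supply-chain processes.
#
# Real background life-cycle databases are proprietary; this module
# generates structurally faithful stand-ins (nonnegative characterization
# factors spanning orders of magnitude, acyclic background supply chains
# attachable to the foreground's product inputs) as pure functions of a
# seed, so every downstream stage is testable and reproducible. No numeric
# resemblance to any real database is intended.

#' Elementary-flow vocabulary
#'
#' The fixed set of elementary flows the synthetic background emits. One
#' "signature" flow maps to each impact category (CO2 to climate change,
#' SO2 to acidification, phosphate to freshwater eutrophication, and so
#' on), plus extra greenhouse gases and the foreground's end-of-life
#' routes, which keeps per-category contributions interpretable in tests.
#'
#' @return Character vector of flow ids.
#' @export
elementary_flow_vocabulary <- function() {
  c("CO2", "CH4", "N2O", "SO2", "phosphate_freshwater", "nitrogen_marine",
    "NOx", "PM2.5", "NMVOC", "CFC11", "U235", "toxicant_freshwater",
    "toxicant_cancer", "toxicant_noncancer", "water_consumed",
    "land_occupation", "fossil_energy", "antimony",
    "waste_residual", "waste_recycled", "wastewater", "paste_to_drain")
}

#' Background product vocabulary
#'
#' Product flows the foreground systems draw from the background: bulk
#' materials, toothpaste ingredients, electricity, supplied water and road
#' transport.
#'
#' @return Character vector of product-flow ids.
#' @export
background_products <- function() {
  c("polymer", "bamboo", "brass", "cardboard",
    "sorbitol", "silica", "sodium_fluoride", "xanthan_gum",
    "sodium_benzoate", "sls", "electricity", "water_supply", "transport")
}

#' Specification for synthetic background generation
#'
#' @param seed integer RNG seed; all generators are pure functions of this
#'   spec (same spec, byte-identical output).
#' @param n_flows number of elementary flows; the first
#'   `length(elementary_flow_vocabulary())` use the fixed vocabulary, any
#'   excess are generic `flow_<k>` ids.
#' @param registry impact registry the factors are generated for.
#' @param factor_range positive log-uniform bounds `(lo, hi)` for factor
#'   magnitudes; factors span orders of magnitude as in real databases.
#' @param depth levels of acyclic background supply chain behind each
#'   attachable product (0 = elementary exchanges only).
#' @param sparsity fraction of (category, flow) factors set to zero, in
#'   `[0, 1]`.
#' @return A classed `synthetic_background_spec`.
#' @export
synthetic_background_spec <- function(seed = 1L,
                                      n_flows = length(elementary_flow_vocabulary()),
                                      registry = default_impact_categories(),
                                      factor_range = c(1e-4, 10),
                                      depth = 2L,
                                      sparsity = 0.3) {
  if (length(factor_range) != 2 || any(factor_range <= 0) ||
      factor_range[1] > factor_range[2])
    stop("factor_range must be positive increasing bounds")
  if (depth < 0) stop("depth must be >= 0")
  if (sparsity < 0 || sparsity > 1) stop("sparsity must lie in [0, 1]")
  if (n_flows < 1) stop("need at least one elementary flow")
  structure(list(seed = as.integer(seed), n_flows = as.integer(n_flows),
                 registry = registry, factor_range = factor_range,
                 depth = as.integer(depth), sparsity = sparsity),
            class = "synthetic_background_spec")
}

spec_flow_ids <- function(spec) {
  vocab <- elementary_flow_vocabulary()
  if (spec$n_flows <= length(vocab)) vocab[seq_len(spec$n_flows)]
  else c(vocab, sprintf("flow_%02d", seq_len(spec$n_flows - length(vocab))))
}

# Run `expr` with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

runif_log <- function(n, range) {
  10^stats::runif(n, log10(range[1]), log10(range[2]))
}

#' Generate a synthetic characterization table
#'
#' Draws a nonnegative factor for every (category, flow) pair, log-uniform
#' within the spec's magnitude bounds, then zeroes a `sparsity` fraction of
#' the pairs. Deterministic in the spec.
#'
#' @param spec a `synthetic_background_spec`.
#' @return Characterization table `(category_id, flow_id, factor, unit)`.
#' @export
generate_cf_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_background_spec"))
  flows <- spec_flow_ids(spec)
  grid <- expand.grid(flow_id = flows, category_id = spec$registry$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  with_seed(spec$seed, {
    fac <- runif_log(n, spec$factor_range)
    fac[stats::runif(n) < spec$sparsity] <- 0
    cf <- data.frame(category_id = grid$category_id, flow_id = grid$flow_id,
                     factor = fac,
                     unit = paste0(
                       spec$registry$unit[match(grid$category_id,
                                                spec$registry$id)],
                       " per unit flow"),
                     stringsAsFactors = FALSE)
    validate_cf_table(cf)
    cf
  })
}

#' Generate linked acyclic background processes
#'
#' Builds one production process per attachable product (level 0) plus
#' `depth` upstream levels of generic material/energy processes. Each
#' process emits 2-4 elementary flows with log-uniform amounts; every
#' process above the deepest level draws 1-2 product inputs from the next
#' level down, so the supply chain is acyclic by construction.
#' Deterministic in the spec.
#'
#' @param spec a `synthetic_background_spec`.
#' @param products product flows to supply
#'   (default [background_products()]).
#' @return List of `lca_process` objects.
#' @export
generate_background_processes <- function(spec,
                                          products = background_products()) {
  stopifnot(inherits(spec, "synthetic_background_spec"))
  flows <- spec_flow_ids(spec)
  with_seed(spec$seed + 1L, {
    levels <- vector("list", spec$depth + 1)
    # deeper levels: generic upstream products
    if (spec$depth > 0) {
      for (k in seq_len(spec$depth)) {
        levels[[k + 1]] <- sprintf("upstream_L%d_%d", k, seq_len(3))
      }
    }
    levels[[1]] <- products
    procs <- list()
    for (k in rev(seq_along(levels))) {
      for (prod in levels[[k]]) {
        n_elem <- sample(2:4, 1)
        elem_flows <- sample(flows, min(n_elem, length(flows)))
        elementary <- stats::setNames(runif_log(length(elem_flows),
                                                c(1e-3, 1)), elem_flows)
        inputs <- numeric(0)
        if (k < length(levels)) {
          nxt <- levels[[k + 1]]
          n_in <- sample(1:2, 1)
          in_flows <- sample(nxt, min(n_in, length(nxt)))
          inputs <- stats::setNames(runif_log(length(in_flows), c(0.01, 1)),
                                    in_flows)
        }
        procs[[length(procs) + 1]] <- process(
          id = paste0("bg_", prod),
          name = paste0("Synthetic background supply of ", prod),
          ref_flow = prod, ref_amount = 1,
          inputs = inputs, elementary = elementary)
      }
    }
    procs
  })
}

#' Attach a background to a foreground system
#'
#' Merges the background process list into the foreground system and
#' verifies the result is closed (every product input supplied) and
#' acyclic.
#'
#' @param fg a `foreground_system`.
#' @param bg list of background `lca_process` objects (or a
#'   `synthetic_background_spec`, in which case the background is
#'   generated).
#' @return A closed `foreground_system` with the foreground's demand and
#'   labels.
#' @export
attach_background <- function(fg, bg) {
  if (inherits(bg, "synthetic_background_spec"))
    bg <- generate_background_processes(bg)
  sys <- foreground_system(c(unname(fg$processes), unname(bg)),
                           fg$demand, fg$labels)
  assert_closed(sys)
  sys
}

#' Inventory totals by iterative demand expansion (test oracle)
#'
#' Computes the elementary-flow totals of a demand by recursive expansion
#' of product inputs, without matrix algebra. Kept deliberately independent
#' of [solve_scaling()] / [aggregate_inventory()] so the two routes
#' cross-validate each other. Only valid on acyclic systems; a cycle is an
#' error.
#'
#' @param sys a closed `foreground_system`.
#' @param demand named demand vector.
#' @return Named elementary-flow totals.
#' @export
expansion_oracle <- function(sys, demand) {
  assert_closed(sys)
  refs <- vapply(sys$processes, `[[`, "", "ref_flow")
  producer <- stats::setNames(names(sys$processes), refs)
  memo <- new.env(parent = emptyenv())
  # per-unit elementary totals for one unit of a product flow
  unit_totals <- function(flow, path) {
    if (flow %in% path) stop("cycle detected at product flow ", flow)
    key <- flow
    if (!is.null(memo[[key]])) return(memo[[key]])
    p <- sys$processes[[producer[[flow]]]]
    scale <- 1 / p$ref_amount
    tot <- p$elementary * scale
    for (fl in names(p$inputs)) {
      sub <- unit_totals(fl, c(path, flow))
      tot <- add_named(tot, sub * (p$inputs[[fl]] * scale))
    }
    memo[[key]] <- tot
    tot
  }
  out <- numeric(0)
  for (fl in names(demand)) {
    if (!fl %in% names(producer))
      stop("demand for flow not produced by any process: ", fl)
    out <- add_named(out, unit_totals(fl, character(0)) * demand[[fl]])
  }
  out
}

add_named <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(keys)), keys)
  if (length(a)) out[names(a)] <- out[names(a)] + a
  if (length(b)) out[names(b)] <- out[names(b)] + b
  out
}
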