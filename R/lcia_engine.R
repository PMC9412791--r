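# Matrix-based life cycle inventory and impact assessment.
#
# The computational structure is the standard one: a technology matrix A
# (product flows x processes; reference products positive, consumed product
# inputs negative), an intervention matrix B (elementary flows x processes),
# a scaling vector s with A s = f for the functional-unit demand f, the
# inventory g = B s, and midpoint scores h[c] = sum_f cf[c, f] g[f].

#' Technology matrix of a product system
#'
#' Rows are the product flows produced inside the system, columns are
#' processes. Each column has exactly one positive reference-product entry;
#' product inputs that are produced inside the system appear as negative
#' entries. Inputs not produced by any process in the system (background
#' cut-offs) are omitted from A and only matter once a background system is
#' attached.
#'
#' @param sys a `foreground_system` (possibly with background attached).
#' @return Numeric matrix with dimnames (flows, processes).
#' @export
technology_matrix <- function(sys) {
  procs <- sys$processes
  refs <- vapply(procs, `[[`, "", "ref_flow")
  A <- matrix(0, nrow = length(refs), ncol = length(procs),
              dimnames = list(unname(refs), names(procs)))
  for (pid in names(procs)) {
    p <- procs[[pid]]
    A[p$ref_flow, pid] <- A[p$ref_flow, pid] + p$ref_amount
    inside <- intersect(names(p$inputs), rownames(A))
    if (length(inside))
      A[inside, pid] <- A[inside, pid] - p$inputs[inside]
  }
  A
}

#' Intervention matrix of a product system
#'
#' Rows are elementary flows, columns processes; entries are signed
#' exchange amounts per unit process operation.
#'
#' @param sys a `foreground_system`.
#' @return Numeric matrix (elementary flows x processes); zero rows if no
#'   process has elementary exchanges.
#' @export
intervention_matrix <- function(sys) {
  procs <- sys$processes
  flows <- sort(unique(unlist(lapply(procs, function(p) names(p$elementary)))))
  B <- matrix(0, nrow = length(flows), ncol = length(procs),
              dimnames = list(flows, names(procs)))
  for (pid in names(procs)) {
    e <- procs[[pid]]$elementary
    if (length(e)) B[names(e), pid] <- B[names(e), pid] + e
  }
  B
}

#' Solve the inventory scaling vector
#'
#' Finds s with `A s = f`. Accepts either a technology matrix or a product
#' system. Demand for a flow no process produces is a coverage error; a
#' singular or numerically ill-conditioned technology matrix is an
#' inventory-solve error. As the foreground chains here are acyclic the
#' direct dense solve always agrees with iterative demand expansion (the
#' test oracle, [expansion_oracle()]).
#'
#' @param A technology matrix or `foreground_system`.
#' @param demand named numeric vector of functional-unit requirements.
#' @return Named scaling vector over processes.
#' @export
solve_scaling <- function(A, demand) {
  if (inherits(A, "foreground_system")) {
    assert_closed(A)
    A <- technology_matrix(A)
  }
  bad <- setdiff(names(demand), rownames(A))
  if (length(bad))
    stop("demand for flow(s) not produced by any process: ",
         paste(bad, collapse = ", "))
  if (nrow(A) != ncol(A))
    stop("technology matrix is not square after restriction to produced flows")
  f <- stats::setNames(numeric(nrow(A)), rownames(A))
  f[names(demand)] <- demand
  if (rcond(A) < .Machine$double.eps * 1e3)
    stop("technology matrix is singular or ill-conditioned")
  s <- solve(A, f)
  stats::setNames(as.numeric(s), colnames(A))
}

# A closed system has every product input supplied by some process inside it.
assert_closed <- function(sys) {
  refs <- vapply(sys$processes, `[[`, "", "ref_flow")
  inputs <- unique(unlist(lapply(sys$processes,
                                 function(p) names(p$inputs))))
  open <- setdiff(inputs, refs)
  if (length(open))
    stop("system has unsupplied product inputs (attach a background): ",
         paste(open, collapse = ", "))
  invisible(sys)
}

#' Aggregate the life cycle inventory
#'
#' @param B intervention matrix (elementary flows x processes).
#' @param s scaling vector over the same processes.
#' @return Named vector of elementary-flow totals `g = B s`.
#' @export
aggregate_inventory <- function(B, s) {
  if (ncol(B) != length(s))
    stop("dimension mismatch between intervention matrix and scaling vector")
  if (!is.null(names(s)) && !identical(colnames(B), names(s)))
    s <- s[colnames(B)]
  drop(B %*% s)
}

#' Characterize an inventory into midpoint scores
#'
#' `score[c] = sum over flows of cf[c, f] * g[f]`, linear and additive in
#' the inventory.
#'
#' @param g named elementary-flow totals.
#' @param cf characterization table: data frame `(category_id, flow_id,
#'   factor, unit)`.
#' @param registry impact registry (defaults to the 16 standard categories).
#' @param strict if TRUE (default), a flow with nonzero total and no factor
#'   row in any category is an error; if FALSE it is treated as zero with a
#'   warning.
#' @param programme,scenario metadata carried on the result.
#' @return An `lcia_result`: list with `programme`, `scenario`, `scores`
#'   (named over all registry ids) and `units`.
#' @export
characterize <- function(g, cf, registry = default_impact_categories(),
                         strict = TRUE, programme = NA_character_,
                         scenario = "baseline") {
  validate_cf_table(cf)
  active <- names(g)[g != 0]
  uncovered <- setdiff(active, unique(cf$flow_id))
  if (length(uncovered)) {
    msg <- paste0("no characterization factor for flow(s): ",
                  paste(uncovered, collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; treated as zero")
  }
  scores <- stats::setNames(numeric(nrow(registry)), registry$id)
  keep <- cf$flow_id %in% names(g) & cf$category_id %in% registry$id
  cfk <- cf[keep, , drop = FALSE]
  if (nrow(cfk)) {
    contrib <- cfk$factor * g[cfk$flow_id]
    agg <- tapply(contrib, cfk$category_id, sum)
    scores[names(agg)] <- agg
  }
  lcia_result(scores, registry, programme = programme, scenario = scenario)
}

#' Construct an LCIA result
#'
#' @param scores named numeric vector, exactly one score per registry id.
#' @param registry impact registry.
#' @param programme,scenario metadata.
#' @return An `lcia_result` object.
#' @export
lcia_result <- function(scores, registry = default_impact_categories(),
                        programme = NA_character_, scenario = "baseline") {
  if (!setequal(names(scores), registry$id))
    stop("scores must cover exactly the registered categories")
  structure(list(programme = programme, scenario = scenario,
                 scores = scores[registry$id],
                 units = stats::setNames(registry$unit, registry$id)),
            class = "lcia_result")
}

#' @export
print.lcia_result <- function(x, ...) {
  cat(sprintf("LCIA result (%s / %s)\n", x$programme, x$scenario))
  df <- data.frame(category = names(x$scores),
                   score = signif(x$scores, 3),
                   unit = unname(x$units[names(x$scores)]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Normalize midpoint scores against per-capita references
#'
#' Divides each category score by its per-person-per-year reference value.
#' The PEF toxicity categories are excluded (reported as `NA` with an
#' explicit excluded flag, never as zero) by default.
#'
#' @param result an `lcia_result`.
#' @param refs data frame `(category_id, reference_value)` covering every
#'   included category with strictly positive values.
#' @param exclusions character vector of category ids to exclude
#'   (default [pef_excluded_toxicity_ids()]).
#' @return Data frame `(category_id, score, reference_value, normalized,
#'   excluded)`.
#' @export
normalize_scores <- function(result, refs = default_normalization_refs(),
                             exclusions = pef_excluded_toxicity_ids()) {
  ids <- names(result$scores)
  included <- setdiff(ids, exclusions)
  i <- match(included, refs$category_id)
  if (anyNA(i))
    stop("missing normalization reference for category: ",
         paste(included[is.na(i)], collapse = ", "))
  if (any(refs$reference_value[i] <= 0))
    stop("normalization references must be > 0")
  ref <- stats::setNames(rep(NA_real_, length(ids)), ids)
  ref[included] <- refs$reference_value[i]
  out <- data.frame(
    category_id = ids,
    score = unname(result$scores),
    reference_value = unname(ref),
    normalized = unname(result$scores / ref),
    excluded = ids %in% exclusions,
    stringsAsFactors = FALSE)
  out$normalized[out$excluded] <- NA_real_
  out
}

#' Run the full midpoint assessment of a closed system
#'
#' Convenience wrapper: scaling solve, inventory aggregation and
#' characterization in one call.
#'
#' @param sys a closed `foreground_system` (background attached).
#' @param cf characterization table.
#' @param demand demand vector (defaults to the system's own).
#' @inheritParams characterize
#' @return An `lcia_result`.
#' @export
assess_system <- function(sys, cf, demand = sys$demand,
                          registry = default_impact_categories(),
                          strict = TRUE, programme = NA_character_,
                          scenario = "baseline") {
  s <- solve_scaling(sys, demand)
  g <- aggregate_inventory(intervention_matrix(sys), s)
  characterize(g, cf, registry, strict = strict,
               programme = programme, scenario = scenario)
}

#' Contribution analysis by programme component
#'
#' Decomposes each category score into the shares of labelled foreground
#' components (e.g. staff travel, water, toothbrush, toothpaste, bus/bag).
#' Attribution is cradle-to-grave: each component's contribution is the
#' full supply-chain impact of its share of the functional-unit demand, so
#' the group scores sum exactly to the total score by linearity.
#'
#' @param sys a closed `foreground_system`.
#' @param cf characterization table.
#' @param grouping named character vector mapping each demanded process id
#'   to a group label; defaults to the labels the system builders attach.
#' @param demand demand vector (defaults to the system's own).
#' @inheritParams characterize
#' @return A `contribution_breakdown`: data frame `(category_id, group,
#'   score, share_pct)`. Shares are percentages of the per-category total;
#'   where a category total is <= 0 or a group score is negative the share
#'   is `NA` and a warning is raised (absolute scores remain valid).
#' @export
contribution_by_group <- function(sys, cf, grouping = sys$labels,
                                  demand = sys$demand,
                                  registry = default_impact_categories(),
                                  strict = TRUE) {
  refs <- vapply(sys$processes, `[[`, "", "ref_flow")
  producer <- stats::setNames(names(sys$processes), refs)
  dem_proc <- producer[names(demand)]
  unlabeled <- setdiff(unname(dem_proc), names(grouping))
  if (length(unlabeled))
    stop("demanded process(es) without a contribution label: ",
         paste(unlabeled, collapse = ", "))
  groups <- unique(unname(grouping[dem_proc]))
  per_group <- lapply(groups, function(gr) {
    d <- demand[grouping[dem_proc] == gr]
    assess_system(sys, cf, demand = d, registry = registry,
                  strict = strict, scenario = gr)$scores
  })
  names(per_group) <- groups
  totals <- Reduce(`+`, per_group)
  rows <- do.call(rbind, lapply(groups, function(gr) {
    sc <- per_group[[gr]]
    share <- 100 * sc / totals
    bad <- totals <= 0 | sc < 0
    if (any(bad)) share[bad] <- NA_real_
    data.frame(category_id = names(sc), group = gr,
               score = unname(sc), share_pct = unname(share),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(rows$share_pct))
    warning("nonpositive totals or negative group scores: ",
            "shares undefined for some categories, reported as NA")
  structure(rows, class = c("contribution_breakdown", "data.frame"))
}

#' Summary statistics of a contribution breakdown
#'
#' Arithmetic mean, minimum and maximum of the per-category percentage
#' shares for each component group, the form in which contribution results
#' are usually reported (e.g. "averaging 28% of the score, ranging from 3%
#' to 45% across categories").
#'
#' @param breakdown a `contribution_breakdown`.
#' @return Data frame `(group, mean_share, min_share, max_share)`.
#' @export
contribution_summary <- function(breakdown) {
  if (is.null(breakdown) || nrow(breakdown) == 0)
    stop("empty contribution breakdown")
  sp <- split(breakdown$share_pct, breakdown$group)
  out <- do.call(rbind, lapply(names(sp), function(gr) {
    v <- sp[[gr]]
    if (all(is.na(v)))
      stop("all shares undefined for group ", gr)
    data.frame(group = gr,
               mean_share = mean(v, na.rm = TRUE),
               min_share = min(v, na.rm = TRUE),
               max_share = max(v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out[order(-out$mean_share), , drop = FALSE]
}

validate_cf_table <- function(cf) {
  required <- c("category_id", "flow_id", "factor", "unit")
  missing <- setdiff(required, names(cf))
  if (length(missing))
    stop("characterization table is missing columns: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(cf$factor)))
    stop("characterization factors must be finite (row ",
         which(!is.finite(cf$factor))[1], ")")
  invisible(cf)
}
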