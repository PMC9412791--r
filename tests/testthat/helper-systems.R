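# Shared fixtures: tiny hand-built systems and alignment helpers.

# Align two named numeric vectors on the union of their names (absent = 0).
align_flows <- function(a, b) {
  keys <- sort(union(names(a), names(b)))
  out <- matrix(0, nrow = length(keys), ncol = 2,
                dimnames = list(keys, c("a", "b")))
  out[names(a), "a"] <- a
  out[names(b), "b"] <- b
  out
}

max_rel_diff <- function(a, b) {
  m <- align_flows(a, b)
  denom <- pmax(abs(m[, "a"]), abs(m[, "b"]))
  d <- abs(m[, "a"] - m[, "b"])
  ok <- denom > 0
  if (!any(ok)) return(0)
  max(d[ok] / denom[ok])
}

# Two-level chain: one brush item needs 0.015 kg polymer; hand expansion of
# a demand for 5 items draws 0.075 kg polymer.
two_level_chain <- function() {
  foreground_system(
    list(
      process("brush", "Brush", "brush_item",
              inputs = c(polymer = 0.015)),
      process("poly", "Polymer", "polymer",
              elementary = c(CO2 = 2))),
    demand = c(brush_item = 5))
}

# Minimal single-flow characterization table.
unit_cf <- function(flow = "CO2", category = "CC", factor = 1) {
  reg <- default_impact_categories()
  data.frame(category_id = category, flow_id = flow, factor = factor,
             unit = paste(category_unit(reg, category), "per unit"),
             stringsAsFactors = FALSE)
}
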