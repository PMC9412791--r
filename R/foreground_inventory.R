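# Foreground product systems for the two toothbrushing programmes.
#
# Everything is expressed per functional unit: one five-year-old child
# receiving the programme for one year. The foreground holds the processes
# the analyst models explicitly (toothbrush and toothpaste supply, tap-water
# use, staff travel, toothbrush-bus or zip-lock-bag provision); material and
# energy inputs are drawn as product flows from a background system.

# ---- quantity helpers -------------------------------------------------------

#' Litres of tap water from a running tap
#'
#' @param flow_L_per_min tap flow rate in litres per minute (a typical UK
#'   tap runs at about 6 L/min).
#' @param seconds total time the tap runs per brushing episode.
#' @return Litres used per episode: `flow_L_per_min * seconds / 60`.
#' @examples
#' tap_run_litres(6, 20)  # 2 L per episode
#' @export
tap_run_litres <- function(flow_L_per_min, seconds) {
  if (flow_L_per_min < 0 || seconds < 0)
    stop("tap flow rate and duration must be nonnegative")
  flow_L_per_min * seconds / 60
}

#' Annual tap-water use
#'
#' @param L_per_episode litres per brushing episode.
#' @param episodes_per_year brushing episodes per year (195 school days for
#'   the supervised programme; 2 x 365 for twice-daily home brushing).
#' @return Litres per child-year.
#' @examples
#' annual_water_litres(2, 195)  # 390 L
#' annual_water_litres(2, 730)  # 1460 L
#' @export
annual_water_litres <- function(L_per_episode, episodes_per_year) {
  if (L_per_episode < 0 || episodes_per_year < 0)
    stop("water per episode and episodes per year must be nonnegative")
  L_per_episode * episodes_per_year
}

#' Generic toothpaste recipe by mass fraction
#'
#' Splits a total toothpaste mass into the seven ingredients of the generic
#' fluoride-toothpaste formulation used here (sodium fluoride active
#' ingredient, silica abrasive, xanthan gum binder, sorbitol humectant,
#' water solvent, sodium benzoate preservative, sodium lauryl sulphate
#' foaming agent). The mass fractions sum to exactly 100%.
#'
#' @param total_mass_g total paste mass in grams.
#' @return Named numeric vector of ingredient masses in grams, summing to
#'   `total_mass_g`.
#' @examples
#' toothpaste_recipe(100)["sorbitol"]  # 53.66 g
#' @export
toothpaste_recipe <- function(total_mass_g) {
  if (total_mass_g < 0) stop("toothpaste mass must be nonnegative")
  fr <- toothpaste_fractions()
  fr * total_mass_g
}

#' @rdname toothpaste_recipe
#' @return `toothpaste_fractions` returns the dimensionless mass fractions
#'   (summing to 1).
#' @export
toothpaste_fractions <- function() {
  c(sodium_fluoride = 0.00315,
    silica          = 0.25,
    xanthan_gum     = 0.015,
    sorbitol        = 0.5366,
    water           = 0.175,
    sodium_benzoate = 0.00275,
    sls             = 0.0175)
}

#' Mixing energy allocated to one toothpaste tube
#'
#' Electricity for industrial paste mixing (a 68 kW, 500 L barrel mixer run
#' for 2.4 hours per batch in the default model), allocated to a single tube
#' by volume share.
#'
#' @param power_kW mixer power draw.
#' @param hours mixing time per batch.
#' @param batch_volume_L batch size in litres (> 0).
#' @param tube_volume_mL tube volume in millilitres (> 0).
#' @return kWh per tube: `power_kW * hours * tube_volume_mL / (batch_volume_L * 1000)`.
#' @examples
#' mixing_energy_per_tube(68, 2.4, 500, 100)  # 0.03264 kWh
#' @export
mixing_energy_per_tube <- function(power_kW, hours, batch_volume_L,
                                   tube_volume_mL) {
  if (batch_volume_L <= 0 || tube_volume_mL <= 0)
    stop("batch and tube volumes must be strictly positive")
  if (power_kW < 0 || hours < 0)
    stop("power and mixing time must be nonnegative")
  power_kW * hours * tube_volume_mL / (batch_volume_L * 1000)
}

#' Delivery travel allocated to one child
#'
#' One member of dental staff drives a small van on a round trip covering
#' two schools (about 180 children) once per delivery; deliveries happen
#' quarterly. The commute leg is configurable and defaults to zero.
#'
#' @param round_trip_km round-trip distance per delivery trip.
#' @param children_per_trip children covered per trip (> 0).
#' @param trips_per_year delivery trips per year.
#' @param commute_km staff commute distance attributed per trip (default 0).
#' @return km per child-year.
#' @export
per_child_travel_km <- function(round_trip_km, children_per_trip,
                                trips_per_year, commute_km = 0) {
  if (children_per_trip <= 0) stop("children per trip must be > 0")
  if (round_trip_km < 0 || trips_per_year < 0 || commute_km < 0)
    stop("distances and trip counts must be nonnegative")
  trips_per_year * (round_trip_km + commute_km) / children_per_trip
}

#' Toothbrush-holder ('bus') mass allocated to one child
#'
#' The supervised programme stores brushes in a ten-brush holder made of
#' 177 g of acrylonitrile-butadiene-styrene, replaced each school term
#' (three per year).
#'
#' @param bus_mass_g holder mass in grams.
#' @param buses_per_year holders used per year.
#' @param children_per_bus children sharing one holder (> 0).
#' @return grams per child-year.
#' @export
per_child_bus_mass <- function(bus_mass_g, buses_per_year, children_per_bus) {
  if (children_per_bus <= 0) stop("children per bus must be > 0")
  if (bus_mass_g < 0 || buses_per_year < 0)
    stop("bus mass and count must be nonnegative")
  bus_mass_g * buses_per_year / children_per_bus
}

# ---- programme parameters ---------------------------------------------------

parameter_field_names <- function() {
  c("brushes_per_year", "tubes_per_year", "paste_g_per_episode",
    "episodes_per_year", "water_L_per_episode", "bus_units_per_year",
    "bus_mass_g", "children_per_bus", "bag_mass_g", "bags_per_year",
    "round_trip_km", "children_per_trip", "trips_per_year", "commute_km",
    "brush_material", "bag_material")
}

#' Programme parameter sets
#'
#' `programme_parameters()` builds a validated parameter list;
#' `supervised_parameters()` and `provision_parameters()` return the default
#' study conditions for the two programmes:
#'
#' * supervised toothbrushing in schools: 5 brushes/child-year, 0.65 tubes
#'   of toothpaste, 0.25 g paste per episode, 195 school-day episodes, 2 L
#'   tap water per episode, three 177 g brush buses shared by 10 children,
#'   quarterly 13 km delivery round trips covering 180 children;
#' * targeted provision of brushes and toothpaste: 4 brushes and 4 tubes
#'   (one 100 ml tube per quarterly pack), 730 twice-daily home episodes,
#'   2 L per episode, 4 zip-lock bags of 1.5 g, same delivery assumptions,
#'   no brush bus.
#'
#' @param ... parameter fields; see `parameter_field_names()`.
#' @return A classed list of programme parameters.
#' @export
programme_parameters <- function(...) {
  p <- list(...)
  unknown <- setdiff(names(p), parameter_field_names())
  if (length(unknown))
    stop("unknown programme parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(parameter_field_names(), names(p))
  if (length(missing))
    stop("missing programme parameter(s): ", paste(missing, collapse = ", "))
  validate_parameters(structure(p[parameter_field_names()],
                                class = "programme_parameters"))
}

validate_parameters <- function(p) {
  num <- setdiff(parameter_field_names(), c("brush_material", "bag_material"))
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("parameter '", f, "' must be a single nonnegative number")
  }
  for (f in c("children_per_bus", "children_per_trip"))
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0")
  if (!p$brush_material %in% c("plastic", "bamboo"))
    stop("brush_material must be 'plastic' or 'bamboo'")
  if (!p$bag_material %in% c("plastic", "paper"))
    stop("bag_material must be 'plastic' or 'paper'")
  p
}

#' @rdname programme_parameters
#' @export
supervised_parameters <- function() {
  programme_parameters(
    brushes_per_year = 5, tubes_per_year = 0.65, paste_g_per_episode = 0.25,
    episodes_per_year = 195, water_L_per_episode = tap_run_litres(6, 20),
    bus_units_per_year = 3, bus_mass_g = 177, children_per_bus = 10,
    bag_mass_g = 0, bags_per_year = 0,
    round_trip_km = 13, children_per_trip = 180, trips_per_year = 4,
    commute_km = 0, brush_material = "plastic", bag_material = "plastic")
}

#' @rdname programme_parameters
#' @export
provision_parameters <- function() {
  programme_parameters(
    brushes_per_year = 4, tubes_per_year = 4,
    paste_g_per_episode = 4 * 100 / 730,
    episodes_per_year = 730, water_L_per_episode = tap_run_litres(6, 20),
    bus_units_per_year = 0, bus_mass_g = 177, children_per_bus = 10,
    bag_mass_g = 1.5, bags_per_year = 4,
    round_trip_km = 13, children_per_trip = 180, trips_per_year = 4,
    commute_km = 0, brush_material = "plastic", bag_material = "plastic")
}

# ---- scenarios --------------------------------------------------------------

#' Sensitivity scenarios
#'
#' A scenario is a named set of parameter overrides applied on top of a
#' programme's baseline parameters. `apply_scenario()` is idempotent for
#' identical overrides and rejects unknown parameter names.
#'
#' @param name scenario label.
#' @param overrides named list of parameter overrides.
#' @return `scenario()` returns a classed scenario object.
#' @export
scenario <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1)
  unknown <- setdiff(names(overrides), parameter_field_names())
  if (length(unknown))
    stop("scenario '", name, "' overrides unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  structure(list(name = name, overrides = overrides), class = "scenario")
}

#' @rdname scenario
#' @param params a `programme_parameters` object.
#' @param scn a `scenario`.
#' @return `apply_scenario()` returns the parameters with overrides applied;
#'   untouched fields are identical.
#' @export
apply_scenario <- function(params, scn) {
  if (!inherits(scn, "scenario")) stop("'scn' must be a scenario object")
  for (f in names(scn$overrides)) params[[f]] <- scn$overrides[[f]]
  validate_parameters(params)
}

#' Default scenario sets for the two programmes
#'
#' The supervised programme ships with the bamboo-toothbrush swap and the
#' doubled (realistically dispensed) toothpaste amount; the provision
#' programme with bamboo brushes, paper bags, both together, and exclusion
#' of at-home water use.
#'
#' @param programme `"supervised"` or `"provision"`.
#' @return Named list of `scenario` objects.
#' @export
default_scenarios <- function(programme = c("supervised", "provision")) {
  programme <- match.arg(programme)
  if (programme == "supervised") {
    list(
      bamboo = scenario("bamboo toothbrush",
                        list(brush_material = "bamboo")),
      double_paste = scenario("0.5 g toothpaste per episode",
                              list(tubes_per_year = 1.3,
                                   paste_g_per_episode = 0.5)))
  } else {
    list(
      bamboo = scenario("bamboo toothbrush",
                        list(brush_material = "bamboo")),
      paper_bag = scenario("paper bag",
                           list(bag_material = "paper")),
      bamboo_paper_bag = scenario("bamboo toothbrush and paper bag",
                                  list(brush_material = "bamboo",
                                       bag_material = "paper")),
      exclude_water = scenario("excluding water use",
                               list(water_L_per_episode = 0)))
  }
}

# ---- process / system constructors ------------------------------------------

#' Construct a unit process
#'
#' @param id,name process identifiers.
#' @param ref_flow id of the flow the process produces.
#' @param ref_amount amount of reference product per unit operation (> 0).
#' @param inputs named numeric vector of product-flow inputs per unit
#'   operation (amounts >= 0).
#' @param elementary named numeric vector of elementary exchanges (signed).
#' @return A classed `lca_process`.
#' @export
process <- function(id, name, ref_flow, ref_amount = 1,
                    inputs = numeric(0), elementary = numeric(0)) {
  if (ref_amount <= 0) stop("reference amount must be > 0 for ", id)
  inputs <- inputs[inputs != 0]
  if (length(inputs) && any(inputs < 0))
    stop("product inputs must be nonnegative for ", id)
  if (ref_flow %in% names(inputs))
    stop("process ", id, " may not consume its own reference product")
  structure(list(id = id, name = name, ref_flow = ref_flow,
                 ref_amount = ref_amount, inputs = inputs,
                 elementary = elementary),
            class = "lca_process")
}

#' Construct a foreground product system
#'
#' @param processes list of `lca_process` objects.
#' @param demand named numeric vector: functional-unit requirement per
#'   product flow. Every demanded flow must be the reference product of
#'   exactly one process, and the product-input graph must be acyclic.
#' @param labels named character vector mapping demanded process ids to
#'   contribution-analysis group labels (optional).
#' @return A classed `foreground_system`.
#' @export
foreground_system <- function(processes, demand, labels = NULL) {
  ids <- vapply(processes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate process ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(processes) <- ids
  refs <- vapply(processes, `[[`, "", "ref_flow")
  if (anyDuplicated(refs))
    stop("product flows produced by more than one process: ",
         paste(unique(refs[duplicated(refs)]), collapse = ", "))
  bad <- setdiff(names(demand), refs)
  if (length(bad))
    stop("demanded flows not produced by any process: ",
         paste(bad, collapse = ", "))
  sys <- structure(list(processes = processes, demand = demand,
                        labels = labels),
                   class = "foreground_system")
  assert_acyclic(sys)
  sys
}

# Topological check on the product-input graph (edges only to flows that are
# produced inside the system; unlinked inputs are background cut-offs).
assert_acyclic <- function(sys) {
  refs <- vapply(sys$processes, `[[`, "", "ref_flow")
  producer <- stats::setNames(names(sys$processes), refs)
  state <- new.env(parent = emptyenv())
  visit <- function(pid, path) {
    if (pid %in% path) stop("cycle detected in product-input graph at ", pid)
    if (isTRUE(state[[pid]])) return(invisible())
    for (fl in names(sys$processes[[pid]]$inputs)) {
      if (fl %in% names(producer)) visit(producer[[fl]], c(path, pid))
    }
    state[[pid]] <- TRUE
  }
  for (pid in names(sys$processes)) visit(pid, character(0))
  invisible(sys)
}

# Component masses and process energies for the foreground bill of
# materials. The toothbrush teardown masses, packaging masses and machine
# energies other than the paste mixer are not study-reported quantities:
# they are documented placeholder defaults standing in for a separately
# published toothbrush inventory, and are exposed here so users can replace
# them.

#' Foreground bill-of-materials placeholders
#'
#' Component masses (kg per item) and energies (kWh per item) for the
#' foreground processes. Apart from the paste-mixer energy, the 100 ml tube
#' volume, the 177 g brush bus and the 1.5 g zip-lock bag, these are
#' placeholder values (e.g. 15 g polypropylene handle + 0.5 g nylon
#' bristles for the plastic brush; 10 g handle for bamboo) and are not
#' study-reported quantities.
#'
#' @return Named list of numeric defaults.
#' @export
component_defaults <- function() {
  list(
    brush_plastic_polymer_kg = 0.0155,   # 15 g PP handle + 0.5 g bristles
    brush_plastic_packaging_kg = 0.004,
    brush_plastic_energy_kWh = 0.02,
    brush_plastic_transport_km = 0.010,
    brush_bamboo_handle_kg = 0.010,
    brush_bamboo_bristle_kg = 0.0005,
    brush_bamboo_brass_kg = 0.0002,
    brush_bamboo_packaging_kg = 0.003,
    brush_bamboo_energy_kWh = 0.015,
    brush_bamboo_transport_km = 0.012,
    tube_content_g = 100,                # 100 ml tube at density 1.0 g/ml
    tube_polymer_kg = 0.010,
    tube_packaging_kg = 0.005,
    tube_fill_energy_kWh = 0.010,
    tube_transport_km = 0.008,
    mixer_power_kW = 68,
    mixer_hours = 2.4,
    mixer_batch_L = 500,
    bus_energy_kWh = 0.03,
    bus_transport_km = 0.005)
}

brush_process <- function(material, comp = component_defaults()) {
  if (material == "plastic") {
    process(
      id = "brush_plastic", name = "Plastic toothbrush, per item",
      ref_flow = "toothbrush",
      inputs = c(polymer = comp$brush_plastic_polymer_kg,
                 cardboard = comp$brush_plastic_packaging_kg,
                 electricity = comp$brush_plastic_energy_kWh,
                 transport = comp$brush_plastic_transport_km),
      elementary = c(waste_residual = comp$brush_plastic_polymer_kg,
                     waste_recycled = comp$brush_plastic_packaging_kg))
  } else {
    process(
      id = "brush_bamboo", name = "Bamboo toothbrush, per item",
      ref_flow = "toothbrush",
      inputs = c(bamboo = comp$brush_bamboo_handle_kg,
                 polymer = comp$brush_bamboo_bristle_kg,
                 brass = comp$brush_bamboo_brass_kg,
                 cardboard = comp$brush_bamboo_packaging_kg,
                 electricity = comp$brush_bamboo_energy_kWh,
                 transport = comp$brush_bamboo_transport_km),
      elementary = c(
        waste_residual = comp$brush_bamboo_handle_kg +
          comp$brush_bamboo_bristle_kg + comp$brush_bamboo_brass_kg,
        waste_recycled = comp$brush_bamboo_packaging_kg))
  }
}

toothpaste_process <- function(comp = component_defaults()) {
  recipe_kg <- toothpaste_recipe(comp$tube_content_g) / 1000
  mix_kWh <- mixing_energy_per_tube(comp$mixer_power_kW, comp$mixer_hours,
                                    comp$mixer_batch_L, comp$tube_content_g)
  inputs <- c(
    sorbitol = unname(recipe_kg["sorbitol"]),
    silica = unname(recipe_kg["silica"]),
    sodium_fluoride = unname(recipe_kg["sodium_fluoride"]),
    xanthan_gum = unname(recipe_kg["xanthan_gum"]),
    sodium_benzoate = unname(recipe_kg["sodium_benzoate"]),
    sls = unname(recipe_kg["sls"]),
    water_supply = unname(recipe_kg["water"]),  # 1 kg ~ 1 L process water
    polymer = comp$tube_polymer_kg,
    cardboard = comp$tube_packaging_kg,
    electricity = mix_kWh + comp$tube_fill_energy_kWh,
    transport = comp$tube_transport_km)
  process(
    id = "toothpaste", name = "Fluoride toothpaste, per 100 ml tube",
    ref_flow = "toothpaste_tube",
    inputs = inputs,
    # empty tube binned, box recycled, paste eventually rinsed to drain
    elementary = c(waste_residual = comp$tube_polymer_kg,
                   waste_recycled = comp$tube_packaging_kg,
                   paste_to_drain = comp$tube_content_g / 1000))
}

water_use_process <- function() {
  process(id = "tap_water_use", name = "Tap water use, per litre",
          ref_flow = "tap_water",
          inputs = c(water_supply = 1),
          elementary = c(wastewater = 1))
}

travel_process <- function() {
  process(id = "staff_travel", name = "Staff delivery travel, per km (small van)",
          ref_flow = "travel_km",
          inputs = c(transport = 1))
}

bus_process <- function(comp = component_defaults()) {
  process(id = "brush_bus", name = "Toothbrush bus holder, per item (177 g ABS)",
          ref_flow = "bus_item",
          inputs = c(polymer = 0.177,
                     electricity = comp$bus_energy_kWh,
                     transport = comp$bus_transport_km),
          elementary = c(waste_residual = 0.177))
}

bag_process <- function(material, bag_mass_g) {
  mass_kg <- bag_mass_g / 1000
  inputs <- if (material == "plastic") c(polymer = mass_kg)
            else c(cardboard = mass_kg)
  process(id = "ziplock_bag",
          name = sprintf("Zip-lock bag (%s), per item", material),
          ref_flow = "bag_item",
          inputs = inputs,
          elementary = c(waste_recycled = mass_kg))
}

#' Build the supervised-toothbrushing product system
#'
#' Per child-year the functional unit demands `brushes_per_year` brushes
#' (default 5), `tubes_per_year` toothpaste tubes (default 0.65), the annual
#' tap water (default 390 L), the per-child share of the toothbrush bus
#' (3 x 177 g holders shared by 10 children) and of the quarterly delivery
#' travel (13 km round trip over 180 children). End-of-life routes follow
#' the stated assumptions: brushes and empty tubes to residual waste,
#' packaging recycled, excess paste and water to the drain.
#'
#' @param params a `programme_parameters` object
#'   (default `supervised_parameters()`).
#' @param comp component placeholder defaults, see [component_defaults()].
#' @return A `foreground_system` with contribution labels
#'   (toothbrush / toothpaste / water / bus / staff travel).
#' @export
build_supervised_system <- function(params = supervised_parameters(),
                                    comp = component_defaults()) {
  brush <- brush_process(params$brush_material, comp)
  procs <- list(brush, toothpaste_process(comp), water_use_process(),
                travel_process(), bus_process(comp))
  demand <- c(
    toothbrush = params$brushes_per_year,
    toothpaste_tube = params$tubes_per_year,
    tap_water = annual_water_litres(params$water_L_per_episode,
                                    params$episodes_per_year),
    travel_km = per_child_travel_km(params$round_trip_km,
                                    params$children_per_trip,
                                    params$trips_per_year,
                                    params$commute_km),
    bus_item = params$bus_units_per_year / params$children_per_bus)
  labels <- c(stats::setNames("toothbrush", brush$id),
              toothpaste = "toothpaste", tap_water_use = "water",
              staff_travel = "staff travel", brush_bus = "bus")
  foreground_system(procs, demand, labels)
}

#' Build the provision-of-brushes-and-toothpaste product system
#'
#' Per child-year: 4 brushes, 4 x 100 ml toothpaste tubes, 4 zip-lock bags
#' of 1.5 g each, 1,460 L of home tap water (2 L per episode, twice daily
#' over 365 days) and the quarterly delivery travel share; no toothbrush
#' bus.
#'
#' @inheritParams build_supervised_system
#' @return A `foreground_system` with contribution labels
#'   (toothbrush / toothpaste / water / bag / staff travel).
#' @export
build_provision_system <- function(params = provision_parameters(),
                                   comp = component_defaults()) {
  brush <- brush_process(params$brush_material, comp)
  procs <- list(brush, toothpaste_process(comp), water_use_process(),
                travel_process(),
                bag_process(params$bag_material, params$bag_mass_g))
  demand <- c(
    toothbrush = params$brushes_per_year,
    toothpaste_tube = params$tubes_per_year,
    tap_water = annual_water_litres(params$water_L_per_episode,
                                    params$episodes_per_year),
    travel_km = per_child_travel_km(params$round_trip_km,
                                    params$children_per_trip,
                                    params$trips_per_year,
                                    params$commute_km),
    bag_item = params$bags_per_year)
  labels <- c(stats::setNames("toothbrush", brush$id),
              toothpaste = "toothpaste", tap_water_use = "water",
              staff_travel = "staff travel", ziplock_bag = "bag")
  foreground_system(procs, demand, labels)
}

#' Build a programme system by name
#'
#' @param programme `"supervised"` or `"provision"`.
#' @param params optional parameter set (defaults to the programme's
#'   defaults).
#' @param comp component placeholder defaults.
#' @return A `foreground_system`.
#' @export
build_programme_system <- function(programme = c("supervised", "provision"),
                                   params = NULL,
                                   comp = component_defaults()) {
  programme <- match.arg(programme)
  if (programme == "supervised")
    build_supervised_system(params %||% supervised_parameters(), comp)
  else
    build_provision_system(params %||% provision_parameters(), comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
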