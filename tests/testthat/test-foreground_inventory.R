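test_that("tap and annual water arithmetic reproduces the stated usage", {
  expect_equal(tap_run_litres(6, 20), 2)
  expect_equal(tap_run_litres(6, 0), 0)
  expect_equal(tap_run_litres(12, 20), 4)
  expect_error(tap_run_litres(-1, 20), "nonnegative")

  expect_equal(annual_water_litres(2, 195), 390)
  expect_equal(annual_water_litres(2, 730), 1460)
  expect_equal(annual_water_litres(0, 195), 0)
  expect_error(annual_water_litres(2, -1), "nonnegative")
})

test_that("toothpaste recipe conserves mass across the seven ingredients", {
  r <- toothpaste_recipe(100)
  expect_length(r, 7L)
  expect_equal(unname(r["sorbitol"]), 53.66)
  expect_equal(unname(r["sodium_fluoride"]), 0.315)
  expect_equal(sum(toothpaste_fractions()), 1, tolerance = 1e-15)
  expect_equal(sum(r), 100, tolerance = 1e-12)
  expect_equal(unname(toothpaste_recipe(0)), rep(0, 7))
  expect_error(toothpaste_recipe(-1), "nonnegative")
  # conservation at arbitrary masses
  for (m in c(0.37, 12, 250)) {
    expect_equal(sum(toothpaste_recipe(m)), m, tolerance = 1e-12 * max(m, 1))
    expect_true(all(toothpaste_recipe(m) >= 0))
  }
})

test_that("mixer energy, travel and bus-mass allocation match hand arithmetic", {
  expect_equal(mixing_energy_per_tube(68, 2.4, 500, 100), 68 * 2.4 / 5000)
  expect_equal(mixing_energy_per_tube(68, 0, 500, 100), 0)
  expect_equal(mixing_energy_per_tube(68, 2.4, 500, 500), 0.1632)
  expect_error(mixing_energy_per_tube(68, 2.4, 0, 100), "strictly positive")

  expect_equal(per_child_travel_km(13, 180, 4), 13 * 4 / 180,
               tolerance = 1e-12)
  expect_equal(per_child_travel_km(13, 180, 1), 13 / 180, tolerance = 1e-12)
  expect_equal(per_child_travel_km(0, 180, 4), 0)
  expect_error(per_child_travel_km(13, 0, 4), "> 0")

  expect_equal(per_child_bus_mass(177, 3, 10), 53.1)
  expect_equal(per_child_bus_mass(177, 1, 10), 17.7)
  expect_equal(per_child_bus_mass(177, 0, 10), 0)
  expect_error(per_child_bus_mass(177, 3, 0), "> 0")
})

test_that("supervised system demands the stated functional-unit amounts", {
  sys <- build_supervised_system()
  expect_equal(unname(sys$demand["tap_water"]), 390)
  expect_equal(unname(sys$demand["toothbrush"]), 5)
  expect_equal(unname(sys$demand["toothpaste_tube"]), 0.65)
  expect_equal(unname(sys$demand["bus_item"]), 0.3)
  expect_equal(unname(sys$demand["travel_km"]), 13 * 4 / 180,
               tolerance = 1e-12)
  expect_true("brush_plastic" %in% names(sys$processes))
  expect_equal(supervised_parameters()$episodes_per_year, 195)
})

test_that("bamboo swap replaces the brush process but not the water demand", {
  p <- apply_scenario(supervised_parameters(),
                      default_scenarios("supervised")$bamboo)
  sys <- build_supervised_system(p)
  expect_true("brush_bamboo" %in% names(sys$processes))
  expect_false("brush_plastic" %in% names(sys$processes))
  expect_equal(unname(sys$demand["tap_water"]), 390)
})

test_that("provision system demands quarterly packs and home water", {
  sys <- build_provision_system()
  expect_equal(unname(sys$demand["toothpaste_tube"]), 4)
  expect_equal(unname(sys$demand["toothbrush"]), 4)
  expect_equal(unname(sys$demand["tap_water"]), 1460)
  expect_equal(unname(sys$demand["bag_item"]), 4)
  expect_equal(provision_parameters()$episodes_per_year, 730)
  bag <- sys$processes$ziplock_bag
  expect_equal(unname(bag$inputs["polymer"]), 0.0015)

  p <- apply_scenario(provision_parameters(),
                      default_scenarios("provision")$exclude_water)
  sys0 <- build_provision_system(p)
  expect_equal(unname(sys0$demand["tap_water"]), 0)
  expect_equal(sys0$demand[names(sys0$demand) != "tap_water"],
               sys$demand[names(sys$demand) != "tap_water"])
})

test_that("scenario application is validated, identity-safe and idempotent", {
  p <- supervised_parameters()
  p2 <- apply_scenario(p, default_scenarios("supervised")$double_paste)
  expect_equal(p2$tubes_per_year, 1.3)
  expect_equal(p2$paste_g_per_episode, 0.5)
  same <- setdiff(parameter_field_names(),
                  c("tubes_per_year", "paste_g_per_episode"))
  expect_equal(p2[same], p[same])

  expect_equal(apply_scenario(p, scenario("noop")), p)
  expect_error(scenario("bad", list(toothbrush_color = "red")),
               "unknown parameter")
  p3 <- apply_scenario(p, scenario("paper", list(bag_material = "paper")))
  expect_equal(p3$bag_material, "paper")
  expect_equal(p3[setdiff(names(p3), "bag_material")],
               p[setdiff(names(p), "bag_material")])
  # idempotent
  scn <- default_scenarios("supervised")$bamboo
  expect_equal(apply_scenario(apply_scenario(p, scn), scn),
               apply_scenario(p, scn))
})

test_that("built systems satisfy acyclicity and demand coverage", {
  for (sys in list(build_supervised_system(), build_provision_system())) {
    refs <- vapply(sys$processes, function(p) p$ref_flow, "")
    expect_true(all(names(sys$demand) %in% refs))
  }
  # a cycle is rejected at construction
  expect_error(
    foreground_system(
      list(process("a", "A", "fa", inputs = c(fb = 1)),
           process("b", "B", "fb", inputs = c(fa = 1))),
      demand = c(fa = 1)),
    "cycle")
  expect_error(
    foreground_system(list(process("a", "A", "fa")), demand = c(fz = 1)),
    "not produced")
})
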