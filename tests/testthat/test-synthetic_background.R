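test_that("generators are pure functions of the spec", {
  spec <- synthetic_background_spec(seed = 42)
  expect_identical(generate_cf_table(spec), generate_cf_table(spec))
  b1 <- generate_background_processes(spec)
  b2 <- generate_background_processes(spec)
  expect_identical(b1, b2)
  # a different seed changes the draw
  other <- generate_cf_table(synthetic_background_spec(seed = 43))
  expect_false(identical(generate_cf_table(spec)$factor, other$factor))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_cf_table(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("factor tables honour sparsity and magnitude bounds", {
  full <- generate_cf_table(synthetic_background_spec(seed = 1, sparsity = 0))
  expect_true(all(full$factor > 0))
  expect_equal(nrow(full), 16 * length(elementary_flow_vocabulary()))

  none <- generate_cf_table(synthetic_background_spec(seed = 1, sparsity = 1))
  expect_true(all(none$factor == 0))

  ones <- generate_cf_table(synthetic_background_spec(
    seed = 1, sparsity = 0, factor_range = c(1, 1)))
  expect_true(all(ones$factor == 1))

  bounded <- generate_cf_table(synthetic_background_spec(
    seed = 2, sparsity = 0, factor_range = c(0.5, 2)))
  expect_true(all(bounded$factor >= 0.5 & bounded$factor <= 2))

  expect_error(synthetic_background_spec(sparsity = 1.2), "sparsity")
  expect_error(synthetic_background_spec(factor_range = c(-1, 1)),
               "factor_range")
  expect_error(synthetic_background_spec(depth = -1), "depth")
})

test_that("background chains have the requested depth structure", {
  flat <- generate_background_processes(
    synthetic_background_spec(seed = 6, depth = 0))
  expect_true(all(vapply(flat, function(p) length(p$inputs) == 0, TRUE)))
  expect_true(all(vapply(flat, function(p) length(p$elementary) > 0, TRUE)))
  expect_setequal(vapply(flat, function(p) p$ref_flow, ""),
                  background_products())

  deep <- generate_background_processes(
    synthetic_background_spec(seed = 6, depth = 3))
  # attachable and acyclic: foreground_system() enforces the invariants
  sys <- attach_background(build_supervised_system(), deep)
  expect_s3_class(sys, "foreground_system")
  top <- vapply(deep, function(p) p$ref_flow, "")
  expect_true(any(grepl("^upstream_L3", top)))
})

test_that("expansion oracle matches hand expansion and handles errors", {
  chain <- two_level_chain()
  g <- expansion_oracle(chain, chain$demand)
  expect_equal(unname(g["CO2"]), 5 * 0.015 * 2)

  single <- foreground_system(
    list(process("p", "P", "f", elementary = c(CO2 = 2, CH4 = 0.1))),
    demand = c(f = 1))
  expect_equal(expansion_oracle(single, c(f = 1)),
               c(CO2 = 2, CH4 = 0.1))

  expect_error(expansion_oracle(single, c(nope = 1)), "not produced")
})

test_that("matrix solve agrees with the expansion oracle on 100 seeded systems", {
  fg_sup <- build_supervised_system()
  fg_prov <- build_provision_system()
  worst <- 0
  for (seed in 1:100) {
    spec <- synthetic_background_spec(seed = seed,
                                      depth = seed %% 4)  # depths 0..3
    bg <- generate_background_processes(spec)
    fg <- if (seed %% 2 == 0) fg_sup else fg_prov
    sys <- attach_background(fg, bg)
    s <- solve_scaling(sys, sys$demand)
    g_matrix <- aggregate_inventory(intervention_matrix(sys), s)
    g_oracle <- expansion_oracle(sys, sys$demand)
    worst <- max(worst, max_rel_diff(g_matrix, g_oracle))
  }
  expect_lt(worst, 1e-9)
})
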