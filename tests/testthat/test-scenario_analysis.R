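test_that("percent change is signed, baseline-relative and scale-invariant", {
  expect_equal(percent_change(1.95, 1.66), -14.8718, tolerance = 1e-4)
  expect_equal(report_percent(percent_change(1.95, 1.66)), -15)
  expect_equal(percent_change(11.7, 19.6), 67.5214, tolerance = 1e-4)
  expect_equal(report_percent(percent_change(11.7, 19.6)), 68)
  expect_equal(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), "zero baseline")
  # scale invariance
  for (k in c(0.001, 2, -7)) {
    expect_equal(percent_change(1.95 * k, 1.66 * k),
                 percent_change(1.95, 1.66), tolerance = 1e-9)
  }
  # half rounds away from zero in both directions
  expect_equal(report_percent(c(2.5, -2.5, 0.49, -0.49)), c(3, -3, 0, 0))
})

test_that("rounding helper reproduces the narrative sensitivity percentages", {
  sup <- reference_lcia_table("supervised")
  pick <- function(tab, id, col) {
    report_percent(percent_change(tab$baseline[tab$category_id == id],
                                  tab[[col]][tab$category_id == id]))
  }
  # bamboo toothbrush, supervised: climate -15, land use +68,
  # freshwater eutrophication -28, minerals/metals -23, water -5
  expect_equal(pick(sup, "CC", "bamboo"), -15)
  expect_equal(pick(sup, "RLU", "bamboo"), 68)
  expect_equal(pick(sup, "EUF", "bamboo"), -28)
  expect_equal(pick(sup, "RMM", "bamboo"), -23)
  expect_equal(pick(sup, "RDW", "bamboo"), -5)

  prov <- reference_lcia_table("provision")
  # excluding water use: climate -36, water -81, freshwater eutroph. -49
  expect_equal(pick(prov, "CC", "exclude_water"), -36)
  expect_equal(pick(prov, "RDW", "exclude_water"), -81)
  expect_equal(pick(prov, "EUF", "exclude_water"), -49)
  # bamboo toothbrush, provision: climate -6
  expect_equal(pick(prov, "CC", "bamboo"), -6)
})

test_that("scenario runs produce the published comparison shapes", {
  spec <- synthetic_background_spec(seed = 4)
  cf <- generate_cf_table(spec)
  bg <- generate_background_processes(spec)

  sup <- run_scenarios("supervised", cf, bg)
  expect_s3_class(sup, "scenario_comparison")
  expect_length(sup$scenarios, 2L)   # baseline + 2 result columns
  expect_equal(nrow(sup$table), 16L)
  expect_true(all(c("baseline", "bamboo", "double_paste",
                    "pct_change_bamboo") %in% names(sup$table)))

  prov <- run_scenarios("provision", cf, bg)
  expect_length(prov$scenarios, 4L)  # baseline + 4 result columns
  expect_setequal(names(prov$scenarios),
                  c("bamboo", "paper_bag", "bamboo_paper_bag",
                    "exclude_water"))

  empty <- run_scenarios("supervised", cf, bg, scenarios = list())
  expect_length(empty$scenarios, 0L)
  expect_equal(names(empty$table),
               c("category_id", "unit", "baseline"))
})

test_that("excluding water removes exactly the water contribution", {
  spec <- synthetic_background_spec(seed = 21)
  cf <- generate_cf_table(spec)
  bg <- generate_background_processes(spec)
  comp <- run_scenarios("provision", cf, bg)

  sys <- attach_background(build_provision_system(), bg)
  cb <- contribution_by_group(sys, cf)
  water <- cb[cb$group == "water", ]
  water_scores <- stats::setNames(water$score, water$category_id)

  base <- comp$baseline$scores
  excl <- comp$scenarios$exclude_water$scores
  expect_equal(excl, base - water_scores[names(base)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("programme comparison yields elementwise differences and ratios", {
  reg <- default_impact_categories()
  a <- lcia_result(stats::setNames(rep(2, 16), reg$id), reg)
  b <- lcia_result(stats::setNames(rep(4, 16), reg$id), reg)
  cmp <- compare_programmes(a, b)
  expect_true(all(cmp$difference == 2))
  expect_true(all(cmp$ratio == 2))

  same <- compare_programmes(a, a)
  expect_true(all(same$difference == 0))
  expect_true(all(same$ratio == 1))

  set.seed(3)
  x <- lcia_result(stats::setNames(runif(16, 1, 5), reg$id), reg)
  y <- lcia_result(stats::setNames(runif(16, 1, 5), reg$id), reg)
  cmp2 <- compare_programmes(x, y)
  expect_equal(cmp2$difference, unname(y$scores - x$scores))
  expect_equal(cmp2$ratio, unname(y$scores / x$scores))

  reg2 <- register_category(reg, "XX", "extra", "m", "u")
  z <- lcia_result(stats::setNames(rep(1, 17), reg2$id), reg2)
  expect_error(compare_programmes(a, z), "different category registries")
})
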