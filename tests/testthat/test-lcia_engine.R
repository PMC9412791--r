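test_that("scaling solve handles diagonal, chained and degenerate systems", {
  # diagonal system: scaling equals demand
  sys <- foreground_system(
    list(process("p1", "P1", "f1", elementary = c(CO2 = 1)),
         process("p2", "P2", "f2", elementary = c(CH4 = 1))),
    demand = c(f1 = 3, f2 = 7))
  s <- solve_scaling(sys, sys$demand)
  expect_equal(s, c(p1 = 3, p2 = 7))

  # two-level chain: 5 brushes at 0.015 kg polymer each draw 0.075 kg
  chain <- two_level_chain()
  s <- solve_scaling(chain, chain$demand)
  expect_equal(unname(s["poly"]), 0.075)
  g <- aggregate_inventory(intervention_matrix(chain), s)
  expect_equal(unname(g["CO2"]), 0.15)

  # demand for an unproduced flow
  expect_error(solve_scaling(technology_matrix(chain), c(unobtainium = 1)),
               "not produced")

  # a zero column makes the matrix singular
  A <- technology_matrix(chain)
  A[, "poly"] <- 0
  expect_error(solve_scaling(A, c(brush_item = 5)), "singular")
})

test_that("technology matrix has one positive reference entry per column", {
  sys <- attach_background(build_supervised_system(),
                           synthetic_background_spec(seed = 3))
  A <- technology_matrix(sys)
  expect_equal(nrow(A), ncol(A))
  for (j in seq_len(ncol(A))) {
    expect_equal(sum(A[, j] > 0), 1L)
  }
})

test_that("inventory aggregation equals brute-force dot products", {
  set.seed(11)
  B <- matrix(rnorm(6 * 4), nrow = 6,
              dimnames = list(paste0("e", 1:6), paste0("p", 1:4)))
  s <- stats::setNames(runif(4), paste0("p", 1:4))
  g <- aggregate_inventory(B, s)
  brute <- vapply(seq_len(6), function(i) sum(B[i, ] * s), 0)
  expect_equal(unname(g), brute, tolerance = 1e-12)
  expect_equal(unname(aggregate_inventory(B, s * 0)), rep(0, 6))
  expect_error(aggregate_inventory(B, s[1:3]), "dimension mismatch")
})

test_that("characterization is the double-loop sum, linear and additive", {
  reg <- default_impact_categories()
  # unit factor: 2 kg CO2 scores 2 in climate change
  res <- characterize(c(CO2 = 2), unit_cf())
  expect_equal(unname(res$scores["CC"]), 2)
  expect_equal(unname(res$scores["RDW"]), 0)
  expect_length(res$scores, 16L)

  # seeded random CF and inventory vs brute-force double loop
  set.seed(42)
  flows <- paste0("f", 1:8)
  cf <- expand.grid(category_id = reg$id, flow_id = flows,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cf$factor <- runif(nrow(cf))
  cf$unit <- "u"
  g1 <- stats::setNames(runif(8), flows)
  g2 <- stats::setNames(runif(8), flows)
  r1 <- characterize(g1, cf)
  brute <- vapply(reg$id, function(c_id) {
    sum(vapply(flows, function(f) {
      cf$factor[cf$category_id == c_id & cf$flow_id == f] * g1[[f]]
    }, 0))
  }, 0)
  expect_equal(r1$scores, brute, tolerance = 1e-12)

  # additivity and homogeneity
  r12 <- characterize(g1 + g2, cf)
  r2 <- characterize(g2, cf)
  expect_equal(r12$scores, r1$scores + r2$scores, tolerance = 1e-12)
  expect_equal(characterize(3 * g1, cf)$scores, 3 * r1$scores,
               tolerance = 1e-12)

  # all-zero factors give all-zero scores
  cf0 <- cf; cf0$factor <- 0
  expect_true(all(characterize(g1, cf0)$scores == 0))

  # strict mode rejects uncovered nonzero flows; lenient warns
  expect_error(characterize(c(CO2 = 1, mystery = 2), unit_cf()),
               "no characterization factor")
  expect_warning(characterize(c(CO2 = 1, mystery = 2), unit_cf(),
                              strict = FALSE),
                 "treated as zero")
})

test_that("doubling demand doubles every midpoint score", {
  spec <- synthetic_background_spec(seed = 5)
  cf <- generate_cf_table(spec)
  sys <- attach_background(build_provision_system(), spec)
  r1 <- assess_system(sys, cf)
  r2 <- assess_system(sys, cf, demand = sys$demand * 2)
  expect_equal(r2$scores, 2 * r1$scores, tolerance = 1e-9)
})

test_that("normalization divides by references and flags PEF exclusions", {
  reg <- default_impact_categories()
  scores <- stats::setNames(rep(5, 16), reg$id)
  res <- lcia_result(scores, reg)
  norm <- normalize_scores(res, default_normalization_refs(reg, value = 1))
  expect_equal(norm$normalized[norm$category_id == "CC"], 5)
  excl <- norm[norm$excluded, "category_id"]
  expect_setequal(excl, pef_excluded_toxicity_ids())
  expect_true(all(is.na(norm$normalized[norm$excluded])))
  expect_false(any(norm$normalized[norm$excluded] %in% 0))

  # forced by division: 8.37 against a reference of 8370 is 0.1%
  scores["RDW"] <- 8.37
  refs <- default_normalization_refs(reg)
  refs$reference_value[refs$category_id == "RDW"] <- 8370
  norm2 <- normalize_scores(lcia_result(scores, reg), refs)
  expect_equal(norm2$normalized[norm2$category_id == "RDW"], 0.001)

  # missing or nonpositive references are errors
  expect_error(normalize_scores(res, refs[refs$category_id != "CC", ]),
               "missing normalization reference")
  refs$reference_value[1] <- 0
  expect_error(normalize_scores(res, refs), "> 0")
  # nonnegative, dimensionless outputs for nonnegative inputs
  expect_true(all(norm$normalized[!norm$excluded] >= 0))
})

test_that("group contributions conserve the total score per category", {
  spec <- synthetic_background_spec(seed = 9)
  cf <- generate_cf_table(spec)
  sys <- attach_background(build_supervised_system(), spec)
  total <- assess_system(sys, cf)
  cb <- contribution_by_group(sys, cf)
  sums <- tapply(cb$score, cb$category_id, sum)
  expect_equal(sums[names(total$scores)], total$scores,
               tolerance = 1e-9, ignore_attr = TRUE)
  shares <- tapply(cb$share_pct, cb$category_id, sum)
  expect_equal(as.vector(shares), rep(100, 16), tolerance = 1e-6)

  # single group and symmetric two-group cases
  one <- foreground_system(
    list(process("a", "A", "fa", elementary = c(CO2 = 1))),
    demand = c(fa = 2), labels = c(a = "only"))
  # only the CC category has a nonzero total here, so the other 15
  # categories legitimately warn about undefined shares
  cb1 <- suppressWarnings(contribution_by_group(one, unit_cf()))
  expect_equal(cb1$share_pct[cb1$category_id == "CC"], 100)

  twin <- foreground_system(
    list(process("a", "A", "fa", elementary = c(CO2 = 1)),
         process("b", "B", "fb", elementary = c(CO2 = 1))),
    demand = c(fa = 1, fb = 1), labels = c(a = "g1", b = "g2"))
  cb2 <- suppressWarnings(contribution_by_group(twin, unit_cf()))
  expect_equal(cb2$share_pct[cb2$category_id == "CC"], c(50, 50))

  # a demanded process without a label is an error
  expect_error(contribution_by_group(twin, unit_cf(),
                                     grouping = c(a = "g1")),
               "without a contribution label")
})

test_that("contribution summary gives mean and range of shares", {
  bd <- data.frame(category_id = rep(c("CC", "RDW"), each = 1),
                   group = "x", score = 1, share_pct = c(10, 50))
  s <- contribution_summary(bd)
  expect_equal(s$mean_share, 30)
  expect_equal(s$min_share, 10)
  expect_equal(s$max_share, 50)

  const <- data.frame(category_id = paste0("c", 1:16), group = "y",
                      score = 1, share_pct = 30)
  s2 <- contribution_summary(const)
  expect_equal(c(s2$mean_share, s2$min_share, s2$max_share), c(30, 30, 30))

  one <- data.frame(category_id = "CC", group = "z", score = 1,
                    share_pct = 100)
  s3 <- contribution_summary(one)
  expect_equal(c(s3$mean_share, s3$min_share, s3$max_share), c(100, 100, 100))

  expect_error(contribution_summary(bd[0, ]), "empty")
})
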