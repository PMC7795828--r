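test_that("piecewise-linear membership interpolates and vanishes outside support", {
  tri <- mf_triangle(25, 50, 75)
  expect_equal(membership(tri, 50), 1)
  expect_equal(membership(tri, 37.5), 0.5)
  expect_equal(membership(tri, 100), 0)
  expect_equal(membership(tri, 0), 0)
  # shoulder trapezoids hold membership 1 at the range edge
  lo <- mf_trapezoid(0, 0, 20, 40)
  expect_equal(membership(lo, 0), 1)
  expect_equal(membership(lo, 30), 0.5)
  hi <- mf_trapezoid(60, 80, 100, 100)
  expect_equal(membership(hi, 100), 1)
  expect_error(membership_function(c(1, 1, 2), c(0, 1, 0)))
  expect_error(membership_function(c(1, 2), c(0, 2)))
})

test_that("centroid defuzzification matches closed forms", {
  g <- seq(0, 100, by = 0.05)
  tri <- mf_triangle(25, 50, 75)
  expect_equal(cog_defuzzify(list(x = g, mu = membership(tri, g))), 50,
               tolerance = 1e-3)
  # plateau [0,20] descending to 40: centroid (1400/3) / 30
  trap <- mf_trapezoid(0, 0, 20, 40)
  expect_equal(cog_defuzzify(list(x = g, mu = membership(trap, g))),
               1400 / 3 / 30, tolerance = 0.05)
  # COG is invariant to uniform scaling: any constant over [20, 60] -> 40
  for (c_ in c(0.2, 0.5, 1)) {
    mu <- ifelse(g >= 20 & g <= 60, c_, 0)
    expect_equal(cog_defuzzify(list(x = g, mu = mu)), 40, tolerance = 0.05)
  }
  expect_error(cog_defuzzify(list(x = g, mu = numeric(length(g)))),
               "no rule fired")
})

test_that("rule evaluation clips consequents and aggregates by pointwise max", {
  fis <- default_fis(resolution = 0.1)
  # sensitivity 0 / similarity 100: exactly one rule at full activation;
  # aggregate equals the unclipped no_change set
  agg <- evaluate_rules(fis, 0, 100)
  expect_equal(agg$mu, membership(fis$drift$terms$no_change, agg$x))
  # inputs in a dead zone of a tiny FIS: aggregate identically zero
  one_term <- fuzzy_variable("v", c(0, 100), list(lo = mf_trapezoid(0, 0, 10, 20)))
  tiny <- fis_config(
    sensitivity = one_term,
    similarity = fuzzy_variable("similarity", c(0, 100),
                                list(lo = mf_trapezoid(0, 0, 10, 20))),
    drift = fuzzy_variable("drift", c(0, 100),
                           list(mid = mf_triangle(25, 50, 75))),
    rules = data.frame(sensitivity = "lo", similarity = "lo", drift = "mid"))
  expect_true(all(evaluate_rules(tiny, 90, 90)$mu == 0))
  # two clipped rules: aggregate is the pointwise max of the clipped sets
  agg2 <- evaluate_rules(fis, 70, 45)
  ref <- numeric(length(agg2$x))
  for (r in seq_len(nrow(fis$rules))) {
    act <- min(membership(fis$sensitivity$terms[[fis$rules$sensitivity[r]]], 70),
               membership(fis$similarity$terms[[fis$rules$similarity[r]]], 45))
    ref <- pmax(ref, pmin(act, membership(fis$drift$terms[[fis$rules$drift[r]]],
                                          agg2$x)))
  }
  expect_equal(agg2$mu, ref)
  expect_warning(evaluate_rules(fis, 150, 50), "clamped")
})

test_that("the default FIS assesses the canonical corner case", {
  fis <- default_fis()
  a <- fis_assess(fis, 0, 100)
  expect_equal(a$crisp, 1400 / 3 / 30, tolerance = 0.05)
  expect_equal(unname(a$degrees["no_change"]), 1)
  expect_equal(drift_verdict(a), "no_change")
  # a degenerate always-firing rule onto a symmetric triangle centres at 50
  all_term <- function(nm) fuzzy_variable(nm, c(0, 100),
                                          list(any = mf_trapezoid(0, 0, 100, 100)))
  degen <- fis_config(
    sensitivity = all_term("sensitivity"),
    similarity = all_term("similarity"),
    drift = fuzzy_variable("drift", c(0, 100),
                           list(mid = mf_triangle(25, 50, 75))),
    rules = data.frame(sensitivity = "any", similarity = "any", drift = "mid"))
  expect_equal(fis_assess(degen, 30, 70)$crisp, 50, tolerance = 1e-6)
})

test_that("output stays in range and degrees stay in [0,1]", {
  fis <- default_fis()
  set.seed(5)
  for (i in 1:25) {
    a <- fis_assess(fis, runif(1, 0, 100), runif(1, 0, 100))
    expect_gte(a$crisp, 0)
    expect_lte(a$crisp, 100)
    expect_true(all(a$degrees >= 0 & a$degrees <= 1))
  }
})

test_that("halving the resolution moves the centroid by less than the coarser step", {
  set.seed(6)
  for (i in 1:10) {
    s <- runif(1, 0, 100); m <- runif(1, 0, 100)
    c1 <- fis_assess(default_fis(resolution = 1), s, m)$crisp
    c2 <- fis_assess(default_fis(resolution = 0.5), s, m)$crisp
    expect_lt(abs(c1 - c2), 1)
  }
})

test_that("the Mamdani pipeline agrees with an independent dense-grid oracle", {
  fis <- default_fis(resolution = 0.05)
  set.seed(8)
  for (i in 1:20) {
    s <- runif(1, 0, 100); m <- runif(1, 0, 100)
    expect_equal(fis_assess(fis, s, m)$crisp, mamdani_oracle(fis, s, m),
                 tolerance = 0.05)
  }
})

test_that("FIS configs load from YAML with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "resolution: 0.1",
    "variables:",
    "  sensitivity:",
    "    range: [0, 100]",
    "    terms:",
    "      low: {trapezoid: [0, 0, 20, 40]}",
    "      high: {trapezoid: [60, 80, 100, 100]}",
    "  similarity:",
    "    range: [0, 100]",
    "    terms:",
    "      low: {trapezoid: [0, 0, 30, 50]}",
    "      high: {trapezoid: [50, 70, 100, 100]}",
    "  drift:",
    "    range: [0, 100]",
    "    terms:",
    "      no_change: {trapezoid: [0, 0, 20, 40]}",
    "      change: {points: [[60, 0], [80, 1], [100, 1]]}",
    "rules:",
    "  - {sensitivity: high, similarity: low, drift: change}",
    "  - {sensitivity: low, similarity: high, drift: no_change}"
  ), path)
  fis <- read_fis_config(path)
  expect_s3_class(fis, "fis_config")
  expect_equal(nrow(fis$rules), 2L)
  expect_equal(membership(fis$drift$terms$change, 80), 1)
  a <- fis_assess(fis, 100, 0)
  expect_equal(drift_verdict(a), "change")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("variables: {}"), bad)
  expect_error(read_fis_config(bad), "rules")
})

test_that("ties in the verdict break toward the more severe term", {
  a <- structure(list(crisp = 50,
                      degrees = c(no_change = 0.4, moderate_change = 0.4,
                                  change = 0.2)),
                 class = "drift_assessment")
  expect_equal(drift_verdict(a), "moderate_change")
})
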