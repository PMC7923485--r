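concave_maut <- function(k_c = 0.3, k_h = 0.5, c_hi = 2e5, h_hi = 1)
  maut_model(utility_curve("power", shape = 0.7, lo = 0, hi = c_hi),
             utility_curve("power", shape = 0.8, lo = 0, hi = h_hi),
             k_c = k_c, k_h = k_h)

acea_base <- function(theta = 0.01, r_h = 0.5)
  list(u = bivariate_utility("interaction", r_c = 1, beta = 0.2,
                             r_h = r_h, theta = theta),
       scenario = health_scenario(0.1, 45000, 50000, 0.5, 1, 0.2),
       plan = insurance_plan(5000), gamma = 1)

test_that("scenario grids validate their levels and base", {
  b <- list(model = concave_maut())
  expect_error(scenario_grid("maut", b, "income", c(3e4, 3e4)),
               "strictly increasing")
  expect_error(scenario_grid("maut", b, "income", 5e4), "at least two")
  g <- scenario_grid("maut", b, "income", c(3e4, 6e4, 9e4), seed = 5L)
  expect_s3_class(g, "scenario_grid")
  expect_identical(g$seed, 5L)
})

test_that("MCDA properties 1-3: trade-off falls with technology cost, rises
          with income and with severity", {
  b <- list(model = concave_maut(), pi = 0.1, p = 20000, coverage = 1,
            income = 8e4, h_eval = 0.4)
  inc <- comparative_statics(
    scenario_grid("maut", b, "income", seq(3e4, 9e4, by = 1.5e4)))
  expect_true(inc$pass)
  expect_identical(inc$property, "MCDA-2")
  cost <- comparative_statics(
    scenario_grid("maut", b, "technology_cost", seq(0, 2e5, by = 5e4)))
  expect_true(cost$pass)
  expect_identical(cost$property, "MCDA-1")
  sev <- comparative_statics(
    scenario_grid("maut", b, "severity", seq(0.1, 0.9, by = 0.2)))
  expect_true(sev$pass)
  expect_identical(sev$property, "MCDA-3")
  # the trade-off strictly moved in each sweep (not vacuous flatness)
  expect_gt(max(inc$values) / min(inc$values), 1 + 1e-6)
})

test_that("ACEA properties 1-3 hold for complements and independent
          utilities", {
  for (theta in c(0, 0.01)) {
    b <- acea_base(theta = theta)
    inc <- comparative_statics(
      scenario_grid("acea", b, "income", c(0.6, 0.8, 1, 1.25, 1.5)))
    expect_true(inc$pass)
    expect_identical(inc$property, "ACEA-2")
    cost <- comparative_statics(
      scenario_grid("acea", b, "technology_cost", seq(0, 2e4, by = 5e3)))
    expect_true(cost$pass)
    expect_identical(cost$property, "ACEA-1")
    sev <- comparative_statics(
      scenario_grid("acea", b, "severity", seq(0.2, 0.7, by = 0.1)))
    expect_true(sev$pass)
    expect_identical(sev$property, "ACEA-3")
  }
})

test_that("infeasible sweep levels are excluded and recorded", {
  b <- list(model = concave_maut(c_hi = 1e5), pi = 0.1, p = 0,
            income = 8e4, h_eval = 0.4)
  rep <- comparative_statics(
    scenario_grid("maut", b, "income", c(5e4, 9e4, 2e5)))
  expect_length(rep$excluded, 1L)
  expect_match(rep$excluded, "outside the MAUT consumption range")
  expect_true(rep$pass)
})

test_that("risk-neutral models yield constant trade-offs on any sweep", {
  m <- maut_model(utility_curve("linear", lo = 0, hi = 2e5),
                  utility_curve("linear", lo = 0, hi = 1),
                  k_c = 0.4, k_h = 0.6)
  rep <- comparative_statics(
    scenario_grid("maut", list(model = m, h_eval = 0.3),
                  "income", seq(3e4, 1.8e5, by = 3e4)))
  v <- rep$values
  expect_lte(stats::sd(v) / mean(v), 1e-10)
  lin_u <- bivariate_utility("additive", r_c = 0, beta = 2000, r_h = 0)
  b <- list(u = lin_u,
            scenario = health_scenario(0.1, 45000, 50000, 0.5, 1, 0.2),
            plan = insurance_plan(0), gamma = 1)
  for (fac in c("income", "severity")) {
    rep <- comparative_statics(
      scenario_grid("acea", b, fac,
                    if (fac == "income") c(0.5, 1, 1.5, 2)
                    else c(0.2, 0.4, 0.6)))
    v <- rep$values
    expect_lte(stats::sd(v) / mean(v), 1e-10)
    expect_true(rep$pass)
  }
})

test_that("greater risk aversion amplifies the trade-off response", {
  # power-utility curvature: exponent 0.5 is more risk averse than 0.9
  delta_vto <- function(r_c) {
    u <- bivariate_utility("additive", r_c = r_c, beta = 0.2, r_h = 0.5)
    s1 <- health_scenario(0.1, 5e4, 5e4, 0.5, 1, 0.2)
    s2 <- health_scenario(0.1, 5.5e4, 5.5e4, 0.5, 1, 0.2)
    abs(acea_vto(u, s2) - acea_vto(u, s1))
  }
  expect_gte(delta_vto(1 - 0.5), delta_vto(1 - 0.9))
})

test_that("trade-offs are positive over random valid models, with invalid
          points excluded rather than counted", {
  set.seed(41)
  maut_cases <- lapply(1:200, function(i) {
    m <- rand_maut()
    p <- rand_point(m)
    list(model = m, c = p$c, h = p$h)
  })
  rep_m <- verify_positivity(maut_cases, "maut")
  expect_true(rep_m$pass)
  expect_identical(length(rep_m$excluded), 0L)
  expect_true(all(rep_m$values > 0))

  acea_cases <- lapply(1:200, function(i)
    list(u = rand_bivariate(), scenario = rand_scenario()))
  rep_a <- verify_positivity(acea_cases, "acea")
  expect_true(rep_a$pass)
  expect_true(all(rep_a$values > 0))

  # a degenerate bracket is excluded and reported, not a violation
  bad <- suppressWarnings(
    maut_model(utility_curve("linear", lo = 0, hi = 1),
               utility_curve("linear", lo = 0, hi = 1),
               k_c = 0.5, k_h = 1))
  rep_bad <- verify_positivity(c(maut_cases[1:3],
                                 list(list(model = bad, c = 1, h = 1))),
                               "maut")
  expect_true(rep_bad$pass)
  expect_length(rep_bad$excluded, 1L)
})

test_that("MAUT and ACEA trade-offs move together under complements and
          independence, and zero perturbations change nothing", {
  cases <- list(
    complements = list(maut = concave_maut(k_c = 0.3, k_h = 0.5),
                       acea = acea_base(theta = 0.01)),
    independent = list(maut = concave_maut(k_c = 0.4, k_h = 0.6),
                       acea = acea_base(theta = 0)))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    rep <- concordance(cs$maut, cs$acea$u, cs$acea$scenario, cs$acea$plan)
    expect_true(rep$full_agreement)
    expect_equal(rep$fraction, 1)
    # every individual change is strict, in the predicted direction
    expect_identical(rep$table$maut_sign,
                     unname(c(income = 1L, cost = -1L, severity = 1L)
                            [rep$table$factor]))
    expect_identical(rep$table$acea_sign, rep$table$maut_sign)
  }
  cs <- cases$complements
  rep0 <- concordance(cs$maut, cs$acea$u, cs$acea$scenario, cs$acea$plan,
                      perturbations = list(income = 0, severity = 0))
  expect_true(all(rep0$table$maut_sign == 0L))
  expect_true(all(rep0$table$acea_sign == 0L))
})

test_that("a substitutes parameterization produces a flagged disagreement", {
  ex <- find_discordant_example(seed = 7L)
  expect_false(ex$report$full_agreement)
  expect_lt(ex$report$fraction, 1)
  expect_lt(ex$maut$constants$K, 0)
  expect_gt(cross_partial(ex$u, ex$scenario$y_w, ex$scenario$h_s), 0)
})

test_that("concordance rejects misaligned configurations", {
  cs <- acea_base()
  small <- concave_maut(c_hi = 4e4)  # cannot hold the perturbed income
  expect_error(concordance(small, cs$u, cs$scenario, cs$plan),
               "configuration error")
  expect_error(concordance(concave_maut(), cs$u, cs$scenario,
                           insurance_plan(0),
                           perturbations = list(cost = 0.1)),
               "positive technology cost")
})

test_that("formulary rule funds iff ICER is at or below the threshold", {
  expect_true(formulary_decision(50000, 100000)$funded)
  expect_false(formulary_decision(150000, 100000)$funded)
  eq <- formulary_decision(100000, 100000)
  expect_true(eq$funded)
  expect_true(eq$indifferent)
  expect_false(formulary_decision(100000, 100000, tie = "reject")$funded)
  expect_error(formulary_decision(5e4, -1), "threshold")
  # scale invariance
  set.seed(42)
  for (i in 1:50) {
    icer <- runif(1, 1e3, 2e5); thr <- runif(1, 1e3, 2e5)
    k <- runif(1, 0.01, 100)
    expect_identical(formulary_decision(icer, thr)$funded,
                     formulary_decision(k * icer, k * thr)$funded)
  }
})
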