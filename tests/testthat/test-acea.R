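log_u <- function(beta = 0.2) bivariate_utility("additive", r_c = 1,
                                                beta = beta, r_h = 0)
base_s <- function(dh_s = 0.25)
  health_scenario(pi = 0.1, y_s = 50000, y_w = 50000, h_s = 0.5, h_w = 1,
                  dh_s = dh_s)

test_that("bivariate families evaluate correctly with consistent partials", {
  u <- log_u()
  expect_equal(eval_bivariate(u, 50000, 1), log(50000) + 0.2)
  expect_equal(partial_c(u, 50000, 1), 1 / 50000)
  expect_equal(partial_h(u, 50000, 1), 0.2)
  expect_equal(cross_partial(u, 50000, 1), 0)

  set.seed(31)
  for (i in 1:30) {
    uu <- rand_bivariate(share = c(-0.2, 0.5))
    cc <- runif(1, 5e3, 8e4); hh <- runif(1, 0.2, 1)
    d_c <- 1e-4 * cc; d_h <- 1e-4
    fd_c <- (eval_bivariate(uu, cc + d_c, hh) -
             eval_bivariate(uu, cc - d_c, hh)) / (2 * d_c)
    fd_h <- (eval_bivariate(uu, cc, hh + d_h) -
             eval_bivariate(uu, cc, hh - d_h)) / (2 * d_h)
    expect_equal(partial_c(uu, cc, hh), fd_c, tolerance = 1e-6)
    expect_equal(partial_h(uu, cc, hh), fd_h, tolerance = 1e-6)
    expect_gt(partial_c(uu, cc, hh), 0)
    expect_gt(partial_h(uu, cc, hh), 0)
  }
})

test_that("custom evaluator utilities get finite-difference partials", {
  u <- bivariate_utility("custom", f = function(c, h) c * h)
  expect_equal(partial_c(u, 2, 3), 3, tolerance = 1e-8)
  expect_equal(partial_h(u, 2, 3), 2, tolerance = 1e-8)
  expect_equal(cross_partial(u, 2, 3), 1, tolerance = 1e-6)
})

test_that("complementarity classification follows the sign of the
          cross-partial", {
  expect_identical(complementarity_class(log_u(), 50000, 0.7), "independent")
  u_comp <- bivariate_utility("custom", f = function(c, h) c * h)
  expect_identical(complementarity_class(u_comp, 10, 0.5), "complements")
  u_sub <- bivariate_utility("custom", f = function(c, h) c + h - c * h)
  expect_identical(complementarity_class(u_sub, 0.5, 0.5), "substitutes")
  u_int <- bivariate_utility("interaction", r_c = 1, beta = 0.2, r_h = 0.5,
                             theta = 0.01)
  expect_identical(complementarity_class(u_int, 3e4, 0.5), "complements")
})

test_that("scenario and plan constructors enforce their invariants", {
  expect_error(health_scenario(1.2, 1e4, 2e4, 0.5, 1, 0), "pi")
  expect_error(health_scenario(0.1, 3e4, 2e4, 0.5, 1, 0), "y_w >= y_s")
  expect_error(health_scenario(0.1, 1e4, 2e4, 1, 0.5, 0), "h_w > h_s")
  expect_error(health_scenario(0.1, 1e4, 2e4, 0.5, 1, 0.7), "dh_s")
  expect_error(insurance_plan(-5), "non-negative")
  expect_error(insurance_plan(10, coverage = 1.4), "coverage")
  expect_error(insurance_plan(10, gamma = 0.5), "gamma")
})

test_that("expected utilities match the state-weighted forms", {
  u <- log_u()
  s <- base_s()
  expect_equal(expected_utility_nr(u, s),
               0.1 * (log(50000) + 0.1) + 0.9 * (log(50000) + 0.2))
  s0 <- health_scenario(0.5, 3e4, 5e4, 0.5, 1, 0.2)
  # degenerate-lottery limits via pi near the endpoints
  eps <- 1e-12
  s_w <- health_scenario(eps, 3e4, 5e4, 0.5, 1, 0.2)
  expect_equal(expected_utility_nr(u, s_w), eval_bivariate(u, 5e4, 1),
               tolerance = 1e-9)
  s_s <- health_scenario(1 - eps, 3e4, 5e4, 0.5, 1, 0.2)
  expect_equal(expected_utility_nr(u, s_s), eval_bivariate(u, 3e4, 0.5),
               tolerance = 1e-9)
  # with no cost, no payment and no gain, R coincides with NR
  s_nogain <- base_s(dh_s = 0)
  expect_equal(expected_utility_r(u, s_nogain, insurance_plan(0), V = 0),
               expected_utility_nr(u, s_nogain))
  # complete coverage charges the fair premium pi * p in both states
  plan <- insurance_plan(p = 10000, coverage = 1)
  ex <- qalyvto:::state_expenses(base_s(), plan, V = 0)
  expect_equal(ex$sigma_s, 0.1 * 10000)
  expect_equal(ex$sigma_w, 0.1 * 10000)
  # payments must leave consumption positive
  expect_error(expected_utility_r(u, base_s(), plan, V = 49500),
               "infeasible payment")
})

test_that("willingness-to-pay solver reaches indifference and matches the
          closed-form log-utility oracle", {
  u <- log_u()
  s <- base_s()
  sol <- solve_max_wtp(u, s, insurance_plan(0))
  # oracle: ln(1 - V/y) = -pi * beta * dh  =>  V = y (1 - exp(-pi beta dh))
  v_oracle <- 50000 * (1 - exp(-0.1 * 0.2 * 0.25))
  expect_equal(sol$V_star, v_oracle, tolerance = 1e-6)
  expect_lte(sol$eu_gap, 1e-10)
  expect_false(sol$truncated)
  expect_equal(sol$sigma_s, sol$V_star)
  expect_equal(sol$sigma_w, sol$V_star)
})

test_that("zero gain at zero cost is worth exactly nothing, and a pure
          premium loss needs compensation", {
  u <- log_u()
  s0 <- base_s(dh_s = 0)
  sol0 <- solve_max_wtp(u, s0, insurance_plan(0))
  expect_equal(sol0$V_star, 0, tolerance = 1e-9)
  solp <- solve_max_wtp(u, s0, insurance_plan(p = 5000, coverage = 1))
  expect_lt(solp$V_star, 0)
  expect_true(solp$truncated)
})

test_that("solver satisfies the expense identities on random scenarios", {
  set.seed(32)
  for (i in 1:25) {
    u <- rand_bivariate()
    s <- rand_scenario()
    plan <- rand_plan(s$y_s)
    sol <- solve_max_wtp(u, s, plan)
    expect_lte(sol$eu_gap, 1e-10)
    ip <- plan$coverage * plan$p
    expect_equal(sol$sigma_s, plan$p - (1 - s$pi) * ip + sol$V_star)
    expect_equal(sol$sigma_w, s$pi * ip + sol$V_star)
  }
})

test_that("trade-off formulas reproduce the log and risk-neutral cases and
          respond to gamma", {
  u <- log_u()
  s <- base_s()
  expect_equal(acea_vto(u, s), 1000)
  expect_equal(acea_pvto(u, s), 10000)
  # risk-neutral u = c + beta h: VTO = pi * beta, PVTO = beta
  lin <- bivariate_utility("additive", r_c = 0, beta = 3000, r_h = 0)
  s2 <- health_scenario(0.2, 3e4, 6e4, 0.5, 1, 0.2)
  expect_equal(acea_vto(lin, s2), 0.2 * 3000)
  expect_equal(acea_pvto(lin, s2), 3000)
  # larger well-state weighting shrinks the trade-off
  expect_lt(acea_vto(u, s, gamma = 2), acea_vto(u, s, gamma = 1))
})

test_that("enrollee and payer trade-offs differ exactly by the disease
          probability", {
  set.seed(33)
  for (i in 1:40) {
    u <- rand_bivariate(share = c(-0.2, 0.5))
    s <- rand_scenario()
    expect_equal(acea_vto(u, s) / acea_pvto(u, s), s$pi, tolerance = 1e-12)
  }
})

test_that("marginal willingness to pay from the solver converges to the
          closed-form trade-off", {
  set.seed(34)
  for (i in 1:10) {
    u <- rand_bivariate()
    s <- rand_scenario(dh_s = 1e-4)
    sol <- solve_max_wtp(u, s, insurance_plan(0))
    expect_equal(sol$V_star / 1e-4, acea_vto(u, s), tolerance = 1e-3)
  }
})
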