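#' Disease scenario for the expected-utility (ACEA) model
#'
#' Describes a healthy enrollee facing a future disease: with probability
#' `pi` the sick state occurs (income `y_s`, health `h_s`, and a treatment
#' would add `dh_s` QALYs), otherwise the well state (income `y_w`, health
#' `h_w`).
#'
#' @param pi Probability of the sick state, in `(0, 1)`.
#' @param y_s,y_w Incomes in the sick and well states (money, `y_w >= y_s > 0`).
#' @param h_s,h_w Health levels in the sick and well states (QALY scale,
#'   `h_w > h_s > 0`).
#' @param dh_s QALY gain from treatment in the sick state
#'   (`0 <= dh_s <= h_w - h_s`: treatment cannot push health past the well
#'   state).
#' @return An object of class `"health_scenario"`.
#' @export
health_scenario <- function(pi, y_s, y_w, h_s, h_w, dh_s) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    x
  }
  pi <- num1(pi, "pi"); y_s <- num1(y_s, "y_s"); y_w <- num1(y_w, "y_w")
  h_s <- num1(h_s, "h_s"); h_w <- num1(h_w, "h_w"); dh_s <- num1(dh_s, "dh_s")
  if (pi <= 0 || pi >= 1)
    stop("`pi` must lie strictly between 0 and 1", call. = FALSE)
  if (y_s <= 0 || y_w < y_s)
    stop("incomes must satisfy y_w >= y_s > 0", call. = FALSE)
  if (h_s <= 0 || h_w <= h_s)
    stop("health levels must satisfy h_w > h_s > 0", call. = FALSE)
  if (dh_s < 0 || h_s + dh_s > h_w + 1e-12)
    stop("`dh_s` must satisfy 0 <= dh_s <= h_w - h_s", call. = FALSE)
  structure(list(pi = pi, y_s = y_s, y_w = y_w, h_s = h_s, h_w = h_w,
                 dh_s = dh_s), class = "health_scenario")
}

#' @export
print.health_scenario <- function(x, ...) {
  cat("Health scenario: P(sick) =", format(x$pi), "\n")
  cat("  sick state: income", format(x$y_s), " health", format(x$h_s),
      " treatment gain", format(x$dh_s), "QALY\n")
  cat("  well state: income", format(x$y_w), " health", format(x$h_w), "\n")
  invisible(x)
}

#' Insurance plan covering a medical technology
#'
#' The plan covers a fraction of the technology cost `p`:
#' \eqn{I(p) = \mathrm{coverage} \cdot p} (complete coverage when
#' `coverage = 1`). The actuarially fair premium is \eqn{\pi I(p)} and the
#' net transfer to the sick individual is \eqn{(1-\pi) I(p)}; when that
#' transfer is below `p` the difference is a sick-state co-payment.
#' `gamma` (\eqn{\ge 1}) is the adjustment factor by which the well-state
#' marginal utility of income is weighted in the value-trade-off
#' denominator (willingness to pay can be larger in the well state because
#' income is larger there).
#'
#' @param p Technology cost (money, `>= 0`).
#' @param coverage Covered fraction of the cost, in `[0, 1]` (default 1,
#'   complete coverage).
#' @param gamma Well-state marginal-utility-of-income adjustment, `>= 1`.
#' @return An object of class `"insurance_plan"`.
#' @export
insurance_plan <- function(p, coverage = 1, gamma = 1) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0)
    stop("`p` (technology cost) must be a single non-negative number",
         call. = FALSE)
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage < 0 || coverage > 1)
    stop("`coverage` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1)
    stop("`gamma` must be >= 1", call. = FALSE)
  structure(list(p = p, coverage = coverage, gamma = gamma),
            class = "insurance_plan")
}

#' @export
print.insurance_plan <- function(x, ...) {
  cat("Insurance plan: technology cost", format(x$p),
      " coverage", format(x$coverage), " gamma", format(x$gamma), "\n")
  invisible(x)
}

#' State expenses under reimbursement
#'
#' Total expenses (premium, co-payment, and the extra payment `V` over and
#' above covered expenses) borne in each state when the technology is
#' reimbursed: \eqn{\Sigma^s = p - (1-\pi) I(p) + V} in the sick state and
#' \eqn{\Sigma^w = \pi I(p) + V} in the well state.
#'
#' @param scenario A [health_scenario()].
#' @param plan An [insurance_plan()].
#' @param V Extra payment over covered expenses (may be negative:
#'   compensation).
#' @return Named list with `sigma_s` and `sigma_w`.
#' @keywords internal
state_expenses <- function(scenario, plan, V = 0) {
  ip <- plan$coverage * plan$p
  list(sigma_s = plan$p - (1 - scenario$pi) * ip + V,
       sigma_w = scenario$pi * ip + V)
}

#' Expected utility without reimbursement (status quo)
#'
#' The no-reimbursement (NR) expected utility: no medical expenses, so
#' consumption equals income in each state and health stays at its initial
#' level, \deqn{E(u)_{NR} = \pi u(y^s, h^s) + (1-\pi) u(y^w, h^w).}
#'
#' @param u A [bivariate_utility()].
#' @param scenario A [health_scenario()].
#' @return Expected utility (a number).
#' @export
expected_utility_nr <- function(u, scenario) {
  stopifnot(inherits(scenario, "health_scenario"))
  pi <- scenario$pi
  pi * eval_bivariate(u, scenario$y_s, scenario$h_s) +
    (1 - pi) * eval_bivariate(u, scenario$y_w, scenario$h_w)
}

#' Expected utility with reimbursement
#'
#' The reimbursement (R) expected utility for an enrollee paying `V` over
#' and above covered expenses:
#' \deqn{E(u)_R = \pi u(y^s - \Sigma^s, h^s + dh^s)
#'   + (1-\pi) u(y^w - \Sigma^w, h^w),}
#' with state expenses as in [state_expenses()]. Strictly decreasing in
#' `V`; equals [expected_utility_nr()] when `p = 0`, `V = 0` and
#' `dh_s = 0`. Payments that drive consumption non-positive in either
#' state raise an infeasible-payment error.
#'
#' @inheritParams expected_utility_nr
#' @param plan An [insurance_plan()].
#' @param V Extra payment over covered expenses (money).
#' @return Expected utility (a number).
#' @export
expected_utility_r <- function(u, scenario, plan, V = 0) {
  stopifnot(inherits(scenario, "health_scenario"),
            inherits(plan, "insurance_plan"))
  ex <- state_expenses(scenario, plan, V)
  c_s <- scenario$y_s - ex$sigma_s
  c_w <- scenario$y_w - ex$sigma_w
  if (c_s <= 0 || c_w <= 0)
    stop("infeasible payment: V = ", format(V), " drives state consumption ",
         "non-positive (c_s = ", format(c_s), ", c_w = ", format(c_w), ")",
         call. = FALSE)
  pi <- scenario$pi
  pi * eval_bivariate(u, c_s, scenario$h_s + scenario$dh_s) +
    (1 - pi) * eval_bivariate(u, c_w, scenario$h_w)
}

#' Maximum willingness to pay via the indifference condition
#'
#' Solves for the extra payment `V*` that makes the enrollee indifferent
#' between reimbursement and the status quo,
#' \eqn{E(u)_R(V^*) = E(u)_{NR}}, by bracketed root-finding (the
#' reimbursement expected utility is strictly decreasing in `V`, so the
#' root is unique) followed by Newton polishing until the expected-utility
#' gap is at most `1e-10`. The implied maximum state expenses
#' \eqn{\Sigma^s, \Sigma^w} are reported alongside. A negative `V*`
#' (flagged `truncated`) means the technology is not worth its premium and
#' the enrollee would need compensation; it is returned, not clamped.
#'
#' @inheritParams expected_utility_r
#' @return An object of class `"wtp_solution"`: list with `V_star`,
#'   `sigma_s`, `sigma_w`, `eu_nr`, `eu_r`, `eu_gap`, `truncated`.
#' @examples
#' u <- bivariate_utility("additive", r_c = 1, beta = 0.2)
#' s <- health_scenario(pi = 0.1, y_s = 50000, y_w = 50000,
#'                      h_s = 0.5, h_w = 1, dh_s = 0.25)
#' solve_max_wtp(u, s, insurance_plan(p = 0))$V_star  # ~ 249.4
#' @export
solve_max_wtp <- function(u, scenario, plan) {
  stopifnot(inherits(scenario, "health_scenario"),
            inherits(plan, "insurance_plan"))
  eu_nr <- expected_utility_nr(u, scenario)
  ex0 <- state_expenses(scenario, plan, 0)
  # feasibility ceiling on V: both state consumptions must stay positive
  v_max <- min(scenario$y_s - ex0$sigma_s, scenario$y_w - ex0$sigma_w)
  if (v_max <= 0)
    stop("no feasible payment: premium/co-payment alone exhausts income ",
         "in some state", call. = FALSE)
  f <- function(V) expected_utility_r(u, scenario, plan, V) - eu_nr
  eps <- 1e-9 * v_max
  upper <- v_max - eps
  f_up <- f(upper)
  if (f_up > 0)
    stop("willingness-to-pay solver did not converge: the enrollee still ",
         "prefers reimbursement at the consumption-exhausting payment ",
         format(upper), " (expected-utility surplus ", format(f_up),
         "); no indifference point within the feasible range", call. = FALSE)
  lower <- min(0, upper) - max(1, abs(scenario$y_w))
  f_lo <- f(lower)
  tries <- 0L
  while (f_lo < 0 && tries < 60L) {  # expand downward until bracketed
    lower <- lower * 2
    f_lo <- f(lower)
    tries <- tries + 1L
  }
  if (f_lo < 0)
    stop("willingness-to-pay solver did not converge: unable to bracket ",
         "the indifference point from below (last lower bound ",
         format(lower), ")", call. = FALSE)
  V <- stats::uniroot(f, lower = lower, upper = upper,
                      f.lower = f_lo, f.upper = f_up,
                      tol = .Machine$double.eps^0.75 * max(1, abs(upper)))$root
  # Newton polish: dE(u)_R/dV = -(pi u_c^s + (1-pi) u_c^w)
  for (it in 1:4) {
    ex <- state_expenses(scenario, plan, V)
    du <- -(scenario$pi *
              partial_c(u, scenario$y_s - ex$sigma_s,
                        scenario$h_s + scenario$dh_s) +
            (1 - scenario$pi) *
              partial_c(u, scenario$y_w - ex$sigma_w, scenario$h_w))
    step <- f(V) / du
    if (!is.finite(step)) break
    V_new <- V - step
    if (V_new >= upper || abs(step) < .Machine$double.eps * max(1, abs(V)))
      break
    V <- V_new
  }
  ex <- state_expenses(scenario, plan, V)
  gap <- abs(f(V))
  structure(list(V_star = V, sigma_s = ex$sigma_s, sigma_w = ex$sigma_w,
                 eu_nr = eu_nr, eu_r = eu_nr + f(V), eu_gap = gap,
                 truncated = V < 0),
            class = "wtp_solution")
}

#' @export
print.wtp_solution <- function(x, ...) {
  cat("Maximum willingness to pay (indifference with status quo)\n")
  cat("  V* =", format(x$V_star),
      if (x$truncated) " [negative: technology not worth its premium]" else "",
      "\n")
  cat("  state expenses: sigma_s =", format(x$sigma_s),
      " sigma_w =", format(x$sigma_w), "\n")
  cat("  residual expected-utility gap:", format(x$eu_gap), "\n")
  invisible(x)
}

acea_eval_point <- function(scenario, plan, at) {
  if (at == "status_quo_income" || is.null(plan) || plan$p == 0) {
    list(c_s = scenario$y_s, c_w = scenario$y_w)
  } else {
    ex <- state_expenses(scenario, plan, 0)
    list(c_s = scenario$y_s - ex$sigma_s, c_w = scenario$y_w - ex$sigma_w)
  }
}

#' ACEA value trade-off (enrollee's money per QALY)
#'
#' The ex ante marginal rate of substitution between sick-state consumption
#' and sick-state health gain at the status quo:
#' \deqn{-\frac{dc^s}{dh^s} = \frac{\pi u_h^s}
#'   {\pi u_c^s + \gamma (1-\pi) u_c^w},}
#' where \eqn{u_h^s, u_c^s} are partials at the sick-state point,
#' \eqn{u_c^w} at the well-state point, and \eqn{\gamma \ge 1} weights the
#' well-state marginal utility of income. By default the partials are
#' evaluated at status-quo incomes (`c_s = y_s`, `c_w = y_w`); setting
#' `at = "premium_adjusted"` evaluates them at premium/co-payment-adjusted
#' consumption (the channel through which a costlier technology lowers the
#' trade-off).
#'
#' @inheritParams expected_utility_nr
#' @param gamma Well-state adjustment factor, `>= 1` (default 1).
#' @param at Evaluation point: `"status_quo_income"` (default) or
#'   `"premium_adjusted"` (requires `plan`).
#' @param plan An [insurance_plan()]; only needed for
#'   `at = "premium_adjusted"`.
#' @return Positive trade-off in money per QALY.
#' @examples
#' u <- bivariate_utility("additive", r_c = 1, beta = 0.2)
#' s <- health_scenario(0.1, 50000, 50000, 0.5, 1, 0.25)
#' acea_vto(u, s)    # 1000
#' acea_pvto(u, s)   # 10000 = acea_vto / pi
#' @export
acea_vto <- function(u, scenario, gamma = 1,
                     at = c("status_quo_income", "premium_adjusted"),
                     plan = NULL) {
  stopifnot(inherits(scenario, "health_scenario"))
  at <- match.arg(at)
  if (at == "premium_adjusted" && is.null(plan))
    stop("`at = \"premium_adjusted\"` requires an insurance `plan`",
         call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1)
    stop("`gamma` must be >= 1", call. = FALSE)
  pt <- acea_eval_point(scenario, plan, at)
  pi <- scenario$pi
  u_h_s <- partial_h(u, pt$c_s, scenario$h_s)
  u_c_s <- partial_c(u, pt$c_s, scenario$h_s)
  u_c_w <- partial_c(u, pt$c_w, scenario$h_w)
  pi * u_h_s / (pi * u_c_s + gamma * (1 - pi) * u_c_w)
}

#' ACEA payer value trade-off (cost change per QALY)
#'
#' The payer's trade-off between the cost of the medical technology and the
#' sick-state health gain,
#' \deqn{\frac{dp}{dh^s} = \frac{u_h^s}{\pi u_c^s + \gamma (1-\pi) u_c^w},}
#' i.e. the maximum increase in technology cost per QALY gained the payer
#' accepts. Identically equal to [acea_vto()] divided by `pi`.
#'
#' @inheritParams acea_vto
#' @return Positive trade-off in money per QALY.
#' @export
acea_pvto <- function(u, scenario, gamma = 1,
                      at = c("status_quo_income", "premium_adjusted"),
                      plan = NULL) {
  stopifnot(inherits(scenario, "health_scenario"))
  at <- match.arg(at)
  if (at == "premium_adjusted" && is.null(plan))
    stop("`at = \"premium_adjusted\"` requires an insurance `plan`",
         call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1)
    stop("`gamma` must be >= 1", call. = FALSE)
  pt <- acea_eval_point(scenario, plan, at)
  pi <- scenario$pi
  u_h_s <- partial_h(u, pt$c_s, scenario$h_s)
  u_c_s <- partial_c(u, pt$c_s, scenario$h_s)
  u_c_w <- partial_c(u, pt$c_w, scenario$h_w)
  u_h_s / (pi * u_c_s + gamma * (1 - pi) * u_c_w)
}
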