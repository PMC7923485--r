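#' Comparative-statics sweep grid
#'
#' Describes a one-factor sweep for [comparative_statics()]: a base model
#' (MAUT or ACEA), the factor to vary — income, technology cost, or
#' severity of disease — and the strictly increasing factor levels.
#'
#' For `kind = "maut"` the base is a list with elements `model` (a
#' [maut_model()]), `pi` (sick-state probability used for the premium),
#' `p` (technology cost), `coverage`, `income` (base income) and `h_eval`
#' (health-gain evaluation point, default the bottom of the health range).
#' The trade-off is evaluated at premium-adjusted consumption
#' `c = income - pi * coverage * p`. Factor levels are incomes (money) for
#' `"income"`, costs (money) for `"technology_cost"`, and health evaluation
#' levels on the gain scale for `"severity"` (a *lower* level means a more
#' severe disease: the patient sits further from full health).
#'
#' For `kind = "acea"` the base is a list with `u` (a
#' [bivariate_utility()]), `scenario` (a [health_scenario()]), `plan` (an
#' [insurance_plan()], optional) and `gamma`. Factor levels are income
#' multipliers applied proportionally to both state incomes for
#' `"income"`, technology costs for `"technology_cost"` (evaluated at
#' premium-adjusted consumption), and sick-state health levels `h_s` for
#' `"severity"`.
#'
#' @param kind `"maut"` or `"acea"`.
#' @param base Base parameterization (see Details).
#' @param factor One of `"income"`, `"technology_cost"`, `"severity"`.
#' @param levels Strictly increasing numeric factor levels (length >= 2).
#' @param seed Optional integer recorded in the report for reproducibility
#'   of randomized grid construction by the caller.
#' @return An object of class `"scenario_grid"`.
#' @export
scenario_grid <- function(kind = c("maut", "acea"), base,
                          factor = c("income", "technology_cost", "severity"),
                          levels, seed = NULL) {
  kind <- match.arg(kind)
  factor <- match.arg(factor)
  if (!is.numeric(levels) || length(levels) < 2L || any(!is.finite(levels)))
    stop("`levels` must be at least two finite numbers", call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("`levels` must be strictly increasing", call. = FALSE)
  if (kind == "maut") {
    stopifnot(inherits(base$model, "maut_model"))
    base$pi <- if (is.null(base$pi)) 0.1 else base$pi
    base$p <- if (is.null(base$p)) 0 else base$p
    base$coverage <- if (is.null(base$coverage)) 1 else base$coverage
    base$income <- if (is.null(base$income)) base$model$u_c$hi else base$income
    base$h_eval <- if (is.null(base$h_eval)) base$model$u_h$lo else base$h_eval
  } else {
    stopifnot(inherits(base$u, "bivariate_utility"),
              inherits(base$scenario, "health_scenario"))
    base$plan <- if (is.null(base$plan)) insurance_plan(0) else base$plan
    base$gamma <- if (is.null(base$gamma)) 1 else base$gamma
  }
  structure(list(kind = kind, base = base, factor = factor,
                 levels = as.numeric(levels), seed = seed),
            class = "scenario_grid")
}

property_id <- function(kind, factor) {
  idx <- c(technology_cost = 1L, income = 2L, severity = 3L)[[factor]]
  paste0(if (kind == "maut") "MCDA-" else "ACEA-", idx)
}

# expected monotone direction of the trade-off as the factor level rises
property_direction <- function(factor) {
  # income up -> VTO up; cost up -> VTO down; severity levels are health
  # levels (higher = less severe) -> VTO down
  if (factor == "income") "non-decreasing" else "non-increasing"
}

maut_sweep_vto <- function(base, factor, level) {
  m <- base$model
  income <- base$income; p <- base$p; h_eval <- base$h_eval
  if (factor == "income") income <- level
  if (factor == "technology_cost") p <- level
  if (factor == "severity") h_eval <- level
  c_eval <- income - base$pi * base$coverage * p
  if (c_eval < m$u_c$lo || c_eval > m$u_c$hi)
    stop("consumption evaluation point ", format(c_eval),
         " outside the MAUT consumption range", call. = FALSE)
  maut_vto(m, c = c_eval, h = h_eval)
}

acea_sweep_vto <- function(base, factor, level) {
  s <- base$scenario; plan <- base$plan
  at <- "status_quo_income"
  if (factor == "income")
    s <- health_scenario(s$pi, s$y_s * level, s$y_w * level,
                         s$h_s, s$h_w, s$dh_s)
  if (factor == "technology_cost") {
    plan <- insurance_plan(level, plan$coverage, plan$gamma)
    at <- "premium_adjusted"
  }
  if (factor == "severity")
    s <- health_scenario(s$pi, s$y_s, s$y_w, level, s$h_w, s$dh_s)
  acea_vto(base$u, s, gamma = base$gamma, at = at, plan = plan)
}

#' Numerical verification of a comparative-statics property
#'
#' Computes the relevant value trade-off at every level of a
#' [scenario_grid()] and tests the monotone direction the theory predicts:
#' the trade-off is non-decreasing in income (MCDA/ACEA Property 2),
#' non-increasing in the technology cost, whose premium lowers consumption
#' (Property 1), and non-increasing in the health level, i.e. larger for
#' more severe disease (Property 3). The monotone directions are
#' guaranteed only under the stated sufficient conditions — interaction
#' constant `K >= 0` on the MAUT side, cross-partial `u_ch >= 0` on the
#' ACEA side, concave utilities — which the caller's base model should
#' satisfy. Adjacent-pair violations smaller than `tol_frac` times the
#' value scale are treated as floating-point ties. Levels at which the
#' trade-off is infeasible (evaluation point outside the model's domain)
#' are excluded and recorded, not fabricated.
#'
#' @param grid A [scenario_grid()].
#' @param tol_frac Tie tolerance as a fraction of the largest absolute
#'   trade-off in the sweep (default `1e-9`).
#' @return An object of class `"property_report"`: property id, per-level
#'   values, verdict, first violating pair (if any), excluded levels.
#' @export
comparative_statics <- function(grid, tol_frac = 1e-9) {
  stopifnot(inherits(grid, "scenario_grid"))
  fn <- if (grid$kind == "maut") maut_sweep_vto else acea_sweep_vto
  vals <- rep(NA_real_, length(grid$levels))
  excluded <- character(0)
  for (i in seq_along(grid$levels)) {
    v <- tryCatch(fn(grid$base, grid$factor, grid$levels[i]),
                  error = function(e) conditionMessage(e))
    if (is.character(v)) {
      excluded <- c(excluded,
                    paste0("level ", format(grid$levels[i]), ": ", v))
    } else vals[i] <- v
  }
  direction <- property_direction(grid$factor)
  ok <- which(!is.na(vals))
  v <- vals[ok]
  tol <- tol_frac * max(abs(v), na.rm = TRUE)
  d <- diff(v)
  viol <- if (direction == "non-decreasing") which(d < -tol) else which(d > tol)
  first_violation <- if (length(viol))
    list(levels = grid$levels[ok][viol[1L] + 0:1], values = v[viol[1L] + 0:1])
  else NULL
  structure(list(property = property_id(grid$kind, grid$factor),
                 kind = grid$kind, factor = grid$factor,
                 direction = direction, levels = grid$levels, values = vals,
                 excluded = excluded, tolerance = tol, seed = grid$seed,
                 pass = length(viol) == 0L, first_violation = first_violation),
            class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat("Property ", x$property, " (", x$factor, " sweep, trade-off ",
      x$direction, "): ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  print(data.frame(level = x$levels, vto = x$values))
  if (!is.null(x$first_violation))
    cat("first violating pair: levels ",
        paste(format(x$first_violation$levels), collapse = " -> "),
        ", values ",
        paste(format(x$first_violation$values), collapse = " -> "), "\n",
        sep = "")
  if (length(x$excluded))
    cat("excluded levels:\n ", paste(x$excluded, collapse = "\n  "), "\n")
  invisible(x)
}

#' @param x A `property_report`.
#' @param ... Passed to [graphics::plot()].
#' @rdname comparative_statics
#' @export
plot.property_report <- function(x, ...) {
  graphics::plot(x$levels, x$values, type = "b",
                 xlab = x$factor, ylab = "value trade-off (money per QALY)",
                 main = paste0("Property ", x$property, ": ",
                               if (x$pass) "pass" else "fail"), ...)
  invisible(x)
}

#' Positivity check of value trade-offs
#'
#' Verifies that the value trade-off is strictly positive over a collection
#' of models and evaluation points. Cases where the trade-off is undefined
#' (e.g. a non-positive MAUT bracket term, possible when `K < 0`) are
#' excluded and reported, not counted as violations.
#'
#' @param cases A list of cases. For `kind = "maut"` each case is a list
#'   `(model, c, h)`; for `kind = "acea"` a list
#'   `(u, scenario, gamma = 1)`.
#' @param kind `"maut"` or `"acea"`.
#' @return An object of class `"positivity_report"` with the computed
#'   trade-offs, excluded cases, any violations, and a `pass` verdict.
#' @export
verify_positivity <- function(cases, kind = c("maut", "acea")) {
  kind <- match.arg(kind)
  stopifnot(is.list(cases), length(cases) > 0L)
  vals <- rep(NA_real_, length(cases))
  excluded <- character(0)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    v <- tryCatch(
      if (kind == "maut") maut_vto(cs$model, cs$c, cs$h)
      else acea_vto(cs$u, cs$scenario,
                    gamma = if (is.null(cs$gamma)) 1 else cs$gamma),
      error = function(e) conditionMessage(e))
    if (is.character(v))
      excluded <- c(excluded, paste0("case ", i, ": ", v))
    else vals[i] <- v
  }
  violations <- which(!is.na(vals) & vals <= 0)
  structure(list(kind = kind, values = vals, excluded = excluded,
                 violations = violations, pass = length(violations) == 0L),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Positivity of ", toupper(x$kind), " value trade-offs: ",
      if (x$pass) "PASS" else "FAIL", " (", sum(!is.na(x$values)),
      " checked, ", length(x$excluded), " excluded)\n", sep = "")
  if (length(x$violations))
    cat("violations at cases:", paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}

sign_with_tol <- function(delta, scale, tol_frac) {
  tol <- tol_frac * max(scale, .Machine$double.xmin)
  if (delta > tol) 1L else if (delta < -tol) -1L else 0L
}

#' Concordance of MAUT and ACEA value trade-offs under shared perturbations
#'
#' The headline reconciliation exercise: parameterize the MAUT and ACEA
#' models on a shared scenario (same incomes, health levels, disease
#' probability, technology cost) and record, for each factor perturbation,
#' whether the MAUT trade-off and the ACEA trade-off move in the same
#' direction. When health and consumption are complements or independent
#' on both sides (`K >= 0` and `u_ch >= 0`, with concave utilities) all
#' signs agree; with substitutes on one side, the frameworks can disagree
#' and recommend inconsistent decisions.
#'
#' Measurement conventions: both trade-offs are evaluated at
#' premium-adjusted consumption (`income - pi * coverage * p`). The MAUT
#' attribute ranges are held fixed across the comparison (the measurement
#' frame is anchored once, at the most severe state contemplated) and a
#' severity step lowers the health *evaluation point* by `severity_delta`
#' QALYs — the paper's "lower health level" channel; re-deriving the
#' attribute range per severity level would instead renormalize the health
#' utility itself, conflating a units change with a preference change. On
#' the ACEA side a severity step lowers the sick-state health `h_s` by the
#' same `severity_delta`.
#'
#' @param maut A [maut_model()] whose consumption range covers the incomes
#'   contemplated (including the income perturbation) and whose health
#'   range covers `severity_delta` times the number of severity steps.
#' @param u A [bivariate_utility()].
#' @param scenario A [health_scenario()] shared by both sides.
#' @param plan An [insurance_plan()]; a strictly positive technology cost
#'   is required when a cost perturbation is requested.
#' @param gamma Well-state adjustment for the ACEA trade-off.
#' @param perturbations Named list with any of `income` (relative change,
#'   e.g. `0.1` for +10\%), `cost` (relative change of the technology
#'   cost), `severity` (number of severity steps).
#' @param severity_delta QALY size of one severity step (default 0.1).
#' @param tol_frac Tie tolerance for calling a change "no change".
#' @return An object of class `"concordance_report"`: per-factor signs of
#'   both trade-off changes, agreement indicators, and the concordance
#'   fraction.
#' @export
concordance <- function(maut, u, scenario, plan = insurance_plan(0),
                        gamma = 1,
                        perturbations = list(income = 0.1, cost = 0.1,
                                             severity = 1),
                        severity_delta = 0.1, tol_frac = 1e-9) {
  stopifnot(inherits(maut, "maut_model"), inherits(u, "bivariate_utility"),
            inherits(scenario, "health_scenario"),
            inherits(plan, "insurance_plan"))
  known <- c("income", "cost", "severity")
  if (length(perturbations) == 0L ||
      !all(names(perturbations) %in% known))
    stop("`perturbations` must be a named list with elements among ",
         paste(known, collapse = ", "), call. = FALSE)
  if (!is.null(perturbations$cost) && plan$p <= 0)
    stop("configuration error: a cost perturbation requires a strictly ",
         "positive technology cost in `plan`", call. = FALSE)
  n_steps <- if (is.null(perturbations$severity)) 0
             else perturbations$severity
  premium <- scenario$pi * plan$coverage * plan$p
  # MAUT measurement frame: fixed ranges; base evaluation point sits
  # (n_steps + 1) * severity_delta above the bottom of the health range so
  # the most severe contemplated state stays one step clear of the floor
  # (where power-family marginal utilities diverge).
  h_base <- maut$u_h$lo + (n_steps + 1) * severity_delta
  c_base <- scenario$y_w - premium
  maut_point <- function(income_mult = 1, cost_mult = 1, steps = 0) {
    cc <- scenario$y_w * income_mult -
      scenario$pi * plan$coverage * plan$p * cost_mult
    hh <- h_base - steps * severity_delta
    if (cc < maut$u_c$lo || cc > maut$u_c$hi)
      stop("configuration error: consumption point ", format(cc),
           " outside the MAUT consumption range [", format(maut$u_c$lo),
           ", ", format(maut$u_c$hi), "]", call. = FALSE)
    if (hh < maut$u_h$lo || hh > maut$u_h$hi)
      stop("configuration error: health point ", format(hh),
           " outside the MAUT health range", call. = FALSE)
    maut_vto(maut, c = cc, h = hh)
  }
  acea_point <- function(income_mult = 1, cost_mult = 1, steps = 0) {
    s <- scenario
    h_s <- s$h_s - steps * severity_delta
    if (h_s <= 0)
      stop("configuration error: severity step drives the sick-state ",
           "health level non-positive", call. = FALSE)
    s <- health_scenario(s$pi, s$y_s * income_mult, s$y_w * income_mult,
                         h_s, s$h_w, s$dh_s)
    pl <- insurance_plan(plan$p * cost_mult, plan$coverage, plan$gamma)
    acea_vto(u, s, gamma = gamma, at = "premium_adjusted", plan = pl)
  }
  maut_base <- maut_point(); acea_base <- acea_point()
  rows <- list()
  for (fac in intersect(known, names(perturbations))) {
    m_new <- switch(fac,
      income   = maut_point(income_mult = 1 + perturbations$income),
      cost     = maut_point(cost_mult = 1 + perturbations$cost),
      severity = maut_point(steps = perturbations$severity))
    a_new <- switch(fac,
      income   = acea_point(income_mult = 1 + perturbations$income),
      cost     = acea_point(cost_mult = 1 + perturbations$cost),
      severity = acea_point(steps = perturbations$severity))
    m_sign <- sign_with_tol(m_new - maut_base,
                            max(abs(m_new), abs(maut_base)), tol_frac)
    a_sign <- sign_with_tol(a_new - acea_base,
                            max(abs(a_new), abs(acea_base)), tol_frac)
    rows[[fac]] <- data.frame(factor = fac,
                              maut_vto = m_new, acea_vto = a_new,
                              maut_sign = m_sign, acea_sign = a_sign,
                              agree = m_sign == a_sign)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 maut_base = maut_base, acea_base = acea_base,
                 n_agree = sum(tab$agree), n_total = nrow(tab),
                 fraction = sum(tab$agree) / nrow(tab),
                 full_agreement = all(tab$agree)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("MAUT/ACEA concordance: ", x$n_agree, "/", x$n_total,
      " sign agreements (base trade-offs ", format(x$maut_base), " / ",
      format(x$acea_base), ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Search for a substitutes counterexample to MAUT/ACEA concordance
#'
#' Randomly draws parameterizations in which the attributes behave as
#' substitutes on the MAUT side (`k_c + k_h > 1`, so `K < 0`) while the
#' ACEA utility treats them as complements (`u_ch > 0`), and runs
#' [concordance()] on each until a sign disagreement is found. Such
#' disagreements demonstrate that with negative attribute interaction the
#' two frameworks can recommend inconsistent formulary decisions.
#'
#' @param seed Integer seed for the random search (deterministic result).
#' @param n_tries Maximum number of random parameterizations to examine.
#' @return A list with the discordant `maut` model, `u`, `scenario`,
#'   `plan`, and the `report` (a `concordance_report` with at least one
#'   disagreement). Errors if no counterexample is found within
#'   `n_tries` draws.
#' @export
find_discordant_example <- function(seed = 1L, n_tries = 200L) {
  with_seed(seed, {
    for (i in seq_len(n_tries)) {
      k_c <- stats::runif(1, 0.45, 0.9)
      k_h <- stats::runif(1, 1.15 - k_c, 0.95)   # k_c + k_h > 1 -> K < 0
      y_w <- stats::runif(1, 3e4, 8e4)
      pi <- stats::runif(1, 0.05, 0.3)
      p <- stats::runif(1, 0.05, 0.3) * y_w
      m <- suppressWarnings(maut_model(
        utility_curve("linear", lo = 0, hi = 2 * y_w),
        utility_curve("linear", lo = 0, hi = 2),
        k_c = k_c, k_h = k_h))
      u <- bivariate_utility("interaction", r_c = 1,
                             beta = stats::runif(1, 0.1, 0.5),
                             r_h = stats::runif(1, 0.2, 0.7),
                             theta = stats::runif(1, 0.005, 0.05))
      scen <- health_scenario(pi, 0.8 * y_w, y_w,
                              h_s = stats::runif(1, 0.4, 0.7), h_w = 1,
                              dh_s = 0.1)
      plan <- insurance_plan(p)
      rep <- tryCatch(concordance(m, u, scen, plan),
                      error = function(e) NULL)
      if (!is.null(rep) && !rep$full_agreement)
        return(list(maut = m, u = u, scenario = scen, plan = plan,
                    report = rep))
    }
    stop("no discordant substitutes example found in ", n_tries, " draws",
         call. = FALSE)
  })
}

#' Formulary decision by the ICER-threshold rule
#'
#' A technology is funded if its incremental cost-effectiveness ratio
#' (ICER) is at or below the willingness-to-pay threshold. At exact
#' equality the decision maker is indifferent; by default the tie is
#' resolved in favour of funding (configurable via `tie`).
#'
#' @param icer Incremental cost-effectiveness ratio (money per QALY).
#' @param threshold Willingness-to-pay threshold (money per QALY, `> 0`).
#' @param tie `"fund"` (default) or `"reject"`: how to resolve
#'   `icer == threshold`.
#' @return An object of class `"decision_outcome"`: `icer`, `threshold`,
#'   `funded`, `indifferent`.
#' @export
formulary_decision <- function(icer, threshold, tie = c("fund", "reject")) {
  tie <- match.arg(tie)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be a single strictly positive number",
         call. = FALSE)
  if (!is.numeric(icer) || length(icer) != 1L || !is.finite(icer))
    stop("`icer` must be a single finite number", call. = FALSE)
  indifferent <- icer == threshold
  funded <- if (indifferent) tie == "fund" else icer < threshold
  structure(list(icer = icer, threshold = threshold, funded = funded,
                 indifferent = indifferent),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat("Formulary decision: ICER ", format(x$icer), " vs threshold ",
      format(x$threshold), " -> ", if (x$funded) "FUND" else "DO NOT FUND",
      if (x$indifferent) " (indifference at equality)" else "", "\n",
      sep = "")
  invisible(x)
}
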