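#' Bivariate state utility u(c, h) for the expected-utility (ACEA) model
#'
#' Utility of an individual over consumption `c` (money) and health level
#' `h` (QALY scale), used in both states of the world (sick/well) of the
#' expected-utility model. Three families:
#'
#' * `"additive"`: \eqn{u(c,h) = g(c) + \beta\, m(h)} — additively
#'   separable, so the cross-partial \eqn{u_{ch} = 0} (health and
#'   consumption are Hicksian q-independent).
#' * `"interaction"`: \eqn{u(c,h) = g(c) + \beta\, m(h) + \theta\, g(c)\,m(h)}
#'   — the sign of \eqn{\theta} is the sign of \eqn{u_{ch}}:
#'   \eqn{\theta > 0} gives q-complements, \eqn{\theta < 0} q-substitutes.
#' * `"custom"`: any user-supplied function `f(c, h)`; partial derivatives
#'   are taken by central finite differences with a step scaled to the
#'   argument (`step_frac * max(1, |x|)`).
#'
#' The consumption and health indices \eqn{g} and \eqn{m} are CRRA-style:
#' \eqn{g(c) = \log c} for relative curvature `r_c = 1`,
#' \eqn{g(c) = c^{1-r_c}/(1-r_c)} otherwise (`r_c = 0` is linear,
#' risk-neutral); likewise \eqn{m(h)} with curvature `r_h`. Positive
#' curvature in `h` makes the marginal utility of health rise as the
#' sick-state health level falls — the channel through which severity of
#' disease raises the value trade-off.
#'
#' Marginal utilities must be strictly positive on the working domain;
#' evaluation at points violating that (possible for strongly negative
#' \eqn{\theta}) raises an error.
#'
#' @param family `"additive"`, `"interaction"` or `"custom"`.
#' @param r_c Relative curvature of the consumption index (`>= 0`; 0 linear,
#'   1 logarithmic).
#' @param beta Health weight (`> 0`), money-comparable utility units per
#'   unit of the health index.
#' @param r_h Relative curvature of the health index (`>= 0`, `< 1` so the
#'   index stays finite at small positive health levels).
#' @param theta Interaction coefficient (family `"interaction"` only).
#' @param f For family `"custom"`: a vectorized function of `(c, h)`.
#' @param step_frac Relative finite-difference step for custom partials.
#' @return An object of class `"bivariate_utility"`.
#' @examples
#' u <- bivariate_utility("additive", r_c = 1, beta = 0.2)  # log(c) + 0.2 h
#' eval_bivariate(u, c = 50000, h = 1)
#' partial_c(u, 50000, 1); partial_h(u, 50000, 1)
#' complementarity_class(u, 50000, 1)   # "independent"
#' @export
bivariate_utility <- function(family = c("additive", "interaction", "custom"),
                              r_c = 1, beta = 1, r_h = 0, theta = 0,
                              f = NULL, step_frac = 1e-5) {
  family <- match.arg(family)
  if (family == "custom") {
    if (!is.function(f))
      stop("family \"custom\" requires an evaluator function `f(c, h)`",
           call. = FALSE)
  } else {
    if (!is.numeric(r_c) || length(r_c) != 1L || r_c < 0)
      stop("`r_c` must be a non-negative number", call. = FALSE)
    if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
      stop("`beta` must be strictly positive", call. = FALSE)
    if (!is.numeric(r_h) || length(r_h) != 1L || r_h < 0 || r_h >= 1)
      stop("`r_h` must lie in [0, 1)", call. = FALSE)
    if (family == "additive") theta <- 0
    if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
      stop("`theta` must be a finite number", call. = FALSE)
  }
  structure(list(family = family, r_c = r_c, beta = beta, r_h = r_h,
                 theta = theta, f = f, step_frac = step_frac),
            class = "bivariate_utility")
}

#' @export
print.bivariate_utility <- function(x, ...) {
  cat("Bivariate state utility u(c, h), family:", x$family, "\n")
  if (x$family != "custom")
    cat("  consumption curvature r_c =", format(x$r_c),
        " health weight beta =", format(x$beta),
        " health curvature r_h =", format(x$r_h),
        if (x$family == "interaction")
          paste(" interaction theta =", format(x$theta)) else "", "\n")
  invisible(x)
}

# CRRA-style index and its derivatives
crra <- function(x, r) {
  if (r == 1) log(x) else x^(1 - r) / (1 - r)
}
crra_d1 <- function(x, r) x^(-r)
crra_d2 <- function(x, r) -r * x^(-r - 1)

#' Evaluate a bivariate utility and its partial derivatives
#'
#' `eval_bivariate()` returns \eqn{u(c,h)}; `partial_c()`, `partial_h()` and
#' `cross_partial()` return \eqn{u_c}, \eqn{u_h} and \eqn{u_{ch}}. For the
#' parametric families the partials are analytic; for `"custom"` utilities
#' they are central finite differences. `partial_c`/`partial_h` raise an
#' error when the marginal utility is not strictly positive (monotonicity
#' violation of the preference model).
#'
#' @param u A [bivariate_utility()].
#' @param c,h Consumption and health levels (`c > 0`, `h > 0`).
#' @return Numeric value(s).
#' @export
eval_bivariate <- function(u, c, h) {
  stopifnot(inherits(u, "bivariate_utility"))
  check_ch(c, h)
  if (u$family == "custom") return(u$f(c, h))
  g <- crra(c, u$r_c); m <- crra(h, u$r_h)
  g + u$beta * m + u$theta * g * m
}

check_ch <- function(c, h) {
  if (any(!is.finite(c)) || any(c <= 0))
    stop("consumption must be strictly positive and finite", call. = FALSE)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("health level must be strictly positive and finite", call. = FALSE)
}

fd_step <- function(x, frac) frac * pmax(1, abs(x))

#' @rdname eval_bivariate
#' @export
partial_c <- function(u, c, h) {
  stopifnot(inherits(u, "bivariate_utility"))
  check_ch(c, h)
  out <- if (u$family == "custom") {
    d <- fd_step(c, u$step_frac)
    (u$f(c + d, h) - u$f(c - d, h)) / (2 * d)
  } else {
    crra_d1(c, u$r_c) * (1 + u$theta * crra(h, u$r_h))
  }
  if (any(out <= 0))
    stop("model violation: marginal utility of consumption is not ",
         "strictly positive at the evaluation point", call. = FALSE)
  out
}

#' @rdname eval_bivariate
#' @export
partial_h <- function(u, c, h) {
  stopifnot(inherits(u, "bivariate_utility"))
  check_ch(c, h)
  out <- if (u$family == "custom") {
    d <- fd_step(h, u$step_frac)
    (u$f(c, h + d) - u$f(c, h - d)) / (2 * d)
  } else {
    crra_d1(h, u$r_h) * (u$beta + u$theta * crra(c, u$r_c))
  }
  if (any(out <= 0))
    stop("model violation: marginal utility of health is not strictly ",
         "positive at the evaluation point", call. = FALSE)
  out
}

#' @rdname eval_bivariate
#' @export
cross_partial <- function(u, c, h) {
  stopifnot(inherits(u, "bivariate_utility"))
  check_ch(c, h)
  if (u$family == "custom") {
    dc <- fd_step(c, u$step_frac); dh <- fd_step(h, u$step_frac)
    (u$f(c + dc, h + dh) - u$f(c + dc, h - dh) -
     u$f(c - dc, h + dh) + u$f(c - dc, h - dh)) / (4 * dc * dh)
  } else {
    u$theta * crra_d1(c, u$r_c) * crra_d1(h, u$r_h)
  }
}

#' Hicksian complementarity classification of health and consumption
#'
#' Classifies the two attributes at a point by the sign of the cross-partial
#' \eqn{u_{ch} = \partial^2 u/\partial c \partial h}: q-complements when
#' positive, q-substitutes when negative, independent (additively separable
#' behaviour) when within a dead band `tol` of zero.
#'
#' @param u A [bivariate_utility()].
#' @param c,h Interior evaluation point.
#' @param tol Dead band for the "independent" verdict (default `1e-8`).
#' @return One of `"complements"`, `"substitutes"`, `"independent"`.
#' @export
complementarity_class <- function(u, c, h, tol = 1e-8) {
  uch <- cross_partial(u, c, h)
  if (!is.finite(uch))
    stop("cross-partial evaluation failed at (c, h) = (",
         format(c), ", ", format(h), ")", call. = FALSE)
  if (uch > tol) "complements" else if (uch < -tol) "substitutes"
  else "independent"
}
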