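#' Normalized single-attribute utility curves
#'
#' Constructs a monotonically increasing utility function over a stated
#' attribute range `[lo, hi]`, normalized so that utility is 0 at the worst
#' level and 1 at the best level. These curves are the building blocks of the
#' two-attribute MAUT value function: one curve for consumption (money units)
#' and one for health gain (QALYs). Three parametric families are supported:
#'
#' * `"linear"` — \eqn{u(x) = (x - lo)/(hi - lo)}; constant marginal utility
#'   (risk neutrality). `shape` is ignored.
#' * `"power"`  — \eqn{u(x) = ((x - lo)/(hi - lo))^\rho} with exponent
#'   \eqn{\rho \in (0, 1]}; concave (risk averse) for \eqn{\rho < 1}.
#' * `"exponential"` — \eqn{u(x) = (1 - e^{-a(x - lo)})/(1 - e^{-a(hi - lo)})}
#'   with rate \eqn{a > 0}; constant absolute risk aversion equal to `a`.
#'
#' All families are normalized by construction, so the endpoint conditions
#' hold to machine precision for any admissible parameters.
#'
#' @param family One of `"linear"`, `"power"`, `"exponential"`.
#' @param shape Shape parameter: the power exponent \eqn{\rho \in (0,1]} or
#'   the exponential rate \eqn{a > 0}. Ignored (may be `NULL`) for the linear
#'   family.
#' @param lo,hi Worst and best attribute levels; `hi > lo`, both finite.
#'   Units are money for a consumption curve and QALYs for a health curve.
#' @return An object of class `"utility_curve"`.
#' @examples
#' uc <- utility_curve("power", shape = 0.5, lo = 0, hi = 1)
#' eval_utility(uc, 0.25)       # 0.5
#' marginal_utility(uc, 0.25)   # 1.0
#' risk_aversion(uc, 0.25)      # 2.0
#' @seealso [eval_utility()], [marginal_utility()], [risk_aversion()]
#' @export
utility_curve <- function(family = c("linear", "power", "exponential"),
                          shape = NULL, lo, hi) {
  family <- match.arg(family)
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi))
    stop("`lo` and `hi` must be single finite numbers", call. = FALSE)
  if (hi <= lo)
    stop("degenerate attribute range: `hi` (", hi,
         ") must be strictly greater than `lo` (", lo, ")", call. = FALSE)
  if (family == "power") {
    if (is.null(shape) || !is.finite(shape) || shape <= 0 || shape > 1)
      stop("`shape`: power exponent must lie in (0, 1], got ",
           format(shape), call. = FALSE)
  } else if (family == "exponential") {
    if (is.null(shape) || !is.finite(shape) || shape <= 0)
      stop("`shape`: exponential rate must be strictly positive, got ",
           format(shape), call. = FALSE)
  } else {
    shape <- NA_real_
  }
  structure(
    list(family = family, shape = as.numeric(shape),
         lo = as.numeric(lo), hi = as.numeric(hi)),
    class = "utility_curve"
  )
}

#' @export
print.utility_curve <- function(x, ...) {
  par_str <- switch(x$family,
    linear      = "",
    power       = paste0(" (exponent ", format(x$shape), ")"),
    exponential = paste0(" (rate ", format(x$shape), ")"))
  cat("Normalized ", x$family, " utility curve", par_str,
      " on [", format(x$lo), ", ", format(x$hi), "]\n", sep = "")
  invisible(x)
}

stop_outside_range <- function(curve, x) {
  bad <- x < curve$lo | x > curve$hi | !is.finite(x)
  if (any(bad))
    stop("attribute level ", format(x[bad][1L]), " outside curve range [",
         format(curve$lo), ", ", format(curve$hi), "]", call. = FALSE)
}

#' Evaluate a normalized utility curve
#'
#' @param curve A [utility_curve()].
#' @param x Attribute level(s) within the curve's range.
#' @return Utility value(s) in `[0, 1]`; 0 at `lo`, 1 at `hi`.
#' @export
eval_utility <- function(curve, x) {
  stopifnot(inherits(curve, "utility_curve"))
  stop_outside_range(curve, x)
  w <- curve$hi - curve$lo
  t <- (x - curve$lo) / w
  switch(curve$family,
    linear      = t,
    power       = t^curve$shape,
    exponential = {
      a <- curve$shape
      (1 - exp(-a * (x - curve$lo))) / (1 - exp(-a * w))
    })
}

#' @param object A [utility_curve()].
#' @param newdata Attribute level(s) at which to evaluate.
#' @param ... Unused.
#' @rdname eval_utility
#' @export
predict.utility_curve <- function(object, newdata, ...) {
  eval_utility(object, newdata)
}

#' Marginal utility of a normalized curve
#'
#' Analytic first derivative \eqn{u'(x)} of the normalized curve. It is the
#' numerator/denominator ingredient of the MAUT value trade-off, which is
#' proportional to the ratio of marginal utilities \eqn{u^{h\prime}/u^{c\prime}}.
#' At the lower endpoint of a power curve with exponent < 1 the derivative is
#' `Inf` (returned as such).
#'
#' @inheritParams eval_utility
#' @return The derivative of [eval_utility()] at `x` (strictly positive).
#' @export
marginal_utility <- function(curve, x) {
  stopifnot(inherits(curve, "utility_curve"))
  stop_outside_range(curve, x)
  w <- curve$hi - curve$lo
  switch(curve$family,
    linear = rep_len(1 / w, length(x)),
    power  = {
      r <- curve$shape
      t <- (x - curve$lo) / w
      r * t^(r - 1) / w
    },
    exponential = {
      a <- curve$shape
      a * exp(-a * (x - curve$lo)) / (1 - exp(-a * w))
    })
}

#' Arrow-Pratt absolute risk aversion of a utility curve
#'
#' Curvature measure \eqn{-u''(x)/u'(x)}: zero for the linear family (risk
#' neutrality), the constant rate `a` for the exponential family, and
#' \eqn{(1-\rho)/(x - lo)} for the power family. Larger values mean faster
#' decrease of marginal utility, i.e. stronger risk aversion.
#'
#' @inheritParams eval_utility
#' @return Non-negative risk-aversion coefficient(s).
#' @export
risk_aversion <- function(curve, x) {
  stopifnot(inherits(curve, "utility_curve"))
  stop_outside_range(curve, x)
  switch(curve$family,
    linear      = rep_len(0, length(x)),
    power       = (1 - curve$shape) / (x - curve$lo),
    exponential = rep_len(curve$shape, length(x)))
}
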