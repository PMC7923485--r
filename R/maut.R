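#' Interaction scaling constant of the multiplicative MAUT form
#'
#' For the two-attribute multiplicative multi-attribute utility function the
#' interaction constant is determined by the two attribute scaling constants:
#' \deqn{K = \frac{1 - k_c - k_h}{k_c\,k_h}.}
#' Its sign tracks the sign of \eqn{1 - k_c - k_h}: when the scaling
#' constants sum to one, \eqn{K = 0} and the value function is additive;
#' when they sum to less than one \eqn{K > 0} (complementary attributes);
#' when they sum to more than one \eqn{K < 0} (substitutes).
#'
#' @param k_c,k_h Scaling constants for consumption and health, each in
#'   `(0, 1]`.
#' @return The interaction constant `K` (a single number, any sign).
#' @examples
#' interaction_constant(0.4, 0.6)  # 0: additive value function
#' interaction_constant(0.3, 0.6)  # > 0: complements
#' @export
interaction_constant <- function(k_c, k_h) {
  check_scaling_constant(k_c, "k_c")
  check_scaling_constant(k_h, "k_h")
  (1 - k_c - k_h) / (k_c * k_h)
}

check_scaling_constant <- function(k, name) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  if (k <= 0 || k > 1)
    stop("invalid scaling constants: `", name, "` must lie in (0, 1], got ",
         format(k), call. = FALSE)
  invisible(k)
}

#' Scaling constants for the two-attribute MAUT model
#'
#' Bundles the consumption and health scaling constants together with the
#' derived interaction constant `K` (see [interaction_constant()]).
#'
#' @inheritParams interaction_constant
#' @return An object of class `"scaling_constants"` with elements `k_c`,
#'   `k_h` and `K`.
#' @export
scaling_constants <- function(k_c, k_h) {
  K <- interaction_constant(k_c, k_h)
  structure(list(k_c = k_c, k_h = k_h, K = K), class = "scaling_constants")
}

#' @export
print.scaling_constants <- function(x, ...) {
  cat("MAUT scaling constants: k_c =", format(x$k_c),
      " k_h =", format(x$k_h), " K =", format(x$K), "\n")
  cat("Attribute interaction:",
      if (x$K > 0) "complements (K > 0)"
      else if (x$K < 0) "substitutes (K < 0)"
      else "additive (K = 0)", "\n")
  invisible(x)
}

#' Derive scaling constants from elicited indifference probabilities
#'
#' In the standard probabilistic-scaling task, the decision maker states the
#' probability `p_h` at which the certain alternative (worst consumption,
#' best health) is indifferent to a lottery between the best corner
#' (probability `p_h`) and the worst corner; that probability *is* the
#' scaling constant \eqn{k_h}. Symmetrically `p_c` yields \eqn{k_c}.
#'
#' @param p_h,p_c Elicited indifference probabilities in `(0, 1]` for the
#'   health and consumption corner alternatives.
#' @return A [scaling_constants()] object with `k_h = p_h`, `k_c = p_c`.
#' @seealso [simulate_elicitation()] for the inverse (model to
#'   probabilities) direction.
#' @export
elicit_scaling_constants <- function(p_h, p_c) {
  if (!is.numeric(p_h) || length(p_h) != 1L || !is.finite(p_h) ||
      p_h <= 0 || p_h > 1)
    stop("`p_h` must be a probability in (0, 1], got ", format(p_h),
         call. = FALSE)
  if (!is.numeric(p_c) || length(p_c) != 1L || !is.finite(p_c) ||
      p_c <= 0 || p_c > 1)
    stop("`p_c` must be a probability in (0, 1], got ", format(p_c),
         call. = FALSE)
  scaling_constants(k_c = p_c, k_h = p_h)
}

#' Two-attribute multiplicative MAUT model over consumption and health
#'
#' Combines two normalized single-attribute utility curves — consumption
#' `u_c` (money units, range typically `[0, y_w]`) and health `u_h` (QALY
#' gain from the sick state, range typically `[0, h_w - h_s]`) — with
#' scaling constants into the multiplicative value function
#' \deqn{V(c,h) = k_c u^c(c) + k_h u^h(h) + K k_c k_h u^c(c) u^h(h),}
#' normalized so that \eqn{V = 0} at the worst corner and \eqn{V = 1} at the
#' best corner. Models with \eqn{K < 0} (attributes behaving as substitutes)
#' are constructible but flagged with a warning, since the monotone
#' comparative-statics properties of the value trade-off are only guaranteed
#' for \eqn{K \ge 0}.
#'
#' @param u_c,u_h [utility_curve()] objects for consumption and health gain.
#' @param constants A [scaling_constants()] object; alternatively supply
#'   `k_c` and `k_h` directly.
#' @param k_c,k_h Scaling constants, used when `constants` is missing.
#' @return An object of class `"maut_model"`.
#' @examples
#' m <- maut_model(utility_curve("linear", lo = 0, hi = 50000),
#'                 utility_curve("linear", lo = 0, hi = 1),
#'                 k_c = 0.3, k_h = 0.6)
#' maut_value(m, c = 50000, h = 0.5)
#' maut_vto(m, c = 50000, h = 0)   # money per QALY at the status quo
#' @export
maut_model <- function(u_c, u_h, constants = NULL, k_c = NULL, k_h = NULL) {
  stopifnot(inherits(u_c, "utility_curve"), inherits(u_h, "utility_curve"))
  if (is.null(constants)) {
    constants <- scaling_constants(k_c, k_h)
  } else if (!inherits(constants, "scaling_constants")) {
    stop("`constants` must be a scaling_constants object", call. = FALSE)
  }
  if (constants$K < 0)
    warning("k_c + k_h > 1: interaction constant K < 0 (attributes behave ",
            "as substitutes); monotone trade-off properties are not ",
            "guaranteed", call. = FALSE)
  structure(list(u_c = u_c, u_h = u_h, constants = constants),
            class = "maut_model")
}

#' @export
print.maut_model <- function(x, ...) {
  cat("Two-attribute multiplicative MAUT model\n")
  cat("  consumption: "); print(x$u_c)
  cat("  health gain: "); print(x$u_h)
  cat("  k_c =", format(x$constants$k_c), " k_h =", format(x$constants$k_h),
      " K =", format(x$constants$K), "\n")
  invisible(x)
}

#' @export
summary.maut_model <- function(object, ...) {
  ct <- object$constants
  # 1% above zero gain: power-family marginals diverge at the exact floor
  h_near <- object$u_h$lo + 0.01 * (object$u_h$hi - object$u_h$lo)
  sq <- maut_vto(object, c = object$u_c$hi, h = h_near)
  out <- list(constants = ct,
              additive = ct$K == 0,
              interaction = if (ct$K > 0) "complements"
                            else if (ct$K < 0) "substitutes" else "additive",
              status_quo_vto = sq, h_near = h_near)
  class(out) <- "summary.maut_model"
  out
}

#' @export
print.summary.maut_model <- function(x, ...) {
  print(x$constants)
  cat("Value trade-off near the status quo (maximum consumption, gain ",
      format(x$h_near), "): ", format(x$status_quo_vto),
      " money per QALY\n", sep = "")
  invisible(x)
}

#' Evaluate the multiplicative MAUT value function
#'
#' @param model A [maut_model()].
#' @param c,h Consumption and health-gain levels inside the model's
#'   attribute ranges (vectors are recycled to common length).
#' @return Value(s) \eqn{V(c,h)} in `[0, 1]`.
#' @export
maut_value <- function(model, c, h) {
  stopifnot(inherits(model, "maut_model"))
  uc <- eval_utility(model$u_c, c)
  uh <- eval_utility(model$u_h, h)
  ct <- model$constants
  ct$k_c * uc + ct$k_h * uh + ct$K * ct$k_c * ct$k_h * uc * uh
}

#' @param object A [maut_model()].
#' @param newdata A list or data frame with components `c` and `h`.
#' @param ... Unused.
#' @rdname maut_value
#' @export
predict.maut_model <- function(object, newdata, ...) {
  maut_value(object, newdata$c, newdata$h)
}

#' MAUT value trade-off (money per QALY)
#'
#' The slope of the indifference curve of \eqn{V(c,h)}, obtained by setting
#' the total differential to zero:
#' \deqn{\frac{dc}{dh} = \frac{\partial V/\partial h}{\partial V/\partial c}
#'  = \frac{u^{h\prime}}{u^{c\prime}}
#'    \frac{k_h + (1-k_c-k_h)\,u^c(c)}{k_c + (1-k_c-k_h)\,u^h(h)},}
#' reported as a positive money-per-QALY magnitude: the amount of
#' consumption the decision maker gives up per unit of health gain while
#' staying indifferent. By default it is evaluated at the status quo of
#' maximum consumption and zero health gain; any in-range point is accepted.
#' When \eqn{K < 0} the bracket terms can turn non-positive, in which case
#' the trade-off is undefined and an error is raised.
#'
#' @param model A [maut_model()].
#' @param c,h Evaluation point; defaults to `(hi_c, lo_h)` — maximum
#'   consumption, zero QALY gain.
#' @return Positive value trade-off(s) in money per QALY.
#' @export
maut_vto <- function(model, c = model$u_c$hi, h = model$u_h$lo) {
  stopifnot(inherits(model, "maut_model"))
  ct <- model$constants
  uc  <- eval_utility(model$u_c, c)
  uh  <- eval_utility(model$u_h, h)
  duc <- marginal_utility(model$u_c, c)
  duh <- marginal_utility(model$u_h, h)
  lin <- 1 - ct$k_c - ct$k_h          # = K * k_c * k_h
  num <- ct$k_h + lin * uc
  den <- ct$k_c + lin * uh
  if (any(den <= 0) || any(num <= 0))
    stop("invalid trade-off point: a bracket term k_j + (1-k_c-k_h) u is ",
         "non-positive (possible only when K < 0)", call. = FALSE)
  (duh / duc) * num / den
}

#' Simulate the corner-lottery elicitation of scaling constants
#'
#' Inverse of [elicit_scaling_constants()]: given a MAUT model, finds the
#' indifference probabilities a decision maker holding that model would
#' state in the probabilistic-scaling task. The certain alternative (worst
#' consumption, best health) has value \eqn{V(c^0, h^*)}, and the
#' best/worst-corner lottery with win probability `p` has expected value
#' \eqn{p \cdot 1 + (1-p)\cdot 0 = p}; indifference therefore pins
#' `p_h = V(c^0, h^*)` (and symmetrically `p_c = V(c^*, h^0)`).
#'
#' @param model A [maut_model()].
#' @return Named numeric vector with elements `p_h` and `p_c`; feeding them
#'   back to [elicit_scaling_constants()] recovers the model's constants.
#' @export
simulate_elicitation <- function(model) {
  stopifnot(inherits(model, "maut_model"))
  c(p_h = maut_value(model, c = model$u_c$lo, h = model$u_h$hi),
    p_c = maut_value(model, c = model$u_c$hi, h = model$u_h$lo))
}

#' Trace an indifference curve of the MAUT value function
#'
#' For each health-gain level in `h_grid`, finds the consumption level `c`
#' at which \eqn{V(c, h)} equals `level`, by bracketed root-finding on the
#' consumption range (the value function is strictly increasing in `c`, so
#' a bracketed root is unique), followed by Newton polishing to drive the
#' residual in `V` below `1e-10`. Levels unattainable at some `h` (the
#' required `c` would fall outside the consumption range) are reported as
#' `NA`, never fabricated.
#'
#' @param model A [maut_model()].
#' @param level Target value-function level (e.g. the status-quo value).
#' @param h_grid Health-gain levels at which to solve for `c`.
#' @return A data frame with columns `h`, `c` (NA where unattainable) and
#'   `residual` (the achieved `V(c,h) - level`).
#' @export
trace_indifference_curve <- function(model, level, h_grid) {
  stopifnot(inherits(model, "maut_model"))
  lo_c <- model$u_c$lo; hi_c <- model$u_c$hi
  ct <- model$constants
  lin <- 1 - ct$k_c - ct$k_h
  c_out <- res_out <- rep(NA_real_, length(h_grid))
  for (i in seq_along(h_grid)) {
    h <- h_grid[i]
    f <- function(cc) maut_value(model, cc, h) - level
    flo <- f(lo_c); fhi <- f(hi_c)
    if (flo > 1e-12 || fhi < -1e-12) next  # level not attainable at this h
    if (abs(flo) <= 1e-15) { c_out[i] <- lo_c; res_out[i] <- flo; next }
    if (abs(fhi) <= 1e-15) { c_out[i] <- hi_c; res_out[i] <- fhi; next }
    root <- stats::uniroot(f, lower = lo_c, upper = hi_c,
                           f.lower = flo, f.upper = fhi,
                           tol = .Machine$double.eps^0.75)$root
    # Newton polish: dV/dc = u_c'(c) * [k_c + (1-k_c-k_h) u_h(h)]
    uh <- eval_utility(model$u_h, h)
    for (it in 1:3) {
      dv <- marginal_utility(model$u_c, root) * (ct$k_c + lin * uh)
      step <- f(root) / dv
      root <- min(max(root - step, lo_c), hi_c)
      if (abs(step) < .Machine$double.eps * max(1, abs(root))) break
    }
    c_out[i] <- root
    res_out[i] <- f(root)
  }
  data.frame(h = h_grid, c = c_out, residual = res_out)
}

#' @param x A [maut_model()].
#' @param levels Value-function levels whose indifference curves to draw.
#' @param n Grid resolution per curve.
#' @param ... Passed to [graphics::plot()].
#' @rdname trace_indifference_curve
#' @export
plot.maut_model <- function(x, levels = c(0.25, 0.5, 0.75), n = 101, ...) {
  h_grid <- seq(x$u_h$lo, x$u_h$hi, length.out = n)
  graphics::plot(NA, xlim = c(x$u_h$lo, x$u_h$hi),
                 xlab = "health gain (QALYs)", ylab = "consumption",
                 ylim = c(x$u_c$lo, x$u_c$hi),
                 main = "MAUT indifference curves", ...)
  for (lv in levels) {
    tr <- trace_indifference_curve(x, lv, h_grid)
    graphics::lines(tr$h, tr$c)
  }
  invisible(x)
}
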