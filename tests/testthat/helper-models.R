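# Random model generators used across the suite. Callers set the seed.

# exponential (CARA) rates are drawn so that rate * range stays moderate;
# otherwise the marginal utility underflows at the top of a money range
rand_curve <- function(lo, hi,
                       families = c("linear", "power", "exponential")) {
  fam <- sample(families, 1L)
  utility_curve(fam,
                shape = switch(fam, linear = NULL,
                               power = runif(1, 0.4, 1),
                               exponential = runif(1, 0.3, 3) / (hi - lo)),
                lo = lo, hi = hi)
}

# MAUT model with K >= 0 (complements/independent) unless substitutes = TRUE
rand_maut <- function(substitutes = FALSE,
                      families = c("linear", "power", "exponential")) {
  repeat {
    k_c <- runif(1, 0.05, 0.95)
    k_h <- runif(1, 0.05, 0.95)
    s <- k_c + k_h
    if ((substitutes && s > 1) || (!substitutes && s <= 1)) break
  }
  build <- function()
    maut_model(rand_curve(0, runif(1, 2e4, 1e5), families),
               rand_curve(0, runif(1, 0.3, 2), families),
               k_c = k_c, k_h = k_h)
  if (substitutes) suppressWarnings(build()) else build()
}

# interior point of the attribute box, away from the edges
rand_point <- function(model, lo_frac = 0.2, hi_frac = 0.8) {
  list(c = model$u_c$lo + runif(1, lo_frac, hi_frac) *
         (model$u_c$hi - model$u_c$lo),
       h = model$u_h$lo + runif(1, lo_frac, hi_frac) *
         (model$u_h$hi - model$u_h$lo))
}

# `share` bounds the interaction term theta * g(c) as a fraction of the
# direct health weight beta at the top of the income box, keeping marginal
# utilities positive over the working domain
rand_bivariate <- function(share = c(0, 0.5)) {
  r_c <- runif(1, 0.3, 1.3)
  beta <- runif(1, 0.1, 1)
  g_ref <- if (r_c == 1) log(1e5) else 1e5^(1 - r_c) / (1 - r_c)
  theta <- runif(1, share[1], share[2]) * beta / max(1, abs(g_ref))
  bivariate_utility(if (theta == 0) "additive" else "interaction",
                    r_c = r_c, beta = beta,
                    r_h = runif(1, 0.1, 0.6), theta = theta)
}

rand_scenario <- function(dh_s = NULL) {
  y_w <- runif(1, 2e4, 8e4)
  h_w <- runif(1, 0.7, 1)
  h_s <- runif(1, 0.2, h_w - 0.15)
  if (is.null(dh_s)) dh_s <- runif(1, 0.05, h_w - h_s)
  health_scenario(pi = runif(1, 0.02, 0.4),
                  y_s = y_w * runif(1, 0.6, 1), y_w = y_w,
                  h_s = h_s, h_w = h_w, dh_s = dh_s)
}

rand_plan <- function(y_s, p_frac = c(0, 0.2)) {
  insurance_plan(p = runif(1, p_frac[1], p_frac[2]) * y_s,
                 coverage = runif(1, 0.5, 1))
}

# finite-difference oracle for the MAUT trade-off: secant of the traced
# indifference curve across a small symmetric step in h
secant_vto <- function(model, c0, h0, step = 1e-4) {
  dlt <- step * (model$u_h$hi - model$u_h$lo)
  lv <- maut_value(model, c0, h0)
  tr <- trace_indifference_curve(model, lv, c(h0 - dlt / 2, h0 + dlt / 2))
  -diff(tr$c) / diff(tr$h)
}
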