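#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario description and validates it against the schema
#' used throughout the package, collecting *all* violations before failing
#' (not just the first). Sections, with units:
#'
#' * `ranges`: `c_lo`, `c_hi` (money), `h_lo`, `h_hi` (QALY gain) — the
#'   MAUT attribute box.
#' * `curves`: `consumption` and `health`, each `{family, shape}` as in
#'   [utility_curve()].
#' * exactly one of `scaling_constants` (`{k_c, k_h}`, each in (0, 1]) or
#'   `elicitation_probs` (`{p_c, p_h}`, indifference probabilities).
#' * `health_scenario`: `pi`, `y_s`, `y_w` (money), `h_s`, `h_w`, `dh_s`
#'   (QALY scale) as in [health_scenario()].
#' * `insurance_plan` (optional): `p` (money), `coverage` in [0, 1],
#'   `gamma >= 1`; defaults to a zero-cost plan.
#' * `acea_utility` (optional): `{family, r_c, beta, r_h, theta}` as in
#'   [bivariate_utility()]; defaults to additive log-consumption utility
#'   with `beta = 0.2`.
#' * `sweeps` (optional): `{factor, levels}` for [comparative_statics()].
#'
#' Money units are arbitrary but must be consistent within a run; health is
#' on the QALY scale.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration (class `"scenario_config"`).
#' @seealso [as_maut_model()], [as_acea_inputs()] to build model objects
#'   from a configuration.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_scenario_config(cfg)
}

#' @param config A raw configuration list (as parsed from YAML).
#' @rdname load_scenario_config
#' @export
validate_scenario_config <- function(config) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, paste0(...))
  num_in <- function(section, field, lo = -Inf, hi = Inf,
                     lo_open = FALSE, hi_open = FALSE, required = TRUE) {
    x <- config[[section]][[field]]
    at <- paste0(section, "$", field)
    if (is.null(x)) {
      if (required) say("missing field ", at)
      return(invisible(NULL))
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      say(at, " must be a single finite number")
      return(invisible(NULL))
    }
    bad_lo <- if (lo_open) x <= lo else x < lo
    bad_hi <- if (hi_open) x >= hi else x > hi
    if (bad_lo || bad_hi)
      say(at, " = ", format(x), " outside ",
          if (lo_open) "(" else "[", format(lo), ", ", format(hi),
          if (hi_open) ")" else "]")
    invisible(NULL)
  }
  for (sec in c("ranges", "curves", "health_scenario"))
    if (is.null(config[[sec]])) say("missing section ", sec)

  if (!is.null(config$ranges)) {
    num_in("ranges", "c_lo"); num_in("ranges", "c_hi")
    num_in("ranges", "h_lo"); num_in("ranges", "h_hi")
    r <- config$ranges
    if (is.numeric(r$c_lo) && is.numeric(r$c_hi) && r$c_hi <= r$c_lo)
      say("ranges: c_hi must exceed c_lo")
    if (is.numeric(r$h_lo) && is.numeric(r$h_hi) && r$h_hi <= r$h_lo)
      say("ranges: h_hi must exceed h_lo")
  }
  if (!is.null(config$curves)) {
    for (side in c("consumption", "health")) {
      cv <- config$curves[[side]]
      if (is.null(cv)) { say("missing section curves$", side); next }
      if (is.null(cv$family) ||
          !cv$family %in% c("linear", "power", "exponential"))
        say("curves$", side, "$family must be one of linear, power, ",
            "exponential")
      else if (cv$family != "linear" &&
               (!is.numeric(cv$shape) || length(cv$shape) != 1L))
        say("curves$", side, "$shape must be a number for family ",
            cv$family)
    }
  }
  has_k <- !is.null(config$scaling_constants)
  has_p <- !is.null(config$elicitation_probs)
  if (has_k && has_p)
    say("scaling_constants and elicitation_probs are mutually exclusive")
  if (!has_k && !has_p)
    say("one of scaling_constants or elicitation_probs is required")
  if (has_k && !has_p) {
    num_in("scaling_constants", "k_c", 0, 1, lo_open = TRUE)
    num_in("scaling_constants", "k_h", 0, 1, lo_open = TRUE)
  }
  if (has_p && !has_k) {
    num_in("elicitation_probs", "p_c", 0, 1, lo_open = TRUE)
    num_in("elicitation_probs", "p_h", 0, 1, lo_open = TRUE)
  }
  if (!is.null(config$health_scenario)) {
    num_in("health_scenario", "pi", 0, 1, lo_open = TRUE, hi_open = TRUE)
    num_in("health_scenario", "y_s", 0, Inf, lo_open = TRUE)
    num_in("health_scenario", "y_w", 0, Inf, lo_open = TRUE)
    num_in("health_scenario", "h_s", 0, Inf, lo_open = TRUE)
    num_in("health_scenario", "h_w", 0, Inf, lo_open = TRUE)
    num_in("health_scenario", "dh_s", 0, Inf)
    hs <- config$health_scenario
    if (is.numeric(hs$y_s) && is.numeric(hs$y_w) && hs$y_w < hs$y_s)
      say("health_scenario: y_w must be >= y_s")
    if (is.numeric(hs$h_s) && is.numeric(hs$h_w) && hs$h_w <= hs$h_s)
      say("health_scenario: h_w must exceed h_s")
  }
  if (!is.null(config$insurance_plan)) {
    num_in("insurance_plan", "p", 0, Inf)
    num_in("insurance_plan", "coverage", 0, 1, required = FALSE)
    num_in("insurance_plan", "gamma", 1, Inf, required = FALSE)
  }
  if (!is.null(config$acea_utility)) {
    au <- config$acea_utility
    if (is.null(au$family) ||
        !au$family %in% c("additive", "interaction", "custom"))
      say("acea_utility$family must be one of additive, interaction, custom")
    num_in("acea_utility", "r_c", 0, Inf, required = FALSE)
    num_in("acea_utility", "beta", 0, Inf, lo_open = TRUE, required = FALSE)
    num_in("acea_utility", "r_h", 0, 1, hi_open = TRUE, required = FALSE)
  }
  if (!is.null(config$sweeps)) {
    sw <- config$sweeps
    if (is.null(sw$factor) ||
        !sw$factor %in% c("income", "technology_cost", "severity"))
      say("sweeps$factor must be one of income, technology_cost, severity")
    lv <- unlist(sw$levels)
    if (!is.numeric(lv) || length(lv) < 2L || any(diff(lv) <= 0))
      say("sweeps$levels must be at least two strictly increasing numbers")
  }
  if (length(errs))
    stop("invalid scenario configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  structure(config, class = "scenario_config")
}

#' Build model objects from a scenario configuration
#'
#' `as_maut_model()` assembles the [maut_model()] (deriving scaling
#' constants from elicitation probabilities when those are given);
#' `as_acea_inputs()` returns the [bivariate_utility()],
#' [health_scenario()] and [insurance_plan()] triple.
#'
#' @param config A validated `scenario_config`.
#' @return A [maut_model()], or a list `(u, scenario, plan, gamma)`.
#' @export
as_maut_model <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  r <- config$ranges
  u_c <- utility_curve(config$curves$consumption$family,
                       config$curves$consumption$shape, r$c_lo, r$c_hi)
  u_h <- utility_curve(config$curves$health$family,
                       config$curves$health$shape, r$h_lo, r$h_hi)
  ct <- if (!is.null(config$scaling_constants))
    scaling_constants(config$scaling_constants$k_c,
                      config$scaling_constants$k_h)
  else
    elicit_scaling_constants(config$elicitation_probs$p_h,
                             config$elicitation_probs$p_c)
  maut_model(u_c, u_h, constants = ct)
}

#' @rdname as_maut_model
#' @export
as_acea_inputs <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  au <- config$acea_utility
  u <- if (is.null(au)) bivariate_utility("additive", r_c = 1, beta = 0.2)
  else bivariate_utility(au$family,
                         r_c = if (is.null(au$r_c)) 1 else au$r_c,
                         beta = if (is.null(au$beta)) 0.2 else au$beta,
                         r_h = if (is.null(au$r_h)) 0 else au$r_h,
                         theta = if (is.null(au$theta)) 0 else au$theta)
  hs <- config$health_scenario
  scenario <- health_scenario(hs$pi, hs$y_s, hs$y_w, hs$h_s, hs$h_w, hs$dh_s)
  ip <- config$insurance_plan
  plan <- if (is.null(ip)) insurance_plan(0)
  else insurance_plan(ip$p,
                      coverage = if (is.null(ip$coverage)) 1 else ip$coverage,
                      gamma = if (is.null(ip$gamma)) 1 else ip$gamma)
  list(u = u, scenario = scenario, plan = plan, gamma = plan$gamma)
}

#' Generate random scenario configurations for property sweeps
#'
#' Draws `n` feasible scenario configurations from documented parameter
#' boxes: scaling constants in `[0.05, 0.95]`, disease probability in
#' `[0.01, 0.5]`, well-state income in `[1e4, 1e5]` (sick-state income
#' 60--100\% of it), health levels in `(0, 1]`. Deterministic given
#' `seed`.
#'
#' Constraints:
#' * `"complements_only"` — every draw has MAUT interaction `K >= 0`
#'   (`k_c + k_h <= 1`) and ACEA cross-partial `u_ch >= 0` (`theta >= 0`).
#' * `"include_substitutes"` — at least one draw has `K < 0` (and a
#'   negative ACEA interaction).
#' * `"risk_neutral_only"` — linear single-attribute curves and a linear
#'   additive bivariate utility.
#'
#' `"complements_only"` and `"include_substitutes"` are mutually
#' unsatisfiable and raise an error.
#'
#' @param n Number of configurations (`> 0`).
#' @param seed Integer seed.
#' @param constraints Character vector of constraint tags (possibly empty).
#' @return A list of `n` validated `scenario_config` objects.
#' @export
generate_fixtures <- function(n, seed, constraints = character()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  known <- c("complements_only", "include_substitutes", "risk_neutral_only")
  if (!all(constraints %in% known))
    stop("unknown constraint tag(s): ",
         paste(setdiff(constraints, known), collapse = ", "), call. = FALSE)
  if (all(c("complements_only", "include_substitutes") %in% constraints))
    stop("unsatisfiable constraints: complements_only excludes substitutes",
         call. = FALSE)
  comp_only <- "complements_only" %in% constraints
  want_subs <- "include_substitutes" %in% constraints
  neutral <- "risk_neutral_only" %in% constraints
  n <- as.integer(n)
  with_seed(seed, {
    draw_one <- function(force_subs = FALSE) {
      repeat {
        k_c <- stats::runif(1, 0.05, 0.95)
        k_h <- stats::runif(1, 0.05, 0.95)
        s <- k_c + k_h
        if (comp_only && s > 1) next
        if (force_subs && s <= 1) next
        break
      }
      theta_sign <- if (k_c + k_h > 1) -1 else 1  # match interaction sign
      y_w <- stats::runif(1, 1e4, 1e5)
      y_s <- y_w * stats::runif(1, 0.6, 1)
      h_w <- stats::runif(1, 0.7, 1)
      h_s <- stats::runif(1, 0.15, h_w - 0.2)
      dh_s <- stats::runif(1, 0, h_w - h_s)
      # exponential rates scale with the attribute range so that
      # rate * range is moderate and marginal utility never underflows
      curve <- function(width) {
        if (neutral) return(list(family = "linear", shape = NULL))
        fam <- sample(c("linear", "power", "exponential"), 1L)
        list(family = fam,
             shape = switch(fam, linear = NULL,
                            power = stats::runif(1, 0.4, 1),
                            exponential = stats::runif(1, 0.2, 2) / width))
      }
      acea <- if (neutral)
        list(family = "additive", r_c = 0, beta = stats::runif(1, 0.1, 1),
             r_h = 0, theta = 0)
      else
        list(family = "interaction", r_c = stats::runif(1, 0.3, 1),
             beta = stats::runif(1, 0.1, 1),
             r_h = stats::runif(1, 0.1, 0.8),
             theta = theta_sign * stats::runif(1, 0, 0.05))
      cfg <- list(
        ranges = list(c_lo = 0, c_hi = y_w, h_lo = 0, h_hi = h_w - h_s),
        curves = list(consumption = curve(y_w), health = curve(h_w - h_s)),
        scaling_constants = list(k_c = k_c, k_h = k_h),
        health_scenario = list(pi = stats::runif(1, 0.01, 0.5),
                               y_s = y_s, y_w = y_w, h_s = h_s, h_w = h_w,
                               dh_s = dh_s),
        insurance_plan = list(p = stats::runif(1, 0, 0.2) * y_s,
                              coverage = 1, gamma = 1),
        acea_utility = acea)
      validate_scenario_config(cfg)
    }
    out <- lapply(seq_len(n), function(i) draw_one())
    if (want_subs &&
        !any(vapply(out, function(cfg)
          cfg$scaling_constants$k_c + cfg$scaling_constants$k_h > 1,
          logical(1L))))
      out[[n]] <- draw_one(force_subs = TRUE)
    out
  })
}

#' Write (and read back) analysis records
#'
#' Writes a non-empty set of records to CSV (stable column order, header
#' row) or JSON (lossless numeric round-trip). `read_report()` reads a
#' file written by `write_report()` back into a data frame.
#'
#' @param records A data frame (or a list of equal-structure lists, which
#'   is converted to one) with at least one row.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must contain at least one record", call. = FALSE)
  ok <- tryCatch({
    if (format == "csv")
      utils::write.csv(records, path, row.names = FALSE)
    else
      jsonlite::write_json(records, path, digits = NA, dataframe = "rows")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write report to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("report file not found: ", path, call. = FALSE)
  if (format == "csv") utils::read.csv(path)
  else as.data.frame(jsonlite::fromJSON(path))
}

#' Canonical digest of a configuration
#'
#' A 32-bit FNV-1a digest of the canonical JSON serialization of a
#' configuration (keys sorted recursively), so the digest is stable under
#' reordering of keys. Used in [run_record()] to identify the exact inputs
#' of a run.
#'
#' @param config A configuration list.
#' @return An 8-character hexadecimal string.
#' @export
config_digest <- function(config) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x))
      lapply(x[order(names(x))], canon)
    else if (is.list(x)) lapply(x, canon)
    else x
  }
  json <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                           digits = 15, null = "null")
  fnv1a32(charToRaw(as.character(json)))
}

#' Provenance record for an analysis run
#'
#' @param config The configuration used (digested via [config_digest()]).
#' @param seed Integer seed of the run.
#' @param outputs Character vector of output file paths.
#' @return A list with `version`, `config_digest`, `seed`, `timestamp`,
#'   `outputs`.
#' @export
run_record <- function(config, seed, outputs = character()) {
  list(version = as.character(utils::packageVersion("qalyvto")),
       config_digest = config_digest(config),
       seed = as.integer(seed),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}
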