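# Scenario container: domain types, validation, YAML input and output.
#
# A scenario fully describes one decomposition problem: per-sex populations
# and observed fracture counts at the baseline year (BY) and end year (EY),
# the binary exposures (risk factors, preventive measures, drug classes with
# side effects) with per-sex prevalences and relative risks, and the
# osteoporosis-medication component. Prevalences are proportions in [0, 1]
# everywhere inside the package; published tables usually print percentages
# and the conversion is the reader's responsibility (recorded in the run log).

#' Uncertainty bounds for a single model parameter
#'
#' @param low,high lower/upper feasible value, `low <= high`.
#' @param source how the bounds were obtained: `"ci95"` (a published 95%
#'   confidence interval), `"pct20"` (central value +/- 20%, the fallback rule
#'   of the extremes analysis), or `"custom"`.
#' @return an object of class `uncertainty_bounds`.
#' @export
uncertainty_bounds <- function(low, high, source = c("custom", "ci95", "pct20")) {
  source <- match.arg(source)
  if (!is_number(low) || !is_number(high) || length(low) != 1 || length(high) != 1)
    fail("uncertainty_bounds: 'low' and 'high' must be single finite numbers")
  if (low > high)
    fail("uncertainty_bounds: low (%g) > high (%g)", low, high)
  structure(list(low = low, high = high, source = source),
            class = "uncertainty_bounds")
}

#' One sex stratum's population and observed fracture counts
#'
#' @param sex stratum label, e.g. `"women"`.
#' @param pop_by,pop_ey population (persons) at baseline/end year; must be > 0.
#' @param observed_by,observed_ey observed fracture counts; `>= 0` and no
#'   larger than the corresponding population. Counts may be non-integer: the
#'   synthetic noise-free mode stores exact implied counts.
#' @param rate_by optional baseline fracture rate per 10,000 to use instead of
#'   `observed_by / pop_by * 1e4`. National reports often publish a rounded
#'   rate whose downstream arithmetic (expected counts) is keyed to the
#'   printed value; supplying it here reproduces that arithmetic.
#' @return an object of class `stratum_record`.
#' @export
stratum_record <- function(sex, pop_by, pop_ey, observed_by, observed_ey,
                           rate_by = NULL) {
  if (!is.character(sex) || length(sex) != 1 || !nzchar(sex))
    fail("stratum_record: 'sex' must be a non-empty label")
  for (f in c("pop_by", "pop_ey")) {
    v <- get(f)
    if (!is_number(v) || length(v) != 1 || v <= 0)
      fail("stratum '%s': field '%s' must be a positive number", sex, f)
  }
  for (f in c("observed_by", "observed_ey")) {
    v <- get(f)
    if (!is_number(v) || length(v) != 1 || v < 0)
      fail("stratum '%s': field '%s' must be >= 0", sex, f)
  }
  if (observed_by > pop_by)
    fail("stratum '%s': field 'observed_by' exceeds 'pop_by'", sex)
  if (observed_ey > pop_ey)
    fail("stratum '%s': field 'observed_ey' exceeds 'pop_ey'", sex)
  if (!is.null(rate_by) && (!is_number(rate_by) || rate_by < 0))
    fail("stratum '%s': field 'rate_by' must be >= 0", sex)
  structure(list(sex = sex, pop_by = pop_by, pop_ey = pop_ey,
                 observed_by = observed_by, observed_ey = observed_ey,
                 rate_by = rate_by),
            class = "stratum_record")
}

factor_categories <- c("risk_factor", "preventive", "drug_side_effect")

#' One binary exposure: prevalences at BY/EY and a relative risk
#'
#' Covers classical risk factors (smoking, type 2 diabetes), preventive
#' exposures (BMI >= 25, physical activity, total hip replacement — all with
#' RR < 1 for hip fracture), and drug classes with side effects
#' (benzodiazepines, z-drugs, glucocorticoids, opioids). All flow through the
#' same PARF machinery; the category only controls which component subtotal
#' the contribution is booked under.
#'
#' @param name unique factor name.
#' @param category one of `"risk_factor"`, `"preventive"`, `"drug_side_effect"`.
#' @param prevalence_by,prevalence_ey named numeric vectors (one entry per
#'   sex) of exposure prevalences as proportions in \[0, 1\]; a single
#'   unnamed number is shared across sexes.
#' @param relative_risk relative risk of hip fracture given exposure, > 0;
#'   per-sex named vector or a single shared value.
#' @param bounds optional named list of [uncertainty_bounds()] (or per-sex
#'   lists of them) for `"prevalence_by"`, `"prevalence_ey"`,
#'   `"relative_risk"`; parameters without bounds fall back to the +/- 20%
#'   rule in the sensitivity analysis.
#' @param reported_nx optional named numeric vector of externally reported
#'   per-sex contributions plus `total` (a reported-outcome annotation, used
#'   by the "published" aggregation track; never recomputed).
#' @param reported_range optional numeric `c(low, high)` reported range for
#'   the factor's total contribution.
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, category, prevalence_by, prevalence_ey,
                        relative_risk, bounds = NULL,
                        reported_nx = NULL, reported_range = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    fail("factor_spec: 'name' must be a non-empty string")
  if (!is.character(category) || length(category) != 1 ||
      !category %in% factor_categories)
    fail("factor '%s': field 'category' must be one of %s", name,
         paste(factor_categories, collapse = ", "))
  obj <- structure(list(name = name, category = category,
                        prevalence_by = prevalence_by,
                        prevalence_ey = prevalence_ey,
                        relative_risk = relative_risk,
                        bounds = bounds,
                        reported_nx = reported_nx,
                        reported_range = reported_range),
                   class = "factor_spec")
  obj
}

# called from scenario() once the stratum labels are known
validate_factor <- function(f, sexes) {
  ctx <- sprintf("factor '%s'", f$name)
  for (fld in c("prevalence_by", "prevalence_ey")) {
    v <- per_sex_vector(f[[fld]], sexes, fld, ctx)
    if (any(v < 0 | v > 1))
      fail("%s: field '%s' must lie in [0, 1] (got %g)", ctx, fld,
           v[which(v < 0 | v > 1)[1]])
    f[[fld]] <- v
  }
  rr <- per_sex_vector(f$relative_risk, sexes, "relative_risk", ctx)
  if (any(rr <= 0))
    fail("%s: field 'relative_risk' must be > 0 (got %g)", ctx, min(rr))
  f$relative_risk <- rr
  if (!is.null(f$reported_nx)) {
    v <- unlist(f$reported_nx)
    need <- c(sexes, "total")
    if (!all(need %in% names(v)))
      fail("%s: 'reported_nx' must name %s", ctx, paste(need, collapse = ", "))
    f$reported_nx <- v[need]
  }
  if (!is.null(f$reported_range)) {
    v <- unlist(f$reported_range)
    if (length(v) != 2 || v[1] > v[2])
      fail("%s: 'reported_range' must be c(low, high) with low <= high", ctx)
    f$reported_range <- stats::setNames(as.numeric(v), c("low", "high"))
  }
  f
}

#' Osteoporosis-medication component inputs
#'
#' The medication term multiplies the number of treated users (OM) by the
#' relative risk reduction of the drug group and by the hip-fracture rate in
#' osteoporosis patients (population rate times the osteoporosis relative
#' risk).
#'
#' @param name medication group name (e.g. `"bisphosphonates"`).
#' @param users_by,users_ey treated users per sex at baseline/end year
#'   (named vectors or shared scalars), `>= 0`.
#' @param rrr relative risk reduction of the treatment, in \[0, 1\].
#' @param osteo_rr relative risk of hip fracture in osteoporosis patients vs
#'   the whole population, per sex, `>= 1`.
#' @param bounds optional named list of [uncertainty_bounds()] for
#'   `"users_ey"`, `"rrr"`, `"osteo_rr"`.
#' @param reported_nx,reported_range as in [factor_spec()].
#' @return an object of class `medication_spec`.
#' @export
medication_spec <- function(name, users_by, users_ey, rrr, osteo_rr,
                            bounds = NULL, reported_nx = NULL,
                            reported_range = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    fail("medication_spec: 'name' must be a non-empty string")
  structure(list(name = name, users_by = users_by, users_ey = users_ey,
                 rrr = rrr, osteo_rr = osteo_rr, bounds = bounds,
                 reported_nx = reported_nx, reported_range = reported_range),
            class = "medication_spec")
}

validate_medication <- function(m, sexes) {
  ctx <- sprintf("medication '%s'", m$name)
  for (fld in c("users_by", "users_ey")) {
    v <- per_sex_vector(m[[fld]], sexes, fld, ctx)
    if (any(v < 0)) fail("%s: field '%s' must be >= 0", ctx, fld)
    m[[fld]] <- v
  }
  if (!is_number(m$rrr) || length(m$rrr) != 1 || m$rrr < 0 || m$rrr > 1)
    fail("%s: field 'rrr' must lie in [0, 1]", ctx)
  orr <- per_sex_vector(m$osteo_rr, sexes, "osteo_rr", ctx)
  if (any(orr < 1))
    fail("%s: field 'osteo_rr' must be >= 1 (risk in osteoporosis patients)", ctx)
  m$osteo_rr <- orr
  if (!is.null(m$reported_nx)) {
    v <- unlist(m$reported_nx)
    need <- c(sexes, "total")
    if (!all(need %in% names(v)))
      fail("%s: 'reported_nx' must name %s", ctx, paste(need, collapse = ", "))
    m$reported_nx <- v[need]
  }
  if (!is.null(m$reported_range)) {
    v <- unlist(m$reported_range)
    if (length(v) != 2 || v[1] > v[2])
      fail("%s: 'reported_range' must be c(low, high) with low <= high", ctx)
    m$reported_range <- stats::setNames(as.numeric(v), c("low", "high"))
  }
  m
}

default_options <- function() {
  list(track = "both",          # published | equations | both
       adjustment = "delta_parf", # delta_parf | parf_ey | none
       interval = "exact",      # exact | normal
       level = 0.95,
       sensitivity = "monotone", # monotone | enumeration | off
       rate_digits = 2,
       pct_digits = 1)
}

#' Assemble and validate a complete scenario
#'
#' @param baseline_year,end_year calendar years delimiting the interval;
#'   `end_year > baseline_year`.
#' @param strata list of [stratum_record()], one per sex; at least one.
#' @param factors list of [factor_spec()]; names must be unique.
#' @param medications list of [medication_spec()].
#' @param options named list overriding the defaults (aggregation track,
#'   adjustment interpretation, interval method, sensitivity mode, display
#'   rounding); unknown option names are rejected.
#' @return a validated object of class `hip_scenario`.
#' @export
scenario <- function(baseline_year, end_year, strata, factors = list(),
                     medications = list(), options = list()) {
  if (!is_number(baseline_year) || !is_number(end_year) ||
      end_year <= baseline_year)
    fail("scenario: 'end_year' must be later than 'baseline_year'")
  if (!is.list(strata) || length(strata) < 1)
    fail("scenario: at least one stratum is required")
  if (!all(vapply(strata, inherits, TRUE, "stratum_record")))
    fail("scenario: 'strata' must be a list of stratum_record objects")
  sexes <- vapply(strata, `[[`, "", "sex")
  if (anyDuplicated(sexes))
    fail("scenario: duplicated stratum label '%s'", sexes[duplicated(sexes)][1])
  names(strata) <- sexes

  if (!all(vapply(factors, inherits, TRUE, "factor_spec")))
    fail("scenario: 'factors' must be a list of factor_spec objects")
  fnames <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(fnames))
    fail("scenario: duplicated factor name '%s'", fnames[duplicated(fnames)][1])
  factors <- lapply(factors, validate_factor, sexes = sexes)
  names(factors) <- fnames

  if (!all(vapply(medications, inherits, TRUE, "medication_spec")))
    fail("scenario: 'medications' must be a list of medication_spec objects")
  medications <- lapply(medications, validate_medication, sexes = sexes)
  names(medications) <- vapply(medications, `[[`, "", "name")

  opts <- default_options()
  check_known_keys(options, names(opts), "scenario options")
  opts[names(options)] <- options
  match_opt <- function(key, choices) {
    if (!opts[[key]] %in% choices)
      fail("scenario options: '%s' must be one of %s", key,
           paste(choices, collapse = ", "))
  }
  match_opt("track", c("published", "equations", "both"))
  match_opt("adjustment", c("delta_parf", "parf_ey", "none"))
  match_opt("interval", c("exact", "normal"))
  match_opt("sensitivity", c("monotone", "enumeration", "off"))

  structure(list(baseline_year = baseline_year, end_year = end_year,
                 strata = strata, factors = factors,
                 medications = medications, options = opts),
            class = "hip_scenario")
}

#' @export
print.hip_scenario <- function(x, ...) {
  cat(sprintf("<hip_scenario> %d-%d: %d strata (%s), %d factors, %d medication groups\n",
              x$baseline_year, x$end_year, length(x$strata),
              paste(names(x$strata), collapse = ", "),
              length(x$factors), length(x$medications)))
  invisible(x)
}

# ---- YAML input / output ----------------------------------------------------

bounds_from_yaml <- function(b, ctx) {
  if (is.null(b)) return(NULL)
  parse_one <- function(x, key) {
    check_known_keys(x, c("low", "high", "source"), paste0(ctx, " bounds ", key))
    if (is.null(x$low) || is.null(x$high))
      fail("%s: bounds for '%s' need 'low' and 'high'", ctx, key)
    uncertainty_bounds(x$low, x$high, x$source %||% "custom")
  }
  out <- list()
  for (key in names(b)) {
    v <- b[[key]]
    if (!is.null(v$low)) {
      out[[key]] <- parse_one(v, key)
    } else {
      # per-sex mapping of bounds
      out[[key]] <- lapply(stats::setNames(nm = names(v)),
                           function(s) parse_one(v[[s]], paste(key, s)))
    }
  }
  out
}

#' Read a scenario from a YAML file
#'
#' The config dialect mirrors the scenario structure: top-level keys
#' `baseline_year`, `end_year`, `strata`, `factors`, `medications`,
#' `options`. Prevalences are proportions in \[0, 1\]; per-sex quantities are
#' mappings keyed by the stratum labels, or a single number shared across
#' sexes. Unknown keys anywhere are rejected with an error naming the key.
#'
#' @param path path to a YAML scenario file.
#' @return a validated `hip_scenario`.
#' @seealso [write_scenario()], [romania_scenario()]
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) fail("read_scenario: file '%s' does not exist", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) fail("read_scenario: parse failure in '%s': %s",
                                           path, conditionMessage(e)))
  scenario_from_list(raw)
}

scenario_from_list <- function(raw) {
  check_known_keys(raw, c("baseline_year", "end_year", "strata", "factors",
                          "medications", "options"), "scenario")
  for (req in c("baseline_year", "end_year", "strata"))
    if (is.null(raw[[req]])) fail("scenario: missing required section '%s'", req)

  strata <- lapply(raw$strata, function(s) {
    check_known_keys(s, c("sex", "pop_by", "pop_ey", "observed_by",
                          "observed_ey", "rate_by"), "stratum")
    if (is.null(s$sex)) fail("stratum: missing required field 'sex'")
    stratum_record(s$sex, s$pop_by, s$pop_ey, s$observed_by, s$observed_ey,
                   rate_by = s$rate_by)
  })

  factors <- lapply(raw$factors %||% list(), function(f) {
    ctx <- sprintf("factor '%s'", f$name %||% "<unnamed>")
    check_known_keys(f, c("name", "category", "prevalence_by", "prevalence_ey",
                          "relative_risk", "bounds", "reported_nx",
                          "reported_range"), ctx)
    if (is.null(f$name)) fail("factor: missing required field 'name'")
    factor_spec(f$name, f$category %||% "", f$prevalence_by, f$prevalence_ey,
                f$relative_risk, bounds = bounds_from_yaml(f$bounds, ctx),
                reported_nx = f$reported_nx, reported_range = f$reported_range)
  })

  medications <- lapply(raw$medications %||% list(), function(m) {
    ctx <- sprintf("medication '%s'", m$name %||% "<unnamed>")
    check_known_keys(m, c("name", "users_by", "users_ey", "rrr", "osteo_rr",
                          "bounds", "reported_nx", "reported_range"), ctx)
    if (is.null(m$name)) fail("medication: missing required field 'name'")
    medication_spec(m$name, m$users_by, m$users_ey, m$rrr, m$osteo_rr,
                    bounds = bounds_from_yaml(m$bounds, ctx),
                    reported_nx = m$reported_nx,
                    reported_range = m$reported_range)
  })

  scenario(raw$baseline_year, raw$end_year, strata, factors, medications,
           raw$options %||% list())
}

per_sex_to_yaml <- function(v) {
  if (isTRUE(attr(v, "shared"))) unname(v[1]) else as.list(v)
}

bounds_to_yaml <- function(b) {
  if (is.null(b)) return(NULL)
  one <- function(x) list(low = x$low, high = x$high, source = x$source)
  lapply(b, function(x) {
    if (inherits(x, "uncertainty_bounds")) one(x) else lapply(x, one)
  })
}

#' Write a scenario back to YAML
#'
#' `read_scenario(write_scenario(x, path))` round-trips to an equal scenario.
#'
#' @param x a `hip_scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "hip_scenario"))
  drop_null <- function(l) l[!vapply(l, is.null, TRUE)]
  out <- list(
    baseline_year = x$baseline_year,
    end_year = x$end_year,
    strata = lapply(unname(x$strata), function(s) drop_null(
      list(sex = s$sex, pop_by = s$pop_by, pop_ey = s$pop_ey,
           observed_by = s$observed_by, observed_ey = s$observed_ey,
           rate_by = s$rate_by))),
    factors = lapply(unname(x$factors), function(f) drop_null(
      list(name = f$name, category = f$category,
           prevalence_by = per_sex_to_yaml(f$prevalence_by),
           prevalence_ey = per_sex_to_yaml(f$prevalence_ey),
           relative_risk = per_sex_to_yaml(f$relative_risk),
           bounds = bounds_to_yaml(f$bounds),
           reported_nx = if (!is.null(f$reported_nx)) as.list(f$reported_nx),
           reported_range = if (!is.null(f$reported_range)) as.list(f$reported_range)))),
    medications = lapply(unname(x$medications), function(m) drop_null(
      list(name = m$name,
           users_by = per_sex_to_yaml(m$users_by),
           users_ey = per_sex_to_yaml(m$users_ey),
           rrr = m$rrr,
           osteo_rr = per_sex_to_yaml(m$osteo_rr),
           bounds = bounds_to_yaml(m$bounds),
           reported_nx = if (!is.null(m$reported_nx)) as.list(m$reported_nx),
           reported_range = if (!is.null(m$reported_range)) as.list(m$reported_range)))),
    options = x$options)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
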