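# Extremes (multidirectional) sensitivity analysis: every model parameter is
# assigned a lower and an upper feasible value — a supplied 95% CI when
# available, otherwise the central value +/- 20% — and the model is evaluated
# at joint corners of the resulting hypercube to bracket the explained count.

# internal: bounds for one scalar parameter, honouring supplied bounds,
# else the +/- 20% rule, clipped to a feasible range
bounds_for <- function(central, supplied = NULL, clip = c(-Inf, Inf)) {
  b <- if (!is.null(supplied)) {
    supplied
  } else {
    uncertainty_bounds(central * 0.8, central * 1.2, "pct20")
  }
  uncertainty_bounds(max(clip[1], b$low), min(clip[2], b$high), b$source)
}

#' Default uncertainty bounds for every parameter of a spec
#'
#' Supplied confidence-interval bounds are used where present; every other
#' parameter gets the central value +/- 20%, with prevalences clipped to
#' \[0, 1\] and the relative risk reduction clipped to \[0, 1\].
#'
#' @param spec a validated `factor_spec` or `medication_spec` (i.e. taken
#'   from a `hip_scenario`, so per-sex fields are named vectors).
#' @return named list: for per-sex parameters a list of
#'   [uncertainty_bounds()] keyed by sex, for scalars a single
#'   `uncertainty_bounds`.
#' @export
default_bounds <- function(spec) UseMethod("default_bounds")

#' @export
default_bounds.factor_spec <- function(spec) {
  sexes <- names(spec$prevalence_by)
  per_sex <- function(field, clip) {
    lapply(stats::setNames(nm = sexes), function(s)
      bounds_for(spec[[field]][[s]], spec$bounds[[field]][[s]], clip))
  }
  list(prevalence_by = per_sex("prevalence_by", c(0, 1)),
       prevalence_ey = per_sex("prevalence_ey", c(0, 1)),
       relative_risk = per_sex("relative_risk", c(1e-9, Inf)))
}

#' @export
default_bounds.medication_spec <- function(spec) {
  sexes <- names(spec$users_ey)
  per_sex <- function(field, clip) {
    lapply(stats::setNames(nm = sexes), function(s)
      bounds_for(spec[[field]][[s]], spec$bounds[[field]][[s]], clip))
  }
  list(users_ey = per_sex("users_ey", c(0, Inf)),
       rrr = bounds_for(spec$rrr, spec$bounds$rrr, c(0, 1)),
       osteo_rr = per_sex("osteo_rr", c(1, Inf)))
}

# internal: one row per varied scalar parameter. Parameters flagged as shared
# across sexes are varied as a single parameter applied to every sex.
param_table <- function(scn) {
  rows <- list()
  push <- function(target, name, field, sex, central, b) {
    rows[[length(rows) + 1]] <<- data.frame(
      target = target, name = name, field = field, sex = sex,
      central = central, low = b$low, high = b$high, source = b$source)
  }
  for (f in scn$factors) {
    db <- default_bounds(f)
    for (field in c("prevalence_by", "prevalence_ey", "relative_risk")) {
      v <- f[[field]]
      if (isTRUE(attr(v, "shared"))) {
        push("factor", f$name, field, NA_character_, v[[1]], db[[field]][[1]])
      } else {
        for (s in names(v)) push("factor", f$name, field, s, v[[s]], db[[field]][[s]])
      }
    }
  }
  for (m in scn$medications) {
    db <- default_bounds(m)
    u <- m$users_ey
    if (isTRUE(attr(u, "shared"))) {
      push("medication", m$name, "users_ey", NA_character_, u[[1]], db$users_ey[[1]])
    } else {
      for (s in names(u)) push("medication", m$name, "users_ey", s, u[[s]], db$users_ey[[s]])
    }
    push("medication", m$name, "rrr", NA_character_, m$rrr, db$rrr)
    orr <- m$osteo_rr
    if (isTRUE(attr(orr, "shared"))) {
      push("medication", m$name, "osteo_rr", NA_character_, orr[[1]], db$osteo_rr[[1]])
    } else {
      for (s in names(orr)) push("medication", m$name, "osteo_rr", s, orr[[s]], db$osteo_rr[[s]])
    }
  }
  if (length(rows) == 0)
    return(data.frame(target = character(), name = character(),
                      field = character(), sex = character(),
                      central = numeric(), low = numeric(), high = numeric(),
                      source = character()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# internal: return a copy of the scenario with the i-th parameter set
apply_params <- function(scn, params, values) {
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    v <- values[i]
    if (p$target == "factor") {
      cur <- scn$factors[[p$name]][[p$field]]
      if (is.na(p$sex)) cur[] <- v else cur[[p$sex]] <- v
      scn$factors[[p$name]][[p$field]] <- cur
    } else {
      if (p$field == "rrr") {
        scn$medications[[p$name]]$rrr <- v
      } else {
        cur <- scn$medications[[p$name]][[p$field]]
        if (is.na(p$sex)) cur[] <- v else cur[[p$sex]] <- v
        scn$medications[[p$name]][[p$field]] <- cur
      }
    }
  }
  scn
}

#' Extremes analysis: bracket the explained count over parameter bounds
#'
#' Every varied parameter (factor prevalences and relative risks; medication
#' end-year users, relative risk reduction, osteoporosis RR) gets bounds from
#' [default_bounds()]. Parameters are varied jointly to their extremes, not
#' one at a time.
#'
#' `mode = "enumeration"` evaluates the full equations-track model at every
#' corner of the bound hypercube (2^k corners; refused above 20 parameters).
#' `mode = "monotone"` probes each parameter's direction at the central point
#' and evaluates the model only at the assembled minimizing and maximizing
#' corners — exact whenever the model output is monotone in each parameter
#' over its bounds, an approximation otherwise.
#'
#' Observed counts and populations are data, not estimated parameters, and
#' are never varied; the excess is therefore fixed, and the min/max percents
#' are the min/max modeled counts over that fixed excess. Bounds of the same
#' factor's BY and EY prevalences are varied independently (no correlation
#' structure is imposed).
#'
#' @param scn a `hip_scenario`.
#' @param mode `"monotone"` (default) or `"enumeration"`.
#' @param adjustment forwarded to [decompose_scenario()].
#' @return object of class `hip_sensitivity`: `min_explained`,
#'   `max_explained`, `min_percent`, `max_percent`, `best` (central
#'   estimate), `per_component` data frame of per-factor/per-medication raw
#'   contribution ranges, `mode`, `n_params`.
#' @export
extremes_analysis <- function(scn, mode = NULL, adjustment = NULL) {
  stopifnot(inherits(scn, "hip_scenario"))
  mode <- mode %||% scn$options$sensitivity
  if (mode == "off") mode <- "monotone"
  if (!mode %in% c("monotone", "enumeration"))
    fail("extremes_analysis: 'mode' must be 'monotone' or 'enumeration'")

  params <- param_table(scn)
  k <- nrow(params)
  objective <- function(values) {
    d <- decompose_scenario(apply_params(scn, params, values),
                            track = "equations", adjustment = adjustment)
    d$nx_modeled
  }
  central <- params$central
  best <- if (k > 0) objective(central) else
    decompose_scenario(scn, track = "equations", adjustment = adjustment)$nx_modeled

  if (k == 0) {
    lo <- hi <- best
  } else if (mode == "enumeration") {
    if (k > 20)
      fail(paste("extremes_analysis: %d parameters is too many for corner",
                 "enumeration (limit 20); use mode = 'monotone'"), k)
    corners <- as.matrix(expand.grid(lapply(seq_len(k), function(i)
      c(params$low[i], params$high[i]))))
    vals <- apply(corners, 1, objective)
    lo <- min(vals); hi <- max(vals)
  } else {
    # probe each parameter's direction, others held central
    dir_up <- logical(k)
    for (i in seq_len(k)) {
      v_lo <- central; v_lo[i] <- params$low[i]
      v_hi <- central; v_hi[i] <- params$high[i]
      dir_up[i] <- objective(v_hi) >= objective(v_lo)
    }
    max_corner <- ifelse(dir_up, params$high, params$low)
    min_corner <- ifelse(dir_up, params$low, params$high)
    lo <- objective(min_corner); hi <- objective(max_corner)
  }

  excess <- decompose_scenario(scn, track = "equations",
                               adjustment = adjustment)$excess
  per_component <- component_ranges(scn, params)

  structure(list(min_explained = lo, max_explained = hi, best = best,
                 min_percent = 100 * lo / excess,
                 max_percent = 100 * hi / excess,
                 per_component = per_component, mode = mode, n_params = k),
            class = "hip_sensitivity")
}

# internal: per-factor / per-medication raw (unadjusted) contribution range,
# enumerating only that component's own parameter corners
component_ranges <- function(scn, params) {
  exp0 <- baseline_expectation(scn)
  ne <- stats::setNames(exp0$strata$expected_ey, exp0$strata$sex)
  rate_by <- stats::setNames(exp0$strata$rate_by, exp0$strata$sex)

  range_of <- function(target, name, f) {
    idx <- which(params$target == target & params$name == name)
    if (length(idx) == 0) return(c(f(numeric(0)), f(numeric(0))))
    corners <- as.matrix(expand.grid(lapply(idx, function(i)
      c(params$low[i], params$high[i]))))
    vals <- apply(corners, 1, function(v) f(stats::setNames(v, idx)))
    c(min(vals), max(vals))
  }

  rows <- list()
  for (fc in scn$factors) {
    eval_factor <- function(vals) {
      f <- fc
      for (nm in names(vals)) {
        p <- params[as.integer(nm), ]
        cur <- f[[p$field]]
        if (is.na(p$sex)) cur[] <- vals[[nm]] else cur[[p$sex]] <- vals[[nm]]
        f[[p$field]] <- cur
      }
      sum(vapply(names(ne), function(s)
        factor_contribution(ne[[s]], f$prevalence_by[[s]],
                            f$prevalence_ey[[s]], f$relative_risk[[s]]),
        numeric(1)))
    }
    r <- range_of("factor", fc$name, eval_factor)
    rows[[length(rows) + 1]] <- data.frame(component = fc$name,
                                           type = fc$category,
                                           low = r[1], high = r[2])
  }
  for (m in scn$medications) {
    eval_med <- function(vals) {
      mm <- m
      for (nm in names(vals)) {
        p <- params[as.integer(nm), ]
        if (p$field == "rrr") {
          mm$rrr <- vals[[nm]]
        } else {
          cur <- mm[[p$field]]
          if (is.na(p$sex)) cur[] <- vals[[nm]] else cur[[p$sex]] <- vals[[nm]]
          mm[[p$field]] <- cur
        }
      }
      sum(vapply(names(ne), function(s)
        medication_contribution(mm$users_ey[[s]], mm$rrr,
                                osteoporosis_rate(rate_by[[s]], mm$osteo_rr[[s]])),
        numeric(1)))
    }
    r <- range_of("medication", m$name, eval_med)
    rows[[length(rows) + 1]] <- data.frame(component = m$name,
                                           type = "medication",
                                           low = r[1], high = r[2])
  }
  if (length(rows) == 0)
    return(data.frame(component = character(), type = character(),
                      low = numeric(), high = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Reported-range bracket for the published track
#'
#' Sums the `reported_range` annotations of every factor and medication
#' group: the joint lower corner is the sum of the per-row lows, the upper
#' corner the sum of the per-row highs.
#'
#' @param scn a `hip_scenario` whose factors and medications all carry
#'   `reported_range` annotations.
#' @return list with `min_explained`, `max_explained`, `min_percent`,
#'   `max_percent`.
#' @export
reported_extremes <- function(scn) {
  stopifnot(inherits(scn, "hip_scenario"))
  specs <- c(scn$factors, scn$medications)
  if (length(specs) == 0) fail("reported_extremes: scenario has no components")
  rngs <- lapply(specs, function(s) {
    if (is.null(s$reported_range))
      fail("reported_extremes: '%s' carries no reported_range annotation", s$name)
    s$reported_range
  })
  lo <- sum(vapply(rngs, `[[`, numeric(1), "low"))
  hi <- sum(vapply(rngs, `[[`, numeric(1), "high"))
  excess <- baseline_expectation(scn)$totals$excess
  list(min_explained = lo, max_explained = hi,
       min_percent = 100 * lo / excess, max_percent = 100 * hi / excess)
}

#' @export
print.hip_sensitivity <- function(x, ...) {
  cat(sprintf("<hip_sensitivity> mode = %s over %d parameters\n",
              x$mode, x$n_params))
  cat(sprintf("  explained in [%.1f, %.1f] (best %.1f); percent in [%.1f, %.1f]\n",
              x$min_explained, x$max_explained, x$best,
              x$min_percent, x$max_percent))
  invisible(x)
}
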