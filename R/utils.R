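#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (`round_half_away(0.5) == 1`,
#' `round_half_away(-0.5) == -1`), unlike base [round()]'s round-half-to-even.
#' Used for all display rounding: expected counts to integers, rates to 2
#' decimals, percentages to 1 decimal.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 0).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(7391.15)       # 7391
#' round_half_away(10.1240, 2)    # 10.12
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Convert between event counts and rates per 10,000 persons
#'
#' All rates in this package are carried per 10,000 person-denominator.
#'
#' @param rate rate per 10,000.
#' @param population persons.
#' @return `rate_to_count()`: expected events; `count_to_rate()` is
#'   [incidence_rate()].
#' @export
rate_to_count <- function(rate, population) rate * population / 1e4

# internal: consistent error signalling that names the offending field
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && all(is.finite(x))

# coerce a YAML per-sex mapping (or scalar) to a named numeric vector over
# the given sex labels; scalars are expanded and flagged as shared
per_sex_vector <- function(x, sexes, field, context) {
  if (is.null(x)) fail("%s: missing required field '%s'", context, field)
  if (length(x) == 1 && is.numeric(x) && is.null(names(x)) && !is.list(x)) {
    out <- stats::setNames(rep(as.numeric(x), length(sexes)), sexes)
    attr(out, "shared") <- TRUE
    return(out)
  }
  x <- unlist(x)
  if (!all(sexes %in% names(x)))
    fail("%s: field '%s' must give a value for each stratum (%s)",
         context, field, paste(sexes, collapse = ", "))
  extra <- setdiff(names(x), sexes)
  if (length(extra) > 0)
    fail("%s: field '%s' names unknown stratum '%s'", context, field, extra[1])
  out <- as.numeric(x[sexes])
  names(out) <- sexes
  attr(out, "shared") <- FALSE
  out
}

check_known_keys <- function(x, allowed, context) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0)
    fail("%s: unknown key '%s' (allowed: %s)", context, unknown[1],
         paste(allowed, collapse = ", "))
  invisible(TRUE)
}
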