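#' Waste composition for one period
#'
#' Bundles, for a time interval `[start, end)`, the categorical mass shares of
#' the incinerated waste and the chlorine mass fraction of each category.
#' Shares must sum to 1; the chlorine estimate is their weighted average.
#'
#' @param start,end Period bounds (calendar years), `start < end`; the period
#'   covers `start` up to but excluding `end`.
#' @param shares Named numeric vector: mass fraction of each waste category.
#' @param category_cl Named numeric vector: chlorine mass fraction of each
#'   category (same names as `shares`).
#' @param tol Tolerance on `sum(shares) == 1`.
#' @return An object of class `waste_composition_period`.
#' @export
waste_composition_period <- function(start, end, shares, category_cl,
                                     tol = 1e-9) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, start < end)
  if (is.null(names(shares)) || is.null(names(category_cl)))
    stop("shares and category_cl must be named by waste category")
  if (!setequal(names(shares), names(category_cl)))
    stop("shares and category_cl must cover the same categories")
  category_cl <- category_cl[names(shares)]
  if (any(shares < 0) || any(shares > 1))
    stop("category shares must lie in [0, 1]")
  if (any(category_cl < 0) || any(category_cl > 1))
    stop("category chlorine fractions must lie in [0, 1]")
  if (abs(sum(shares) - 1) > tol)
    stop("category shares sum to ", format(sum(shares)),
         ", not 1 (tolerance ", format(tol), ")")
  structure(
    list(start = start, end = end, shares = shares, category_cl = category_cl),
    class = "waste_composition_period"
  )
}

#' @export
print.waste_composition_period <- function(x, ...) {
  cat("Waste composition, period [", x$start, ", ", x$end, ")\n", sep = "")
  print(data.frame(share = x$shares, cl_fraction = x$category_cl))
  cat("Estimated chlorine content:",
      format(100 * estimate_chlorine(x), digits = 3), "wt%\n")
  invisible(x)
}

#' Estimate waste chlorine content from categorical composition
#'
#' The average chlorine content of the input waste is the share-weighted
#' average of the per-category chlorine contents:
#' `Cl = sum_j Cl_j * n_j`.
#'
#' @param comp A [waste_composition_period()].
#' @return Chlorine weight fraction (dimensionless), bounded by the minimum
#'   and maximum category values.
#' @examples
#' comp <- waste_composition_period(
#'   1995, 2005,
#'   shares = c(plastics = 0.1, organics = 0.9),
#'   category_cl = c(plastics = 0.05, organics = 0.002)
#' )
#' estimate_chlorine(comp)
#' @export
estimate_chlorine <- function(comp) {
  stopifnot(inherits(comp, "waste_composition_period"))
  sum(comp$shares * comp$category_cl)
}

#' Classify waste chlorine content against the critical profile threshold
#'
#' Stack congener profiles fall into two regimes separated by a critical
#' waste-chlorine band of 0.8--1.1 wt%. Band endpoints are inclusive.
#'
#' @param cl Chlorine weight fraction in `[0, 1)`.
#' @param band Threshold band as a fraction, default `c(0.008, 0.011)`.
#' @return `"below_threshold"`, `"in_band"` or `"above_threshold"`.
#' @examples
#' classify_chlorine_regime(0.007) # below_threshold
#' @export
classify_chlorine_regime <- function(cl, band = c(0.008, 0.011)) {
  stopifnot(length(cl) == 1L, is.finite(cl), cl >= 0, cl < 1,
            length(band) == 2L, band[1] <= band[2])
  if (cl < band[1]) "below_threshold"
  else if (cl <= band[2]) "in_band"
  else "above_threshold"
}

#' Build an annual waste timeline from period-level values
#'
#' Archive sources give waste mass, chlorine and metal content as period
#' averages; the emission model runs on calendar years. `mode = "step"` holds
#' each period's value constant over its years; `mode = "linear"`
#' interpolates between period midpoints (constant extrapolation beyond the
#' first/last midpoint).
#'
#' @param periods Data frame with columns `start`, `end` (years, `[start,
#'   end)`) and one or more value columns (e.g. `m_waste`, `f_cl`,
#'   `f_metal`).
#' @param horizon Integer vector of years to cover (need not be the full
#'   period union, but must be covered by it).
#' @param mode `"step"` or `"linear"`.
#' @return An object of class `waste_timeline`: a data frame with column
#'   `year` plus the value columns, one row per year of `horizon`.
#' @examples
#' p <- data.frame(start = c(1958, 1965), end = c(1965, 1975),
#'                 f_cl = c(0.003, 0.004))
#' build_timeline(p, 1958:1974)
#' @export
build_timeline <- function(periods, horizon, mode = c("step", "linear")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(periods), all(c("start", "end") %in% names(periods)))
  value_cols <- setdiff(names(periods), c("start", "end"))
  if (!length(value_cols)) stop("periods has no value columns")
  horizon <- sort(as.integer(horizon))
  periods <- periods[order(periods$start), , drop = FALSE]
  if (any(periods$end[-nrow(periods)] > periods$start[-1]))
    stop("periods overlap")
  covered <- unlist(Map(seq, periods$start, periods$end - 1L))
  uncovered <- setdiff(horizon, covered)
  if (length(uncovered))
    stop("years not covered by any period: ",
         paste(range(uncovered), collapse = "-"))
  out <- data.frame(year = horizon)
  for (col in value_cols) {
    v <- periods[[col]]
    if (mode == "step") {
      idx <- findInterval(horizon, periods$start)
      out[[col]] <- v[idx]
    } else {
      mid <- (periods$start + periods$end) / 2
      out[[col]] <- stats::approx(mid, v, xout = horizon, rule = 2)$y
    }
  }
  validate_waste_timeline(out)
}

validate_waste_timeline <- function(df) {
  stopifnot(is.data.frame(df), "year" %in% names(df))
  if (nrow(df) > 1L && any(diff(df$year) != 1L))
    stop("timeline years must be contiguous")
  vals <- df[setdiff(names(df), "year")]
  if (any(unlist(vals) < 0, na.rm = TRUE))
    stop("timeline values must be nonnegative")
  for (col in intersect(c("f_cl", "f_metal"), names(df)))
    if (any(df[[col]] >= 1)) stop(col, " must be below 1 (a weight fraction)")
  class(df) <- c("waste_timeline", "data.frame")
  df
}

#' Assemble a waste timeline from annual columns
#'
#' Direct constructor when annual data are already at year granularity.
#'
#' @param year Integer years (contiguous).
#' @param m_waste Waste mass flow (t/yr).
#' @param f_cl Chlorine weight fraction.
#' @param f_metal Metal weight fraction.
#' @return A `waste_timeline` data frame.
#' @export
waste_timeline <- function(year, m_waste, f_cl, f_metal) {
  validate_waste_timeline(data.frame(
    year = as.integer(year), m_waste = m_waste, f_cl = f_cl, f_metal = f_metal
  ))
}
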