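#' Bundled ESP worked example: pre-ESP profile and ESP efficiencies
#'
#' The package ships the tabulated phase-resolved congener profile measured
#' before an electrostatic precipitator and the matching per-congener,
#' per-phase concentration-based removal efficiencies (percent), as
#' estimated for an ESP operating in the de novo synthesis temperature
#' window. This is the package's canonical worked example: propagating the
#' profile through the stage reproduces the published post-ESP profile.
#'
#' @return List with `profile` (a [phase_profile()], label "before ESP")
#'   and `stage` (an [apcd_stage()] named `"ESP"`).
#' @examples
#' fx <- esp_example()
#' after <- propagate_profile(fx$profile, fx$stage)
#' profile_marginals(after)$phase
#' @export
esp_example <- function() {
  pp <- system.file("extdata", "vallon_esp_profile.csv",
                    package = "dioxinrecon", mustWork = TRUE)
  ps <- system.file("extdata", "vallon_esp_eta.csv",
                    package = "dioxinrecon", mustWork = TRUE)
  list(profile = read_profile_csv(pp, label = "before ESP"),
       stage = read_stage_csv(ps, name = "ESP",
                              temperature = c(290, 275)))
}

#' Bundled waste-chlorine period estimates
#'
#' Five archive-derived periods of average waste chlorine content
#' (weight fraction) for a 1958--2005 plant history, rising from 0.3 to
#' 0.7 wt% with the growing plastics share of household waste.
#'
#' @return Data frame with columns `start`, `end`, `f_cl`.
#' @export
chlorine_periods <- function() {
  utils::read.csv(system.file("extdata", "vallon_chlorine_periods.csv",
                              package = "dioxinrecon", mustWork = TRUE))
}

#' Default kinetic constants (synthetic placeholder calibration)
#'
#' Loads `kinetic_constants_synthetic.csv`: formation constants `k1` for
#' the three congeners with literature calibrations and the shared
#' decomposition constant `k2`. The bundled numbers are order-of-magnitude
#' synthetic placeholders (chosen so a 1e5 t/yr plant yields furnace
#' production of order tens of g/yr); replace the file with a fitted
#' calibration for quantitative work.
#'
#' @param congener Optional congener name to select a single entry.
#' @param path Optional alternative CSV (columns `congener,k1,k2`).
#' @return If `congener` given, a [kinetic_parameters()]; otherwise the full
#'   data frame.
#' @export
read_kinetic_constants_csv <- function(congener = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinetic_constants_synthetic.csv",
                        package = "dioxinrecon", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("congener", "k1", "k2") %in% names(tab)))
  if (is.null(congener)) return(tab)
  row <- tab[tab$congener == congener, , drop = FALSE]
  if (!nrow(row)) stop("no kinetic constants for '", congener, "' in ", path)
  kinetic_parameters(row$congener[1], row$k1[1], row$k2[1])
}

#' Default congener soil half-lives (synthetic literature-range defaults)
#'
#' Loads `half_lives_synthetic.csv`: soil half-lives in years, increasing
#' with chlorination level as reported for field soils. The bundled values
#' are generic literature-range defaults labelled synthetic; site-specific
#' work should supply measured values via `path`.
#'
#' @param path Optional alternative CSV (columns
#'   `congener,half_life_years`).
#' @return Named 17-vector of half-lives (years), canonical order.
#' @export
read_half_lives_csv <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "half_lives_synthetic.csv",
                        package = "dioxinrecon", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("congener", "half_life_years") %in% names(tab)))
  check_congener_vector(stats::setNames(tab$half_life_years, tab$congener),
                        "half-life table")
}

#' Default Clausius-Clapeyron vapor-pressure slopes
#'
#' Per-congener slopes `b_i` (K) of `log10 p = a - b/T`, for the
#' temperature repartitioning operator. Derived from typical PCDD/F
#' vaporization enthalpies (about 90--110 kJ/mol, increasing with
#' chlorination): `b = dHvap / (R ln 10)`.
#'
#' @return Named 17-vector of slopes (K).
#' @export
default_vp_slopes <- function() {
  reg <- congener_registry()
  dhvap <- 90e3 + 5e3 * (reg$chlorination - 4)  # J/mol
  stats::setNames(dhvap / (8.314 * log(10)), reg$name)
}

#' Synthetic plant-like annual waste timeline
#'
#' Deterministic-plus-noise synthetic timeline emulating a mid-century
#' urban incinerator: waste throughput rising steeply to about 1970,
#' declining to 1990, rising again to closure; chlorine content stepping up
#' with the plastics share (the bundled period table); metal content
#' declining to 1990 then recovering. Clearly synthetic -- shape only, for
#' demos and tests.
#'
#' @param seed Integer seed for the multiplicative noise.
#' @param years Year range, default 1958:2005.
#' @param noise_sd Lognormal sd of year-to-year throughput noise
#'   (default 0.03; 0 gives the smooth shape).
#' @return A [waste_timeline()].
#' @export
synthetic_waste_timeline <- function(seed = 1L, years = 1958:2005,
                                     noise_sd = 0.03) {
  set.seed(as.integer(seed))
  knots_y <- c(1958, 1964, 1970, 1980, 1990, 1998, 2005)
  knots_m <- c(30e3, 75e3, 110e3, 95e3, 70e3, 85e3, 100e3)
  m <- stats::spline(knots_y, knots_m, xout = years)$y
  m <- pmax(m, 0) * exp(stats::rnorm(length(years), 0, noise_sd))
  cl <- build_timeline(chlorine_periods(), years, mode = "step")$f_cl
  fm <- stats::approx(c(1958, 1975, 1990, 2005),
                      c(0.040, 0.033, 0.025, 0.030), xout = years)$y
  waste_timeline(years, m, cl, fm)
}
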