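#' APCD scenario for a period of plant operation
#'
#' One configuration of the flue-gas train over `[start, end)`: which stages
#' operate and the scalar aggregate removal efficiency of each. The emission
#' quantity track uses these scalars (profile shape uses the full
#' per-congener propagation of [propagate_profile()]).
#'
#' @param start,end Period bounds (years, `[start, end)`).
#' @param overall_eta Named numeric vector of per-stage aggregate
#'   efficiencies (fractions, each at most 1; negative allowed), e.g.
#'   `c(ESP = -1.61, WS = 0.40)`.
#' @return Object of class `apcd_scenario`.
#' @export
apcd_scenario <- function(start, end, overall_eta) {
  stopifnot(start < end, is.numeric(overall_eta))
  if (any(overall_eta > 1)) stop("aggregate efficiencies cannot exceed 1")
  if (is.null(names(overall_eta))) stop("overall_eta must be named by stage")
  structure(list(start = start, end = end, overall_eta = overall_eta),
            class = "apcd_scenario")
}

#' Default APCD scenarios for an ESP-then-wet-scrubber plant history
#'
#' Electrostatic precipitator alone for the first period, ESP plus wet
#' scrubber afterwards. The ESP's aggregate efficiency defaults to the
#' propagation-derived -161% (net formation in the de novo temperature
#' window); the wet scrubber bound is a scenario convention, not a validated
#' estimate, and is exposed as an argument.
#'
#' @param esp_period,ws_period Year ranges `c(start, end)`.
#' @param eta_esp Aggregate ESP efficiency (fraction).
#' @param eta_ws Aggregate wet-scrubber efficiency (fraction), e.g. 0 or
#'   0.40.
#' @return List of two [apcd_scenario()] objects.
#' @export
default_scenarios <- function(esp_period = c(1958, 1982),
                              ws_period = c(1982, 2006),
                              eta_esp = -1.61, eta_ws = 0) {
  list(
    apcd_scenario(esp_period[1], esp_period[2], c(ESP = eta_esp)),
    apcd_scenario(ws_period[1], ws_period[2], c(ESP = eta_esp, WS = eta_ws))
  )
}

new_emission_series <- function(df, congener_g = NULL) {
  stopifnot(all(c("year", "furnace_g") %in% names(df)))
  if (any(df$furnace_g < 0, na.rm = TRUE)) stop("emissions must be nonnegative")
  class(df) <- c("emission_series", "data.frame")
  attr(df, "congener_g") <- congener_g
  df
}

#' @export
print.emission_series <- function(x, ...) {
  cat("Annual PCDD/F emission series, ", min(x$year), "-", max(x$year),
      "\n", sep = "")
  cat(sprintf("  furnace production: total %.1f g over %d years\n",
              sum(x$furnace_g), nrow(x)))
  if ("stack_g" %in% names(x))
    cat(sprintf("  stack emission:     total %.1f g\n", sum(x$stack_g)))
  if (!is.null(attr(x, "congener_g")))
    cat("  per-congener split attached (17 congeners)\n")
  invisible(x)
}

#' Annual furnace-side PCDD/F production
#'
#' For each year of the waste timeline, evaluates the kinetic model for the
#' reference congener under that year's waste composition, scales up to
#' total PCDD/Fs by the reference congener's pre-treatment profile share,
#' and multiplies by the year's waste throughput.
#'
#' @param timeline A [waste_timeline()] (columns `year`, `m_waste` t/yr,
#'   `f_cl`, `f_metal`).
#' @param params [kinetic_parameters()] of the reference congener (`k1` in
#'   ng per kg waste per unit `E_Cl * E_metal` per second).
#' @param ref_share Reference congener's share of total PCDD/Fs in the
#'   pre-treatment profile, `(0, 1]`.
#' @param furnace List with `residence_time` (s), `oxygen` (ratio) and
#'   `temperature` (degC); constant across years.
#' @param config [influence_config()] mapping `(f_cl, f_metal, oxygen,
#'   temperature)` to the kinetic factors; default identity.
#' @return An `emission_series` data frame with columns `year`, `furnace_g`
#'   (g/yr).
#' @export
annual_furnace_production <- function(timeline, params, ref_share,
                                      furnace = list(residence_time = 2,
                                                     oxygen = 1.2,
                                                     temperature = 950),
                                      config = influence_config("identity")) {
  stopifnot(inherits(timeline, "waste_timeline"),
            all(c("m_waste", "f_cl", "f_metal") %in% names(timeline)))
  if (anyNA(timeline[c("m_waste", "f_cl", "f_metal")]))
    stop("timeline has missing year data")
  furnace_g <- vapply(seq_len(nrow(timeline)), function(i) {
    fac <- influence_factors(config, timeline$f_cl[i], timeline$f_metal[i],
                             furnace$oxygen, furnace$temperature)
    cond <- furnace_conditions(furnace$temperature, furnace$residence_time,
                               fac$lambda_oxygen, fac$e_cl, fac$e_metal)
    gen_ng_kg <- total_from_reference(congener_generation(params, cond),
                                      ref_share)
    # t/yr * 1e3 kg/t * ng/kg * 1e-9 g/ng
    timeline$m_waste[i] * gen_ng_kg * 1e-6
  }, numeric(1))
  new_emission_series(data.frame(year = timeline$year, furnace_g = furnace_g))
}

#' Apply APCD scenarios to a furnace production series
#'
#' Stack emission in a year is furnace production times the product of the
#' per-stage survival factors `(1 - eta)` of the scenario covering that
#' year. Negative efficiencies inflate emissions (the device is a net
#' source).
#'
#' @param series `emission_series` with `furnace_g`.
#' @param scenarios List of [apcd_scenario()] covering every year.
#' @return The series with a `stack_g` column added.
#' @export
apply_apcd <- function(series, scenarios) {
  stopifnot(inherits(series, "emission_series"))
  if (inherits(scenarios, "apcd_scenario")) scenarios <- list(scenarios)
  factor_of <- function(year) {
    for (sc in scenarios)
      if (year >= sc$start && year < sc$end) return(prod(1 - sc$overall_eta))
    stop("no APCD scenario covers year ", year)
  }
  series$stack_g <- series$furnace_g *
    vapply(series$year, factor_of, numeric(1))
  new_emission_series(series, attr(series, "congener_g"))
}

#' Split annual totals into per-congener emissions
#'
#' Multiplies each year's stack (or furnace, if no stack column) total by
#' the stack congener profile of the period covering that year.
#'
#' @param series `emission_series`.
#' @param profiles List of entries `list(start =, end =, profile =)` where
#'   `profile` is a [congener_profile()]; periods must cover every year.
#' @return The series with attribute `congener_g`: a year-by-17 matrix of
#'   per-congener annual masses (g) whose rows sum to the split totals.
#' @export
congener_split <- function(series, profiles) {
  stopifnot(inherits(series, "emission_series"))
  total <- if ("stack_g" %in% names(series)) series$stack_g
           else series$furnace_g
  shares <- matrix(NA_real_, nrow(series), 17L,
                   dimnames = list(series$year, congener_names()))
  for (i in seq_len(nrow(series))) {
    hit <- NULL
    for (p in profiles)
      if (series$year[i] >= p$start && series$year[i] < p$end) { hit <- p; break }
    if (is.null(hit)) stop("no stack profile covers year ", series$year[i])
    shares[i, ] <- check_congener_vector(unclass(hit$profile), "stack profile")
  }
  new_emission_series(as.data.frame(series), congener_g = shares * total)
}
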