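#' Soil-fate parameters
#'
#' Emitted PCDD/Fs are assumed to deposit within the study area (the
#' deliberate overestimating default `deposition_fraction = 1`) and then
#' decay in soil by congener-specific first-order kinetics. A per-congener
#' multiplicative sorption/retention factor is available for
#' sorption-adjusted comparisons with soil surveys.
#'
#' @param half_life Named 17-vector of congener soil half-lives (years),
#'   strictly positive (`Inf` disables decay).
#' @param deposition_fraction Fraction of stack emissions settling in the
#'   study area, in `[0, 1]`.
#' @param sorption_factor Per-congener retention adjustment in `[0, 1]`
#'   (scalar recycled), default 1.
#' @param evaluation_year Year at which residuals are evaluated.
#' @return Object of class `soil_fate_params`.
#' @export
soil_fate_params <- function(half_life, deposition_fraction = 1,
                             sorption_factor = 1, evaluation_year) {
  half_life <- check_congener_vector(half_life, "half-life vector")
  if (any(half_life <= 0)) stop("half-lives must be strictly positive")
  stopifnot(deposition_fraction >= 0, deposition_fraction <= 1)
  if (length(sorption_factor) == 1L)
    sorption_factor <- stats::setNames(rep(sorption_factor, 17L),
                                       congener_names())
  sorption_factor <- check_congener_vector(sorption_factor, "sorption factors")
  if (any(sorption_factor < 0) || any(sorption_factor > 1))
    stop("sorption factors must lie in [0, 1]")
  stopifnot(is.numeric(evaluation_year), length(evaluation_year) == 1L)
  structure(list(half_life = half_life,
                 deposition_fraction = deposition_fraction,
                 sorption_factor = sorption_factor,
                 evaluation_year = evaluation_year),
            class = "soil_fate_params")
}

# emissions: year-by-17 matrix (g/yr), rownames = years
check_emission_matrix <- function(emissions) {
  if (inherits(emissions, "emission_series")) {
    emissions <- attr(emissions, "congener_g")
    if (is.null(emissions))
      stop("emission series has no per-congener split; run congener_split()")
  }
  m <- as.matrix(emissions)
  if (is.null(rownames(m))) stop("emission matrix must have years as rownames")
  colnames(m) <- names(check_congener_vector(
    stats::setNames(seq_len(ncol(m)), colnames(m)), "emission matrix"))
  m <- m[, congener_names(), drop = FALSE]
  if (any(m < 0)) stop("emissions must be nonnegative")
  m
}

#' Residual soil amount of each congener at the evaluation year
#'
#' Each year's deposited mass decays exponentially with the congener's soil
#' half-life: `residual_i = sum_y E_i(y) * dep * sorp_i *
#' 2^(-(Y - y) / t_half_i)`.
#'
#' @param emissions Year-by-congener matrix of annual emitted masses (g),
#'   with years as rownames, or an `emission_series` carrying a
#'   [congener_split()].
#' @param params [soil_fate_params()].
#' @return Object of class `soil_residual`: named 17-vector of residual
#'   masses (g) with attribute `fraction` (the residual congener profile,
#'   summing to 1 when the total is positive).
#' @export
residual_amount <- function(emissions, params) {
  stopifnot(inherits(params, "soil_fate_params"))
  m <- check_emission_matrix(emissions)
  years <- as.numeric(rownames(m))
  if (any(years > params$evaluation_year))
    stop("emissions after the evaluation year ", params$evaluation_year)
  elapsed <- params$evaluation_year - years
  decay <- 2^(-outer(elapsed, 1 / params$half_life))   # years x congeners
  res <- colSums(m * decay) * params$deposition_fraction *
    params$sorption_factor
  tot <- sum(res)
  structure(res, class = "soil_residual",
            fraction = if (tot > 0) res / tot else res)
}

#' @export
print.soil_residual <- function(x, ...) {
  cat("Residual PCDD/F soil amounts (g):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Uncertainty bands on the residual soil congener profile
#'
#' Congener soil half-lives are poorly transferable between sites; their
#' nominal values are perturbed independently per congener by multiplicative
#' factors drawn uniformly over `1 + variation` (default -50% to +100%),
#' and the residual profile fractions are recomputed for each draw.
#'
#' @param emissions As in [residual_amount()].
#' @param params [soil_fate_params()] holding the nominal half-lives.
#' @param variation Length-2 numeric: relative change bounds, default
#'   `c(-0.5, 1)`.
#' @param n_samples Number of Monte-Carlo draws (default 1e5; use 1e6 to
#'   match survey-grade band estimates).
#' @param seed Integer seed; same seed, same bands.
#' @param probs Quantile probabilities, default 2.5% and 97.5%.
#' @return Data frame with columns `congener`, `frac` (nominal fraction),
#'   `frac_lo`, `frac_hi`.
#' @export
residual_profile_uncertainty <- function(emissions, params,
                                         variation = c(-0.5, 1),
                                         n_samples = 1e5, seed = 1L,
                                         probs = c(0.025, 0.975)) {
  stopifnot(inherits(params, "soil_fate_params"),
            length(variation) == 2L, variation[1] <= variation[2],
            variation[1] > -1, n_samples >= 1)
  m <- check_emission_matrix(emissions)
  if (!nrow(m) || sum(m) == 0) stop("empty emission input")
  years <- as.numeric(rownames(m))
  elapsed <- params$evaluation_year - years
  if (any(elapsed < 0)) stop("emissions after the evaluation year")
  deposit <- t(m) * params$deposition_fraction * params$sorption_factor
  point <- attr(residual_amount(emissions, params), "fraction")

  set.seed(as.integer(seed))
  lo <- 1 + variation[1]
  hi <- 1 + variation[2]
  # mult[i, s]: half-life multiplier for congener i in draw s
  mult <- matrix(stats::runif(17L * n_samples, lo, hi), nrow = 17L)
  res <- matrix(0, 17L, n_samples)
  for (i in 1:17) {
    hl <- params$half_life[i] * mult[i, ]
    res[i, ] <- colSums(deposit[i, ] * 2^(-outer(elapsed, 1 / hl)))
  }
  frac <- sweep(res, 2L, colSums(res), "/")
  q <- apply(frac, 1L, stats::quantile, probs = probs, names = FALSE)
  data.frame(congener = congener_names(), frac = unname(point),
             frac_lo = q[1, ], frac_hi = q[2, ])
}

#' TEQ of a residual soil burden under one or more TEF schemes
#'
#' @param residual A `soil_residual` (or named 17-vector of masses, g).
#' @param tables A single TEF table or a (possibly named) list of them;
#'   defaults to both bundled schemes.
#' @return Named numeric vector: g TEQ per scheme.
#' @export
residual_teq <- function(residual,
                         tables = list(WHO2005 = tef_table("WHO2005"),
                                       WHO2022 = tef_table("WHO2022"))) {
  if (!is.list(tables)) tables <- list(tables)
  nm <- names(tables)
  if (is.null(nm))
    nm <- vapply(tables, function(t) attr(t, "scheme") %||% "TEQ",
                 character(1))
  out <- vapply(tables, function(t) teq(unclass(residual), t), numeric(1))
  stats::setNames(out, nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
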