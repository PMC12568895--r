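#' Phase-resolved PCDD/F congener profile
#'
#' A relative mass-fraction vector over the 34 congener-by-phase entries
#' (17 congeners x gaseous/particulate), normalized to 1. This is the object
#' that removal-efficiency propagation acts on.
#'
#' @param fractions A 17 x 2 numeric matrix (rows in canonical congener
#'   order, columns `gaseous`, `particulate`) or a data frame with columns
#'   `congener`, `phase`, `fraction`. Entries must be nonnegative and sum to
#'   1 within `tol` (pass `normalize = TRUE` to rescale exact-positive
#'   inputs, e.g. percent data).
#' @param label Optional stage label (e.g. `"before ESP"`).
#' @param normalize If `TRUE`, divide by the total instead of requiring it
#'   to be 1.
#' @param tol Normalization tolerance.
#' @return An object of class `phase_profile`: the 17 x 2 matrix with a
#'   `label` attribute.
#' @export
phase_profile <- function(fractions, label = NULL, normalize = FALSE,
                          tol = 1e-9) {
  if (is.data.frame(fractions)) {
    stopifnot(all(c("congener", "phase", "fraction") %in% names(fractions)))
    fractions <- long_to_matrix(fractions, "fraction")
  }
  m <- as.matrix(fractions)
  m <- check_phase_matrix(m, what = "phase profile")
  if (any(m < 0)) stop("profile fractions must be nonnegative")
  tot <- sum(m)
  if (normalize) {
    if (tot <= 0) stop("cannot normalize a profile with total <= 0")
    m <- m / tot
  } else if (abs(tot - 1) > tol) {
    stop("profile fractions sum to ", format(tot),
         ", not 1 (use normalize = TRUE for unnormalized input)")
  }
  structure(m, class = "phase_profile", label = label)
}

# Coerce long (congener, phase, value) to canonical 17 x 2 matrix.
long_to_matrix <- function(df, value_col) {
  cn <- congener_names()
  ph <- phase_names()
  m <- matrix(NA_real_, 17L, 2L, dimnames = list(cn, ph))
  df$phase <- match_phase(df$phase)
  for (k in seq_len(nrow(df)))
    m[df$congener[k], df$phase[k]] <- df[[value_col]][k]
  m
}

match_phase <- function(x) {
  out <- phase_names()[pmatch(tolower(x), phase_names(), duplicates.ok = TRUE)]
  # accept the G./P. shorthand used in tabulated profiles
  out[toupper(x) %in% c("G", "G.")] <- "gaseous"
  out[toupper(x) %in% c("P", "P.")] <- "particulate"
  if (anyNA(out)) stop("unknown phase label(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

check_phase_matrix <- function(m, what) {
  cn <- congener_names()
  ph <- phase_names()
  if (is.null(dimnames(m))) {
    if (!all(dim(m) == c(17L, 2L)))
      stop(what, " must be a 17 x 2 matrix in canonical order")
    dimnames(m) <- list(cn, ph)
    return(m)
  }
  rn <- check_congener_vector(stats::setNames(seq_len(nrow(m)), rownames(m)),
                              what = what)
  m <- m[rn, , drop = FALSE]          # rows now in canonical order
  rownames(m) <- cn
  colnames(m) <- match_phase(colnames(m))
  if (anyDuplicated(colnames(m)) || !setequal(colnames(m), ph))
    stop(what, " must have columns 'gaseous' and 'particulate'")
  m[, ph, drop = FALSE]
}

#' @export
print.phase_profile <- function(x, digits = 4, ...) {
  lab <- attr(x, "label")
  cat("Phase-resolved PCDD/F profile",
      if (!is.null(lab)) paste0(" (", lab, ")"), "\n", sep = "")
  m <- unclass(x)
  attr(m, "label") <- NULL
  print(round(100 * cbind(m, total = rowSums(m)), digits - 2))
  ph <- colSums(m)
  cat(sprintf("Phase totals: gaseous %.1f%%, particulate %.1f%%\n",
              100 * ph[1], 100 * ph[2]))
  invisible(x)
}

#' Collapsed (phase-summed) congener profile
#'
#' @param fractions Named numeric 17-vector of relative mass fractions.
#' @param normalize,tol As in [phase_profile()].
#' @return Named numeric vector of class `congener_profile` summing to 1.
#' @export
congener_profile <- function(fractions, normalize = FALSE, tol = 1e-9) {
  x <- check_congener_vector(fractions, what = "congener profile")
  if (any(x < 0)) stop("profile fractions must be nonnegative")
  tot <- sum(x)
  if (normalize) {
    if (tot <= 0) stop("cannot normalize a profile with total <= 0")
    x <- x / tot
  } else if (abs(tot - 1) > tol) {
    stop("congener profile sums to ", format(tot), ", not 1")
  }
  structure(x, class = "congener_profile")
}

#' @export
print.congener_profile <- function(x, ...) {
  cat("PCDD/F congener profile (% of total):\n")
  print(round(100 * unclass(x), 2))
  invisible(x)
}

#' Air pollution control device (APCD) stage
#'
#' Per-congener, per-phase concentration-based removal efficiencies for one
#' device (or device chain). Efficiencies are dimensionless fractions, at
#' most 1 (complete removal); negative values denote net formation inside
#' the device, as happens in electrostatic precipitators operating in the
#' 200--400 degC de novo synthesis window.
#'
#' @param name Device name, e.g. `"ESP"` or `"WS"`.
#' @param eta 17 x 2 matrix (or long data frame with columns `congener`,
#'   `phase`, `eta`) of removal efficiencies.
#' @param temperature Optional inlet/outlet temperature window, degC,
#'   length-2 numeric `c(inlet, outlet)`.
#' @param fill_missing If `TRUE`, absent entries default to 0 (no effect);
#'   otherwise all 34 entries must be present.
#' @return An object of class `apcd_stage`.
#' @export
apcd_stage <- function(name, eta, temperature = c(NA_real_, NA_real_),
                       fill_missing = FALSE) {
  if (is.data.frame(eta)) {
    stopifnot(all(c("congener", "phase", "eta") %in% names(eta)))
    eta <- long_to_matrix(eta, "eta")
  }
  m <- check_phase_matrix(as.matrix(eta), what = "efficiency matrix")
  if (anyNA(m)) {
    if (!fill_missing)
      stop("efficiency matrix has missing entries; set fill_missing = TRUE ",
           "to default them to 0")
    m[is.na(m)] <- 0
  }
  if (any(m > 1)) stop("removal efficiencies cannot exceed 1")
  stopifnot(length(temperature) == 2L)
  structure(list(name = name, eta = m, temperature = as.numeric(temperature)),
            class = "apcd_stage")
}

#' @export
print.apcd_stage <- function(x, ...) {
  cat("APCD stage '", x$name, "'", sep = "")
  if (!anyNA(x$temperature))
    cat(sprintf(" (%.0f -> %.0f degC)", x$temperature[1], x$temperature[2]))
  cat("\nRemoval efficiencies (% of concentration):\n")
  print(round(100 * x$eta, 1))
  invisible(x)
}

#' Concentration-based removal efficiency of a device
#'
#' `eta = 1 - c_out / c_in`. Negative values mean the device is a net source
#' (outlet concentration above inlet).
#'
#' @param c_in Inlet mass concentration(s), strictly positive.
#' @param c_out Outlet mass concentration(s), nonnegative.
#' @return Removal efficiency (fraction, vectorized), in `(-Inf, 1]`.
#' @examples
#' removal_efficiency(100, 25)  # 0.75
#' removal_efficiency(100, 261) # -1.61: net formation
#' @export
removal_efficiency <- function(c_in, c_out) {
  if (any(c_in <= 0))
    stop("inlet concentration must be strictly positive (efficiency undefined)")
  if (any(c_out < 0)) stop("outlet concentration must be nonnegative")
  1 - c_out / c_in
}

stage_eta <- function(stage) {
  if (inherits(stage, "apcd_stage")) stage$eta else stage
}

#' Propagate a profile through an APCD stage
#'
#' Applies the per-entry survival factors `(1 - eta)` and renormalizes:
#' `R_out = R_in (1 - eta) / sum_k (1 - eta_k) R_in_k`, the sum running over
#' all 34 congener-by-phase entries for a phase-resolved profile (17 for a
#' collapsed one). The normalizing denominator is the stage's total
#' concentration pass-through ratio `C_out_total / C_in_total` and is
#' attached as attribute `pass_through`; it equals `1 - eta_aggregate`.
#'
#' @param profile A [phase_profile()] (or [congener_profile()] with a
#'   17-vector `stage`).
#' @param stage An [apcd_stage()]; for collapsed profiles, a named 17-vector
#'   of efficiencies.
#' @return Profile of the same class, normalized to 1, with attribute
#'   `pass_through`.
#' @export
propagate_profile <- function(profile, stage) {
  eta <- stage_eta(stage)
  if (inherits(profile, "congener_profile")) {
    eta <- check_congener_vector(eta, what = "efficiency vector")
    if (any(eta > 1)) stop("removal efficiencies cannot exceed 1")
    surv <- (1 - eta) * unclass(profile)
    d <- sum(surv)
    if (d <= 0) stop("total pass-through is nonpositive; cannot renormalize")
    out <- congener_profile(surv / d)
  } else {
    stopifnot(inherits(profile, "phase_profile"))
    surv <- (1 - eta) * unclass(profile)
    d <- sum(surv)
    if (d <= 0) stop("total pass-through is nonpositive; cannot renormalize")
    lab <- attr(profile, "label")
    nm <- if (inherits(stage, "apcd_stage")) stage$name else "stage"
    out <- phase_profile(surv / d,
                         label = paste(c(lab, paste("after", nm)),
                                       collapse = ", "))
  }
  attr(out, "pass_through") <- d
  out
}

#' Aggregate removal efficiency over a subset of profile entries
#'
#' The inlet-weighted efficiency `1 - sum_S R (1 - eta) / sum_S R`, i.e. the
#' concentration-based efficiency the device shows on the summed subset
#' (all entries, one phase, or one family).
#'
#' @param profile Inlet [phase_profile()].
#' @param stage An [apcd_stage()].
#' @param subset `"all"`, `"gaseous"`, `"particulate"`, `"PCDD"` or
#'   `"PCDF"`.
#' @return Aggregate efficiency (fraction).
#' @export
aggregate_efficiency <- function(profile, stage,
                                 subset = c("all", "gaseous", "particulate",
                                            "PCDD", "PCDF")) {
  subset <- match.arg(subset)
  stopifnot(inherits(profile, "phase_profile"))
  R <- unclass(profile)
  eta <- stage_eta(stage)
  sel <- matrix(TRUE, 17L, 2L)
  if (subset %in% phase_names()) sel[, colnames(R) != subset] <- FALSE
  if (subset %in% c("PCDD", "PCDF"))
    sel[congener_registry()$family != subset, ] <- FALSE
  w <- sum(R[sel])
  if (w <= 0) stop("subset '", subset, "' carries no inlet mass")
  1 - sum((R * (1 - eta))[sel]) / w
}

#' Congener and phase marginals of a phase-resolved profile
#'
#' @param profile A [phase_profile()].
#' @return List with `congener` (a [congener_profile()]: gas + particulate
#'   per congener) and `phase` (named length-2 vector of phase totals);
#'   both sum to 1.
#' @export
profile_marginals <- function(profile) {
  stopifnot(inherits(profile, "phase_profile"))
  m <- unclass(profile)
  list(congener = congener_profile(rowSums(m), normalize = TRUE),
       phase = colSums(m))
}

#' Repartition a profile between phases for a different temperature
#'
#' Gas/particle partitioning of semivolatile PCDD/Fs follows congener vapor
#' pressure, which rises with temperature. This operator moves mass between
#' the two phases of each congener -- preserving every congener's total --
#' assuming the gas/particle ratio is proportional to (subcooled-liquid)
#' vapor pressure with a log-linear Clausius-Clapeyron model per congener:
#' `log10 p_i(T) = a_i - b_i / T[K]`. Only the slopes `b_i` matter for the
#' ratio between two temperatures. It is the package's stand-in for
#' reference-plant temperature corrections; the model is deliberately
#' pluggable via `vp_params`.
#'
#' @param profile A [phase_profile()].
#' @param t_ref Temperature the profile was observed at (degC).
#' @param t_target Temperature to repartition to (degC).
#' @param vp_params Named numeric 17-vector of positive Clausius-Clapeyron
#'   slopes `b_i` (K), or a data frame with columns `congener`, `b`.
#' @return A [phase_profile()] with identical per-congener totals; for
#'   `t_target > t_ref` every congener's gaseous share weakly increases.
#' @export
repartition_by_temperature <- function(profile, t_ref, t_target, vp_params) {
  stopifnot(inherits(profile, "phase_profile"))
  if (t_ref < -273.15 || t_target < -273.15)
    stop("temperatures below absolute zero are not physical")
  if (is.data.frame(vp_params)) {
    stopifnot(all(c("congener", "b") %in% names(vp_params)))
    vp_params <- stats::setNames(vp_params$b, vp_params$congener)
  }
  b <- check_congener_vector(vp_params, what = "vapor-pressure slopes")
  if (any(b <= 0)) stop("Clausius-Clapeyron slopes must be positive")
  tK_ref <- t_ref + 273.15
  tK_tgt <- t_target + 273.15
  # odds(gas : particle) scale with the vapor-pressure ratio
  ratio <- 10^(b * (1 / tK_ref - 1 / tK_tgt))
  m <- unclass(profile)
  tot <- rowSums(m)
  g <- ifelse(tot > 0, m[, "gaseous"] / tot, 0)
  odds <- ifelse(g < 1, g / (1 - g), Inf)
  g_new <- ifelse(is.infinite(odds), 1, odds * ratio / (1 + odds * ratio))
  out <- cbind(gaseous = tot * g_new, particulate = tot * (1 - g_new))
  phase_profile(out, label = attr(profile, "label"))
}

#' Propagate a profile through an ordered chain of APCD stages
#'
#' @param profile0 Initial (post-combustion, pre-treatment)
#'   [phase_profile()].
#' @param stages List of [apcd_stage()] objects, ordered furnace to stack.
#' @return List of profiles of length `length(stages) + 1`; element 1 is the
#'   input, element `k + 1` the profile after stage `k`. The attribute
#'   `cumulative_pass_through` holds the running product of per-stage
#'   pass-through ratios (length `length(stages)`).
#' @export
chain_stages <- function(profile0, stages) {
  stopifnot(inherits(profile0, "phase_profile"))
  out <- vector("list", length(stages) + 1L)
  out[[1L]] <- profile0
  pass <- numeric(length(stages))
  p <- profile0
  for (k in seq_along(stages)) {
    p <- propagate_profile(p, stages[[k]])
    pass[k] <- attr(p, "pass_through")
    out[[k + 1L]] <- p
  }
  attr(out, "cumulative_pass_through") <- cumprod(pass)
  out
}

#' Pearson correlation between two congener profiles
#'
#' Comparison helper for validating modeled congener fractions against
#' measured ones (e.g. predicted fly-ash fractions vs. fractions measured in
#' ESP washwater).
#'
#' @param x,y Named 17-vectors of congener fractions (any common scale).
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(x, y) {
  x <- check_congener_vector(x, "profile x")
  y <- check_congener_vector(y, "profile y")
  stats::cor(x, y)
}
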