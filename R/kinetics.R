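#' Kinetic parameters for furnace-side PCDD/F generation
#'
#' Two-step first-order kinetics: carbonaceous waste forms each congener
#' with rate constant `k1` (per congener), and formed PCDD/Fs decompose with
#' a shared rate constant `k2`. Calibrated constants exist in the literature
#' for three congeners (2,3,7,8-TeCDF, OCDF, 1,2,3,6,7,8-HxCDD); they are
#' consumed from an editable CSV, never hard-coded
#' (see [read_kinetic_constants_csv()]).
#'
#' @param congener Congener name (canonical string).
#' @param k1 Formation rate constant, 1/s, nonnegative. Carries the yield
#'   scale: units of generated congener mass (ng per kg waste) per unit
#'   `E_Cl * E_metal` per second.
#' @param k2 Decomposition rate constant, 1/s, strictly positive.
#' @return Object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(congener, k1, k2) {
  if (!congener %in% congener_names())
    stop("unknown congener: ", congener)
  stopifnot(is.finite(k1), k1 >= 0, is.finite(k2), k2 > 0)
  structure(list(congener = congener, k1 = k1, k2 = k2),
            class = "kinetic_parameters")
}

#' Furnace operating conditions
#'
#' @param temperature Furnace temperature, degC.
#' @param residence_time Flue-gas residence time in the furnace, s,
#'   nonnegative.
#' @param oxygen_ratio Oxygen (excess-air) ratio lambda, dimensionless,
#'   positive.
#' @param e_cl Chlorine influence factor (weight-fraction term),
#'   nonnegative.
#' @param e_metal Metal influence factor (weight-fraction term),
#'   nonnegative.
#' @return Object of class `furnace_conditions`.
#' @export
furnace_conditions <- function(temperature, residence_time, oxygen_ratio,
                               e_cl, e_metal) {
  stopifnot(residence_time >= 0, oxygen_ratio > 0, e_cl >= 0, e_metal >= 0)
  structure(list(temperature = temperature, residence_time = residence_time,
                 oxygen_ratio = oxygen_ratio, e_cl = e_cl, e_metal = e_metal),
            class = "furnace_conditions")
}

#' Congener generation in the furnace
#'
#' Closed-form solution of the formation/decomposition balance:
#' `P_i = (k1_i * E_Cl * E_metal / k2) * (1 - exp(-k2 * lambda * t))`.
#' The result rises from 0 at `t = 0`, is increasing and concave in `t`, and
#' saturates at `k1 * E_Cl * E_metal / k2`.
#'
#' @param params [kinetic_parameters()].
#' @param conditions [furnace_conditions()].
#' @return Generated congener mass per unit waste mass (ng/kg waste, given
#'   `k1` in the units documented there).
#' @export
congener_generation <- function(params, conditions) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(conditions, "furnace_conditions"))
  with(conditions,
       params$k1 * e_cl * e_metal / params$k2 *
         -expm1(-params$k2 * oxygen_ratio * residence_time))
}

#' Select the reference congener for quantity scale-up
#'
#' Among the congeners with calibrated kinetic constants, the one with the
#' largest share in the (pre-treatment) congener profile is used: a large
#' share makes the scale-up least sensitive to profile-estimation error.
#' Ties break to the earlier canonical index.
#'
#' @param profile A [congener_profile()] (or named 17-vector of shares).
#' @param available Character vector of congener names with kinetic
#'   constants.
#' @return The selected congener name.
#' @export
select_reference_congener <- function(profile,
                                      available = c("2,3,7,8-TeCDF", "OCDF",
                                                    "1,2,3,6,7,8-HxCDD")) {
  if (!length(available)) stop("no congeners with kinetic constants available")
  unknown <- setdiff(available, congener_names())
  if (length(unknown)) stop("unknown congener(s): ",
                            paste(unknown, collapse = ", "))
  shares <- check_congener_vector(unclass(profile), "congener profile")
  # canonical order makes which.max's first-hit rule the stated tie-break
  cand <- shares[intersect(congener_names(), available)]
  names(cand)[which.max(cand)]
}

#' Scale a reference-congener amount up to total PCDD/Fs
#'
#' `total = ref_amount / ref_share`, where `ref_share` is the reference
#' congener's mass fraction of total PCDD/Fs in the pre-treatment profile
#' (e.g. OCDF's 20.7%).
#'
#' @param ref_amount Generated reference-congener amount (any mass unit).
#' @param ref_share Reference congener's profile share, in `(0, 1]`.
#' @return Total PCDD/F amount in the same unit as `ref_amount`.
#' @export
total_from_reference <- function(ref_amount, ref_share) {
  if (any(ref_share <= 0)) stop("reference share must be positive")
  if (any(ref_share > 1)) stop("reference share cannot exceed 1")
  ref_amount / ref_share
}

#' Influence-factor configuration
#'
#' Maps raw waste/operation descriptors (chlorine and metal weight
#' fractions, oxygen ratio, furnace temperature) to the kinetic model's
#' effective factors `E_Cl`, `E_metal`, `lambda_oxygen`. Three rule types:
#'
#' * `"identity"` -- pass-through: the weight fractions and oxygen ratio are
#'   used directly (the model equation's literal reading).
#' * `"linear"` -- factors scale linearly with the inputs, normalized so the
#'   stated reference conditions map to 1.
#' * `"table"` -- piecewise-linear interpolation in per-factor lookup
#'   tables (`data.frame(x, value)`).
#'
#' The exact functional forms behind a given calibration are a data
#' question; this configuration object keeps the contract stable while
#' letting users supply their own mapping.
#'
#' @param type `"identity"`, `"linear"` or `"table"`.
#' @param reference For `"linear"`: named list/vector with reference
#'   `f_cl`, `f_metal`, `oxygen`.
#' @param tables For `"table"`: named list of data frames (`e_cl`,
#'   `e_metal`, `lambda`), each with columns `x`, `value`.
#' @return Object of class `influence_config`.
#' @export
influence_config <- function(type = c("identity", "linear", "table"),
                             reference = NULL, tables = NULL) {
  type <- match.arg(type)
  if (type == "linear") {
    if (is.null(reference) ||
        !all(c("f_cl", "f_metal", "oxygen") %in% names(reference)))
      stop("linear config requires reference f_cl, f_metal and oxygen")
    if (any(unlist(reference[c("f_cl", "f_metal", "oxygen")]) <= 0))
      stop("linear config reference values must be positive")
  }
  if (type == "table") {
    need <- c("e_cl", "e_metal", "lambda")
    if (is.null(tables) || !all(need %in% names(tables)))
      stop("table config requires lookup tables: ",
           paste(need, collapse = ", "))
    for (nm in need)
      stopifnot(is.data.frame(tables[[nm]]),
                all(c("x", "value") %in% names(tables[[nm]])))
  }
  structure(list(type = type, reference = reference, tables = tables),
            class = "influence_config")
}

#' Evaluate influence factors for given waste and operating inputs
#'
#' @param cfg An [influence_config()].
#' @param f_cl Chlorine weight fraction of the waste.
#' @param f_metal Metal weight fraction of the waste.
#' @param oxygen Oxygen ratio (dimensionless) or, for a `"table"` config,
#'   whatever abscissa its `lambda` table is expressed in.
#' @param temperature Furnace temperature, degC (reserved for
#'   temperature-adjusted calibrations; unused by the built-in rules).
#' @return List with `e_cl`, `e_metal`, `lambda_oxygen`.
#' @export
influence_factors <- function(cfg, f_cl, f_metal, oxygen,
                              temperature = NULL) {
  stopifnot(inherits(cfg, "influence_config"))
  if (any(c(f_cl, f_metal, oxygen) < 0)) stop("inputs must be nonnegative")
  switch(cfg$type,
    identity = list(e_cl = f_cl, e_metal = f_metal, lambda_oxygen = oxygen),
    linear = list(
      e_cl = f_cl / cfg$reference[["f_cl"]],
      e_metal = f_metal / cfg$reference[["f_metal"]],
      lambda_oxygen = oxygen / cfg$reference[["oxygen"]]
    ),
    table = list(
      e_cl = interp_table(cfg$tables$e_cl, f_cl),
      e_metal = interp_table(cfg$tables$e_metal, f_metal),
      lambda_oxygen = interp_table(cfg$tables$lambda, oxygen)
    )
  )
}

interp_table <- function(tab, x) {
  stats::approx(tab$x, tab$value, xout = x, rule = 2)$y
}
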