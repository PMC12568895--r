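#' Canonical registry of the 17 toxic PCDD/F congeners
#'
#' The 2,3,7,8-substituted polychlorinated dibenzo-p-dioxins (7 congeners) and
#' dibenzofurans (10 congeners) are the toxicologically relevant subset of the
#' 210 possible PCDD/F congeners. Every vector-valued object in this package
#' (profiles, efficiencies, half-lives, TEFs) uses the fixed canonical order
#' returned here: dioxins first, furans second, each family ordered by
#' increasing chlorination.
#'
#' @return A data frame with one row per congener and columns `name`,
#'   `family` (`"PCDD"` or `"PCDF"`), `chlorination` (integer, 4--8) and
#'   `index` (0-based canonical position).
#' @examples
#' congener_registry()
#' @export
congener_registry <- function() {
  name <- c(
    "2,3,7,8-TeCDD", "1,2,3,7,8-PeCDD", "1,2,3,4,7,8-HxCDD",
    "1,2,3,6,7,8-HxCDD", "1,2,3,7,8,9-HxCDD", "1,2,3,4,6,7,8-HpCDD", "OCDD",
    "2,3,7,8-TeCDF", "1,2,3,7,8-PeCDF", "2,3,4,7,8-PeCDF",
    "1,2,3,4,7,8-HxCDF", "1,2,3,6,7,8-HxCDF", "1,2,3,7,8,9-HxCDF",
    "2,3,4,6,7,8-HxCDF", "1,2,3,4,6,7,8-HpCDF", "1,2,3,4,7,8,9-HpCDF", "OCDF"
  )
  data.frame(
    name = name,
    family = rep(c("PCDD", "PCDF"), times = c(7L, 10L)),
    chlorination = c(4L, 5L, 6L, 6L, 6L, 7L, 8L, 4L, 5L, 5L, 6L, 6L, 6L, 6L, 7L, 7L, 8L),
    index = 0:16,
    stringsAsFactors = FALSE
  )
}

#' Canonical congener names
#'
#' @return Character vector of the 17 canonical congener names, in canonical
#'   order.
#' @export
congener_names <- function() congener_registry()$name

#' The two PCDD/F phases
#'
#' Stack-gas PCDD/Fs partition between the gas phase and the particle-bound
#' phase; phase-resolved profiles carry one entry per congener and phase.
#'
#' @return `c("gaseous", "particulate")`
#' @export
phase_names <- function() c("gaseous", "particulate")

#' Load a toxic equivalency factor (TEF) table
#'
#' TEFs express the toxic potency of each congener relative to 2,3,7,8-TeCDD
#' (whose TEF is 1 by definition). Two consensus schemes are bundled as an
#' editable CSV (`tef_tables.csv` under `extdata`); users may point `path` at
#' their own file with the same layout (columns `congener,scheme,tef`).
#'
#' @param scheme `"WHO2005"` or `"WHO2022"`.
#' @param path Optional path to a TEF CSV; defaults to the bundled table.
#' @return Named numeric vector of 17 nonnegative TEFs in canonical order,
#'   with attribute `scheme`.
#' @examples
#' tef <- tef_table("WHO2005")
#' tef[["2,3,7,8-TeCDD"]] # 1 by definition
#' @export
tef_table <- function(scheme = c("WHO2005", "WHO2022"), path = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(path)) {
    path <- system.file("extdata", "tef_tables.csv", package = "dioxinrecon",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$scheme == scheme, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no TEF entries for scheme '", scheme, "' in ", path)
  tef <- tab$tef
  names(tef) <- tab$congener
  tef <- check_congener_vector(tef, what = "TEF table")
  if (any(tef < 0)) stop("TEF values must be nonnegative")
  structure(tef, scheme = scheme)
}

# Reorder a named 17-vector into canonical order; error on missing/unknown
# congeners or duplicates. Shared by every module that takes congener vectors.
check_congener_vector <- function(x, what = "congener vector") {
  cn <- congener_names()
  if (is.null(names(x))) {
    if (length(x) != 17L)
      stop(what, " must have 17 entries (or be named by congener)")
    names(x) <- cn
    return(x)
  }
  unknown <- setdiff(names(x), cn)
  if (length(unknown))
    stop(what, ": unknown congener name(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(cn, names(x))
  if (length(missing))
    stop(what, ": missing congener(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(names(x)))
    stop(what, ": duplicated congener names")
  x[cn]
}

#' Toxic equivalent (TEQ) mass of a congener mass vector
#'
#' Computes `sum(mass_i * TEF_i)`: the mass of 2,3,7,8-TeCDD that would carry
#' the same toxic potency as the mixture.
#'
#' @param masses Named numeric vector of per-congener masses (g); all 17
#'   congeners must be present and nonnegative.
#' @param table TEF table from [tef_table()] (or any named 17-vector of
#'   nonnegative factors).
#' @return TEQ mass (g TEQ), a single number.
#' @examples
#' m <- setNames(rep(0, 17), congener_names())
#' m["2,3,7,8-TeCDD"] <- 1
#' teq(m, tef_table("WHO2005")) # 1 g TEQ
#' @export
teq <- function(masses, table = tef_table("WHO2005")) {
  masses <- check_congener_vector(masses, what = "mass vector")
  if (any(!is.finite(masses))) stop("mass vector contains non-finite values")
  if (any(masses < 0)) stop("negative mass for congener(s): ",
                            paste(names(masses)[masses < 0], collapse = ", "))
  table <- check_congener_vector(table, what = "TEF table")
  sum(masses * table)
}
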