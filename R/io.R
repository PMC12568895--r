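#' Read a phase-resolved profile from CSV
#'
#' Schema: columns `congener`, `phase`, `fraction`, optional `units`
#' (`"percent"` or `"fraction"`; a units column overrides the argument).
#' All 34 congener-by-phase entries must be present, nonnegative, and sum
#' to 1 (100 for percent) within tolerance.
#'
#' @param path CSV path.
#' @param units `"fraction"` or `"percent"` when no units column is
#'   present.
#' @param label Optional profile label.
#' @param tol Normalization tolerance (on the fraction scale).
#' @return A [phase_profile()].
#' @export
read_profile_csv <- function(path, units = c("fraction", "percent"),
                             label = NULL, tol = 0.01) {
  units <- match.arg(units)
  df <- read_checked_csv(path, c("congener", "phase", "fraction"))
  if ("units" %in% names(df)) units <- unique(df$units)
  if (length(units) != 1L || !units %in% c("fraction", "percent"))
    stop("units must be uniformly 'fraction' or 'percent' in ", path)
  if (units == "percent") df$fraction <- df$fraction / 100
  m <- long_to_matrix(df, "fraction")
  if (anyNA(m)) stop("profile in ", path, " is missing entries")
  if (any(m < 0)) stop("profile in ", path, " has negative entries")
  tot <- sum(m)
  if (abs(tot - 1) > tol)
    stop("profile in ", path, " sums to ", format(tot),
         " (deficit ", format(1 - tot), "); expected 1 within ", tol)
  phase_profile(m, label = label, normalize = TRUE)
}

#' Write a phase-resolved profile to CSV
#'
#' @param profile A [phase_profile()].
#' @param path Output CSV path.
#' @param units `"fraction"` or `"percent"`.
#' @export
write_profile_csv <- function(profile, path,
                              units = c("fraction", "percent")) {
  units <- match.arg(units)
  m <- unclass(profile)
  df <- data.frame(
    congener = rep(rownames(m), 2L),
    phase = rep(colnames(m), each = 17L),
    fraction = c(m[, 1L], m[, 2L]) * if (units == "percent") 100 else 1,
    units = units
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an APCD stage efficiency table from CSV
#'
#' Schema: columns `congener`, `phase`, `eta`, optional `units`
#' (`"percent"` or `"fraction"`).
#'
#' @param path CSV path.
#' @param name Stage name.
#' @param units Efficiency units when no units column present.
#' @param temperature Optional inlet/outlet temperatures (degC).
#' @param fill_missing Passed to [apcd_stage()].
#' @return An [apcd_stage()].
#' @export
read_stage_csv <- function(path, name = "stage",
                           units = c("fraction", "percent"),
                           temperature = c(NA_real_, NA_real_),
                           fill_missing = FALSE) {
  units <- match.arg(units)
  df <- read_checked_csv(path, c("congener", "phase", "eta"))
  if ("units" %in% names(df)) units <- unique(df$units)
  if (length(units) != 1L || !units %in% c("fraction", "percent"))
    stop("units must be uniformly 'fraction' or 'percent' in ", path)
  if (units == "percent") df$eta <- df$eta / 100
  apcd_stage(name, df[c("congener", "phase", "eta")],
             temperature = temperature, fill_missing = fill_missing)
}

#' Write an APCD stage to CSV
#' @param stage An [apcd_stage()].
#' @param path Output path.
#' @param units `"fraction"` or `"percent"`.
#' @export
write_stage_csv <- function(stage, path, units = c("fraction", "percent")) {
  units <- match.arg(units)
  m <- stage$eta
  df <- data.frame(
    congener = rep(rownames(m), 2L),
    phase = rep(colnames(m), each = 17L),
    eta = c(m[, 1L], m[, 2L]) * if (units == "percent") 100 else 1,
    units = units
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an annual waste timeline CSV
#'
#' Schema: `year,m_waste,f_cl,f_metal`.
#' @param path CSV path.
#' @return A [waste_timeline()].
#' @export
read_timeline_csv <- function(path) {
  df <- read_checked_csv(path, c("year", "m_waste", "f_cl", "f_metal"))
  waste_timeline(df$year, df$m_waste, df$f_cl, df$f_metal)
}

#' @rdname read_timeline_csv
#' @param timeline A [waste_timeline()].
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(as.data.frame(timeline), path, row.names = FALSE)
  invisible(path)
}

#' Read / write emission series CSVs
#'
#' Long schema: `year,furnace_g,stack_g` plus, when a congener split is
#' attached, one `congener,mass_g` row pair per year and congener.
#' `read_emissions_csv` accepts either the annual-totals schema or the long
#' per-congener schema (`year,congener,mass_g`).
#'
#' @param series An `emission_series`.
#' @param path CSV path.
#' @export
write_emissions_csv <- function(series, path) {
  cg <- attr(series, "congener_g")
  if (is.null(cg)) {
    utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  } else {
    df <- data.frame(
      year = rep(as.integer(rownames(cg)), times = 17L),
      congener = rep(colnames(cg), each = nrow(cg)),
      mass_g = as.vector(cg)
    )
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_emissions_csv
#' @return `read_emissions_csv`: a year-by-congener matrix (long schema) or
#'   `emission_series` (totals schema).
#' @export
read_emissions_csv <- function(path) {
  df <- read_checked_csv(path, "year")
  if (all(c("congener", "mass_g") %in% names(df))) {
    years <- sort(unique(df$year))
    m <- matrix(0, length(years), 17L,
                dimnames = list(years, congener_names()))
    for (k in seq_len(nrow(df)))
      m[as.character(df$year[k]), df$congener[k]] <- df$mass_g[k]
    return(m)
  }
  if (!"furnace_g" %in% names(df))
    stop("unrecognized emissions schema in ", path)
  new_emission_series(df)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a structured run configuration (YAML)
#'
#' Minimal schema: `horizon: [start, end]`, file paths under `inputs:`
#' (`timeline`, `profile`, `stage`, `kinetic_constants`, `half_lives`),
#' `scenarios:` (list of `start`, `end`, `eta:` name-value maps),
#' `reference_congener` (optional), `furnace:` (`residence_time`, `oxygen`,
#' `temperature`), `seed`, `outdir`.
#'
#' @param path YAML file path.
#' @return Named list with validated fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$horizon) || length(cfg$horizon) != 2L)
    stop("config must define horizon: [start, end]")
  for (f in cfg$inputs)
    if (!file.exists(f)) stop("configured input file not found: ", f)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}
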