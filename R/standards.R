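# Guideline registries, toxicity/exposure constants and classification rubrics.

#' Catalogue of recognised water-chemistry parameters
#'
#' The sixteen parameters handled by the package, in canonical units:
#' mg/L for all solutes, uS/cm for electrical conductivity (`EC`),
#' ppt for `salinity`, FTU for `turbidity`, mV for `ORP`, unitless `pH`.
#'
#' @return Character vector of canonical parameter names.
#' @export
parameter_catalogue <- function() {
  c("pH", "alkalinity", "free_CO2", "EC", "ORP", "salinity", "TDS", "TH",
    "turbidity", "NaCl", "Ca", "Cl", "Cd", "Cu", "Ni", "Pb")
}

#' Heavy metals covered by the ecological and health risk modules
#' @return Character vector `c("Cd", "Cu", "Ni", "Pb")`.
#' @export
metal_catalogue <- function() c("Cd", "Cu", "Ni", "Pb")

# A standard is either a scalar upper limit (length 1), a two-sided interval
# (length 2, lo < hi), or NA (no standard declared by that authority).
.standards_tables <- function() {
  list(
    WHO = list(
      pH = c(6.5, 8.5), alkalinity = c(200, 600), free_CO2 = 10, EC = 250,
      ORP = NA, salinity = NA, TDS = c(600, 1000), TH = 300, turbidity = 4,
      NaCl = c(200, 300), Ca = 75, Cl = 250,
      Cd = 0.003, Cu = 2.0, Ni = 0.07, Pb = 0.01
    ),
    USEPA = list(
      pH = c(6.5, 8.5), alkalinity = c(30, 400), free_CO2 = NA, EC = c(50, 1500),
      ORP = NA, salinity = 1, TDS = 500, TH = 200, turbidity = 5,
      NaCl = 500, Ca = NA, Cl = 250,
      Cd = 0.005, Cu = 1.0, Ni = NA, Pb = 0.015
    ),
    ISDW = list(
      pH = c(6.5, 8.5), alkalinity = 200, free_CO2 = NA, EC = NA,
      ORP = NA, salinity = 1, TDS = 500, TH = 300, turbidity = 5,
      NaCl = NA, Ca = 75, Cl = 250,
      Cd = 0.003, Cu = 0.05, Ni = 0.02, Pb = 0.1
    ),
    BDWS = list(
      pH = c(6.5, 8.5), alkalinity = c(20, 200), free_CO2 = NA, EC = c(50, 1500),
      ORP = NA, salinity = 0.6, TDS = 1000, TH = c(200, 500), turbidity = 10,
      NaCl = 600, Ca = 75, Cl = c(150, 600),
      Cd = 0.005, Cu = 1.0, Ni = 0.1, Pb = 0.05
    )
  )
}

#' Drinking-water guideline registry
#'
#' Scalar limits and two-sided interval standards per parameter for the WHO,
#' USEPA, Indian (ISDW) and Bangladeshi (BDWS) drinking-water standards, plus
#' user-supplied custom tables. Scalar standards are upper bounds; interval
#' standards (e.g. pH 6.5--8.5) are two-sided. ORP carries no standard in any
#' registry.
#'
#' @param authority One of `"WHO"`, `"USEPA"`, `"ISDW"`, `"BDWS"`, `"custom"`.
#' @param custom Named list of standards (scalar, length-2 interval, or `NA`)
#'   used when `authority = "custom"`, or to override individual entries of a
#'   built-in authority.
#' @return An object of class `guideline_registry`: a list with `authority`,
#'   `standards` (named list) and a `provenance` note.
#' @examples
#' reg <- guideline_registry("BDWS")
#' standard_value(reg, "Cd")       # 0.005 mg/L
#' standard_value(reg, "pH")       # c(6.5, 8.5)
#' @export
guideline_registry <- function(authority = c("WHO", "USEPA", "ISDW", "BDWS", "custom"),
                               custom = NULL) {
  authority <- match.arg(authority)
  tables <- .standards_tables()
  if (authority == "custom") {
    if (is.null(custom)) stop("authority 'custom' requires a 'custom' standards list")
    std <- custom
    prov <- "user-supplied"
  } else {
    std <- tables[[authority]]
    if (!is.null(custom)) std[names(custom)] <- custom
    prov <- sprintf("%s drinking-water standards (transcribed defaults)", authority)
  }
  bad <- vapply(std, function(s) {
    if (all(is.na(s))) return(FALSE)
    if (length(s) == 2) return(!(s[1] < s[2]))
    length(s) == 1 && s <= 0
  }, logical(1))
  if (any(bad)) {
    stop("invalid standard(s) for: ", paste(names(std)[bad], collapse = ", "),
         " (scalar limits must be > 0, intervals must satisfy lo < hi)")
  }
  structure(list(authority = authority, standards = std, provenance = prov),
            class = "guideline_registry")
}

#' Look up a standard for one parameter
#'
#' @param registry A [guideline_registry()].
#' @param parameter Parameter name.
#' @return Scalar limit, length-2 interval, or `NA` when the authority
#'   declares no standard (e.g. ORP everywhere).
#' @export
standard_value <- function(registry, parameter) {
  stopifnot(inherits(registry, "guideline_registry"))
  if (!parameter %in% names(registry$standards)) return(NA_real_)
  registry$standards[[parameter]]
}

#' Upper bound of a standard (scalar limit, or the interval's upper edge)
#'
#' Used where a single reference concentration is required (contamination
#' factors, relative weights).
#'
#' @inheritParams standard_value
#' @return Scalar, or `NA` if no standard exists.
#' @export
standard_upper <- function(registry, parameter) {
  s <- standard_value(registry, parameter)
  if (all(is.na(s))) return(NA_real_)
  max(s)
}

#' @export
print.guideline_registry <- function(x, ...) {
  cat("Guideline registry:", x$authority, "\n")
  n <- sum(!vapply(x$standards, function(s) all(is.na(s)), logical(1)))
  cat(sprintf("  %d of %d parameters carry a standard\n", n, length(x$standards)))
  invisible(x)
}

#' Reference standards for contamination factors
#'
#' One scalar reference concentration per parameter (ORP excluded): the
#' Bangladeshi (BDWS) upper bounds, with WHO's 10 mg/L for free CO2, which has
#' no BDWS limit. Fifteen parameters, matching the divisor of the modified
#' contamination index.
#'
#' @param overrides Optional named numeric vector replacing individual entries.
#' @return Named numeric vector of 15 reference concentrations.
#' @export
cf_standards <- function(overrides = NULL) {
  bdws <- guideline_registry("BDWS")
  pars <- setdiff(parameter_catalogue(), "ORP")
  si <- vapply(pars, function(p) standard_upper(bdws, p), numeric(1))
  si["free_CO2"] <- 10   # WHO; BDWS declares none
  if (!is.null(overrides)) si[names(overrides)] <- overrides
  if (any(is.na(si)) || any(si <= 0)) stop("contamination-factor standards must be positive")
  si
}

#' Toxicity and exposure constants for the four heavy metals
#'
#' Holds, per metal: the toxic response factor (TRF; Cd 30, Cu/Ni/Pb 5), the
#' ecological-risk reference standard Si (mg/L; Cd 0.003, Pb 0.01, Ni 0.02,
#' Cu 0.05 -- a mixed-authority set chosen for internal consistency with the
#' ecological-risk scale, see the methods vignette; Cu's value matches no
#' single authority and is flagged in the provenance note), ingestion and
#' dermal toxic reference doses (RfD, ug/kg-day), cancer slope factors
#' (CSF, kg day/mg; Cu has none and is excluded from carcinogenic risk;
#' Pb's default 8.5e-3 treats the nominal "8.5" as a unit slip), and dermal
#' permeability coefficients Kp (cm/h).
#'
#' @param overrides Named list of named numeric vectors (e.g.
#'   `list(csf = c(Pb = 8.5))`) replacing individual constants.
#' @return Object of class `toxicity_registry`.
#' @examples
#' tox <- toxicity_registry()
#' tox$trf[["Cd"]]   # 30
#' tox$csf[["Pb"]]   # 0.0085
#' @export
toxicity_registry <- function(overrides = NULL) {
  reg <- list(
    trf     = c(Cd = 30,    Cu = 5,     Ni = 5,      Pb = 5),
    eri_si  = c(Cd = 0.003, Cu = 0.05,  Ni = 0.02,   Pb = 0.01),
    rfd_ing = c(Cd = 0.5,   Cu = 40,    Ni = 20,     Pb = 1.4),
    rfd_der = c(Cd = 0.005, Cu = 12,    Ni = 5.4,    Pb = 0.42),
    csf     = c(Cd = 6.1,   Ni = 0.84,  Pb = 0.0085),
    kp      = c(Cd = 0.001, Cu = 0.001, Ni = 0.0002, Pb = 0.004),
    provenance = paste("TRF and RfD/CSF/Kp as published; ERI Si mixed-authority",
                       "(Cu 0.05 mg/L matches no single authority);",
                       "Pb CSF scaled to 8.5e-3 kg day/mg")
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(reg)) stop("unknown toxicity table: ", nm)
      reg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    }
  }
  num <- unlist(reg[c("trf", "eri_si", "rfd_ing", "rfd_der", "csf", "kp")])
  if (any(!is.finite(num)) || any(num <= 0)) stop("toxicity constants must be positive")
  structure(reg, class = "toxicity_registry")
}

#' Exposure cohort definitions for health-risk assessment
#'
#' Defaults follow the USEPA-style parameter set used for drinking-water
#' exposure: ingestion rate IR (L/day), exposure frequency EF (days/year),
#' exposure period EP (years), body weight BW (kg), averaging time
#' AT = EP x 365 (days), exposed skin area SA (cm2), exposure time ET (h/day)
#' and the dermal unit conversion factor CFconv = 0.0001 L/cm3.
#'
#' @param name `"child"`, `"adult_male"`, `"adult_female"` or `"custom"`.
#' @param ... For `"custom"` (or to override defaults): named values among
#'   `IR`, `EF`, `EP`, `BW`, `AT`, `SA`, `ET`, `CFconv`.
#' @return Object of class `exposure_cohort` (named list of constants).
#' @examples
#' ch <- exposure_cohort("child")
#' ch$IR * ch$EF * ch$EP / (ch$BW * ch$AT)  # daily dose coefficient ~0.0599
#' @export
exposure_cohort <- function(name = c("child", "adult_male", "adult_female", "custom"), ...) {
  name <- match.arg(name)
  defaults <- list(
    child        = list(IR = 1.0, EF = 350, EP = 6,  BW = 16, SA = 6800,  ET = 1.0),
    adult_male   = list(IR = 2.0, EF = 350, EP = 30, BW = 70, SA = 19000, ET = 0.5),
    adult_female = list(IR = 1.6, EF = 350, EP = 30, BW = 55, SA = 16000, ET = 0.75)
  )
  co <- if (name == "custom") list() else defaults[[name]]
  dots <- list(...)
  co[names(dots)] <- dots
  required <- c("IR", "EF", "EP", "BW", "SA", "ET")
  if (!all(required %in% names(co)))
    stop("cohort must define: ", paste(setdiff(required, names(co)), collapse = ", "))
  if (is.null(co$AT)) co$AT <- co$EP * 365
  if (is.null(co$CFconv)) co$CFconv <- 1e-4
  vals <- unlist(co[c(required, "AT", "CFconv")])
  if (any(!is.finite(vals)) || any(vals <= 0)) stop("all exposure constants must be positive")
  co$name <- name
  structure(co, class = "exposure_cohort")
}

#' The three default cohorts
#' @return Named list of [exposure_cohort()] objects (child, adult_male,
#'   adult_female).
#' @export
default_cohorts <- function() {
  nm <- c("child", "adult_male", "adult_female")
  stats::setNames(lapply(nm, exposure_cohort), nm)
}

# Rubric representation: data.frame(lower, label, aw) with half-open
# intervals [lower_i, lower_{i+1}); a value exactly on a boundary takes the
# upper class.
.rubric <- function(lower, label, aw) data.frame(lower = lower, label = label, aw = aw,
                                                 stringsAsFactors = FALSE)

#' Classification rubrics for the contamination indices
#'
#' Ordered class boundaries, labels (very low ... very high) and integer
#' arbitrary weights Aw (1--5) per index, plus the weighted-contamination-index
#' (WCI) grade bounds. Intervals are contiguous and half-open (closed below,
#' open above); printed gaps in the source tables are closed at the lower edge.
#'
#' @return Object of class `rubric_set`: named list of rubric tables.
#' @export
default_rubric <- function() {
  structure(list(
    TCI = .rubric(c(0, 8, 16, 32),       c("low", "medium", "high", "very high"), c(2, 3, 4, 5)),
    MCI = .rubric(c(0, 1.5, 2, 4, 8),    c("very low", "low", "medium", "high", "very high"), 1:5),
    PLI = .rubric(c(0, 0.5, 1),          c("low", "medium", "high"), c(2, 3, 4)),
    NPI = .rubric(c(0, 1, 2.5, 7),       c("very low", "low", "medium", "high"), 1:4),
    MPI = .rubric(c(0, 0.3, 1, 2.5, 7),  c("very low", "low", "medium", "high", "very high"), 1:5),
    WCI = .rubric(c(0, 0.07, 0.2, 0.4, 0.67),
                  c("very low", "low", "medium", "high", "very high"), rep(NA_integer_, 5))
  ), class = "rubric_set")
}
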