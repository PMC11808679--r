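# Sample tables: construction, CSV I/O, unit conversion, descriptive
# statistics, guideline compliance.

# Multiplicative factors into canonical units (mg/L solutes, uS/cm EC,
# ppt salinity, FTU turbidity, mV ORP). A unit map entry of "ug/L" on a
# solute column divides by 1000 at load time.
.unit_factor <- function(parameter, unit) {
  if (is.null(unit) || is.na(unit) || !nzchar(unit)) return(1)
  tab <- c("mg/L" = 1, "ug/L" = 1e-3, "µg/L" = 1e-3, "g/L" = 1e3,
           "uS/cm" = 1, "mS/cm" = 1e3, "ppt" = 1, "FTU" = 1, "NTU" = 1,
           "mV" = 1, "V" = 1e3, "pH" = 1)
  if (!unit %in% names(tab)) stop("unknown unit '", unit, "' for parameter ", parameter)
  tab[[unit]]
}

.validate_samples <- function(df) {
  if (anyDuplicated(df$station_id))
    stop("duplicate station ids: ",
         paste(unique(df$station_id[duplicated(df$station_id)]), collapse = ", "))
  pars <- intersect(parameter_catalogue(), names(df))
  for (p in setdiff(pars, c("pH", "ORP"))) {
    bad <- which(!is.na(df[[p]]) & df[[p]] < 0)
    if (length(bad))
      stop(sprintf("negative concentration for %s at row %d (station %s)",
                   p, bad[1], df$station_id[bad[1]]))
  }
  if ("pH" %in% pars) {
    bad <- which(!is.na(df$pH) & (df$pH <= 0 | df$pH >= 14))
    if (length(bad))
      stop(sprintf("pH out of (0, 14) at row %d (station %s)", bad[1], df$station_id[bad[1]]))
  }
  invisible(df)
}

#' Build a sample table from a data frame
#'
#' @param df Data frame with columns `station_id`, `longitude`, `latitude`
#'   and any subset of [parameter_catalogue()], already in canonical units.
#' @return Object of class `sample_table` (a data.frame with a
#'   `metals_measured` logical column: `FALSE` where all four metal cells are
#'   missing).
#' @export
sample_table <- function(df) {
  stopifnot(is.data.frame(df), "station_id" %in% names(df))
  df$station_id <- as.character(df$station_id)
  if (!"longitude" %in% names(df)) df$longitude <- NA_real_
  if (!"latitude" %in% names(df)) df$latitude <- NA_real_
  unknown <- setdiff(names(df), c("station_id", "longitude", "latitude",
                                  "metals_measured", parameter_catalogue()))
  if (length(unknown))
    stop("unknown parameter column(s): ", paste(unknown, collapse = ", "),
         " (see parameter_catalogue())")
  .validate_samples(df)
  metals <- intersect(metal_catalogue(), names(df))
  df$metals_measured <- if (length(metals))
    apply(!is.na(as.matrix(df[, metals, drop = FALSE])), 1, any) else FALSE
  ord <- c("station_id", "longitude", "latitude",
           intersect(parameter_catalogue(), names(df)), "metals_measured")
  structure(df[ord], class = c("sample_table", "data.frame"))
}

#' Read a per-station water-chemistry CSV
#'
#' Expects one row per station with header
#' `station_id,longitude,latitude,<parameter>...`; missing cells are empty
#' strings. Values are converted to canonical units at load time via
#' `unit_map`.
#'
#' @param path CSV path.
#' @param unit_map Optional named character vector of declared units per
#'   parameter column (e.g. `c(Cd = "ug/L")`); unmapped columns are assumed
#'   canonical.
#' @return A [sample_table()].
#' @export
load_samples <- function(path, unit_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!"station_id" %in% names(df)) stop("CSV must have a 'station_id' column")
  for (p in intersect(parameter_catalogue(), names(df))) {
    u <- if (!is.null(unit_map) && p %in% names(unit_map)) unit_map[[p]] else NA
    df[[p]] <- as.numeric(df[[p]]) * .unit_factor(p, u)
  }
  sample_table(df)
}

#' Write a sample table to CSV
#'
#' Values are written in canonical units; missing cells become empty strings,
#' so `load_samples(write_samples(x, f))` round-trips to declared precision.
#'
#' @param samples A [sample_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "sample_table"))
  out <- samples[setdiff(names(samples), "metals_measured")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.sample_table <- function(x, ...) {
  pars <- intersect(parameter_catalogue(), names(x))
  cat(sprintf("Sample table: %d stations, %d parameters (%d with metal data)\n",
              nrow(x), length(pars), sum(x$metals_measured)))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more stations\n")
  invisible(x)
}

#' Descriptive statistics per parameter
#'
#' Minimum, maximum, arithmetic mean and sample standard deviation over
#' non-missing values, per parameter.
#'
#' @param samples A [sample_table()].
#' @return Data frame (class `descriptive_stats`) with columns `parameter`,
#'   `n`, `min`, `max`, `mean`, `sd`. Parameters whose values are all missing
#'   get `n = 0` and `NA` statistics (never zero).
#' @export
describe <- function(samples) {
  stopifnot(inherits(samples, "sample_table"))
  pars <- intersect(parameter_catalogue(), names(samples))
  rows <- lapply(pars, function(p) {
    v <- samples[[p]][!is.na(samples[[p]])]
    if (length(v) == 0)
      return(data.frame(parameter = p, n = 0L, min = NA_real_, max = NA_real_,
                        mean = NA_real_, sd = NA_real_))
    data.frame(parameter = p, n = length(v), min = min(v), max = max(v),
               mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  structure(do.call(rbind, rows), class = c("descriptive_stats", "data.frame"))
}

# TRUE/FALSE/NA per value against a scalar upper limit or two-sided interval.
.within_standard <- function(values, std) {
  if (all(is.na(std))) return(rep(NA, length(values)))
  if (length(std) == 2) values >= std[1] & values <= std[2] else values <= std[1]
}

#' Guideline-compliance accounting
#'
#' Percentage of samples within each authority's standard, per parameter, and
#' the unweighted mean across the authorities that declare a standard for that
#' parameter. Missing values are excluded from numerator and denominator; a
#' value is compliant iff it is at or below a scalar limit, or inside a
#' two-sided interval standard.
#'
#' @param samples A [sample_table()].
#' @param registries List of [guideline_registry()] objects (defaults to the
#'   four built-in authorities).
#' @param digits Rounding precision for percentages (default 0, matching the
#'   whole-percent convention of published compliance tables).
#' @return Data frame (class `compliance_table`): one row per parameter, one
#'   percentage column per authority, plus `mean_pct`.
#' @export
compliance <- function(samples,
                       registries = lapply(c("WHO", "USEPA", "ISDW", "BDWS"),
                                           guideline_registry),
                       digits = 0) {
  stopifnot(inherits(samples, "sample_table"))
  auth <- vapply(registries, `[[`, character(1), "authority")
  pars <- intersect(parameter_catalogue(), names(samples))
  out <- data.frame(parameter = pars, stringsAsFactors = FALSE)
  pct <- matrix(NA_real_, nrow = length(pars), ncol = length(auth),
                dimnames = list(pars, auth))
  for (p in pars) {
    v <- samples[[p]][!is.na(samples[[p]])]
    for (j in seq_along(registries)) {
      ok <- .within_standard(v, standard_value(registries[[j]], p))
      if (!all(is.na(ok)) && length(v))
        pct[p, j] <- round(100 * mean(ok), digits)
    }
  }
  out <- cbind(out, as.data.frame(pct))
  out$mean_pct <- round(rowMeans(pct, na.rm = TRUE), digits)
  out$mean_pct[apply(is.na(pct), 1, all)] <- NA_real_
  rownames(out) <- NULL
  structure(out, class = c("compliance_table", "data.frame"))
}
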