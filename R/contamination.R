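# Contamination factor and the aggregate contamination indices
# (TCI, MCI, PLI, NPI, MPI, WCI) with rubric classification.

#' Contamination factor
#'
#' Ratio of a measured concentration to its reference standard, CF = M / S.
#' Interval standards contribute their upper bound.
#'
#' @param value Measured concentration (>= 0, canonical units).
#' @param standard Scalar limit or length-2 interval (upper bound used).
#' @return CF, a dimensionless ratio.
#' @examples
#' contamination_factor(0.129, 0.005)  # Cd at its observed maximum -> 25.8
#' @export
contamination_factor <- function(value, standard) {
  s <- max(standard)
  if (!is.finite(s) || s <= 0) stop("standard must be a positive finite number")
  if (any(value < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  value / s
}

#' Total contamination index: the sum of contamination factors
#' @param cf Numeric vector of contamination factors (length >= 1).
#' @return Sum of `cf`.
#' @export
tci <- function(cf) {
  if (length(cf) == 0) stop("empty CF vector")
  sum(cf)
}

#' Modified contamination index: the mean contamination factor
#'
#' TCI divided by the number of CF terms, i.e. the number of parameters with
#' a standard (15 under the default standard set).
#'
#' @inheritParams tci
#' @param n Divisor; defaults to `length(cf)`.
#' @return TCI / n.
#' @export
mci <- function(cf, n = length(cf)) tci(cf) / n

#' Pollution load index: the geometric mean of contamination factors
#'
#' Zero CF terms degenerate the geometric mean, so they are replaced by a
#' configurable floor before taking the nth root (with a warning).
#'
#' @inheritParams tci
#' @param zero_floor Replacement for zero CF terms (default 1e-6).
#' @return `(prod(cf))^(1/length(cf))` after zero substitution.
#' @examples
#' pli(c(4, 1))        # 2
#' pli(c(0.5, 2, 1))   # 1
#' @export
pli <- function(cf, zero_floor = 1e-6) {
  if (length(cf) == 0) stop("empty CF vector")
  if (any(cf < 0)) stop("CF must be >= 0")
  if (any(cf == 0)) {
    warning("zero CF term(s) replaced by floor ", zero_floor, " in PLI")
    cf[cf == 0] <- zero_floor
  }
  exp(mean(log(cf)))
}

#' Nemerow pollution index
#'
#' Emphasises the worst contaminant by combining the maximum and mean
#' contamination factor: NPI = sqrt((CFmax^2 + CFmean^2) / 2).
#'
#' @inheritParams tci
#' @return NPI.
#' @export
npi <- function(cf) {
  if (length(cf) == 0) stop("empty CF vector")
  sqrt((max(cf)^2 + mean(cf)^2) / 2)
}

#' Metal pollution index
#'
#' Sum over the heavy metals of measured concentration divided by its maximum
#' allowable concentration. Stations without metal data have an undefined
#' MPI; stations with partial metal data are computed over the available
#' metals with a warning.
#'
#' @param metals Named numeric vector of metal concentrations (mg/L); `NA`
#'   marks unmeasured metals.
#' @param cmax Named numeric vector of maximum allowable concentrations
#'   (default: BDWS limits).
#' @return MPI, or `NA` when no metal was measured.
#' @examples
#' mpi(c(Cd = 0.01, Cu = 0, Ni = 0, Pb = 0))  # 2
#' @export
mpi <- function(metals, cmax = c(Cd = 0.005, Cu = 1.0, Ni = 0.1, Pb = 0.05)) {
  if (any(cmax <= 0)) stop("cmax limits must be positive")
  use <- names(metals)[!is.na(metals)]
  use <- intersect(use, names(cmax))
  if (length(use) == 0) return(NA_real_)
  if (length(use) < length(cmax))
    warning("MPI computed over partial metal data: ", paste(use, collapse = ", "))
  sum(metals[use] / cmax[use])
}

#' Classify an index value against its rubric
#'
#' Half-open interval lookup (closed below, open above): a value exactly on a
#' printed boundary takes the upper class. Undefined inputs (`NA`) return
#' label `"not assessed"` with Aw 0; an undefined MPI is reported with the
#' conventional printed form (value 0, label "very low", Aw 0) by [mpi_row()].
#'
#' @param value Index value.
#' @param index Index id: one of `"TCI"`, `"MCI"`, `"PLI"`, `"NPI"`, `"MPI"`,
#'   `"WCI"`.
#' @param rubric A [default_rubric()].
#' @return List with `label` and integer `aw`.
#' @examples
#' classify_index(7.08, "TCI")   # low, Aw 2
#' classify_index(1.67, "PLI")   # high, Aw 4
#' @export
classify_index <- function(value, index, rubric = default_rubric()) {
  if (!index %in% names(rubric)) stop("no rubric for index ", index)
  if (is.na(value)) return(list(label = "not assessed", aw = 0L))
  tab <- rubric[[index]]
  i <- findInterval(value, tab$lower)
  if (i == 0) i <- 1  # values below the first bound take the first class
  list(label = tab$label[i], aw = as.integer(tab$aw[i]))
}

#' Weighted contamination index
#'
#' Aggregates the arbitrary weights Aw of the five contamination indices into
#' a single score in [0, 1]. The default aggregator is
#' `sum(aw) / (5 * number of indices with Aw > 0)`; it is pluggable because
#' the exact published aggregation is under-determined (see the methods
#' vignette) -- the default does not reproduce the published WCI column.
#'
#' @param aw Integer vector of five Aw values (0 allowed; 0 marks an index
#'   that was not assessed).
#' @param aggregator Function `(aw) -> value`, replacing the default.
#' @param rubric A [default_rubric()] used for grading.
#' @return List with `wci`, `label`.
#' @examples
#' wci(c(5, 5, 5, 5, 5))  # 1, very high
#' wci(c(2, 1, 2, 2, 0))  # 7/20 = 0.35 over the 4 active indices
#' @export
wci <- function(aw, aggregator = NULL, rubric = default_rubric()) {
  stopifnot(length(aw) == 5, all(aw >= 0), all(aw <= 5))
  active <- sum(aw > 0)
  if (active == 0) return(list(wci = NA_real_, label = "not assessed"))
  value <- if (is.null(aggregator)) sum(aw) / (5 * active) else aggregator(aw)
  list(wci = value, label = classify_index(value, "WCI", rubric)$label)
}

# MPI printed convention: stations without metal data print "0.00 very low 0".
mpi_row <- function(metals, cmax, rubric) {
  v <- mpi(metals, cmax)
  if (is.na(v)) return(list(mpi = 0, label = "very low", aw = 0L))
  cl <- classify_index(v, "MPI", rubric)
  list(mpi = v, label = cl$label, aw = cl$aw)
}

#' Contamination indices for every station of a sample table
#'
#' Computes per-station contamination factors over the parameters with a
#' standard (ORP carries none and is excluded), the five aggregate indices
#' with class labels and arbitrary weights, and the weighted contamination
#' index.
#'
#' @param samples A [sample_table()].
#' @param standards Named vector of scalar reference concentrations
#'   (default [cf_standards()], 15 parameters).
#' @param cmax Metal limits for MPI (default BDWS).
#' @param rubric A [default_rubric()].
#' @param wci_aggregator Optional replacement WCI aggregator.
#' @return Data frame (class `contamination_result`): one row per station
#'   with columns `TCI`, `MCI`, `PLI`, `NPI`, `MPI`, their labels and Aw,
#'   and `WCI` + label. Per-station CF vectors are attached as attribute
#'   `"cf"` (stations x parameters matrix).
#' @export
contamination_indices <- function(samples, standards = cf_standards(),
                                  cmax = c(Cd = 0.005, Cu = 1.0, Ni = 0.1, Pb = 0.05),
                                  rubric = default_rubric(),
                                  wci_aggregator = NULL) {
  stopifnot(inherits(samples, "sample_table"))
  pars <- intersect(names(standards), names(samples))
  if (length(pars) == 0) stop("no parameters with standards present in samples")
  cfm <- sapply(pars, function(p) contamination_factor(samples[[p]], standards[[p]]))
  cfm <- matrix(cfm, nrow = nrow(samples), dimnames = list(samples$station_id, pars))

  rows <- lapply(seq_len(nrow(samples)), function(i) {
    cf <- cfm[i, ]
    cf <- cf[!is.na(cf)]
    v_tci <- tci(cf); v_mci <- mci(cf)
    v_pli <- suppressWarnings(pli(cf)); v_npi <- npi(cf)
    met <- vapply(names(cmax), function(m)
      if (m %in% names(samples)) samples[[m]][i] else NA_real_, numeric(1))
    mp <- suppressWarnings(mpi_row(met, cmax, rubric))
    c_tci <- classify_index(v_tci, "TCI", rubric)
    c_mci <- classify_index(v_mci, "MCI", rubric)
    c_pli <- classify_index(v_pli, "PLI", rubric)
    c_npi <- classify_index(v_npi, "NPI", rubric)
    aw <- c(c_tci$aw, c_mci$aw, c_pli$aw, c_npi$aw, mp$aw)
    w <- wci(aw, aggregator = wci_aggregator, rubric = rubric)
    data.frame(station_id = samples$station_id[i],
               TCI = v_tci, TCI_class = c_tci$label, TCI_aw = c_tci$aw,
               MCI = v_mci, MCI_class = c_mci$label, MCI_aw = c_mci$aw,
               PLI = v_pli, PLI_class = c_pli$label, PLI_aw = c_pli$aw,
               NPI = v_npi, NPI_class = c_npi$label, NPI_aw = c_npi$aw,
               MPI = mp$mpi, MPI_class = mp$label, MPI_aw = mp$aw,
               WCI = w$wci, WCI_class = w$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cf") <- cfm
  structure(out, class = c("contamination_result", "data.frame"))
}
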