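# USEPA-framework exposure and risk: average daily intake by ingestion and
# dermal contact, hazard quotient/index, carcinogenic risk.

#' Average daily intake via ingestion
#'
#' ADI = C x IR x EF x EP / (BW x AT), in mg/kg-day for C in mg/L.
#'
#' @param conc Concentration (mg/L, >= 0).
#' @param cohort An [exposure_cohort()].
#' @return ADI (mg/kg-day).
#' @examples
#' adi_ingestion(0.129, exposure_cohort("child"))  # ~7.73e-3
#' @export
adi_ingestion <- function(conc, cohort) {
  stopifnot(inherits(cohort, "exposure_cohort"))
  conc * cohort$IR * cohort$EF * cohort$EP / (cohort$BW * cohort$AT)
}

#' Average daily intake via dermal absorption
#'
#' ADI = C x SA x Kp x ET x EF x EP x CFconv / (BW x AT), in mg/kg-day; the
#' unit conversion factor CFconv (L/cm3) converts the skin-area x permeability
#' product into litres of water contacted.
#'
#' @inheritParams adi_ingestion
#' @param metal Metal id (selects the permeability coefficient Kp).
#' @param registry A [toxicity_registry()].
#' @return ADI (mg/kg-day).
#' @export
adi_dermal <- function(conc, metal, cohort, registry = toxicity_registry()) {
  stopifnot(inherits(cohort, "exposure_cohort"), inherits(registry, "toxicity_registry"))
  if (!metal %in% names(registry$kp)) stop("no Kp entry for metal ", metal)
  conc * cohort$SA * registry$kp[[metal]] * cohort$ET * cohort$EF * cohort$EP *
    cohort$CFconv / (cohort$BW * cohort$AT)
}

#' Hazard quotient
#'
#' HQ = ADI / RfD with ADI in mg/kg-day and the reference dose in ug/kg-day;
#' the mg-to-ug conversion (x1000) is performed here, the single documented
#' unit conversion of the risk chain.
#'
#' @param adi Average daily intake (mg/kg-day).
#' @param rfd Toxic reference dose (ug/kg-day, > 0).
#' @return HQ (dimensionless); HQ < 1 is deemed safe.
#' @export
hazard_quotient <- function(adi, rfd) {
  if (any(rfd <= 0)) stop("RfD must be positive")
  (adi * 1000) / rfd
}

#' Hazard index
#'
#' Total noncarcinogenic risk: the sum of ingestion and dermal hazard
#' quotients over metals. HI < 1 is acceptable.
#'
#' @param hq Numeric vector of hazard quotients (ingestion and dermal terms).
#' @return List with `hi` and `label` (`"acceptable"` iff HI < 1).
#' @export
hazard_index <- function(hq) {
  hi <- sum(hq, na.rm = TRUE)
  list(hi = hi, label = if (hi < 1) "acceptable" else "exceeds limit")
}

#' Carcinogenic risk of one metal for one cohort
#'
#' CRI = ADI_ing x CSF, CRD = ADI_der x CSF, CR = CRI + CRD. Copper has no
#' cancer slope factor and yields `NA` components.
#'
#' @inheritParams adi_dermal
#' @return List with `cri`, `crd`, `cr` and `label` (`"acceptable"` iff
#'   CR < 1e-6, the single-element threshold; the multi-element total is
#'   compared to 1e-4 downstream).
#' @examples
#' carcinogenic_risk(0.129, "Cd", exposure_cohort("child"))$cr  # ~4.72e-2
#' @export
carcinogenic_risk <- function(conc, metal, cohort, registry = toxicity_registry()) {
  if (!metal %in% names(registry$csf))
    return(list(cri = NA_real_, crd = NA_real_, cr = NA_real_, label = "no slope factor"))
  csf <- registry$csf[[metal]]
  cri <- adi_ingestion(conc, cohort) * csf
  crd <- adi_dermal(conc, metal, cohort, registry) * csf
  cr <- cri + crd
  list(cri = cri, crd = crd, cr = cr,
       label = if (cr < 1e-6) "acceptable" else "exceeds 1e-6")
}

#' Health risk assessment for every station and cohort
#'
#' Long-format USEPA-style exposure assessment: per station x cohort x metal
#' rows with ingestion/dermal average daily intakes (mg/kg-day), hazard
#' quotients, and carcinogenic risk components; per station x cohort totals
#' (hazard index HI, total carcinogenic risk) as attribute `"totals"`.
#'
#' @param samples A [sample_table()].
#' @param cohorts Named list of [exposure_cohort()]s (default
#'   [default_cohorts()]).
#' @param registry A [toxicity_registry()].
#' @return Data frame (class `healthrisk_result`) with columns `station_id`,
#'   `cohort`, `metal`, `ADI_ing`, `ADI_der`, `HQ_ing`, `HQ_der`, `CRI`,
#'   `CRD`, `CR`. Attribute `"totals"`: data frame with `HI`, `HI_label`,
#'   `CR_total`, `CR_label` (total compared to the 1e-4 multi-element
#'   threshold).
#' @export
health_risk <- function(samples, cohorts = default_cohorts(),
                        registry = toxicity_registry()) {
  stopifnot(inherits(samples, "sample_table"))
  metals <- intersect(metal_catalogue(), names(samples))
  if (length(metals) == 0) stop("samples contain no metal columns")
  st <- samples[samples$metals_measured, , drop = FALSE]
  rows <- list(); totals <- list()
  for (co_name in names(cohorts)) {
    co <- cohorts[[co_name]]
    for (i in seq_len(nrow(st))) {
      hq_all <- c()
      cr_all <- c()
      for (m in metals) {
        v <- st[[m]][i]
        if (is.na(v)) next
        a_ing <- adi_ingestion(v, co)
        a_der <- adi_dermal(v, m, co, registry)
        hq_i <- hazard_quotient(a_ing, registry$rfd_ing[[m]])
        hq_d <- hazard_quotient(a_der, registry$rfd_der[[m]])
        cr <- carcinogenic_risk(v, m, co, registry)
        rows[[length(rows) + 1]] <- data.frame(
          station_id = st$station_id[i], cohort = co_name, metal = m,
          ADI_ing = a_ing, ADI_der = a_der, HQ_ing = hq_i, HQ_der = hq_d,
          CRI = cr$cri, CRD = cr$crd, CR = cr$cr, stringsAsFactors = FALSE)
        hq_all <- c(hq_all, hq_i, hq_d)
        if (!is.na(cr$cr)) cr_all <- c(cr_all, cr$cr)
      }
      hi <- hazard_index(hq_all)
      cr_tot <- sum(cr_all)
      totals[[length(totals) + 1]] <- data.frame(
        station_id = st$station_id[i], cohort = co_name,
        HI = hi$hi, HI_label = hi$label, CR_total = cr_tot,
        CR_label = if (cr_tot < 1e-4) "acceptable" else "exceeds 1e-4",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "totals") <- do.call(rbind, totals)
  structure(out, class = c("healthrisk_result", "data.frame"))
}
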