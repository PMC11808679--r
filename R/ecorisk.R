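# Hakanson-style potential ecological risk.

#' Ecological risk of an individual metal
#'
#' ERI = TRF x C / Si, the toxic response factor times the ratio of the
#' measured concentration to the metal's reference standard.
#'
#' @param conc Concentration (mg/L, >= 0).
#' @param metal Metal id (`"Cd"`, `"Cu"`, `"Ni"`, `"Pb"`).
#' @param registry A [toxicity_registry()].
#' @return ERI (dimensionless).
#' @examples
#' eri(0.129, "Cd")  # 30 * 0.129 / 0.003 = 1290
#' eri(0.271, "Pb")  # 5 * 0.271 / 0.01 = 135.5
#' @export
eri <- function(conc, metal, registry = toxicity_registry()) {
  stopifnot(inherits(registry, "toxicity_registry"))
  if (!metal %in% names(registry$trf) || !metal %in% names(registry$eri_si))
    stop("no TRF/Si entry for metal ", metal)
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  registry$trf[[metal]] * conc / registry$eri_si[[metal]]
}

#' Potential ecological risk: the sum of per-metal ERI values
#' @param eri_values Numeric vector of ERI values (length >= 1; NAs dropped).
#' @return PER.
#' @export
per_index <- function(eri_values) {
  if (length(eri_values) == 0) stop("empty ERI vector")
  sum(eri_values, na.rm = TRUE)
}

#' Classify a per-metal ecological risk value
#'
#' Half-open bounds: low < 40, moderate 40--80, considerable 80--160,
#' high 160--320, very high >= 320 (a value on a boundary takes the upper
#' class).
#'
#' @param value ERI value (>= 0).
#' @return Label.
#' @export
classify_eri <- function(value) {
  labs <- c("low", "moderate", "considerable", "high", "very high")
  labs[findInterval(value, c(40, 80, 160, 320)) + 1]
}

#' Classify a potential ecological risk value
#'
#' low < 150, medium 150--300, considerable 300--600, extreme >= 600.
#'
#' @param value PER value (>= 0).
#' @return Label.
#' @export
classify_per <- function(value) {
  labs <- c("low", "medium", "considerable", "extreme")
  labs[findInterval(value, c(150, 300, 600)) + 1]
}

#' Ecological risk for every station of a sample table
#'
#' Per-metal ERI and total PER with class labels, for stations with metal
#' data.
#'
#' @param samples A [sample_table()].
#' @param registry A [toxicity_registry()].
#' @return Data frame (class `ecorisk_result`): columns `ERI_<metal>`,
#'   `ERI_<metal>_class`, `PER`, `PER_class` per station with metals
#'   measured.
#' @export
ecological_risk <- function(samples, registry = toxicity_registry()) {
  stopifnot(inherits(samples, "sample_table"))
  metals <- intersect(metal_catalogue(), names(samples))
  if (length(metals) == 0) stop("samples contain no metal columns")
  keep <- samples$metals_measured
  st <- samples[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(st)), function(i) {
    ev <- vapply(metals, function(m) {
      v <- st[[m]][i]
      if (is.na(v)) NA_real_ else eri(v, m, registry)
    }, numeric(1))
    out <- data.frame(station_id = st$station_id[i], stringsAsFactors = FALSE)
    for (m in metals) {
      out[[paste0("ERI_", m)]] <- ev[[m]]
      out[[paste0("ERI_", m, "_class")]] <-
        if (is.na(ev[[m]])) NA_character_ else classify_eri(ev[[m]])
    }
    out$PER <- per_index(ev)
    out$PER_class <- classify_per(out$PER)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ecorisk_result", "data.frame"))
}
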