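# Weighted-arithmetic water quality index.

#' Quality rating of one parameter
#'
#' Qi = 100 x |Vm - Vi| / |Vs - Vi|, the measured value's distance from the
#' ideal as a percentage of the standard's distance from the ideal. The
#' absolute-value form keeps sub-ideal pH from producing negative ratings.
#' The ideal value Vi is 0 for every parameter except pH (Vi = 7).
#'
#' @param vm Measured value.
#' @param vs Standard value (scalar).
#' @param vi Ideal value (default 0).
#' @return Qi (>= 0; 100 when the measurement sits exactly at the standard).
#' @examples
#' quality_rating(8.2, 8.5, 7)  # 80
#' @export
quality_rating <- function(vm, vs, vi = 0) {
  if (any(vs == vi)) stop("standard and ideal value must differ")
  100 * abs(vm - vi) / abs(vs - vi)
}

#' Relative weight of one parameter
#'
#' Wi = 1 / Vs: parameters with stringent standards weigh more.
#'
#' @param vs Standard value (> 0).
#' @return Wi.
#' @export
relative_weight <- function(vs) {
  if (any(vs <= 0)) stop("standard must be positive")
  1 / vs
}

# Vs per parameter for WQI: scalar standards as-is; interval standards use
# the bound farther from the ideal value (pH -> 8.5, alkalinity -> 600).
.wqi_vs <- function(registry, parameter, vi) {
  s <- standard_value(registry, parameter)
  if (all(is.na(s))) return(NA_real_)
  if (length(s) == 2) s[which.max(abs(s - vi))] else s
}

.wqi_grade <- function(value) {
  # contiguous half-open closure of the printed 0-25 / 26-50 / ... bounds
  g <- findInterval(value, c(0, 25, 50, 75, 100), left.open = TRUE) + 0
  g[value == 0] <- 1
  labs <- c("Excellent", "Good", "Poor", "Very poor", "Unsuitable")
  list(grade = as.integer(g), label = labs[g])
}

#' Weighted-arithmetic water quality index per station
#'
#' WQI = sum(Wi Qi) / sum(Wi) over the parameters carrying a standard in the
#' chosen registry (default WHO; ORP and any parameter without a standard
#' are excluded). Graded Excellent (0, 25], Good (25, 50], Poor (50, 75],
#' Very poor (75, 100], Unsuitable (> 100).
#'
#' @param samples A [sample_table()].
#' @param registry A [guideline_registry()]; default WHO, the conventional
#'   Vs source for this index.
#' @param ideal Named vector of ideal values; default 0 everywhere except
#'   pH = 7.
#' @return Data frame (class `wqi_result`): `station_id`, `WQI`, `grade`
#'   (1--5), `label`. Per-parameter Qi and Wi matrices are attached as
#'   attributes `"qi"` and `"wi"`.
#' @export
water_quality_index <- function(samples, registry = guideline_registry("WHO"),
                                ideal = c(pH = 7)) {
  stopifnot(inherits(samples, "sample_table"))
  pars <- intersect(parameter_catalogue(), names(samples))
  vi <- stats::setNames(rep(0, length(pars)), pars)
  vi[names(ideal)[names(ideal) %in% pars]] <- ideal[names(ideal) %in% pars]
  vs <- vapply(pars, function(p) .wqi_vs(registry, p, vi[[p]]), numeric(1))
  usable <- pars[!is.na(vs) & vs != vi[pars]]
  if (length(usable) == 0) stop("no parameter carries a usable standard")
  wi <- vapply(usable, function(p) relative_weight(vs[[p]]), numeric(1))
  qi <- sapply(usable, function(p) quality_rating(samples[[p]], vs[[p]], vi[[p]]))
  qi <- matrix(qi, nrow = nrow(samples), dimnames = list(samples$station_id, usable))
  wqi_vals <- vapply(seq_len(nrow(samples)), function(i) {
    ok <- !is.na(qi[i, ])
    if (!any(ok)) return(NA_real_)
    sum(wi[ok] * qi[i, ok]) / sum(wi[ok])
  }, numeric(1))
  gr <- .wqi_grade(wqi_vals)
  out <- data.frame(station_id = samples$station_id, WQI = wqi_vals,
                    grade = gr$grade, label = gr$label, stringsAsFactors = FALSE)
  attr(out, "qi") <- qi
  attr(out, "wi") <- wi
  structure(out, class = c("wqi_result", "data.frame"))
}

#' Distribution of water-quality grades
#'
#' @param wqi_values Numeric vector of WQI values.
#' @return Data frame with `label` and `percent` per grade class.
#' @examples
#' grade_distribution(c(10, 30))  # 50 % Excellent, 50 % Good
#' @export
grade_distribution <- function(wqi_values) {
  if (length(wqi_values) == 0) stop("empty WQI vector")
  gr <- .wqi_grade(wqi_values)
  labs <- c("Excellent", "Good", "Poor", "Very poor", "Unsuitable")
  pct <- 100 * vapply(labs, function(l) mean(gr$label == l), numeric(1))
  data.frame(label = labs, percent = unname(pct), stringsAsFactors = FALSE)
}
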