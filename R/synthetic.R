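# Synthetic groundwater-chemistry generator.
#
# Emulates the statistical structure of coastal shallow-aquifer chemistry:
# right-skewed (lognormal) solute marginals, a near-collinear salinity block
# (EC, TDS, salinity, NaCl, Cl, TH, turbidity, Ca) correlated on the log
# scale, TDS a fixed fraction of EC, slightly alkaline pH, negative ORP, and
# weakly coupled heavy metals with occasional exceedance spikes.

# Per-parameter target mean/SD for the lognormal marginals (canonical units).
.synth_targets <- function() {
  data.frame(
    parameter = c("alkalinity", "free_CO2", "EC", "salinity", "TH", "turbidity",
                  "NaCl", "Ca", "Cl", "Cd", "Cu", "Ni", "Pb"),
    mean = c(452.1, 8.85, 1522, 0.52, 151.9, 1.17, 472.6, 60.78, 472.6,
             0.026, 0.008, 0.084, 0.213),
    sd   = c(43.5, 2.86, 946.8, 0.50, 128.1, 1.55, 459.7, 50.88, 278.6,
             0.038, 0.005, 0.089, 0.055),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic sample generator
#'
#' @param n_stations Number of stations (default 20, the study design size).
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)` for
#'   uniform station placement (default a ~0.05 x 0.12 degree coastal block).
#' @param rho Pairwise log-scale correlation within the salinity block
#'   (EC, salinity, TH, turbidity, NaCl, Ca, Cl); default 0.95. Must satisfy
#'   `0 <= rho < 1` so the implied equicorrelation matrix is positive
#'   definite.
#' @param targets Data frame `parameter, mean, sd` of marginal targets
#'   (defaults emulate brackish coastal groundwater; see the methods
#'   vignette).
#' @param tds_fraction TDS is generated as `tds_fraction * EC` times a small
#'   lognormal noise term (default 0.6386, the typical ionic TDS/EC ratio).
#' @param tds_log_sd Log-scale SD of the TDS noise term (default 0.02).
#' @param ph_band pH is uniform on this band (default `c(7.24, 8.2)`).
#' @param orp_mean,orp_sd ORP is normal with these moments (default -42.13,
#'   10.62) and clamped below zero.
#' @param exceedance_prob Per-metal probability of an exceedance spike
#'   (default 0.05, i.e. about one hotspot station in twenty).
#' @param spike_factor Named multiplier applied to a spiked metal draw
#'   (defaults scale each metal toward its observed maximum).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_stations = 20,
                         bbox = c(90.18, 90.23, 22.63, 22.75),
                         rho = 0.95,
                         targets = .synth_targets(),
                         tds_fraction = 0.6386,
                         tds_log_sd = 0.02,
                         ph_band = c(7.24, 8.2),
                         orp_mean = -42.13, orp_sd = 10.62,
                         exceedance_prob = 0.05,
                         spike_factor = c(Cd = 5, Cu = 2, Ni = 2.5, Pb = 1.3)) {
  stopifnot(n_stations >= 4, rho >= 0, rho < 1, length(bbox) == 4,
            bbox[1] < bbox[2], bbox[3] < bbox[4],
            tds_fraction > 0, tds_log_sd > 0, ph_band[1] < ph_band[2],
            orp_sd > 0, exceedance_prob >= 0, exceedance_prob <= 1,
            all(spike_factor > 0))
  if (any(targets$mean <= 0) || any(targets$sd <= 0))
    stop("all marginal target means and SDs must be positive")
  structure(list(n_stations = n_stations, bbox = bbox, rho = rho,
                 targets = targets, tds_fraction = tds_fraction,
                 tds_log_sd = tds_log_sd, ph_band = ph_band,
                 orp_mean = orp_mean, orp_sd = orp_sd,
                 exceedance_prob = exceedance_prob, spike_factor = spike_factor),
            class = "synth_config")
}

# Moment-matched lognormal parameters: if X ~ LN(mu, sigma) has mean m, sd s
# then sigma^2 = log(1 + s^2/m^2), mu = log(m) - sigma^2/2.
.lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a synthetic sample table
#'
#' Deterministic given `seed`. The salinity block is drawn from a
#' multivariate lognormal with pairwise correlation `rho` on the log scale
#' (equicorrelation, sampled via the Cholesky factor); TDS is a fixed
#' fraction of EC plus lognormal noise; pH is uniform in its band; ORP is
#' negative; metals are lognormal with configured exceedance spikes;
#' coordinates are uniform in the bounding box.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @return A [sample_table()].
#' @examples
#' s <- generate_samples(synth_config(), seed = 1)
#' cor(log(s$EC), log(s$TDS))  # > 0.9 by construction
#' @export
generate_samples <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  block_pars <- c("EC", "salinity", "TH", "turbidity", "NaCl", "Ca", "Cl")
  indep_pars <- c("alkalinity", "free_CO2")
  metals <- metal_catalogue()
  tg <- config$targets
  rownames(tg) <- tg$parameter
  missing <- setdiff(c(block_pars, indep_pars, metals), tg$parameter)
  if (length(missing)) stop("targets missing for: ", paste(missing, collapse = ", "))

  n <- config$n_stations
  b <- length(block_pars)
  R <- matrix(config$rho, b, b); diag(R) <- 1
  L <- tryCatch(chol(R), error = function(e)
    stop("implied correlation matrix is not positive definite"))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  z <- matrix(stats::rnorm(n * b), n, b) %*% L
  block <- sapply(seq_len(b), function(j) {
    p <- .lnorm_params(tg[block_pars[j], "mean"], tg[block_pars[j], "sd"])
    exp(p$mu + p$sigma * z[, j])
  })
  colnames(block) <- block_pars

  indep <- sapply(indep_pars, function(pp) {
    p <- .lnorm_params(tg[pp, "mean"], tg[pp, "sd"])
    stats::rlnorm(n, p$mu, p$sigma)
  })

  met <- sapply(metals, function(mm) {
    p <- .lnorm_params(tg[mm, "mean"], tg[mm, "sd"])
    v <- stats::rlnorm(n, p$mu, p$sigma)
    spike <- stats::runif(n) < config$exceedance_prob
    v[spike] <- v[spike] * config$spike_factor[[mm]]
    v
  })

  df <- data.frame(
    station_id = sprintf("SY-%02d", seq_len(n)),
    longitude = stats::runif(n, config$bbox[1], config$bbox[2]),
    latitude = stats::runif(n, config$bbox[3], config$bbox[4]),
    pH = stats::runif(n, config$ph_band[1], config$ph_band[2]),
    ORP = pmin(stats::rnorm(n, config$orp_mean, config$orp_sd), -0.1),
    TDS = config$tds_fraction * block[, "EC"] *
      stats::rlnorm(n, -config$tds_log_sd^2 / 2, config$tds_log_sd)
  )
  df <- cbind(df, as.data.frame(block), as.data.frame(indep), as.data.frame(met))
  sample_table(df)
}
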