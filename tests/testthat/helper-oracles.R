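# Brute-force oracles, kept independent of the package implementation.

# Two-pass descriptive statistics.
oracle_describe <- function(v) {
  v <- v[!is.na(v)]
  m <- sum(v) / length(v)
  list(n = length(v), min = min(v), max = max(v), mean = m,
       sd = sqrt(sum((v - m)^2) / (length(v) - 1)))
}

# Contamination indices recomputed with explicit loops.
oracle_indices <- function(cf) {
  s <- 0; p <- 1; mx <- -Inf
  for (x in cf) { s <- s + x; p <- p * max(x, 1e-6); mx <- max(mx, x) }
  mean_cf <- s / length(cf)
  list(tci = s, mci = mean_cf, pli = p^(1 / length(cf)),
       npi = sqrt((mx^2 + mean_cf^2) / 2))
}

# Exposure chain evaluated term by term.
oracle_cr <- function(conc, IR, EF, EP, BW, SA, Kp, ET, CFconv, csf) {
  AT <- EP * 365
  adi_i <- conc * IR * EF * EP / (BW * AT)
  adi_d <- conc * SA * Kp * ET * EF * EP * CFconv / (BW * AT)
  list(adi_i = adi_i, adi_d = adi_d, cr = (adi_i + adi_d) * csf)
}

# Weighted-mean WQI from first principles.
oracle_wqi <- function(vm, vs, vi) {
  qi <- 100 * abs(vm - vi) / abs(vs - vi)
  wi <- 1 / vs
  sum(wi * qi) / sum(wi)
}

# A tiny deterministic sample table used across tests.
tiny_samples <- function() {
  sample_table(data.frame(
    station_id = c("A", "B", "C", "D"),
    longitude = c(90.19, 90.20, 90.21, 90.22),
    latitude = c(22.65, 22.67, 22.70, 22.72),
    pH = c(7.3, 7.8, 8.1, 7.5),
    EC = c(800, 1500, 3000, 1200),
    TDS = c(500, 950, 1900, 760),
    Cd = c(0.002, 0.02, NA, 0.004),
    Pb = c(0.05, 0.2, NA, 0.1)
  ))
}
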