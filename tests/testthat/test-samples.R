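test_that("CSV load is an identity for canonical units and converts declared ones", {
  s <- generate_samples(synth_config(), seed = 11)
  f <- tempfile(fileext = ".csv")
  write_samples(s, f)
  s2 <- load_samples(f)
  expect_equal(nrow(s2), 20)
  expect_equal(s2$EC, s$EC, tolerance = 1e-12)
  expect_equal(s2$Cd, s$Cd, tolerance = 1e-12)

  # declared ug/L divides into mg/L
  raw <- utils::read.csv(f, check.names = FALSE)
  raw$Cd <- raw$Cd * 1000
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(raw, f2, row.names = FALSE, na = "")
  s3 <- load_samples(f2, unit_map = c(Cd = "ug/L"))
  expect_equal(s3$Cd, s$Cd, tolerance = 1e-9)
})

test_that("loader rejects duplicates, negatives and unknown parameters", {
  df <- data.frame(station_id = c("A", "A"), pH = c(7, 7.5))
  expect_error(sample_table(df), "duplicate")
  df2 <- data.frame(station_id = c("A", "B"), Cd = c(0.01, -0.01))
  expect_error(sample_table(df2), "negative.*Cd.*row 2", ignore.case = TRUE)
  df3 <- data.frame(station_id = "A", arsenic = 1)
  expect_error(sample_table(df3), "unknown parameter")
})

test_that("stations with no metal cells are flagged metals_measured = FALSE", {
  df <- data.frame(station_id = paste0("S", 1:20),
                   pH = rep(7.5, 20),
                   Cd = c(rep(NA, 11), runif(9, 0.001, 0.1)),
                   Cu = c(rep(NA, 11), runif(9, 0.001, 0.01)),
                   Ni = c(rep(NA, 11), runif(9, 0.01, 0.2)),
                   Pb = c(rep(NA, 11), runif(9, 0.05, 0.25)))
  s <- sample_table(df)
  expect_identical(sum(s$metals_measured), 9L)
  expect_false(any(s$metals_measured[1:11]))
})

test_that("describe matches a two-pass oracle and the back-derived Cd series", {
  # Cd concentrations implied by the printed per-metal ecological risks
  t4 <- paper_fixture("table4")
  cd <- t4$Cd * 0.003 / 30
  expect_equal(sort(cd)[1:2], c(0.006, 0.009))
  s <- sample_table(data.frame(station_id = t4$station_id, Cd = cd))
  d <- describe(s)
  row <- d[d$parameter == "Cd", ]
  o <- oracle_describe(cd)
  expect_equal(row$min, 0.006)
  expect_equal(row$max, 0.129)
  expect_equal(row$mean, o$mean)
  expect_equal(row$sd, o$sd)
  expect_equal(row$mean, 0.0264, tolerance = 2e-3)
  expect_equal(row$sd, 0.0387, tolerance = 2e-3)

  # permutation invariance on random tables
  set.seed(42)
  for (i in 1:5) {
    v <- rlnorm(30, 2, 1)
    s1 <- sample_table(data.frame(station_id = paste0("x", 1:30), TDS = v))
    s2 <- sample_table(data.frame(station_id = paste0("x", 1:30), TDS = sample(v)))
    expect_equal(describe(s1)$mean, describe(s2)$mean)
    expect_equal(describe(s1)$sd, describe(s2)$sd)
  }

  # degenerate cases
  s3 <- sample_table(data.frame(station_id = c("a", "b", "c"), TH = c(5, 5, 5)))
  d3 <- describe(s3)
  expect_equal(d3$mean[d3$parameter == "TH"], 5)
  expect_equal(d3$sd[d3$parameter == "TH"], 0)
  s4 <- sample_table(data.frame(station_id = c("a", "b"), Cd = c(NA_real_, NA_real_)))
  d4 <- describe(s4)
  expect_equal(d4$n[d4$parameter == "Cd"], 0L)
  expect_true(is.na(d4$mean[d4$parameter == "Cd"]))
})

test_that("compliance counts values inside scalar and interval standards", {
  ph <- runif(20, 6.6, 8.4)
  s <- sample_table(data.frame(station_id = paste0("S", 1:20), pH = ph))
  cp <- compliance(s)
  expect_equal(unname(unlist(cp[cp$parameter == "pH", c("WHO", "USEPA", "ISDW", "BDWS")])),
               c(100, 100, 100, 100))

  th <- c(rep(100, 19), 600)  # exactly 19/20 under the BDWS interval
  s2 <- sample_table(data.frame(station_id = paste0("S", 1:20), TH = th))
  cp2 <- compliance(s2)
  expect_equal(cp2[cp2$parameter == "TH", "BDWS"], 0)  # 100 falls below the interval
  th3 <- c(rep(300, 19), 600)
  s3 <- sample_table(data.frame(station_id = paste0("S", 1:20), TH = th3))
  cp3 <- compliance(s3)
  expect_equal(cp3[cp3$parameter == "TH", "BDWS"], 95)

  # 10 of 20 above a scalar limit -> 50 %
  tds <- c(rep(400, 10), rep(600, 10))
  s4 <- sample_table(data.frame(station_id = paste0("S", 1:20), TDS = tds))
  cp4 <- compliance(s4)
  expect_equal(cp4[cp4$parameter == "TDS", "USEPA"], 50)

  # tightening a scalar limit never increases compliance
  v <- rlnorm(50, 5, 1)
  s5 <- sample_table(data.frame(station_id = paste0("S", 1:50), TDS = v))
  lims <- sort(rlnorm(10, 5, 1))
  pcts <- vapply(lims, function(L) {
    reg <- guideline_registry("custom", custom = list(TDS = L))
    cpL <- compliance(s5, registries = list(reg), digits = 6)
    cpL[cpL$parameter == "TDS", "custom"]
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("authorities without a standard are excluded from the per-parameter mean", {
  s <- sample_table(data.frame(station_id = c("a", "b"), Ni = c(0.01, 0.05)))
  cp <- compliance(s)
  row <- cp[cp$parameter == "Ni", ]
  expect_true(is.na(row$USEPA))  # no Ni standard there
  expect_equal(row$mean_pct, round(mean(c(row$WHO, row$ISDW, row$BDWS))))
})
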