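test_that("contamination factor is the measured/standard ratio", {
  expect_equal(contamination_factor(0.129, 0.005), 25.8)
  expect_equal(contamination_factor(5, 5), 1)
  expect_equal(contamination_factor(0, 3), 0)
  expect_equal(contamination_factor(9, c(6.5, 8.5)), 9 / 8.5)  # interval -> upper bound
  expect_error(contamination_factor(1, 0))
  expect_error(contamination_factor(-1, 1))
})

test_that("TCI, MCI, PLI and NPI agree with hand values and the loop oracle", {
  expect_equal(tci(rep(1, 15)), 15)
  expect_equal(mci(rep(1, 15)), 1)
  expect_equal(mci(numeric(15) + 36.57 / 15), 2.438, tolerance = 1e-3)
  expect_equal(round(36.57 / 15, 2), 2.44)
  expect_equal(pli(c(4, 1)), 2)
  expect_equal(pli(c(0.5, 2, 1)), 1)
  expect_equal(pli(rep(1, 15)), 1)
  expect_equal(npi(c(3)), 3)
  expect_equal(npi(rep(1, 4)), 1)
  # max/mean pair consistent with a published row: CFmax 5.17, CFmean 2.438
  cf <- c(5.17, rep((15 * 2.438 - 5.17) / 14, 14))
  expect_equal(npi(cf), 4.04, tolerance = 5e-3)

  set.seed(101)
  for (i in 1:20) {
    cf <- runif(sample(2:6, 1), 0, 8)
    o <- oracle_indices(cf)
    expect_equal(tci(cf), o$tci)
    expect_equal(mci(cf), o$mci)
    expect_equal(suppressWarnings(pli(cf)), o$pli, tolerance = 1e-10)
    expect_equal(npi(cf), o$npi)
  }
})

test_that("MPI sums concentration/limit ratios and handles missing metals", {
  expect_equal(mpi(c(Cd = 0.005, Cu = 1, Ni = 0.1, Pb = 0.05)), 4)
  expect_equal(mpi(c(Cd = 0.01, Cu = 0, Ni = 0, Pb = 0)), 2)
  expect_true(is.na(mpi(c(Cd = NA, Cu = NA, Ni = NA, Pb = NA))))
  expect_warning(v <- mpi(c(Cd = 0.01, Cu = NA, Ni = NA, Pb = NA)), "partial")
  expect_equal(v, 2)
})

test_that("rubric classification matches the published class/weight pairs", {
  expect_equal(classify_index(7.08, "TCI"), list(label = "low", aw = 2L))
  expect_equal(classify_index(1.67, "PLI"), list(label = "high", aw = 4L))
  expect_equal(classify_index(0.99, "NPI"), list(label = "very low", aw = 1L))
  # boundary values take the upper class
  expect_equal(classify_index(8, "TCI")$label, "medium")
  expect_equal(classify_index(NA, "MPI"), list(label = "not assessed", aw = 0L))
})

test_that("every published contamination row classifies to its printed label", {
  t3 <- paper_fixture("table3")
  rub <- default_rubric()
  for (idx in c("TCI", "MCI", "PLI", "NPI")) {
    for (i in seq_len(nrow(t3))) {
      # a 2-decimal printed value sitting exactly on a class boundary is
      # ambiguous (the unrounded value may fall either side); skip those
      if (t3[[idx]][i] %in% rub[[idx]]$lower) next
      cl <- classify_index(t3[[idx]][i], idx)
      expect_equal(cl$label, t3[[paste0(idx, "_class")]][i],
                   label = sprintf("%s label at %s", idx, t3$station_id[i]))
      expect_equal(cl$aw, as.integer(t3[[paste0(idx, "_aw")]][i]),
                   label = sprintf("%s Aw at %s", idx, t3$station_id[i]))
    }
  }
  # TCI = 15 * MCI on every printed row, at 2-decimal rounding
  expect_true(all(abs(t3$TCI / 15 - t3$MCI) <= 0.005 + 1e-9))
})

test_that("WCI aggregates arbitrary weights into [0, 1]", {
  expect_equal(wci(c(5, 5, 5, 5, 5)), list(wci = 1, label = "very high"))
  expect_equal(wci(c(1, 1, 1, 1, 1))$wci, 0.2)
  expect_equal(wci(c(1, 1, 1, 1, 1))$label, "medium")
  expect_equal(wci(c(2, 1, 2, 2, 0))$wci, 0.35)  # four active indices
  expect_equal(wci(c(0, 0, 0, 0, 0))$label, "not assessed")
  # pluggable aggregator
  expect_equal(wci(c(2, 2, 2, 2, 2), aggregator = function(a) sum(a) / 25)$wci, 0.4)
})

test_that("station-level indices are scale-invariant and monotone", {
  s <- generate_samples(synth_config(), seed = 3)
  std <- cf_standards()
  r1 <- suppressWarnings(contamination_indices(s, standards = std))
  k <- 3.7
  s2 <- s
  for (p in names(std)) if (p %in% names(s2)) s2[[p]] <- s2[[p]] * k
  class(s2) <- class(s)
  r2 <- suppressWarnings(contamination_indices(s2, standards = std * k,
                                               cmax = c(Cd = 0.005, Cu = 1, Ni = 0.1, Pb = 0.05) * k))
  for (idx in c("TCI", "MCI", "PLI", "NPI", "MPI"))
    expect_equal(r2[[idx]], r1[[idx]], tolerance = 1e-10)

  # raising one concentration never lowers any index
  s3 <- s
  s3$Pb <- s3$Pb * 2
  class(s3) <- class(s)
  r3 <- suppressWarnings(contamination_indices(s3, standards = std))
  for (idx in c("TCI", "MCI", "NPI", "MPI"))
    expect_true(all(r3[[idx]] >= r1[[idx]] - 1e-12))

  # AM-GM: the geometric mean never exceeds the arithmetic mean
  expect_true(all(r1$PLI <= r1$MCI + 1e-12))
  # Nemerow bounds: CFmax/sqrt(2) <= NPI <= CFmax
  cfm <- attr(r1, "cf")
  cfmax <- apply(cfm, 1, max)
  expect_true(all(r1$NPI >= cfmax / sqrt(2) - 1e-12))
  expect_true(all(r1$NPI <= cfmax + 1e-12))
})

test_that("stations without metal data get the printed MPI convention", {
  df <- data.frame(station_id = c("m", "n"), pH = c(7.5, 7.6),
                   TDS = c(900, 1000), Cd = c(0.02, NA), Cu = c(0.01, NA),
                   Ni = c(0.05, NA), Pb = c(0.1, NA))
  s <- sample_table(df)
  r <- suppressWarnings(contamination_indices(s, standards = cf_standards()[c("pH", "TDS", "Cd", "Cu", "Ni", "Pb")]))
  expect_equal(r$MPI[2], 0)
  expect_equal(r$MPI_class[2], "very low")
  expect_equal(r$MPI_aw[2], 0L)
  expect_gt(r$MPI[1], 0)
})
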