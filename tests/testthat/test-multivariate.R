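test_that("correlation matrix is symmetric, bounded and catches exact relations", {
  s <- generate_samples(synth_config(), seed = 2)
  s$TDS <- 0.64 * s$EC  # exact linear relation
  class(s) <- c("sample_table", "data.frame")
  cm <- correlation_matrix(s)
  expect_equal(cm, t(cm))
  expect_true(all(abs(cm[!is.na(cm)]) <= 1 + 1e-12))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_equal(cm["EC", "TDS"], 1)

  big <- sample_table(data.frame(station_id = paste0("s", 1:1000),
                                 EC = rlnorm(1000), TDS = rlnorm(1000)))
  expect_lt(abs(correlation_matrix(big)["EC", "TDS"]), 0.1)

  anti <- sample_table(data.frame(station_id = c("a", "b", "c"),
                                  ORP = c(-1, -2, -3), EC = c(1, 2, 3)))
  expect_equal(correlation_matrix(anti)["ORP", "EC"], -1)

  const <- sample_table(data.frame(station_id = c("a", "b", "c"),
                                   TH = c(5, 5, 5), EC = c(1, 2, 3)))
  expect_warning(cmc <- correlation_matrix(const), "zero-variance")
  expect_true(is.na(cmc["TH", "EC"]))
})

test_that("PCA explains variance that sums to one, with deterministic signs", {
  s <- generate_samples(synth_config(n_stations = 40), seed = 4)
  p <- pca_analysis(s)
  expect_equal(sum(p$explained), 1)
  expect_true(all(diff(p$explained) <= 1e-12))
  for (j in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }

  # two perfectly correlated variables: PC1 explains everything
  d <- data.frame(station_id = paste0("s", 1:10), EC = 1:10, TDS = 2 * (1:10))
  p2 <- pca_analysis(sample_table(d))
  expect_equal(p2$explained[1], 1)

  # three independent standardized variables at large n: each about 1/3
  set.seed(9)
  d3 <- sample_table(data.frame(station_id = paste0("s", 1:2000),
                                EC = rnorm(2000, 1000, 100),
                                TDS = rnorm(2000, 800, 80),
                                TH = rnorm(2000, 150, 20)))
  p3 <- pca_analysis(d3)
  expect_true(all(abs(p3$explained - 1 / 3) < 0.05))
})

test_that("a high-correlation block dominates PC1 as block eigenvalue theory predicts", {
  # 7 log-correlated variables at rho = 0.95 plus TDS ~ EC: leading
  # eigenvalue of the correlation matrix near 1 + 7 * 0.95 over 16 variables
  s <- generate_samples(synth_config(n_stations = 400), seed = 6)
  logged <- as.data.frame(s)
  for (p in setdiff(parameter_catalogue(), c("pH", "ORP")))
    logged[[p]] <- log(logged[[p]])
  class(logged) <- c("sample_table", "data.frame")
  pc <- pca_analysis(logged)
  expect_gt(pc$explained[1], 0.35)
  expect_lt(pc$explained[1], 0.65)
})

test_that("Ward clustering separates obvious groups deterministically", {
  d <- data.frame(station_id = paste0("s", 1:4), EC = c(0, 1, 10, 11),
                  TDS = c(0, 1, 10, 11))
  s <- sample_table(d)
  cl <- hierarchical_clusters(s, "stations", k = 2)
  expect_equal(unname(cl[1]), unname(cl[2]))
  expect_equal(unname(cl[3]), unname(cl[4]))
  expect_false(cl[[1]] == cl[[3]])

  cl4 <- hierarchical_clusters(s, "stations", k = 4)
  expect_equal(length(unique(cl4)), 4)
  expect_error(hierarchical_clusters(s, "stations", k = 5))

  # permutation invariance up to relabelling
  perm <- c(3, 1, 4, 2)
  s2 <- sample_table(d[perm, ])
  cl2 <- hierarchical_clusters(s2, "stations", k = 2)
  expect_equal(outer(cl[perm], cl[perm], "=="), outer(cl2, cl2, "=="),
               ignore_attr = TRUE)

  # clustering parameters instead of stations
  s3 <- generate_samples(synth_config(), seed = 12)
  clp <- hierarchical_clusters(s3, "parameters", k = 3)
  expect_equal(length(unique(clp)), 3)
})

test_that("IDW is a convex interpolator that honours station nodes", {
  st <- data.frame(longitude = c(0, 1, 0.5), latitude = c(0, 0, 1),
                   value = c(0, 10, 4))
  g <- idw_interpolate(st, cellsize = 0.1, bbox = c(-0.2, 1.2, -0.2, 1.2))
  expect_true(all(g$values >= 0 - 1e-12 & g$values <= 10 + 1e-12))

  # constant field stays constant
  stc <- transform(st, value = 3)
  gc <- idw_interpolate(stc, cellsize = 0.25)
  expect_equal(as.numeric(gc$values), rep(3, length(gc$values)))

  # equidistant cell between two stations is the midpoint for any power
  st2 <- data.frame(longitude = c(-1, 1), latitude = c(0, 0), value = c(0, 10))
  for (p in c(1, 2, 5)) {
    g2 <- idw_interpolate(st2, cellsize = 2, bbox = c(-1, 1, -1, 1), power = p)
    expect_equal(as.numeric(g2$values), 5)
  }

  # hand-computed three-station probe at p = 2
  probe <- function(x, y) {
    d2 <- (x - st$longitude)^2 + (y - st$latitude)^2
    sum(st$value / d2) / sum(1 / d2)
  }
  g3 <- idw_interpolate(st, cellsize = 1, bbox = c(0, 1, 0, 1), power = 2)
  expect_equal(g3$values[1, 1], probe(0.5, 0.5), tolerance = 1e-12)

  # a cell centred on a station takes the station value exactly
  st3 <- data.frame(longitude = 0.5, latitude = 0.5, value = 7)
  g4 <- idw_interpolate(rbind(st, st3), cellsize = 1, bbox = c(0, 1, 0, 1))
  expect_equal(g4$values[1, 1], 7)
})

test_that("ESRI ASCII rasters round-trip their header and values", {
  st <- data.frame(longitude = c(0, 1), latitude = c(0, 1), value = c(1, 9))
  g <- idw_interpolate(st, cellsize = 0.5, bbox = c(0, 1, 0, 1))
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "^ncols 2$")
  expect_match(lines[2], "^nrows 2$")
  expect_match(lines[6], "^NODATA_value")
  vals <- as.matrix(read.table(f, skip = 6))
  expect_equal(unname(vals), unname(g$values), tolerance = 1e-10)
})
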