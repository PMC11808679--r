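# Supporting multivariate statistics (correlation, PCA, Ward clustering)
# and inverse-distance-weighted interpolation onto raster grids.

# Numeric parameter matrix from a sample table.
.param_matrix <- function(samples, parameters = NULL) {
  pars <- intersect(parameter_catalogue(), names(samples))
  if (!is.null(parameters)) pars <- intersect(parameters, pars)
  m <- as.matrix(as.data.frame(samples)[pars])
  rownames(m) <- samples$station_id
  m
}

#' Pearson correlation matrix of water parameters
#'
#' Pairwise-complete Pearson correlations; zero-variance columns yield `NA`
#' entries (flagged with a warning).
#'
#' @param samples A [sample_table()].
#' @param parameters Optional subset of parameters.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(samples, parameters = NULL) {
  m <- .param_matrix(samples, parameters)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs", method = "pearson"))
}

#' Principal component analysis of water parameters
#'
#' Columns are standardized to zero mean and unit variance by default
#' (parameter units differ by orders of magnitude), so the decomposition is
#' of the correlation matrix. Components are ordered by decreasing variance
#' with a deterministic sign convention: each component's largest-magnitude
#' loading is positive.
#'
#' @param samples A [sample_table()].
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @param parameters Optional subset of parameters.
#' @return List (class `pca_result`): `loadings` (parameters x components),
#'   `scores` (stations x components), `explained` (variance fractions,
#'   summing to 1 over all components).
#' @export
pca_analysis <- function(samples, standardize = TRUE, parameters = NULL) {
  m <- .param_matrix(samples, parameters)
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (ncol(m) < 2 || nrow(m) < 3) stop("PCA needs >= 2 complete parameters and >= 3 stations")
  if (ncol(m) > nrow(m))
    warning("more parameters than stations: decomposition is rank-deficient")
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(loadings = loadings, scores = scores,
                 explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", ncol(x$loadings), "components\n")
  cat("Explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained[seq_len(min(5, length(x$explained)))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Agglomerative clustering with Ward linkage on Euclidean distances
#'
#' Clusters either stations or parameters, after per-column standardization
#' (so distances are not dominated by the largest-unit parameter). Uses
#' Ward's criterion (`ward.D2`) on Euclidean distances; tie-breaking follows
#' input order, so the labelling is deterministic.
#'
#' @param samples A [sample_table()].
#' @param axis `"stations"` or `"parameters"`.
#' @param k Number of clusters (1 <= k <= number of items).
#' @param parameters Optional subset of parameters.
#' @return Integer cluster labels named by item, with the `hclust` linkage
#'   record attached as attribute `"linkage"`.
#' @export
hierarchical_clusters <- function(samples, axis = c("stations", "parameters"),
                                  k = 2, parameters = NULL) {
  axis <- match.arg(axis)
  m <- .param_matrix(samples, parameters)
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  m <- scale(m)
  m <- m[, !apply(m, 2, anyNA), drop = FALSE]  # constant columns scale to NaN
  if (axis == "parameters") m <- t(m)
  if (k < 1 || k > nrow(m)) stop("k must be between 1 and the number of items")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "linkage") <- hc
  labels
}

#' Inverse-distance-weighted interpolation onto a raster grid
#'
#' Cell value = sum(wi zi) / sum(wi) with wi = di^-p over all stations
#' (no neighbour cutoff); a cell within `tol` of a station takes that
#' station's value exactly. Coordinates are treated as planar decimal
#' degrees, adequate at sub-degree extents.
#'
#' @param stations Data frame with `longitude`, `latitude` and `value`
#'   columns (or a [sample_table()] plus `parameter`).
#' @param parameter Parameter to interpolate when `stations` is a sample
#'   table.
#' @param cellsize Grid cell size in degrees.
#' @param bbox Optional `c(lon_min, lon_max, lat_min, lat_max)`; default the
#'   station extent padded by one cell.
#' @param power IDW power p > 0 (default 2).
#' @param tol Station-coincidence tolerance in degrees (default 1e-9).
#' @param nodata Value written for cells that cannot be computed.
#' @return Object of class `raster_grid`: list with `values` (matrix,
#'   row 1 = northernmost), `xllcorner`, `yllcorner`, `cellsize`, `ncols`,
#'   `nrows`, `nodata`.
#' @export
idw_interpolate <- function(stations, parameter = NULL, cellsize = 0.005,
                            bbox = NULL, power = 2, tol = 1e-9, nodata = -9999) {
  if (inherits(stations, "sample_table")) {
    if (is.null(parameter)) stop("give 'parameter' when interpolating a sample table")
    stations <- data.frame(longitude = stations$longitude,
                           latitude = stations$latitude,
                           value = stations[[parameter]])
  }
  stations <- stations[stats::complete.cases(stations[c("longitude", "latitude", "value")]), ]
  if (nrow(stations) == 0) stop("no stations with finite coordinates and values")
  if (power <= 0) stop("power must be > 0")
  if (is.null(bbox)) {
    bbox <- c(min(stations$longitude) - cellsize, max(stations$longitude) + cellsize,
              min(stations$latitude) - cellsize, max(stations$latitude) + cellsize)
  }
  ncols <- max(1L, ceiling((bbox[2] - bbox[1]) / cellsize))
  nrows <- max(1L, ceiling((bbox[4] - bbox[3]) / cellsize))
  xs <- bbox[1] + (seq_len(ncols) - 0.5) * cellsize
  ys <- bbox[3] + (seq_len(nrows) - 0.5) * cellsize
  vals <- matrix(NA_real_, nrow = nrows, ncol = ncols)
  for (r in seq_len(nrows)) {
    y <- ys[nrows - r + 1]  # row 1 = top (north)
    dx <- outer(xs, stations$longitude, `-`)
    dy <- y - stations$latitude
    d <- sqrt(sweep(dx^2, 2, dy^2, `+`))
    hit <- d < tol
    w <- d^(-power)
    num <- w %*% stations$value
    den <- rowSums(w)
    row_vals <- as.numeric(num / den)
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      row_vals[idx[, 1]] <- stations$value[idx[, 2]]
    }
    vals[r, ] <- row_vals
  }
  structure(list(values = vals, xllcorner = bbox[1], yllcorner = bbox[3],
                 cellsize = cellsize, ncols = ncols, nrows = nrows,
                 nodata = nodata),
            class = "raster_grid")
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: header lines `ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`, then rows of cell values from the
#' northernmost row down.
#'
#' @param grid A `raster_grid` from [idw_interpolate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncols),
               sprintf("nrows %d", grid$nrows),
               sprintf("xllcorner %.10g", grid$xllcorner),
               sprintf("yllcorner %.10g", grid$yllcorner),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %g", grid$nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
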