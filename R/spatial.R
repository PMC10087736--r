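#' Construct a land/sea grid
#'
#' A regular latitude/longitude grid of cell centers with a boolean sea mask,
#' used for least-cost over-sea geographic distances.
#'
#' @param lat_axis,lon_axis strictly monotone vectors of cell-center
#'   coordinates (degrees).
#' @param mask logical matrix, \code{length(lat_axis)} rows x
#'   \code{length(lon_axis)} columns; \code{TRUE} = sea.
#' @return Object of class \code{sea_grid}.
#' @export
sea_grid <- function(lat_axis, lon_axis, mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (length(lat_axis) < 1 || length(lon_axis) < 1) stop("empty axes")
  if (any(diff(lat_axis) <= 0) && any(diff(lat_axis) >= 0)) {
    stop("lat_axis must be strictly monotone")
  }
  if (any(diff(lon_axis) <= 0) && any(diff(lon_axis) >= 0)) {
    stop("lon_axis must be strictly monotone")
  }
  if (!identical(dim(mask), c(length(lat_axis), length(lon_axis)))) {
    stop("mask must be length(lat_axis) x length(lon_axis)")
  }
  if (!any(mask)) stop("grid has no sea cell")
  structure(list(lat_axis = as.numeric(lat_axis),
                 lon_axis = as.numeric(lon_axis), mask = mask),
            class = "sea_grid")
}

#' @export
print.sea_grid <- function(x, ...) {
  cat(sprintf("sea_grid: %d x %d cells, %.1f%% sea, lat [%g, %g], lon [%g, %g]\n",
              length(x$lat_axis), length(x$lon_axis), 100 * mean(x$mask),
              min(x$lat_axis), max(x$lat_axis),
              min(x$lon_axis), max(x$lon_axis)))
  invisible(x)
}

#' Read / write a sea grid
#'
#' The gridded text format has two header lines, \code{lat: v1 v2 ...} and
#' \code{lon: v1 v2 ...}, followed by a 0/1 matrix (rows = latitudes,
#' 1 = sea). A CSV cell list with columns \code{lat}, \code{lon}, \code{sea}
#' is also accepted.
#'
#' @param path input file.
#' @return A \code{\link{sea_grid}}.
#' @export
read_sea_grid <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^lat:", first)) {
    lines <- readLines(path)
    lat <- as.numeric(strsplit(sub("^lat:\\s*", "", lines[1]), "\\s+")[[1]])
    lon <- as.numeric(strsplit(sub("^lon:\\s*", "", lines[2]), "\\s+")[[1]])
    rows <- lapply(lines[-(1:2)], function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
    mask <- do.call(rbind, rows) == 1L
    sea_grid(lat, lon, mask)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("lat", "lon", "sea") %in% names(df))) {
      stop("cell-list grid CSV needs columns lat, lon, sea")
    }
    lat <- sort(unique(df$lat))
    lon <- sort(unique(df$lon))
    mask <- matrix(FALSE, length(lat), length(lon))
    mask[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$sea != 0
    sea_grid(lat, lon, mask)
  }
}

#' @rdname read_sea_grid
#' @param grid a \code{\link{sea_grid}}.
#' @export
write_sea_grid <- function(grid, path) {
  stopifnot(inherits(grid, "sea_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("lat:", paste(grid$lat_axis, collapse = " ")), con)
  writeLines(paste("lon:", paste(grid$lon_axis, collapse = " ")), con)
  apply(grid$mask * 1L, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

# haversine distance in km between (lon, lat) points, Earth radius 6371 km
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371)
}

snap_stations_to_cells <- function(stations, grid, max_snap_km = 500) {
  sea_idx <- which(grid$mask, arr.ind = TRUE)
  centers <- cbind(lon = grid$lon_axis[sea_idx[, 2]],
                   lat = grid$lat_axis[sea_idx[, 1]])
  vapply(seq_len(nrow(stations)), function(s) {
    d <- haversine_km(cbind(stations$lon[s], stations$lat[s]), centers)
    k <- which.min(d)
    if (d[k] > max_snap_km) {
      stop("station '", stations$station_id[s], "' is ", round(d[k]),
           " km from the nearest sea cell (limit ", max_snap_km, " km)")
    }
    k  # index into sea_idx rows
  }, integer(1))
}

# igraph over sea cells, 8-connected, haversine edge weights (km)
sea_cell_graph <- function(grid) {
  mask <- grid$mask
  nr <- nrow(mask); nc <- ncol(mask)
  cellid <- matrix(NA_integer_, nr, nc)
  cellid[mask] <- seq_len(sum(mask))
  sea_idx <- which(mask, arr.ind = TRUE)
  centers <- cbind(lon = grid$lon_axis[sea_idx[, 2]],
                   lat = grid$lat_axis[sea_idx[, 1]])
  # offsets covering each undirected neighbour pair once: E, SE, S, SW
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  from <- to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    i2 <- sea_idx[, 1] + di
    j2 <- sea_idx[, 2] + dj
    ok <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    ok[ok] <- mask[cbind(i2[ok], j2[ok])]
    from <- c(from, cellid[sea_idx[ok, , drop = FALSE]])
    to <- c(to, cellid[cbind(i2[ok], j2[ok])])
  }
  w <- haversine_km(centers[from, , drop = FALSE], centers[to, , drop = FALSE])
  g <- igraph::make_empty_graph(n = sum(mask), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(graph = g, centers = centers)
}

#' Least-cost over-sea geographic distance matrix
#'
#' Each station is snapped to its nearest sea cell center; the geographic
#' distance between two stations is the length (km) of the shortest path on
#' the 8-connected sea-cell graph with haversine edge weights (Earth radius
#' 6371 km), i.e. the minimal distance without crossing land. Two stations
#' snapping to the same cell are at distance 0.
#'
#' @param stations station data.frame (see \code{\link{read_stations}}).
#' @param grid a \code{\link{sea_grid}}.
#' @param max_snap_km maximum allowed station-to-cell snapping distance.
#' @return A geographic \code{\link{dist_matrix}} in km.
#' @export
sea_distance_matrix <- function(stations, grid, max_snap_km = 500) {
  stations <- validate_stations(stations)
  stopifnot(inherits(grid, "sea_grid"))
  snap <- snap_stations_to_cells(stations, grid, max_snap_km)
  sg <- sea_cell_graph(grid)
  cells <- unique(snap)  # several stations may share a cell
  du <- igraph::distances(sg$graph, v = cells, to = cells,
                          algorithm = "dijkstra")
  d <- du[match(snap, cells), match(snap, cells)]
  if (any(is.infinite(d))) {
    bad <- which(is.infinite(d), arr.ind = TRUE)[1, ]
    stop("stations '", stations$station_id[bad[1]], "' and '",
         stations$station_id[bad[2]],
         "' lie in disconnected sea components")
  }
  dimnames(d) <- list(stations$station_id, stations$station_id)
  d <- (d + t(d)) / 2  # exact symmetry against fp asymmetry
  dist_matrix(d, "geographic")
}

#' Principal component analysis of station environmental variables
#'
#' Environmental variables are (optionally) normalized, then standardized to
#' zero mean and unit variance, and a PCA is run on the correlation
#' structure. Axes are retained by the Kaiser-Guttman criterion: eigenvalue
#' strictly greater than the mean eigenvalue (which is 1 after
#' standardization). An explicit \code{n_axes} overrides the criterion.
#'
#' @param stations station data.frame with environmental columns.
#' @param normalize \code{"none"} or \code{"log1p"}; \code{log1p} is applied
#'   to \code{log1p_vars} before standardization (useful for right-skewed
#'   nutrient concentrations).
#' @param log1p_vars variables to log1p-transform (default: all, when
#'   \code{normalize = "log1p"}).
#' @param n_axes optional fixed number of leading axes to keep.
#' @return Object of class \code{env_pca}: \code{scores} (station x axis),
#'   \code{eigenvalues}, \code{var_frac}, \code{kept_axes}, \code{loadings}.
#' @export
env_pca <- function(stations, normalize = c("none", "log1p"),
                    log1p_vars = NULL, n_axes = NULL) {
  normalize <- match.arg(normalize)
  stations <- validate_stations(stations)
  env <- env_columns(stations)
  if (nrow(stations) < 3) stop("need at least 3 stations for a PCA")
  if (length(env) < 2) stop("need at least 2 environmental variables")
  x <- as.matrix(stations[env])
  rownames(x) <- stations$station_id
  if (normalize == "log1p") {
    vars <- if (is.null(log1p_vars)) env else log1p_vars
    if (any(x[, vars] < -1)) stop("log1p normalization needs values > -1")
    x[, vars] <- log1p(x[, vars])
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant environmental variable(s): ",
         paste(env[sds == 0], collapse = ", "))
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pca$sdev^2
  # strict inequality, with a relative tolerance so exactly-degenerate
  # spectra (all eigenvalues equal) keep nothing rather than half
  kept <- which(eig > mean(eig) * (1 + 1e-8))
  if (!is.null(n_axes)) {
    kept <- seq_len(n_axes)
  } else if (length(kept) == 0) {
    stop("no axis passes the Kaiser-Guttman criterion (all eigenvalues at or ",
         "below the mean); pass an explicit n_axes")
  }
  structure(list(scores = pca$x, eigenvalues = eig,
                 var_frac = eig / sum(eig), kept_axes = kept,
                 loadings = pca$rotation),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("env_pca: %d stations x %d variables; %d axis(es) kept (%s%% of variance)\n",
              nrow(x$scores), length(x$eigenvalues), length(x$kept_axes),
              paste(sprintf("%.1f", 100 * x$var_frac[x$kept_axes]), collapse = ", ")))
  invisible(x)
}

#' Environmental distance matrix from retained PCA axes
#'
#' Euclidean distance between stations in the space of the retained principal
#' axes. Scores are used as-is: each axis already scales with the square root
#' of its eigenvalue, so axes contribute in proportion to the variance they
#' carry. \code{reweight = TRUE} additionally multiplies each axis by its
#' variance fraction (an alternative, more aggressive weighting).
#'
#' @param pca an \code{\link{env_pca}}.
#' @param reweight apply eigenvalue-fraction reweighting (default FALSE).
#' @return An environmental \code{\link{dist_matrix}} (unitless).
#' @export
env_distance_matrix <- function(pca, reweight = FALSE) {
  stopifnot(inherits(pca, "env_pca"))
  s <- pca$scores[, pca$kept_axes, drop = FALSE]
  if (reweight) s <- sweep(s, 2, pca$var_frac[pca$kept_axes], `*`)
  d <- as.matrix(stats::dist(s))
  dist_matrix(d, "environmental")
}

#' Construct a Lagrangian connectivity set
#'
#' Directed station x station matrices from Lagrangian ocean-transport
#' products: probability of connection (PC) per dispersal horizon (months),
#' and mean connection time (MCT, days). Matrices may be asymmetric.
#'
#' @param pc_by_horizon named list of directed probability matrices, one per
#'   horizon; names are months (default horizons 3, 6, 12).
#' @param mct directed matrix of mean connection times (days, > 0
#'   off-diagonal).
#' @return Object of class \code{connectivity_set}.
#' @export
connectivity_set <- function(pc_by_horizon, mct) {
  mct <- as.matrix(mct)
  labels <- rownames(mct)
  if (is.null(labels) || !identical(labels, colnames(mct))) {
    stop("mct needs identical row/column station labels")
  }
  pc_by_horizon <- lapply(pc_by_horizon, as.matrix)
  for (h in names(pc_by_horizon)) {
    m <- pc_by_horizon[[h]]
    if (!identical(rownames(m), labels) || !identical(colnames(m), labels)) {
      stop("station labels of PC horizon ", h, " do not match the MCT matrix")
    }
    off <- m[row(m) != col(m)]
    if (any(off < 0 | off > 1, na.rm = TRUE)) {
      stop("PC entries must be probabilities in [0, 1]")
    }
  }
  off <- mct[row(mct) != col(mct)]
  if (any(off <= 0, na.rm = TRUE)) stop("off-diagonal MCT entries must be > 0 days")
  structure(list(pc_by_horizon = pc_by_horizon, mct = mct, labels = labels),
            class = "connectivity_set")
}

#' Read a connectivity set from TSV files
#' @param pc_paths named character vector of PC matrix TSVs, names = horizon
#'   months (e.g. \code{c("3" = "pc_3m.tsv", ...)}).
#' @param mct_path MCT matrix TSV.
#' @return A \code{\link{connectivity_set}}.
#' @export
read_connectivity <- function(pc_paths, mct_path) {
  read_m <- function(p) as.matrix(utils::read.table(p, header = TRUE, sep = "\t",
                                                    row.names = 1, check.names = FALSE))
  connectivity_set(lapply(pc_paths, read_m), read_m(mct_path))
}

#' Oceanographic distances from a Lagrangian connectivity set
#'
#' PC: for each directed pair, the probability of connection is averaged
#' arithmetically over the dispersal horizons (integrating seasonal to annual
#' circulation), then symmetrized by taking the maximum of the two directions.
#' MCT: symmetrized by the minimum of the two directions. The PC diagonal is
#' undefined (ignored downstream); the MCT diagonal is 0.
#'
#' @param conn a \code{\link{connectivity_set}}.
#' @return List with elements \code{pc} (kind \code{pc_connectivity}) and
#'   \code{mct} (kind \code{mct}), both \code{\link{dist_matrix}} objects.
#' @export
oceanographic_distances <- function(conn) {
  stopifnot(inherits(conn, "connectivity_set"))
  pc_mean <- Reduce(`+`, conn$pc_by_horizon) / length(conn$pc_by_horizon)
  pc <- pmax(pc_mean, t(pc_mean))
  diag(pc) <- NA_real_
  mct <- pmin(conn$mct, t(conn$mct))
  diag(mct) <- 0
  list(pc = dist_matrix(pc, "pc_connectivity"),
       mct = dist_matrix(mct, "mct"))
}
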