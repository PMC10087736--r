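test_that("sea grid validation and both file formats round-trip", {
  g <- sea_grid(c(10, 11, 12), c(20, 21), matrix(TRUE, 3, 2))
  f <- withr::local_tempfile(fileext = ".txt")
  write_sea_grid(g, f)
  back <- read_sea_grid(f)
  expect_equal(back$lat_axis, g$lat_axis)
  expect_equal(back$mask, g$mask)
  # CSV cell-list flavour
  fc <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(lat = c(10, 11, 12), lon = c(20, 21))
  df$sea <- c(1, 1, 0, 1, 1, 1)
  write.csv(df, fc, row.names = FALSE)
  gc <- read_sea_grid(fc)
  expect_equal(sum(gc$mask), 5)
  expect_error(sea_grid(c(1, 1), c(0, 1), matrix(TRUE, 2, 2)), "monotone")
  expect_error(sea_grid(1:2, 1:2, matrix(FALSE, 2, 2)), "sea")
})

test_that("stations in the same cell are at distance zero", {
  g <- sea_grid(c(0, 1), c(0, 1), matrix(TRUE, 2, 2))
  st <- data.frame(station_id = c("a", "b"), lat = c(0.01, 0.02), lon = c(0.01, 0))
  d <- sea_distance_matrix(st, g)
  expect_equal(d["a", "b"], 0)
})

test_that("adjacent equatorial cells one degree apart are ~111.19 km apart", {
  g <- sea_grid(c(-1, 0, 1), c(0, 1, 2), matrix(TRUE, 3, 3))
  st <- data.frame(station_id = c("a", "b"), lat = c(0, 0), lon = c(0, 1))
  d <- sea_distance_matrix(st, g)
  expect_equal(d["a", "b"], 111.19, tolerance = 1e-4)
  expect_equal(d["a", "b"], oracle_haversine_km(0, 0, 0, 1), tolerance = 1e-9)
})

test_that("paths around a land wall equal the brute-force Dijkstra oracle", {
  mask <- matrix(TRUE, 5, 5)
  mask[2:5, 3] <- FALSE  # wall with one gap at the first row
  g <- sea_grid(seq(40, 44), seq(0, 4), mask)
  st <- data.frame(station_id = c("w", "e"), lat = c(44, 44), lon = c(1, 3))
  d <- sea_distance_matrix(st, g)
  w <- oracle_cell_weights(g)
  idx <- which(g$mask, arr.ind = TRUE)
  cell_of <- function(lat, lon) which(idx[, 1] == match(lat, g$lat_axis) &
                                      idx[, 2] == match(lon, g$lon_axis))
  od <- oracle_dijkstra(w, cell_of(44, 1))
  expect_equal(d["w", "e"], od[cell_of(44, 3)], tolerance = 1e-9)
  expect_gt(d["w", "e"], oracle_haversine_km(44, 1, 44, 3))  # forced detour
})

test_that("disconnected sea components raise an error naming the pair", {
  mask <- matrix(TRUE, 3, 3)
  mask[, 2] <- FALSE  # full wall
  g <- sea_grid(c(0, 1, 2), c(0, 1, 2), mask)
  st <- data.frame(station_id = c("west", "east"), lat = c(1, 1), lon = c(0, 2))
  expect_error(sea_distance_matrix(st, g), "west.*east|east.*west")
})

test_that("grid paths cannot undercut the geodesic beyond one cell diagonal", {
  set.seed(3)
  g <- sea_grid(seq(30, 36), seq(10, 18), matrix(runif(7 * 9) > 0.2, 7, 9))
  cells <- which(g$mask, arr.ind = TRUE)
  pick <- cells[sample(nrow(cells), 5), ]
  st <- data.frame(station_id = paste0("s", 1:5),
                   lat = g$lat_axis[pick[, 1]], lon = g$lon_axis[pick[, 2]])
  d <- sea_distance_matrix(st, g)  # this seed's mask is connected
  diag_km <- oracle_haversine_km(30, 10, 31, 11)
  for (i in 1:4) for (j in (i + 1):5) {
    gc <- oracle_haversine_km(st$lat[i], st$lon[i], st$lat[j], st$lon[j])
    expect_gte(d[i, j], gc - diag_km)
  }
})

test_that("eroding sea to land never shortens any over-sea distance", {
  mask1 <- matrix(TRUE, 5, 5)
  g1 <- sea_grid(seq(40, 44), seq(0, 4), mask1)
  mask2 <- mask1; mask2[2:4, 3] <- FALSE  # partial wall, still connected
  g2 <- sea_grid(seq(40, 44), seq(0, 4), mask2)
  st <- data.frame(station_id = c("a", "b", "c"),
                   lat = c(42, 42, 40), lon = c(0, 4, 2))
  d1 <- sea_distance_matrix(st, g1)
  d2 <- sea_distance_matrix(st, g2)
  expect_true(all(unclass(d2) >= unclass(d1) - 1e-9))
})

test_that("Kaiser-Guttman retention keeps axes above the mean eigenvalue", {
  set.seed(21)
  n <- 20
  base <- rnorm(n)
  st <- data.frame(station_id = paste0("s", 1:n), lat = runif(n), lon = runif(n),
                   v1 = base + rnorm(n, sd = 0.1),
                   v2 = base + rnorm(n, sd = 0.1),
                   v3 = rnorm(n), v4 = rnorm(n))
  p <- env_pca(st)
  expect_true(all(p$eigenvalues[p$kept_axes] > mean(p$eigenvalues)))
  expect_true(all(p$eigenvalues[-p$kept_axes] <= mean(p$eigenvalues)))
})

test_that("two perfectly correlated variables collapse to one axis with all variance", {
  st <- data.frame(station_id = c("a", "b", "c", "d"), lat = 1:4, lon = 1:4,
                   v1 = c(1, 2, 3, 4), v2 = c(2, 4, 6, 8))
  p <- env_pca(st)
  expect_equal(p$kept_axes, 1L)
  expect_equal(p$var_frac[1], 1)
})

test_that("exactly uncorrelated variables defeat the criterion and demand n_axes", {
  # Helmert contrasts: centered, mutually orthogonal columns -> sample
  # correlation matrix is exactly the identity, all eigenvalues exactly 1
  h <- stats::contr.helmert(5)
  st <- data.frame(station_id = paste0("s", 1:5), lat = 1:5, lon = 1:5,
                   v1 = h[, 1], v2 = h[, 2], v3 = h[, 3], v4 = h[, 4])
  expect_error(env_pca(st), "n_axes")
  p <- env_pca(st, n_axes = 2)
  expect_equal(p$kept_axes, 1:2)
})

test_that("constant environmental variables are rejected", {
  st <- data.frame(station_id = c("a", "b", "c"), lat = 1:3, lon = 1:3,
                   v1 = c(1, 1, 1), v2 = c(1, 2, 3))
  expect_error(env_pca(st), "constant")
})

test_that("environmental distance is Euclidean over the kept axes", {
  pca <- structure(list(scores = rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0)),
                        eigenvalues = c(2, 1), var_frac = c(2 / 3, 1 / 3),
                        kept_axes = 1:2), class = "env_pca")
  d <- env_distance_matrix(pca)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
})

test_that("environmental distances match a naive loop and satisfy the triangle inequality", {
  set.seed(9)
  n <- 5
  st <- data.frame(station_id = paste0("s", 1:n), lat = runif(n), lon = runif(n),
                   t = rnorm(n), s = rnorm(n), o = rnorm(n), ch = rnorm(n))
  p <- env_pca(st, n_axes = 3)
  d <- env_distance_matrix(p)
  sc <- p$scores[, 1:3]
  for (i in 1:n) for (j in 1:n) {
    expect_equal(d[i, j], sqrt(sum((sc[i, ] - sc[j, ])^2)), tolerance = 1e-12)
  }
  for (k in 1:20) {
    tri <- sample(n, 3)
    expect_lte(d[tri[1], tri[2]], d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
  }
})

test_that("oceanographic distances average horizons, then take max PC / min MCT", {
  lab <- c("a", "b")
  mk <- function(ab, ba) matrix(c(NA, ba, ab, NA), 2, dimnames = list(lab, lab))
  pc <- list("3" = mk(0.1, 2e-4), "6" = mk(0.2, 4e-4), "12" = mk(0.6, 9e-4))
  mct <- matrix(c(0, 30, 80, 0), 2, dimnames = list(lab, lab))
  oc <- oceanographic_distances(connectivity_set(pc, mct))
  expect_equal(oc$pc["a", "b"], 0.3)   # mean {0.1, 0.2, 0.6} beats mean {2,4,9}e-4
  expect_equal(oc$pc["b", "a"], 0.3)
  expect_true(is.na(oc$pc["a", "a"]))
  expect_equal(oc$mct["a", "b"], 30)   # min of the two directions
  expect_equal(diag(unclass(oc$mct)), c(a = 0, b = 0))
})

test_that("connectivity sets reject mismatched labels and invalid entries", {
  lab <- c("a", "b")
  ok <- matrix(c(NA, 0.1, 0.1, NA), 2, dimnames = list(lab, lab))
  mct <- matrix(c(0, 5, 5, 0), 2, dimnames = list(lab, lab))
  bad_lab <- ok; dimnames(bad_lab) <- list(c("a", "x"), c("a", "x"))
  expect_error(connectivity_set(list("3" = bad_lab), mct), "labels")
  bad_p <- ok; bad_p[1, 2] <- 1.4
  expect_error(connectivity_set(list("3" = bad_p), mct), "probabilities")
  bad_t <- mct; bad_t[1, 2] <- -3
  expect_error(connectivity_set(list("3" = ok), bad_t), "> 0")
})
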