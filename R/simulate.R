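#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' emulating a Mediterranean-style basin survey: 13 stations on a two-basin
#' sea grid, 9 correlated environmental variables with an east-west
#' temperature/oligotrophy gradient, distance-decaying asymmetric Lagrangian
#' connectivity, sparse metagenomic read counts.
#'
#' Scenarios: \code{island} (Balding-Nichols differentiation \code{F},
#' spatially unstructured), \code{ibd} (logit-frequency Gaussian process
#' decaying with over-sea distance: isolation-by-distance), \code{ibe}
#' (per-SNP environmental effects on logit frequency:
#' isolation-by-environment), \code{null} (one panmictic population).
#'
#' @param n_stations number of stations (>= 2).
#' @param n_snps number of biallelic SNPs (>= 1).
#' @param scenario one of \code{island}, \code{ibd}, \code{ibe}, \code{null}.
#' @param F island-model differentiation in (0, 1): the variance of station
#'   frequencies around the ancestral frequency p is \code{F p (1 - p)}.
#' @param beta_env ibe effect magnitude: each SNP gets an environmental
#'   coefficient of \code{+beta_env} or \code{-beta_env} (random sign) acting
#'   on the standardized first environmental variable of the station's logit
#'   frequency.
#' @param sigma_noise residual logit noise sd per (snp, station) in the ibe
#'   and ibd scenarios (baseline differentiation unrelated to the driver).
#' @param station_sd_spread lognormal sd of the per-station multiplier on
#'   \code{sigma_noise}: stations differ in divergence scale, so pairs carry
#'   baseline differentiation variance not explained by any distance layer.
#' @param dist_decay_km ibd Gaussian-process correlation length (km).
#' @param sigma_gp ibd Gaussian-process marginal sd on the logit scale.
#' @param mean_coverage mean vertical coverage per (snp, station) cell.
#' @param coverage_model \code{"poisson"} or \code{"negbin"} (the latter
#'   zero-inflates coverage and reproduces station pairs with no shared SNP).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @param grid list: \code{lat_range}, \code{lon_range}, \code{res} (degrees),
#'   \code{ridge} (logical: land ridge splitting the basin in two),
#'   \code{ridge_gap} (sea cells left open in the ridge).
#' @param env_gradient strength of the east-west environmental gradient in sd
#'   units (0 = spatially exchangeable environment).
#' @param conn list: \code{pc0} baseline connection probability,
#'   \code{pc_decay_km} PC decay length at the 3-month horizon (scales
#'   linearly with horizon), \code{horizons} months, \code{mct_speed_km_day}
#'   advection speed, \code{mct_base_days} minimum connection time,
#'   \code{asym_sd} lognormal sd of the directed asymmetry noise.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_stations = 13, n_snps = 3000,
                       scenario = c("island", "ibd", "ibe", "null"),
                       F = 0.15, beta_env = 1.0, sigma_noise = 0.8,
                       station_sd_spread = 0.4,
                       dist_decay_km = 1500, sigma_gp = 1.4,
                       mean_coverage = 10,
                       coverage_model = c("poisson", "negbin"),
                       dispersion = 1, seed = 1,
                       grid = list(), env_gradient = 0.4, conn = list()) {
  scenario <- match.arg(scenario)
  coverage_model <- match.arg(coverage_model)
  grid_def <- list(lat_range = c(30, 45), lon_range = c(-5, 36), res = 1,
                   ridge = TRUE, ridge_gap = 3)
  conn_def <- list(pc0 = 0.5, pc_decay_km = 750, horizons = c(3, 6, 12),
                   mct_speed_km_day = 20, mct_base_days = 5, asym_sd = 0.8)
  grid <- utils::modifyList(grid_def, grid)
  conn <- utils::modifyList(conn_def, conn)
  cfg <- list(n_stations = as.integer(n_stations), n_snps = as.integer(n_snps),
              scenario = scenario, F = F, beta_env = beta_env,
              sigma_noise = sigma_noise,
              station_sd_spread = station_sd_spread,
              dist_decay_km = dist_decay_km,
              sigma_gp = sigma_gp, mean_coverage = mean_coverage,
              coverage_model = coverage_model, dispersion = dispersion,
              seed = as.integer(seed), grid = grid,
              env_gradient = env_gradient, conn = conn)
  stopifnot(cfg$n_stations >= 2, cfg$n_snps >= 1,
            cfg$F > 0, cfg$F < 1, cfg$dist_decay_km > 0,
            cfg$mean_coverage > 0, cfg$sigma_gp > 0, grid$res > 0)
  structure(cfg, class = "sim_config")
}

# fixed catalogue of the 9 environmental variables: plausible Mediterranean
# surface means/sds and the sign with which each loads on the east-west
# warm/oligotrophic gradient and on a shared latent water-mass factor.
# Temperature is the high-communality master variable (large latent load,
# small idiosyncratic noise): the nutrient block co-varies with it, as in
# stratified oligotrophic basins.
env_catalogue <- function() {
  data.frame(
    name = c("temperature", "salinity", "ammonium", "nitrate", "nitrite",
             "phosphate", "silicate", "oxygen", "chlorophyll_a"),
    mean = c(19, 38, 0.05, 1.5, 0.08, 0.06, 1.2, 5.5, 0.15),
    sd = c(1.5, 0.45, 0.02, 0.6, 0.03, 0.025, 0.45, 0.35, 0.06),
    grad_load = c(1, 0.6, -0.5, -1, -0.7, -0.9, -0.6, -0.8, -1),
    latent_load = c(0.9, 0.3, 0.6, 0.6, 0.6, 0.6, 0.6, 0.4, 0.5),
    noise_sd = c(0.25, rep(0.6, 8)),
    stringsAsFactors = FALSE)
}

#' Simulate stations, sea grid and connectivity
#'
#' Builds a rectangular sea basin (optionally split by a land ridge with a
#' strait, giving two sub-basins), places stations on distinct sea cells,
#' draws 9 correlated environmental variables with a configurable east-west
#' gradient, and derives directed Lagrangian connectivity products: PC
#' matrices decaying exponentially with over-sea distance (decay length
#' proportional to the dispersal horizon) under multiplicative lognormal
#' asymmetry noise, and MCT increasing linearly with distance plus noise.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List of class \code{sim_stations}: \code{stations} (data.frame),
#'   \code{grid} (\code{\link{sea_grid}}), \code{conn}
#'   (\code{\link{connectivity_set}}), \code{sea_dist} (geographic
#'   \code{\link{dist_matrix}}).
#' @export
simulate_stations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$grid
  lat <- seq(g$lat_range[1] + g$res / 2, g$lat_range[2], by = g$res)
  lon <- seq(g$lon_range[1] + g$res / 2, g$lon_range[2], by = g$res)
  mask <- matrix(TRUE, length(lat), length(lon))
  if (isTRUE(g$ridge)) {
    jr <- round(length(lon) / 2)
    gap <- seq_len(min(g$ridge_gap, length(lat)))  # strait at the southern edge
    mask[-gap, jr] <- FALSE
  }
  grid <- sea_grid(lat, lon, mask)
  sea_cells <- which(mask, arr.ind = TRUE)
  if (config$n_stations > nrow(sea_cells)) {
    stop("cannot place ", config$n_stations, " stations on ",
         nrow(sea_cells), " sea cells")
  }
  pick <- sample(nrow(sea_cells), config$n_stations)
  st_lat <- lat[sea_cells[pick, 1]]
  st_lon <- lon[sea_cells[pick, 2]]
  ids <- sprintf("st%02d", seq_len(config$n_stations))
  # environment: standardized east-west gradient + shared latent water-mass
  # factor + idiosyncratic noise, mapped to each variable's mean/sd
  cat_env <- env_catalogue()
  gvec <- as.numeric(scale(st_lon))
  if (any(!is.finite(gvec))) gvec <- rep(0, config$n_stations)
  h <- stats::rnorm(config$n_stations)
  env <- sapply(seq_len(nrow(cat_env)), function(v) {
    z <- config$env_gradient * cat_env$grad_load[v] * gvec +
      cat_env$latent_load[v] * h +
      stats::rnorm(config$n_stations, sd = cat_env$noise_sd[v])
    pmax(cat_env$mean[v] + cat_env$sd[v] * z, 0.001)
  })
  colnames(env) <- cat_env$name
  stations <- data.frame(station_id = ids, lat = st_lat, lon = st_lon,
                         env, stringsAsFactors = FALSE)
  sea_dist <- sea_distance_matrix(stations, grid)
  d <- unclass(sea_dist)
  cn <- config$conn
  pc_by_horizon <- lapply(cn$horizons, function(hm) {
    decay <- cn$pc_decay_km * hm / cn$horizons[1]
    noise <- matrix(exp(stats::rnorm(length(d), sd = cn$asym_sd)), nrow(d))
    m <- pmin(cn$pc0 * exp(-d / decay) * noise, 1)
    dimnames(m) <- dimnames(d)
    diag(m) <- NA_real_
    m
  })
  names(pc_by_horizon) <- as.character(cn$horizons)
  mct_noise <- matrix(exp(stats::rnorm(length(d), sd = cn$asym_sd / 2)), nrow(d))
  mct <- (d / cn$mct_speed_km_day + cn$mct_base_days) * mct_noise
  dimnames(mct) <- dimnames(d)
  diag(mct) <- 0
  structure(list(stations = stations, grid = grid,
                 conn = connectivity_set(pc_by_horizon, mct),
                 sea_dist = sea_dist),
            class = "sim_stations")
}

#' Simulate true station allele frequencies with known structure
#'
#' Per SNP, an ancestral frequency \code{p ~ Uniform(0.05, 0.95)} is drawn,
#' then station frequencies according to the scenario:
#' \describe{
#'   \item{island}{\code{Beta(p (1-F)/F, (1-p)(1-F)/F)} independently per
#'     station (Balding-Nichols; station-frequency variance \code{F p (1-p)}).}
#'   \item{ibd}{logit frequencies \code{logit(p) + z}, \code{z} a zero-mean
#'     Gaussian process over stations with covariance
#'     \code{sigma_gp^2 exp(-d_sea / dist_decay_km)}.}
#'   \item{ibe}{\code{logit(p) + b_l * z_env + noise} with per-SNP coefficient
#'     \code{b_l ~ N(0, beta_env^2)} and \code{z_env} the standardized first
#'     environmental variable.}
#'   \item{null}{all stations share \code{p} exactly.}
#' }
#'
#' @param config a \code{\link{sim_config}}.
#' @param sim_stations output of \code{\link{simulate_stations}}.
#' @return Object of class \code{truth_set}: \code{true_freqs} (station x SNP
#'   matrix), \code{p_ancestral}, \code{scenario}, and scenario-specific
#'   parameters as drawn (\code{env_coef} for ibe).
#' @export
simulate_frequencies <- function(config, sim_stations) {
  stopifnot(inherits(config, "sim_config"), inherits(sim_stations, "sim_stations"))
  set.seed(config$seed + 1L)
  ns <- config$n_stations
  nl <- config$n_snps
  p <- stats::runif(nl, 0.05, 0.95)
  extras <- list()
  freqs <- switch(
    config$scenario,
    island = {
      if (config$F < 1e-8) {
        matrix(rep(p, each = ns), ns, nl)
      } else {
        shape_scale <- (1 - config$F) / config$F
        matrix(stats::rbeta(ns * nl, rep(p, each = ns) * shape_scale,
                            rep(1 - p, each = ns) * shape_scale), ns, nl)
      }
    },
    ibd = {
      d <- unclass(sim_stations$sea_dist)
      sigma <- config$sigma_gp^2 * exp(-d / config$dist_decay_km)
      cf <- chol(sigma + diag(1e-8, ns))
      z <- crossprod(cf, matrix(stats::rnorm(ns * nl), ns, nl))
      sd_s <- config$sigma_noise *
        exp(config$station_sd_spread * stats::rnorm(ns))
      extras$station_noise_sd <- sd_s
      eta <- matrix(rep(stats::qlogis(p), each = ns), ns, nl) + z +
        matrix(stats::rnorm(ns * nl), ns, nl) * sd_s
      stats::plogis(eta)
    },
    ibe = {
      z_env <- as.numeric(scale(sim_stations$stations[[env_catalogue()$name[1]]]))
      b <- sample(c(-config$beta_env, config$beta_env), nl, replace = TRUE)
      sd_s <- config$sigma_noise *
        exp(config$station_sd_spread * stats::rnorm(ns))
      extras$env_coef <- b
      extras$station_noise_sd <- sd_s
      eta <- matrix(rep(stats::qlogis(p), each = ns), ns, nl) +
        outer(z_env, b) +
        matrix(stats::rnorm(ns * nl), ns, nl) * sd_s
      stats::plogis(eta)
    },
    null = matrix(rep(p, each = ns), ns, nl))
  rownames(freqs) <- sim_stations$stations$station_id
  colnames(freqs) <- sprintf("snp%05d", seq_len(nl))
  structure(c(list(true_freqs = freqs, p_ancestral = p,
                   scenario = config$scenario), extras),
            class = "truth_set")
}

#' Sample metagenomic read counts from true frequencies
#'
#' Per (snp, station) cell, vertical coverage is drawn from the configured
#' coverage model (Poisson, or negative-binomial for over-dispersed /
#' zero-inflated coverage); the alternate-read count is
#' Binomial(coverage, true frequency). Cells with zero coverage are
#' unobserved; SNPs with no covered station are dropped from the table, as
#' they would never be called from reads.
#'
#' @param truth a \code{\link{simulate_frequencies}} truth set.
#' @param config the same \code{\link{sim_config}}.
#' @return An \code{\link{allele_count_table}}.
#' @export
sample_reads <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  freqs <- t(truth$true_freqs)  # snps x stations
  n <- length(freqs)
  cov <- switch(config$coverage_model,
                poisson = stats::rpois(n, config$mean_coverage),
                negbin = stats::rnbinom(n, mu = config$mean_coverage,
                                        size = 1 / config$dispersion))
  alt <- stats::rbinom(n, cov, freqs)
  ac <- matrix(alt, nrow(freqs), dimnames = dimnames(freqs))
  rc <- matrix(cov - alt, nrow(freqs), dimnames = dimnames(freqs))
  nt <- c("A", "C", "G", "T")
  ref_nt <- sample(nt, nrow(freqs), replace = TRUE)
  alt_nt <- vapply(ref_nt, function(r) sample(setdiff(nt, r), 1), character(1))
  snps <- data.frame(snp_id = rownames(freqs), contig = "contig_1",
                     pos = seq_len(nrow(freqs)), ref = ref_nt, alt = alt_nt,
                     stringsAsFactors = FALSE)
  keep <- rowSums(rc + ac) > 0
  allele_count_table(snps[keep, , drop = FALSE], rc[keep, , drop = FALSE],
                     ac[keep, , drop = FALSE],
                     species_label = paste0("synthetic_", config$scenario))
}

#' Run the full generator: stations + truth + read counts
#'
#' @param config a \code{\link{sim_config}}.
#' @return List of class \code{sim_dataset}: \code{config}, \code{stations}
#'   (a \code{sim_stations} list), \code{truth}, \code{table}.
#' @export
simulate_dataset <- function(config) {
  st <- simulate_stations(config)
  truth <- simulate_frequencies(config, st)
  tab <- sample_reads(truth, config)
  structure(list(config = config, stations = st, truth = truth, table = tab),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Emits the file formats consumed by \code{\link{run_pipeline}}:
#' \code{allele_counts.tsv}, \code{stations.csv}, \code{seagrid.txt},
#' \code{pc_<h>m.tsv} per horizon, \code{mct.tsv}, and \code{truth.tsv}
#' (true station x SNP frequencies).
#'
#' @param sim a \code{\link{simulate_dataset}} result.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_allele_counts(sim$table, file.path(dir, "allele_counts.tsv"))
  write_stations(sim$stations$stations, file.path(dir, "stations.csv"))
  write_sea_grid(sim$stations$grid, file.path(dir, "seagrid.txt"))
  conn <- sim$stations$conn
  for (h in names(conn$pc_by_horizon)) {
    m <- conn$pc_by_horizon[[h]]
    df <- data.frame(station = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, sprintf("pc_%sm.tsv", h)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df <- data.frame(station = rownames(conn$mct), conn$mct, check.names = FALSE)
  utils::write.table(df, file.path(dir, "mct.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tf <- data.frame(station = rownames(sim$truth$true_freqs),
                   sim$truth$true_freqs, check.names = FALSE)
  utils::write.table(tf, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
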