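#' Pipeline configuration
#'
#' A declarative description of one end-to-end run: input file paths, filter
#' parameters, PCA options, regression options, output directory and seed.
#' Accepts a YAML file path or a named list; unspecified fields take
#' defaults. The resolved configuration is written alongside the outputs so
#' every run is reproducible from its own record.
#'
#' @param config named list or path to a YAML file.
#' @return Validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    allele_counts = NULL, allele_format = "tsv", sample_map = NULL,
    stations = NULL, seagrid = NULL,
    pc_files = NULL,        # named list/vector: horizon months -> path
    mct_file = NULL,
    species_label = "unknown",
    min_cov = 4, sigma_mult = 2, min_alt = 1,
    pca_normalize = "none", pca_n_axes = NULL,
    terms = c("geo", "env", "pc", "mct"),
    permutation_check = FALSE, n_perm = 999,
    max_snap_km = 500,
    out_dir = "metafst_out", seed = 1)
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  needed <- c("allele_counts", "stations")
  for (f in needed) {
    if (is.null(cfg[[f]])) stop("pipeline config needs '", f, "'")
  }
  file_fields <- c("allele_counts", "stations", "seagrid", "mct_file")
  for (f in file_fields) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("configured file does not exist: ", f, " = ", cfg[[f]])
    }
  }
  if ("geo" %in% cfg$terms && is.null(cfg$seagrid)) {
    stop("term 'geo' requested but no 'seagrid' file configured")
  }
  if ("pc" %in% cfg$terms && is.null(cfg$pc_files)) {
    stop("term 'pc' requested but no 'pc_files' configured")
  }
  if (("mct" %in% cfg$terms || "pc" %in% cfg$terms) && is.null(cfg$mct_file)) {
    stop("oceanographic terms requested but no 'mct_file' configured")
  }
  if (!is.null(cfg$pc_files)) {
    for (p in unlist(cfg$pc_files)) {
      if (!file.exists(p)) stop("configured PC file does not exist: ", p)
    }
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes filter -> FST -> distance layers -> BIC regression on the
#' configured inputs and writes all intermediate matrices, a results-table
#' summary, the differentiation-class histogram counts, the dendrogram
#' (Newick) with its mean-imputed heatmap matrix, and a JSON run manifest
#' (versions, seed, resolved parameters, per-stage record counts and output
#' checksums). Any stage failure aborts with the stage name and cause.
#'
#' @param config a \code{\link{pipeline_config}} (or list / YAML path).
#' @param heatmap also render a heatmap PNG (requires the pheatmap package).
#' @return The manifest list, invisibly. All outputs under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config, heatmap = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  set.seed(config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metafst")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = unclass(config),
    stages = list())

  # stage 1: load + coverage filter
  filt <- run_stage("filter", {
    tab <- read_allele_counts(config$allele_counts, config$allele_format,
                              config$species_label,
                              sample_map = config$sample_map)
    ftab <- filter_snps_by_coverage(tab, min_cov = config$min_cov,
                                    sigma_mult = config$sigma_mult,
                                    min_alt = config$min_alt)
    list(raw = tab, table = ftab, log = attr(ftab, "filter_log"))
  })
  manifest$stages$filter <- c(
    list(snps_in = nrow(filt$raw$snps), snps_out = nrow(filt$table$snps),
         stations = length(filt$table$stations)),
    filt$log[c("n_cells_in", "n_below_min_cov", "n_above_upper",
               "n_below_min_alt", "n_cells_kept", "n_snps_removed")])

  # stage 2: genomic differentiation
  fst <- run_stage("fst", {
    res <- pairwise_fst_matrix(filt$table)
    write_dist_matrix(res$matrix, file.path(out, "genomic_fst.tsv"))
    cl <- cluster_stations(res$matrix)
    write_dendrogram(cl, file.path(out, "dendrogram.nwk"))
    write_dist_matrix(dist_matrix(cl$imputed, "genomic"),
                      file.path(out, "genomic_fst_imputed.tsv"))
    classes <- table(classify_fst(res$matrix[upper.tri(res$matrix)]))
    utils::write.table(
      data.frame(class = names(classes), n_pairs = as.integer(classes)),
      file.path(out, "fst_classes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(file.path(out, "fst_heatmap.png"), 800, 700)
      pheatmap::pheatmap(cl$imputed,
                         clustering_distance_rows = stats::as.dist(cl$imputed),
                         clustering_distance_cols = stats::as.dist(cl$imputed),
                         clustering_method = "complete",
                         main = filt$table$species_label)
      grDevices::dev.off()
    }
    list(res = res, classes = classes, clustering = cl)
  })
  upper <- fst$res$matrix[upper.tri(fst$res$matrix)]
  manifest$stages$fst <- list(
    n_pairs = length(upper),
    n_pairs_with_shared_snps = sum(!is.na(upper)),
    n_pairs_missing = sum(is.na(upper)),
    global_fst = fst$res$global_fst,
    class_counts = as.list(stats::setNames(as.integer(fst$classes),
                                           names(fst$classes))))

  # stage 3: explanatory distance layers
  dists <- run_stage("distances", {
    stations <- read_stations(config$stations)
    ids <- filt$table$stations
    missing_st <- setdiff(ids, stations$station_id)
    if (length(missing_st)) {
      stop("stations absent from metadata: ", paste(missing_st, collapse = ", "))
    }
    stations <- stations[match(ids, stations$station_id), , drop = FALSE]
    layers <- list()
    if ("geo" %in% config$terms) {
      grid <- read_sea_grid(config$seagrid)
      layers$geo <- sea_distance_matrix(stations, grid, config$max_snap_km)
      write_dist_matrix(layers$geo, file.path(out, "geographic_km.tsv"))
    }
    if ("env" %in% config$terms) {
      pca <- env_pca(stations, normalize = config$pca_normalize,
                     n_axes = config$pca_n_axes)
      layers$env <- env_distance_matrix(pca)
      layers$env_pca <- pca
      write_dist_matrix(layers$env, file.path(out, "environmental.tsv"))
    }
    if (any(c("pc", "mct") %in% config$terms)) {
      pc_paths <- unlist(config$pc_files)
      conn <- read_connectivity(pc_paths, config$mct_file)
      if (!setequal(conn$labels, ids)) {
        stop("connectivity station labels do not match the allele-count table")
      }
      oc <- oceanographic_distances(connectivity_set(
        lapply(conn$pc_by_horizon, function(m) m[ids, ids]),
        conn$mct[ids, ids]))
      if ("pc" %in% config$terms) {
        layers$pc <- oc$pc
        write_dist_matrix(oc$pc, file.path(out, "pc_connectivity.tsv"))
      }
      if ("mct" %in% config$terms) {
        layers$mct <- oc$mct
        write_dist_matrix(oc$mct, file.path(out, "mct_days.tsv"))
      }
    }
    layers
  })
  manifest$stages$distances <- list(
    layers = intersect(c("geo", "env", "pc", "mct"), names(dists)),
    env_axes_kept = if (!is.null(dists$env_pca)) length(dists$env_pca$kept_axes) else NULL)

  # stage 4: driver attribution
  reg <- run_stage("regression", {
    obs <- assemble_pairs(fst$res$matrix, geo = dists$geo, env = dists$env,
                          pc = dists$pc, mct = dists$mct)
    fit <- exhaustive_bic_select(obs, terms = intersect(config$terms,
                                                        sub("^x_", "", grep("^x_", names(obs), value = TRUE))))
    write_regression_report(fit, file.path(out, "regression_summary.tsv"),
                            file.path(out, "bic_table.tsv"))
    perm <- NULL
    if (isTRUE(config$permutation_check) && !fit$null_selected) {
      perm <- permutation_check(obs, fit, n_perm = config$n_perm)
    }
    list(obs = obs, fit = fit, perm = perm)
  })
  manifest$stages$regression <- list(
    n_pairs_used = nrow(reg$obs),
    selected_terms = if (reg$fit$null_selected) character(0) else reg$fit$selected_terms,
    overall_f_pvalue = reg$fit$overall_f_pvalue,
    r2_percent = if (reg$fit$null_selected) NULL else reg$fit$r2_percent,
    beta = as.list(reg$fit$beta),
    permutation_p = if (!is.null(reg$perm)) reg$perm$p_value else NULL)

  outputs <- list.files(out, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest$outputs <- as.list(tools::md5sum(sort(outputs)))
  yaml::write_yaml(unclass(config), file.path(out, "resolved_config.yaml"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  message("pipeline complete: 4 stages, outputs in ", out)
  invisible(manifest)
}
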