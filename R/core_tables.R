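#' Construct an allele-count table
#'
#' The central container of the package: per-SNP, per-station read counts for
#' the reference and alternate allele of one species. Counts are stored as two
#' SNP x station integer matrices; a (snp, station) cell with zero total
#' coverage is "unobserved" at that station. After
#' \code{\link{filter_snps_by_coverage}}, observed means the cell passed the
#' coverage window.
#'
#' @param snps data.frame with columns \code{snp_id}, \code{contig},
#'   \code{pos} (1-based), \code{ref}, \code{alt}; alleles must be single
#'   nucleotides in \code{A,C,G,T} and \code{ref != alt}.
#' @param ref_counts,alt_counts non-negative integer matrices, one row per SNP
#'   (in the order of \code{snps}), one column per station; column names are
#'   the station ids.
#' @param species_label character scalar naming the species.
#' @return An object of class \code{allele_count_table}: a list with elements
#'   \code{species_label}, \code{snps}, \code{ref_counts}, \code{alt_counts},
#'   \code{stations}.
#' @seealso \code{\link{read_allele_counts}},
#'   \code{\link{filter_snps_by_coverage}}, \code{\link{coverage}}
#' @export
allele_count_table <- function(snps, ref_counts, alt_counts,
                               species_label = "unknown") {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "contig", "pos", "ref", "alt")
  if (!all(req %in% names(snps))) {
    stop("'snps' must have columns: ", paste(req, collapse = ", "))
  }
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  storage.mode(ref_counts) <- "integer"
  storage.mode(alt_counts) <- "integer"
  x <- structure(
    list(species_label = as.character(species_label)[1],
         snps = snps,
         ref_counts = ref_counts,
         alt_counts = alt_counts,
         stations = colnames(ref_counts)),
    class = "allele_count_table")
  validate_allele_count_table(x)
}

validate_allele_count_table <- function(x) {
  snps <- x$snps
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id values: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  nt <- c("A", "C", "G", "T")
  bad <- !(snps$ref %in% nt) | !(snps$alt %in% nt) | snps$ref == snps$alt
  if (any(bad)) {
    stop("invalid alleles (must be distinct single nucleotides A/C/G/T) for: ",
         paste(utils::head(snps$snp_id[bad], 5), collapse = ", "))
  }
  if (any(snps$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (nrow(x$ref_counts) != nrow(snps) || nrow(x$alt_counts) != nrow(snps)) {
    stop("count matrices must have one row per SNP")
  }
  if (!identical(colnames(x$ref_counts), colnames(x$alt_counts))) {
    stop("ref and alt count matrices must share station columns")
  }
  if (is.null(colnames(x$ref_counts))) stop("count matrices need station ids as column names")
  if (anyDuplicated(colnames(x$ref_counts))) stop("duplicate station ids")
  if (anyNA(x$ref_counts) || anyNA(x$alt_counts) ||
      any(x$ref_counts < 0) || any(x$alt_counts < 0)) {
    stop("read counts must be non-negative and non-missing")
  }
  rownames(x$ref_counts) <- rownames(x$alt_counts) <- snps$snp_id
  x
}

#' @export
print.allele_count_table <- function(x, ...) {
  cov <- coverage(x)
  obs <- cov > 0
  cat(sprintf("allele_count_table: '%s', %d SNPs x %d stations\n",
              x$species_label, nrow(x$snps), length(x$stations)))
  cat(sprintf("  observed cells: %d (%.1f%%); mean vertical coverage of observed cells: %.2fx\n",
              sum(obs), 100 * mean(obs),
              if (any(obs)) mean(cov[obs]) else NA_real_))
  invisible(x)
}

#' Vertical coverage of an allele-count table
#'
#' Vertical coverage of a cell is the number of reads aligned at that SNP
#' position in that station, i.e. \code{ref_count + alt_count}.
#'
#' @param table an \code{\link{allele_count_table}}.
#' @return Integer SNP x station matrix.
#' @export
coverage <- function(table) {
  stopifnot(inherits(table, "allele_count_table"))
  table$ref_counts + table$alt_counts
}

#' Read an allele-count table from TSV or VCF
#'
#' The TSV dialect is long format, tab-separated, UTF-8, with a header row and
#' columns \code{snp_id}, \code{contig}, \code{pos}, \code{ref}, \code{alt},
#' \code{station}, \code{ref_count}, \code{alt_count}; absent (snp, station)
#' combinations are unobserved cells. VCF input (v4.x) is read via the
#' per-sample allele-depth (AD) field; indel records are dropped and
#' multi-allelic sites are reduced to biallelic by keeping the alternate
#' allele with the largest read support summed over all stations.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param species_label species name attached to the table.
#' @param sample_map for VCF input, a named character vector mapping VCF
#'   sample names to station ids (\code{c(sample = "station", ...)}). When
#'   \code{NULL}, sample names are used as station ids unchanged.
#' @return An \code{\link{allele_count_table}}.
#' @export
read_allele_counts <- function(path, format = c("tsv", "vcf"),
                               species_label = "unknown", sample_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    read_allele_counts_tsv(path, species_label)
  } else {
    read_allele_counts_vcf(path, species_label, sample_map)
  }
}

read_allele_counts_tsv <- function(path, species_label) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  req <- c("snp_id", "contig", "pos", "ref", "alt", "station",
           "ref_count", "alt_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  for (col in c("pos", "ref_count", "alt_count")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  bad <- which(is.na(df$pos) | is.na(df$ref_count) | is.na(df$alt_count))
  if (length(bad)) {
    # +1 for the header row
    stop("malformed row(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path)
  }
  dup <- duplicated(df[c("snp_id", "station")])
  if (any(dup)) {
    stop("duplicate (snp_id, station) entries, first at line ",
         which(dup)[1] + 1L, " of ", path)
  }
  snps <- unique(df[c("snp_id", "contig", "pos", "ref", "alt")])
  if (anyDuplicated(snps$snp_id)) {
    stop("snp_id with inconsistent contig/pos/alleles across rows in ", path)
  }
  stations <- unique(df$station)
  i <- match(df$snp_id, snps$snp_id)
  j <- match(df$station, stations)
  rc <- ac <- matrix(0L, nrow(snps), length(stations),
                     dimnames = list(snps$snp_id, stations))
  rc[cbind(i, j)] <- df$ref_count
  ac[cbind(i, j)] <- df$alt_count
  allele_count_table(snps, rc, ac, species_label)
}

read_allele_counts_vcf <- function(path, species_label, sample_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF has no per-sample AD (allele depth) field")
  samples <- colnames(ad)
  stations <- if (is.null(sample_map)) samples else {
    if (!all(samples %in% names(sample_map))) {
      stop("sample_map is missing entries for: ",
           paste(setdiff(samples, names(sample_map)), collapse = ", "))
    }
    unname(sample_map[samples])
  }
  n <- nrow(fix)
  keep <- logical(n)
  ref <- alt <- character(n)
  rc <- ac <- matrix(0L, n, length(samples))
  for (r in seq_len(n)) {
    ref_r <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    depths <- lapply(ad[r, ], function(s) {
      if (is.na(s)) return(NULL)
      suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
    })
    # pick the alternate allele with most read support summed over stations
    alt_tot <- vapply(seq_along(alts), function(k) {
      sum(vapply(depths, function(d) {
        if (is.null(d) || length(d) < k + 1 || is.na(d[k + 1])) 0L else d[k + 1]
      }, integer(1)))
    }, numeric(1))
    k <- which.max(alt_tot)
    alt_r <- alts[k]
    if (nchar(ref_r) != 1 || nchar(alt_r) != 1 ||
        !(ref_r %in% c("A", "C", "G", "T")) || !(alt_r %in% c("A", "C", "G", "T"))) {
      next  # indel or symbolic allele: not a SNP
    }
    keep[r] <- TRUE
    ref[r] <- ref_r
    alt[r] <- alt_r
    rc[r, ] <- vapply(depths, function(d) {
      if (is.null(d) || is.na(d[1])) 0L else d[1]
    }, integer(1))
    ac[r, ] <- vapply(depths, function(d) {
      if (is.null(d) || length(d) < k + 1 || is.na(d[k + 1])) 0L else d[k + 1]
    }, integer(1))
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  n_multi <- sum(keep & grepl(",", fix[, "ALT"], fixed = TRUE))
  if (n_multi > 0) {
    message(n_multi, " multi-allelic site(s) reduced to biallelic by majority alternate")
  }
  if (any(!keep)) message(sum(!keep), " non-SNP (indel) record(s) dropped")
  snps <- data.frame(
    snp_id = paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"]),
    contig = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE)
  rc <- rc[keep, , drop = FALSE]
  ac <- ac[keep, , drop = FALSE]
  colnames(rc) <- colnames(ac) <- stations
  allele_count_table(snps, rc, ac, species_label)
}

#' Write an allele-count table as TSV
#'
#' Emits the long TSV dialect read by \code{\link{read_allele_counts}}, one
#' row per observed cell (coverage > 0), SNPs in table order and stations in
#' table order within each SNP, so that write -> read -> write round-trips
#' bit-identically.
#'
#' @param table an \code{\link{allele_count_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_allele_counts <- function(table, path) {
  stopifnot(inherits(table, "allele_count_table"))
  cov <- coverage(table)
  idx <- which(t(cov) > 0)  # station-fastest -> stations in order within snp
  ns <- length(table$stations)
  i <- (idx - 1L) %/% ns + 1L
  j <- (idx - 1L) %% ns + 1L
  df <- data.frame(
    snp_id = table$snps$snp_id[i],
    contig = table$snps$contig[i],
    pos = table$snps$pos[i],
    ref = table$snps$ref[i],
    alt = table$snps$alt[i],
    station = table$stations[j],
    ref_count = table$ref_counts[cbind(i, j)],
    alt_count = table$alt_counts[cbind(i, j)],
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter SNP cells by the per-station vertical-coverage window
#'
#' For each station independently, the mean \code{mu} and sample standard
#' deviation \code{sigma} of vertical coverage are computed over that
#' station's covered SNPs (coverage >= 1). A (snp, station) cell is retained
#' iff its coverage \code{c} satisfies \code{min_cov <= c < mu +
#' sigma_mult * sigma} and its alternate-read count is at least
#' \code{min_alt}. The lower bound screens spurious low-support calls; the
#' upper bound removes positions whose excess coverage suggests recruitment of
#' reads from closely related species. Cells failing the window are zeroed
#' (unobserved); SNPs retained at no station are removed from the table.
#'
#' A station with fewer than two covered SNPs has an undefined sigma; only the
#' lower bound is applied there, with a warning.
#'
#' @param table an \code{\link{allele_count_table}}.
#' @param min_cov minimum vertical coverage (default 4 reads).
#' @param sigma_mult multiplier of sigma for the upper bound (default 2).
#' @param min_alt minimum alternate-read count per retained cell (default 1;
#'   set 0 to apply the coverage window only).
#' @return A new filtered \code{allele_count_table}. The per-rule counts of
#'   removed cells are reported via \code{message()} and attached as attribute
#'   \code{"filter_log"} (a list with \code{n_cells_in},
#'   \code{n_below_min_cov}, \code{n_above_upper}, \code{n_below_min_alt},
#'   \code{n_cells_kept}, \code{n_snps_removed}, and the per-station
#'   \code{mu}, \code{sigma}, \code{upper}).
#' @export
filter_snps_by_coverage <- function(table, min_cov = 4, sigma_mult = 2,
                                    min_alt = 1) {
  stopifnot(inherits(table, "allele_count_table"))
  if (nrow(table$snps) == 0) stop("empty allele-count table")
  cov <- coverage(table)
  ns <- length(table$stations)
  mu <- sigma <- upper <- setNames(rep(NA_real_, ns), table$stations)
  keep <- matrix(FALSE, nrow(cov), ncol(cov), dimnames = dimnames(cov))
  for (j in seq_len(ns)) {
    covered <- cov[, j] >= 1
    n_cov <- sum(covered)
    if (n_cov >= 2) {
      mu[j] <- mean(cov[covered, j])
      sigma[j] <- stats::sd(cov[covered, j])
      upper[j] <- mu[j] + sigma_mult * sigma[j]
    } else {
      if (n_cov == 1) mu[j] <- cov[covered, j]
      upper[j] <- Inf
      warning("station '", table$stations[j], "' has < 2 covered SNPs; ",
              "sigma undefined, applying only the lower coverage bound",
              call. = FALSE)
    }
    keep[, j] <- cov[, j] >= min_cov & cov[, j] < upper[j] &
      table$alt_counts[, j] >= min_alt
  }
  observed <- cov > 0
  log <- list(
    n_cells_in = sum(observed),
    n_below_min_cov = sum(observed & cov < min_cov),
    n_above_upper = sum(observed & sweep(cov, 2, upper, ">=")),
    n_below_min_alt = sum(observed & table$alt_counts < min_alt),
    n_cells_kept = sum(keep),
    mu = mu, sigma = sigma, upper = upper)
  rc <- table$ref_counts
  ac <- table$alt_counts
  rc[!keep] <- 0L
  ac[!keep] <- 0L
  snp_keep <- rowSums(keep) > 0
  log$n_snps_removed <- sum(!snp_keep)
  out <- allele_count_table(table$snps[snp_keep, , drop = FALSE],
                            rc[snp_keep, , drop = FALSE],
                            ac[snp_keep, , drop = FALSE],
                            table$species_label)
  message(sprintf(
    paste0("coverage filter: %d/%d observed cells kept ",
           "(%d below %d reads, %d at/above mu+%gsigma, %d below %d alt reads); ",
           "%d SNP(s) removed entirely"),
    log$n_cells_kept, log$n_cells_in, log$n_below_min_cov, min_cov,
    log$n_above_upper, sigma_mult, log$n_below_min_alt, min_alt,
    log$n_snps_removed))
  attr(out, "filter_log") <- log
  out
}

#' Read station metadata
#'
#' CSV with columns \code{station_id}, \code{lat}, \code{lon}, then one column
#' per environmental variable (e.g. temperature in deg C, salinity in PSU,
#' nutrient concentrations in mmol m^-3, oxygen in ml l^-1, chlorophyll a in
#' mg m^-3). Missing environmental values are rejected: every station must
#' carry the full variable set.
#'
#' @param path CSV file path.
#' @return A validated \code{data.frame} (the station table).
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_stations(df)
}

#' @rdname read_stations
#' @param stations a data.frame to validate in place of a file.
#' @export
validate_stations <- function(stations) {
  req <- c("station_id", "lat", "lon")
  miss <- setdiff(req, names(stations))
  if (length(miss)) stop("station table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(stations$station_id)) stop("duplicate station ids")
  if (any(stations$lat < -90 | stations$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(stations$lon < -180 | stations$lon > 180)) stop("longitude outside [-180, 180]")
  env <- env_columns(stations)
  if (length(env) && anyNA(stations[env])) {
    stop("missing environmental values; every station needs the full variable set")
  }
  stations$station_id <- as.character(stations$station_id)
  stations
}

env_columns <- function(stations) {
  setdiff(names(stations), c("station_id", "lat", "lon"))
}

#' Write station metadata as CSV
#' @param stations a station data.frame (see \code{\link{read_stations}}).
#' @param path output path.
#' @export
write_stations <- function(stations, path) {
  utils::write.csv(validate_stations(stations), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct a station-by-station distance matrix
#'
#' A plain numeric matrix with station ids as dimnames and a \code{"kind"}
#' attribute in \code{genomic}, \code{geographic}, \code{environmental},
#' \code{pc_connectivity}, \code{mct}. Matrices are symmetric with zero
#' diagonal; missing (NA) off-diagonal entries are allowed only for
#' \code{genomic} (station pairs sharing no SNP), and the diagonal of
#' \code{pc_connectivity} is undefined (NA, ignored downstream).
#'
#' @param values square numeric matrix with identical row/column station ids.
#' @param kind matrix kind (see above).
#' @return The validated matrix with class \code{dist_matrix}.
#' @export
dist_matrix <- function(values, kind = c("genomic", "geographic",
                                         "environmental", "pc_connectivity",
                                         "mct")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values))) {
    stop("distance matrix needs identical row/column station labels")
  }
  if (!isTRUE(all.equal(values, t(values)))) stop("distance matrix must be symmetric")
  off <- values[row(values) != col(values)]
  if (anyNA(off) && kind != "genomic") {
    stop("missing entries only allowed for kind = 'genomic'")
  }
  if (any(off < 0, na.rm = TRUE)) stop("distances must be non-negative")
  if (kind == "pc_connectivity") {
    diag(values) <- NA_real_
  } else {
    if (any(abs(diag(values)) > 1e-12, na.rm = TRUE)) stop("diagonal must be zero")
    diag(values) <- 0
  }
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (kind = %s), %d stations, %d missing pair(s)\n",
              attr(x, "kind"), nrow(x),
              sum(is.na(x[upper.tri(x)]))))
  print(unclass(x), ...)
  invisible(x)
}

#' Read / write a distance matrix as TSV
#'
#' First row and first column carry station labels; missing entries are
#' written as \code{NA}.
#'
#' @param path TSV path.
#' @param kind matrix kind, see \code{\link{dist_matrix}}.
#' @export
read_dist_matrix <- function(path, kind = "genomic") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  dist_matrix(m, kind)
}

#' @rdname read_dist_matrix
#' @param m a \code{\link{dist_matrix}} (or plain labelled matrix).
#' @export
write_dist_matrix <- function(m, path) {
  df <- data.frame(station = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
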