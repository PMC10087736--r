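#' Alternate-allele frequency at one station
#'
#' The frequency of the alternate allele at a SNP in a station is
#' \code{alt_count / (ref_count + alt_count)}. A cell with zero coverage has
#' no defined frequency (the SNP is unobserved there).
#'
#' @param table an \code{\link{allele_count_table}} (normally post-filter).
#' @param snp_id,station cell to query.
#' @return Frequency in \code{[0, 1]}, or \code{NA} if unobserved.
#' @seealso \code{\link{allele_frequencies}} for the full matrix.
#' @export
allele_frequency <- function(table, snp_id, station) {
  p <- allele_frequencies(table)
  i <- match(snp_id, table$snps$snp_id)
  j <- match(station, table$stations)
  if (is.na(i)) stop("unknown snp_id: ", snp_id)
  if (is.na(j)) stop("unknown station: ", station)
  p[i, j]
}

#' Alternate-allele frequency matrix
#'
#' @param table an \code{\link{allele_count_table}}.
#' @return SNP x station matrix of alternate-allele frequencies, \code{NA}
#'   where the cell is unobserved (zero coverage).
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "allele_count_table"))
  cov <- coverage(table)
  p <- table$alt_counts / cov
  p[cov == 0] <- NA_real_
  p
}

#' Per-SNP FST between two stations (Wright, pair-restricted)
#'
#' For alternate-allele frequencies \code{p1}, \code{p2} at the two stations
#' of a pair, the mean frequency \code{pbar = (p1 + p2) / 2} is computed over
#' those two stations only (never over all stations). With total expected
#' heterozygosity \code{H_T = 2 pbar (1 - pbar)} and mean within-station
#' heterozygosity \code{H_S = p1 (1 - p1) + p2 (1 - p2)},
#' \deqn{F_{ST} = (H_T - H_S) / H_T = (p_1 - p_2)^2 / (4 \bar p (1 - \bar p)).}
#' FST is undefined (NA) when \code{H_T = 0}, i.e. both stations fixed for the
#' same allele; such SNPs carry no information and are excluded from the
#' pair's median.
#'
#' @param p1,p2 frequencies in \code{[0, 1]}; vectorized.
#' @return FST values in \code{[0, 1]}, \code{NA} where undefined.
#' @export
snp_pair_fst <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  # algebraically (H_T - H_S) = (p1 - p2)^2 / 2; this form is non-negative in
  # floating point
  fst <- (p1 - p2)^2 / (2 * ht)
  fst[ht == 0] <- NA_real_
  pmin(fst, 1)
}

#' Pairwise median-FST genomic distance matrix
#'
#' For each unordered pair of stations, the shared-SNP set is the set of SNPs
#' observed (post-filter) at both stations; the pair's genomic distance is the
#' median of the defined per-SNP FST values (\code{\link{snp_pair_fst}}) over
#' that set. Pairs sharing no SNP get a missing entry (no genomic
#' differentiation can be computed). The global FST is the arithmetic mean of
#' the non-missing pairwise entries, each unordered pair counted once.
#'
#' @param table a filtered \code{\link{allele_count_table}}.
#' @param keep_per_snp if \code{TRUE}, also return the long table of per-SNP
#'   FST values for every pair (can be large).
#' @return An object of class \code{pairwise_fst}: list with \code{matrix} (a
#'   genomic \code{\link{dist_matrix}}), \code{n_shared_snps} (station x
#'   station integer matrix), \code{global_fst}, and optionally
#'   \code{per_snp}.
#' @export
pairwise_fst_matrix <- function(table, keep_per_snp = FALSE) {
  stopifnot(inherits(table, "allele_count_table"))
  if (length(table$stations) < 2) stop("need at least 2 stations")
  p <- allele_frequencies(table)
  res <- pairwise_fst_from_freqs(p, snp_ids = table$snps$snp_id,
                                 keep_per_snp = keep_per_snp)
  res
}

#' Pairwise median FST from a frequency matrix
#'
#' Same computation as \code{\link{pairwise_fst_matrix}} but starting from a
#' SNP x station matrix of allele frequencies (\code{NA} = unobserved). With
#' true population frequencies this is the infinite-coverage estimate, free of
#' read-sampling noise.
#'
#' @param p SNP x station frequency matrix; column names are station ids.
#' @param snp_ids optional SNP ids for the per-SNP long table.
#' @param keep_per_snp keep the per-SNP FST long table.
#' @return A \code{pairwise_fst} object (see \code{\link{pairwise_fst_matrix}}).
#' @export
pairwise_fst_from_freqs <- function(p, snp_ids = NULL, keep_per_snp = FALSE) {
  p <- as.matrix(p)
  stations <- colnames(p)
  if (is.null(stations)) stop("frequency matrix needs station column names")
  ns <- length(stations)
  if (ns < 2) stop("need at least 2 stations")
  if (is.null(snp_ids)) snp_ids <- rownames(p)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(p)))
  m <- matrix(NA_real_, ns, ns, dimnames = list(stations, stations))
  nshared <- matrix(0L, ns, ns, dimnames = list(stations, stations))
  diag(m) <- 0
  per_snp <- if (keep_per_snp) vector("list", ns * (ns - 1) / 2) else NULL
  k <- 0L
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      k <- k + 1L
      shared <- !is.na(p[, i]) & !is.na(p[, j])
      nshared[i, j] <- nshared[j, i] <- sum(shared)
      if (!any(shared)) next
      fst <- snp_pair_fst(p[shared, i], p[shared, j])
      if (keep_per_snp) {
        per_snp[[k]] <- data.frame(snp_id = snp_ids[shared],
                                   station_a = stations[i],
                                   station_b = stations[j],
                                   fst = fst, stringsAsFactors = FALSE)
      }
      fst <- fst[!is.na(fst)]  # drop SNPs fixed for the same allele
      if (length(fst)) m[i, j] <- m[j, i] <- stats::median(fst)
    }
  }
  gm <- dist_matrix(m, "genomic")
  structure(
    list(matrix = gm,
         n_shared_snps = nshared,
         global_fst = global_fst(gm),
         per_snp = if (keep_per_snp) do.call(rbind, per_snp) else NULL),
    class = "pairwise_fst")
}

#' Global FST: mean of non-missing pairwise entries
#' @param m a genomic \code{\link{dist_matrix}} (or \code{pairwise_fst}).
#' @return Mean of the non-missing off-diagonal entries, each unordered pair
#'   counted once.
#' @export
global_fst <- function(m) {
  if (inherits(m, "pairwise_fst")) m <- m$matrix
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' @export
print.pairwise_fst <- function(x, ...) {
  nmiss <- sum(is.na(x$matrix[upper.tri(x$matrix)]))
  cat(sprintf("pairwise_fst: %d stations, %d pair(s) with no shared SNP\n",
              nrow(x$matrix), nmiss))
  cat(sprintf("  global FST (mean pairwise): %.4f [%s differentiation]\n",
              x$global_fst, classify_fst(x$global_fst)))
  invisible(x)
}

#' Classify an FST value into differentiation classes
#'
#' Standard population-genetics bins: below 0.05 little, 0.05-0.15 moderate,
#' 0.15-0.25 high, above 0.25 very high differentiation. Boundary values fall
#' in the lower-open/upper-closed class, so 0.05 and 0.15 are moderate and
#' 0.25 is high.
#'
#' @param fst numeric vector in \code{[0, 1]}.
#' @return Factor with levels \code{little < moderate < high < very_high}.
#' @export
classify_fst <- function(fst) {
  if (any(fst < 0 | fst > 1, na.rm = TRUE)) stop("FST must lie in [0, 1]")
  lev <- c("little", "moderate", "high", "very_high")
  out <- ifelse(fst < 0.05, "little",
         ifelse(fst <= 0.15, "moderate",
         ifelse(fst <= 0.25, "high", "very_high")))
  factor(out, levels = lev, ordered = TRUE)
}

#' Complete-linkage clustering of stations on a genomic distance matrix
#'
#' Missing pairwise entries (station pairs sharing no SNP) are replaced by the
#' mean of the non-missing off-diagonal entries, for clustering only; the
#' regression stage never sees imputed values. Agglomeration is hierarchical
#' with complete linkage.
#'
#' @param m a genomic \code{\link{dist_matrix}} (or \code{pairwise_fst}).
#' @return List of class \code{fst_clustering}: \code{hclust} (a
#'   \code{stats::hclust} tree), \code{imputed} (the imputed matrix used), and
#'   \code{n_imputed}.
#' @export
cluster_stations <- function(m) {
  if (inherits(m, "pairwise_fst")) m <- m$matrix
  if (nrow(m) < 2) stop("need at least 2 stations")
  off <- upper.tri(m)
  if (all(is.na(m[off]))) stop("all pairwise entries missing; cannot cluster")
  imp <- unclass(m)
  fill <- mean(imp[off], na.rm = TRUE)
  n_imputed <- sum(is.na(imp[off]))
  imp[is.na(imp)] <- fill
  diag(imp) <- 0
  hc <- stats::hclust(stats::as.dist(imp), method = "complete")
  structure(list(hclust = hc, imputed = imp, n_imputed = n_imputed),
            class = "fst_clustering")
}

#' @export
print.fst_clustering <- function(x, ...) {
  cat(sprintf("fst_clustering: complete linkage on %d stations (%d pair(s) mean-imputed)\n",
              nrow(x$imputed), x$n_imputed))
  print(x$hclust)
  invisible(x)
}

#' Export a station dendrogram in Newick format
#' @param clustering an \code{fst_clustering} from \code{\link{cluster_stations}}.
#' @param path output file.
#' @export
write_dendrogram <- function(clustering, path) {
  stopifnot(inherits(clustering, "fst_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
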