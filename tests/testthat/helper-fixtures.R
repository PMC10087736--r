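# in-code fixtures and independent oracles shared across test files

# small allele-count table from a long specification:
# counts = list(station = list(c(ref, alt) per snp))
make_table <- function(ref, alt, stations = NULL, species = "toy") {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(stations)) stations <- sprintf("s%d", seq_len(ncol(ref)))
  colnames(ref) <- colnames(alt) <- stations
  n <- nrow(ref)
  nts <- c("A", "C", "G", "T")
  snps <- data.frame(snp_id = sprintf("snp%03d", seq_len(n)),
                     contig = "c1", pos = seq_len(n),
                     ref = rep(nts[1], n), alt = rep(nts[2], n),
                     stringsAsFactors = FALSE)
  allele_count_table(snps, ref, alt, species)
}

random_table <- function(n_snps, n_stations, p_zero = 0.3, max_cov = 30) {
  cov <- matrix(stats::rbinom(n_snps * n_stations, max_cov, 0.4), n_snps)
  cov[stats::runif(length(cov)) < p_zero] <- 0L
  alt <- matrix(stats::rbinom(length(cov), as.vector(cov), 0.5), n_snps)
  make_table(cov - alt, alt, sprintf("st%d", seq_len(n_stations)))
}

# brute-force double-loop oracle for the coverage filter: returns the set of
# retained "snp|station" cell keys
oracle_filter_cells <- function(tab, min_cov = 4, sigma_mult = 2, min_alt = 1) {
  kept <- character(0)
  for (j in seq_along(tab$stations)) {
    covs <- numeric(0)
    for (i in seq_len(nrow(tab$snps))) {
      ci <- tab$ref_counts[i, j] + tab$alt_counts[i, j]
      if (ci >= 1) covs <- c(covs, ci)
    }
    if (length(covs) >= 2) {
      m <- sum(covs) / length(covs)
      s <- sqrt(sum((covs - m)^2) / (length(covs) - 1))
      up <- m + sigma_mult * s
    } else {
      up <- Inf
    }
    for (i in seq_len(nrow(tab$snps))) {
      ci <- tab$ref_counts[i, j] + tab$alt_counts[i, j]
      if (ci >= min_cov && ci < up && tab$alt_counts[i, j] >= min_alt) {
        kept <- c(kept, paste(tab$snps$snp_id[i], tab$stations[j], sep = "|"))
      }
    }
  }
  sort(kept)
}

observed_cells <- function(tab) {
  cov <- tab$ref_counts + tab$alt_counts
  idx <- which(cov > 0, arr.ind = TRUE)
  sort(paste(tab$snps$snp_id[idx[, 1]], tab$stations[idx[, 2]], sep = "|"))
}

# independent per-pair median FST: explicit loops, heterozygosity form,
# own median
oracle_fst_matrix <- function(tab) {
  ns <- length(tab$stations)
  m <- matrix(NA_real_, ns, ns, dimnames = list(tab$stations, tab$stations))
  diag(m) <- 0
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      vals <- numeric(0)
      for (i in seq_len(nrow(tab$snps))) {
        ca <- tab$ref_counts[i, a] + tab$alt_counts[i, a]
        cb <- tab$ref_counts[i, b] + tab$alt_counts[i, b]
        if (ca == 0 || cb == 0) next
        p1 <- tab$alt_counts[i, a] / ca
        p2 <- tab$alt_counts[i, b] / cb
        pb <- (p1 + p2) / 2
        ht <- 2 * pb * (1 - pb)
        if (ht == 0) next
        hs <- p1 * (1 - p1) + p2 * (1 - p2)
        vals <- c(vals, (ht - hs) / ht)
      }
      if (length(vals)) {
        v <- sort(vals)
        n <- length(v)
        med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
        m[a, b] <- m[b, a] <- med
      }
    }
  }
  m
}

# naive O(n^3) complete-linkage agglomeration; returns sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link < best) { best <- link; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# O(V^2) Dijkstra on an explicit weight matrix (Inf = no edge)
oracle_dijkstra <- function(w, source) {
  n <- nrow(w)
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!done)[which.min(dist[!done])]
    if (!length(u) || is.infinite(dist[u])) break
    done[u] <- TRUE
    for (v in seq_len(n)) {
      if (!done[v] && w[u, v] < Inf && dist[u] + w[u, v] < dist[v]) {
        dist[v] <- dist[u] + w[u, v]
      }
    }
  }
  dist
}

# closed-form haversine, written out (not via geosphere), km
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(a))
}

# explicit 8-connected sea-cell weight matrix for the Dijkstra oracle
oracle_cell_weights <- function(grid) {
  idx <- which(grid$mask, arr.ind = TRUE)
  n <- nrow(idx)
  w <- matrix(Inf, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (abs(idx[a, 1] - idx[b, 1]) <= 1 && abs(idx[a, 2] - idx[b, 2]) <= 1) {
        w[a, b] <- oracle_haversine_km(grid$lat_axis[idx[a, 1]], grid$lon_axis[idx[a, 2]],
                                       grid$lat_axis[idx[b, 1]], grid$lon_axis[idx[b, 2]])
      }
    }
  }
  w
}

# exhaustive OLS/BIC by the normal equations
oracle_bic_select <- function(obs, terms = c("geo", "env", "pc", "mct")) {
  n <- nrow(obs)
  subsets <- list(character(0))
  for (tm in terms) subsets <- c(subsets, lapply(subsets, c, tm))
  bic <- vapply(subsets, function(s) {
    X <- matrix(1, n, 1)
    for (tm in s) X <- cbind(X, obs[[paste0("x_", tm)]])
    beta <- solve(t(X) %*% X, t(X) %*% obs$y)
    rss <- sum((obs$y - X %*% beta)^2)
    n * log(rss / n) + ncol(X) * log(n)
  }, numeric(1))
  sizes <- lengths(subsets)
  cand <- which(bic == min(bic))
  best <- cand[which.min(sizes[cand])]
  list(terms = sort(subsets[[best]]), bic = bic[best], all_bic = bic)
}

random_pair_obs <- function(n = 78, terms = c("geo", "env", "pc", "mct"),
                            signal = NULL) {
  obs <- data.frame(station_a = paste0("a", seq_len(n)),
                    station_b = paste0("b", seq_len(n)),
                    y = stats::rnorm(n), stringsAsFactors = FALSE)
  for (tm in terms) obs[[paste0("x_", tm)]] <- stats::rnorm(n)
  if (!is.null(signal)) {
    for (tm in names(signal)) obs$y <- obs$y + signal[[tm]] * obs[[paste0("x_", tm)]]
  }
  class(obs) <- c("pair_obs", "data.frame")
  obs
}

# minimal VCF with AD fields: biallelic row, multi-allelic row, indel row
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMP1", "SAMP2", sep = "\t"),
    paste("chr1", "100", ".", "A", "C", ".", "PASS", ".", "GT:AD",
          "0/1:8,2", "1/1:0,5", sep = "\t"),
    paste("chr1", "200", ".", "A", "C,T", ".", "PASS", ".", "GT:AD",
          "0/1:5,1,4", "0/1:3,0,6", sep = "\t"),
    paste("chr1", "300", ".", "A", "AT", ".", "PASS", ".", "GT:AD",
          "0/1:4,3", "0/0:5,0", sep = "\t"))
  writeLines(lines, path)
  path
}

quiet_filter <- function(...) {
  suppressMessages(suppressWarnings(filter_snps_by_coverage(...)))
}

# drop class/kind attributes, keep dim + dimnames, for matrix comparisons
strip_dm <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}
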