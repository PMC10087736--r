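test_that("per-SNP pair FST has the closed-form heterozygosity values", {
  # pbar = 0.5, H_T = 0.5, H_S = 0.32 -> (0.5 - 0.32)/0.5
  expect_equal(snp_pair_fst(0.2, 0.8), 0.36)
  expect_equal(snp_pair_fst(0.37, 0.37), 0)
  expect_equal(snp_pair_fst(0, 1), 1)
  expect_equal(snp_pair_fst(1, 0), 1)
  expect_true(is.na(snp_pair_fst(0, 0)))  # both fixed for the same allele
  expect_true(is.na(snp_pair_fst(1, 1)))
  expect_error(snp_pair_fst(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(snp_pair_fst(0.5, 1.2), "\\[0, 1\\]")
})

test_that("allele frequencies are alt/(ref+alt), absent at zero coverage", {
  tab <- make_table(ref = cbind(c(8L, 0L, 4L, 0L)), alt = cbind(c(2L, 5L, 0L, 0L)))
  expect_equal(allele_frequency(tab, "snp001", "s1"), 0.2)
  expect_equal(allele_frequency(tab, "snp002", "s1"), 1.0)
  expect_equal(allele_frequency(tab, "snp003", "s1"), 0.0)
  expect_true(is.na(allele_frequency(tab, "snp004", "s1")))
})

test_that("pairwise entry is the median FST over shared SNPs", {
  # frequencies chosen so the three shared per-SNP FSTs are {0, 0.1, 0.5}:
  # p-pairs (0.5, 0.5) -> 0; (0.3, 0.5) -> 0.1/... compute directly instead
  p <- cbind(s1 = c(0.5, 0.2, 0.1), s2 = c(0.5, 0.4, 0.9))
  per_snp <- snp_pair_fst(p[, 1], p[, 2])
  res <- pairwise_fst_from_freqs(p)
  expect_equal(res$matrix["s1", "s2"], median(per_snp))
  expect_equal(res$n_shared_snps["s1", "s2"], 3L)
})

test_that("even-count medians take the midpoint of the central values", {
  p <- cbind(s1 = c(0.1, 0.1, 0.5, 0.5), s2 = c(0.9, 0.5, 0.9, 0.1))
  per_snp <- sort(snp_pair_fst(p[, 1], p[, 2]))
  res <- pairwise_fst_from_freqs(p)
  expect_equal(res$matrix["s1", "s2"], (per_snp[2] + per_snp[3]) / 2)
})

test_that("pairs sharing no SNP get missing entries; global FST averages the rest", {
  # s1/s3 never observed together
  ref <- cbind(c(4L, 4L, 0L, 0L), c(4L, 4L, 4L, 4L), c(0L, 0L, 4L, 4L))
  alt <- cbind(c(1L, 2L, 0L, 0L), c(2L, 1L, 1L, 2L), c(0L, 0L, 2L, 1L))
  tab <- make_table(ref, alt)
  res <- pairwise_fst_matrix(tab)
  expect_true(is.na(res$matrix["s1", "s3"]))
  expect_equal(res$n_shared_snps["s1", "s3"], 0L)
  non_missing <- res$matrix[upper.tri(res$matrix)]
  expect_equal(res$global_fst, mean(non_missing, na.rm = TRUE))
  # the simple arithmetic case
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3)
  m <- m + t(m)
  expect_equal(global_fst(dist_matrix(m, "genomic")), 0.2)
})

test_that("median-FST matrix equals the brute-force double loop on random tables", {
  set.seed(7)
  for (rep in 1:15) {
    tab <- random_table(sample(10:40, 1), 5)
    res <- pairwise_fst_matrix(tab)
    expect_equal(strip_dm(res$matrix), oracle_fst_matrix(tab), tolerance = 1e-12)
  }
})

test_that("FST matrix is within [0,1], symmetric, and invariant to row/column order", {
  set.seed(11)
  tab <- random_table(30, 4)
  res <- pairwise_fst_matrix(tab)
  vals <- res$matrix[upper.tri(res$matrix)]
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  expect_equal(strip_dm(res$matrix), t(strip_dm(res$matrix)))
  # permute SNPs and stations
  perm_snp <- sample(nrow(tab$snps))
  perm_st <- c(3, 1, 4, 2)
  tab2 <- allele_count_table(tab$snps[perm_snp, ],
                             tab$ref_counts[perm_snp, perm_st],
                             tab$alt_counts[perm_snp, perm_st])
  res2 <- pairwise_fst_matrix(tab2)
  expect_equal(strip_dm(res2$matrix)[tab$stations, tab$stations],
               strip_dm(res$matrix))
})

test_that("differentiation classes follow the standard bins with closed upper bounds", {
  expect_equal(as.character(classify_fst(c(0.136, 0.476, 0.045))),
               c("moderate", "very_high", "little"))
  expect_equal(as.character(classify_fst(c(0.05, 0.15, 0.25, 0.2500001))),
               c("moderate", "moderate", "high", "very_high"))
  expect_equal(as.character(classify_fst(0.0499999)), "little")
  expect_error(classify_fst(1.2), "\\[0, 1\\]")
})

test_that("complete-linkage clustering merges an unambiguous ultrametric correctly", {
  m <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- cluster_stations(dist_matrix(m, "genomic"))
  expect_equal(cl$hclust$height, c(0.1, 0.5))
  first_merge <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(first_merge, c("A", "B"))
})

test_that("missing entries are mean-imputed for clustering only", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- m["b", "a"] <- 0.1
  m["a", "c"] <- m["c", "a"] <- 0.3
  m["b", "c"] <- m["c", "b"] <- NA
  cl <- cluster_stations(dist_matrix(m, "genomic"))
  expect_equal(cl$imputed["b", "c"], 0.2)  # mean of 0.1 and 0.3
  expect_equal(cl$n_imputed, 1)
  all_na <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  diag(all_na) <- 0
  expect_error(cluster_stations(dist_matrix(all_na, "genomic")), "missing")
})

test_that("merge heights equal the naive O(n^3) agglomeration oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    cl <- cluster_stations(dist_matrix(m, "genomic"))
    expect_equal(sort(cl$hclust$height), oracle_complete_linkage_heights(m),
                 tolerance = 1e-12)
  }
})

test_that("read sampling inflates FST; the bias shrinks with coverage", {
  # island model truth shared across coverage levels (paired seeds)
  inflation <- function(mean_cov, seed) {
    cfg <- sim_config(scenario = "island", F = 0.15, n_snps = 800,
                      n_stations = 8, mean_coverage = mean_cov, seed = seed)
    sim <- simulate_dataset(cfg)
    inf <- pairwise_fst_from_freqs(t(sim$truth$true_freqs))
    ft <- quiet_filter(sim$table)
    est <- pairwise_fst_matrix(ft)
    est$global_fst - inf$global_fst
  }
  gaps <- vapply(1:3, function(s) {
    c(low = inflation(5, 100 + s), high = inflation(50, 100 + s))
  }, numeric(2))
  expect_true(all(gaps["low", ] > 0))
  expect_true(all(gaps["high", ] < gaps["low", ]))
})
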