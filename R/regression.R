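#' Normalized genomic distance FST/(1 - FST)
#'
#' The linearized genomic distance used as the regression response. An FST of
#' exactly 1 has no finite normalized distance; such pairs are returned as
#' \code{NA} with a warning and dropped by \code{\link{assemble_pairs}}.
#'
#' @param fst numeric vector in \code{[0, 1]}.
#' @return \code{fst / (1 - fst)}, \code{NA} where \code{fst == 1}.
#' @export
normalize_fst <- function(fst) {
  if (any(fst < 0 | fst > 1, na.rm = TRUE)) stop("FST must lie in [0, 1]")
  out <- fst / (1 - fst)
  if (any(fst == 1, na.rm = TRUE)) {
    warning("FST = 1 has undefined normalized distance; pair(s) dropped",
            call. = FALSE)
    out[fst == 1] <- NA_real_
  }
  out
}

#' Assemble per-pair regression observations
#'
#' Builds one observation per unordered station pair with a non-missing
#' genomic entry: the response \code{y = FST/(1-FST)} and the four candidate
#' regressors (geographic km, environmental PCA distance, probability of
#' connection, mean connection time in days). Pairs with missing genomic FST
#' are excluded, never imputed.
#'
#' @param genomic genomic \code{\link{dist_matrix}} (or \code{pairwise_fst}).
#' @param geo,env,pc,mct the explanatory \code{\link{dist_matrix}} layers;
#'   any of them may be \code{NULL} to omit that candidate term.
#' @return data.frame of class \code{pair_obs} with columns
#'   \code{station_a}, \code{station_b}, \code{y} and the available
#'   \code{x_geo}, \code{x_env}, \code{x_pc}, \code{x_mct}.
#' @export
assemble_pairs <- function(genomic, geo = NULL, env = NULL, pc = NULL,
                           mct = NULL) {
  if (inherits(genomic, "pairwise_fst")) genomic <- genomic$matrix
  labels <- rownames(genomic)
  layers <- list(x_geo = geo, x_env = env, x_pc = pc, x_mct = mct)
  layers <- layers[!vapply(layers, is.null, logical(1))]
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!setequal(rownames(m), labels)) {
      stop("station labels of ", nm, " do not match the genomic matrix")
    }
    layers[[nm]] <- m[labels, labels]
  }
  ut <- which(upper.tri(genomic), arr.ind = TRUE)
  y <- normalize_fst(genomic[upper.tri(genomic)])
  obs <- data.frame(station_a = labels[ut[, 1]], station_b = labels[ut[, 2]],
                    y = y, stringsAsFactors = FALSE)
  for (nm in names(layers)) obs[[nm]] <- layers[[nm]][upper.tri(genomic)]
  obs <- obs[!is.na(obs$y), , drop = FALSE]
  xcols <- setdiff(names(obs), c("station_a", "station_b", "y"))
  if (length(xcols) && any(!is.finite(as.matrix(obs[xcols])))) {
    stop("non-finite regressor values in assembled pairs")
  }
  rownames(obs) <- NULL
  class(obs) <- c("pair_obs", "data.frame")
  obs
}

# OLS fit of y on the given terms (x_<term> columns), intercept always
# included; returns coefficients, RSS, R^2, t and F tests
fit_pair_model <- function(obs, terms) {
  n <- nrow(obs)
  X <- cbind(`(Intercept)` = rep(1, n))
  for (tm in terms) X <- cbind(X, obs[[paste0("x_", tm)]])
  colnames(X) <- c("(Intercept)", terms)
  fit <- stats::lm.fit(X, obs$y)
  k <- fit$rank
  rss <- sum(fit$residuals^2)
  tss <- sum((obs$y - mean(obs$y))^2)
  sigma2 <- rss / (n - k)
  XtX_inv <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- fit$coefficients[seq_len(k)] / se
  pval <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  # overall F: selected model vs intercept-only
  f_p <- if (length(terms)) {
    f <- ((tss - rss) / length(terms)) / sigma2
    stats::pf(f, length(terms), n - k, lower.tail = FALSE)
  } else NA_real_
  list(terms = terms, coefficients = fit$coefficients, se = se,
       t_pvalues = pval, rss = rss, r2 = r2, overall_f_pvalue = f_p,
       n = n, k = k, rank_ok = k == ncol(X))
}

bic_of <- function(n, rss, k) n * log(rss / n) + k * log(n)

#' Exhaustive BIC model selection for drivers of genomic differentiation
#'
#' Fits ordinary least squares of \code{y = FST/(1-FST)} on every subset of
#' the candidate distance terms (the intercept is always included; with the
#' four standard terms this is 2^4 = 16 models) and selects the subset
#' minimizing \eqn{BIC = n \ln(RSS/n) + k \ln(n)}, with \code{k} the number
#' of estimated coefficients including the intercept. Ties are broken toward
#' the smaller model. The selected model is reported with its coefficients,
#' two-sided t-test p-values per term (significance threshold
#' \code{alpha}), the Fisher F-test of the selected model against the
#' intercept-only null, and the determination coefficient R^2 in percent.
#'
#' @param obs a \code{pair_obs} data.frame from \code{\link{assemble_pairs}}.
#' @param terms candidate terms; defaults to those present in \code{obs}.
#' @param alpha significance threshold for the per-term t tests.
#' @return Object of class \code{ibd_ibe_fit}: \code{selected_terms},
#'   \code{beta} (named, incl. intercept), \code{t_pvalues},
#'   \code{overall_f_pvalue}, \code{r2_percent}, \code{bic_table} (all
#'   subsets with RSS, k, BIC), \code{n}, \code{alpha},
#'   \code{significant_terms}.
#' @export
exhaustive_bic_select <- function(obs, terms = NULL, alpha = 0.05) {
  xcols <- grep("^x_", names(obs), value = TRUE)
  if (is.null(terms)) terms <- sub("^x_", "", xcols)
  missing_terms <- setdiff(paste0("x_", terms), names(obs))
  if (length(missing_terms)) {
    stop("obs lacks column(s): ", paste(missing_terms, collapse = ", "))
  }
  n <- nrow(obs)
  if (n < 6) stop("need at least 6 pair observations, got ", n)
  # guard against collinear regressors: drop offenders up front
  X_full <- as.matrix(cbind(1, obs[paste0("x_", terms)]))
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    keep <- qr_full$pivot[seq_len(qr_full$rank)]
    dropped <- setdiff(seq_len(ncol(X_full)), keep)
    dropped_terms <- terms[dropped - 1]
    warning("dropping collinear term(s): ", paste(dropped_terms, collapse = ", "),
            call. = FALSE)
    terms <- setdiff(terms, dropped_terms)
  }
  nt <- length(terms)
  subsets <- lapply(0:(2^nt - 1), function(b) terms[bitwAnd(b, 2^(seq_len(nt) - 1)) > 0])
  fits <- lapply(subsets, function(s) fit_pair_model(obs, s))
  bic <- vapply(fits, function(f) bic_of(n, f$rss, f$k), numeric(1))
  k_all <- vapply(fits, `[[`, numeric(1), "k")
  # minimal BIC; exact ties broken toward the smaller model
  cand <- which(bic == min(bic))
  best <- cand[which.min(k_all[cand])]
  sel <- fits[[best]]
  bic_table <- data.frame(
    terms = vapply(subsets, function(s) if (length(s)) paste(s, collapse = "+") else "(intercept)",
                   character(1)),
    n_terms = lengths(subsets),
    k = k_all, rss = vapply(fits, `[[`, numeric(1), "rss"), bic = bic,
    selected = seq_along(fits) == best,
    stringsAsFactors = FALSE)
  tp <- sel$t_pvalues[-1]
  structure(
    list(selected_terms = sel$terms,
         beta = sel$coefficients,
         t_pvalues = tp,
         overall_f_pvalue = sel$overall_f_pvalue,
         r2_percent = 100 * sel$r2,
         bic_table = bic_table[order(bic_table$bic), ],
         n = n, alpha = alpha,
         significant_terms = names(tp)[!is.na(tp) & tp < alpha],
         null_selected = length(sel$terms) == 0),
    class = "ibd_ibe_fit")
}

#' @export
print.ibd_ibe_fit <- function(x, ...) {
  cat("Drivers of genomic differentiation (exhaustive BIC selection)\n")
  cat(sprintf("  n pairs: %d; models compared: %d\n", x$n, nrow(x$bic_table)))
  if (x$null_selected) {
    cat("  selected model: intercept-only (no distance term improves BIC)\n")
  } else {
    cat("  selected terms:", paste(x$selected_terms, collapse = ", "), "\n")
    for (tm in x$selected_terms) {
      cat(sprintf("    beta_%s = %.4g  (t-test p = %.4g%s)\n", tm, x$beta[tm],
                  x$t_pvalues[tm],
                  if (tm %in% x$significant_terms) ", significant" else ""))
    }
    cat(sprintf("  overall F-test vs null model: p = %.4g\n", x$overall_f_pvalue))
    cat(sprintf("  R2 = %.2f%%\n", x$r2_percent))
  }
  invisible(x)
}

#' Write the selection result as a summary table (plus full BIC trace)
#'
#' One row shaped like a results table: overall p-value, selected terms,
#' coefficients and their p-values, R^2 in percent. A second TSV receives the
#' full 2^t-model BIC table.
#'
#' @param result an \code{ibd_ibe_fit}.
#' @param path summary TSV path.
#' @param bic_path optional path for the full BIC table TSV.
#' @return \code{path}, invisibly.
#' @export
write_regression_report <- function(result, path, bic_path = NULL) {
  stopifnot(inherits(result, "ibd_ibe_fit"))
  row <- data.frame(overall_p = result$overall_f_pvalue,
                    selected_terms = if (result$null_selected) "(none)" else
                      paste(result$selected_terms, collapse = "+"),
                    stringsAsFactors = FALSE)
  for (tm in result$selected_terms) {
    row[[paste0("beta_", tm)]] <- unname(result$beta[tm])
    row[[paste0("p_", tm)]] <- unname(result$t_pvalues[tm])
  }
  row$r2_percent <- if (result$null_selected) NA_real_ else result$r2_percent
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bic_path)) {
    utils::write.table(result$bic_table, bic_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Permutation (Mantel-style) cross-check of the selected model
#'
#' Pairwise observations are not independent: pairs sharing a station are
#' correlated, which plain OLS ignores. As a cross-check, station identities
#' are permuted (rows/columns of the genomic matrix relabelled), the selected
#' model is refit on each permuted pairing, and the p-value is the fraction
#' of permutations whose R^2 reaches the observed one. Pairs whose permuted
#' genomic entry is missing are dropped, mirroring the unpermuted analysis.
#'
#' @param obs a \code{pair_obs} data.frame.
#' @param result an \code{ibd_ibe_fit} with at least one selected term.
#' @param n_perm number of permutations.
#' @return List with \code{p_value}, \code{observed_r2}, \code{n_perm}.
#' @export
permutation_check <- function(obs, result, n_perm = 999) {
  stopifnot(inherits(result, "ibd_ibe_fit"))
  if (result$null_selected) stop("selected model has no terms to check")
  stations <- sort(unique(c(obs$station_a, obs$station_b)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  y_lookup <- stats::setNames(obs$y, key(obs$station_a, obs$station_b))
  obs_r2 <- fit_pair_model(obs, result$selected_terms)$r2
  perm_r2 <- vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(sample(stations), stations)
    yp <- y_lookup[key(perm[obs$station_a], perm[obs$station_b])]
    ok <- !is.na(yp)
    if (sum(ok) < length(result$selected_terms) + 2) return(NA_real_)
    o2 <- obs[ok, , drop = FALSE]
    o2$y <- yp[ok]
    fit_pair_model(o2, result$selected_terms)$r2
  }, numeric(1))
  perm_r2 <- perm_r2[!is.na(perm_r2)]
  list(p_value = (1 + sum(perm_r2 >= obs_r2)) / (1 + length(perm_r2)),
       observed_r2 = obs_r2, n_perm = length(perm_r2))
}
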