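#' QC threshold set
#'
#' Bundles the marker/sample quality thresholds used when cleaning a
#' reference panel: minimum minor allele frequency, maximum per-SNP and
#' per-individual missingness, and the LD pruning parameters. Defaults match
#' the panel-level properties the estimator expects (MAF > 1\%, per-SNP
#' missingness < 5\%, per-individual missingness < 1\%, pairwise r-squared
#' below 0.1 within a sliding window).
#'
#' @param min_maf minimum minor allele frequency in `[0, 0.5]` (strict:
#'   retained SNPs have MAF `> min_maf`).
#' @param max_snp_missing maximum per-SNP missing fraction (strict).
#' @param max_ind_missing maximum per-individual missing fraction (strict).
#' @param ld_r2 squared-correlation pruning threshold in `(0, 1]`.
#' @param ld_window sliding window size in markers (`>= 2`).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01, max_snp_missing = 0.05,
                          max_ind_missing = 0.01, ld_r2 = 0.1,
                          ld_window = 50) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_snp_missing >= 0, max_snp_missing <= 1,
            max_ind_missing >= 0, max_ind_missing <= 1,
            ld_r2 > 0, ld_r2 <= 1)
  if (ld_window < 2) stop("ld_window must be >= 2")
  structure(list(min_maf = min_maf, max_snp_missing = max_snp_missing,
                 max_ind_missing = max_ind_missing, ld_r2 = ld_r2,
                 ld_window = as.integer(ld_window)),
            class = "qc_thresholds")
}

minor_af <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Minor allele frequency filter
#'
#' Retains SNPs whose minor allele frequency, computed over non-missing
#' genotypes of the pooled samples, is strictly greater than `min_maf`.
#'
#' @param x a [genotype_matrix()].
#' @param min_maf frequency threshold in `[0, 0.5]`.
#' @return filtered `genotype_matrix`; removed variant IDs in attribute
#'   `removed`.
#' @export
filter_maf <- function(x, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  maf <- minor_af(x$G)
  keep <- !is.nan(maf) & maf > min_maf
  if (!any(keep)) warning("all SNPs removed by the MAF filter")
  out <- subset_genotypes(x, variants = which(keep))
  attr(out, "removed") <- x$variants$id[!keep]
  out
}

#' Missingness filters
#'
#' Applies the per-SNP missingness filter first, then the per-individual
#' filter on the surviving markers; both are strict (kept rows/columns have
#' missing fraction `< threshold`).
#'
#' @param x a [genotype_matrix()].
#' @param max_snp_missing,max_ind_missing fractions in `[0, 1]`.
#' @return filtered `genotype_matrix`; attributes `removed_snps` and
#'   `removed_samples` list what was dropped.
#' @export
filter_missingness <- function(x, max_snp_missing = 0.05,
                               max_ind_missing = 0.01) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1,
            max_ind_missing >= 0, max_ind_missing <= 1)
  snp_miss <- colMeans(is.na(x$G))
  keep_v <- snp_miss < max_snp_missing
  y <- subset_genotypes(x, variants = which(keep_v))
  ind_miss <- if (n_variants(y) > 0) rowMeans(is.na(y$G)) else
    rep(0, n_samples(y))
  keep_s <- ind_miss < max_ind_missing
  if (!any(keep_v) || !any(keep_s))
    warning("missingness filter produced an empty matrix")
  out <- subset_genotypes(y, samples = which(keep_s))
  attr(out, "removed_snps") <- x$variants$id[!keep_v]
  attr(out, "removed_samples") <- x$samples[!keep_s]
  out
}

# Squared Pearson correlation between mean-imputed genotype columns.
impute_means <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2]]
  G
}

#' Greedy LD pruning
#'
#' Left-to-right scan within each chromosome: a marker is removed when its
#' squared Pearson correlation (on mean-imputed genotype vectors) with any of
#' the previous `window - 1` retained markers on the same chromosome strictly
#' exceeds `r2_threshold`; the earlier marker is always the one kept.
#'
#' @param x a [genotype_matrix()].
#' @param r2_threshold squared-correlation threshold in `(0, 1]`.
#' @param window sliding window size in markers (`>= 2`).
#' @return pruned `genotype_matrix`; removed variant IDs in attribute
#'   `removed`.
#' @export
ld_prune <- function(x, r2_threshold = 0.1, window = 50) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (window < 2) stop("window must be >= 2")
  G <- impute_means(x$G)
  keep <- logical(n_variants(x))
  for (chrom in unique(x$variants$chrom)) {
    cols <- which(x$variants$chrom == chrom)
    retained <- integer(0)
    for (j in cols) {
      recent <- utils::tail(retained, window - 1)
      r2 <- if (length(recent) > 0)
        suppressWarnings(cor(G[, j], G[, recent, drop = FALSE]))^2 else
          numeric(0)
      r2[is.na(r2)] <- 0  # constant columns carry no LD information
      if (all(r2 <= r2_threshold)) retained <- c(retained, j)
    }
    keep[retained] <- TRUE
  }
  out <- subset_genotypes(x, variants = which(keep))
  attr(out, "removed") <- x$variants$id[!keep]
  out
}

#' Fraction of marker pairs in low LD
#'
#' Computes the fraction of all SNP pairs whose squared correlation is
#' strictly below `r2_threshold`. Above `max_pairs` pairs a seeded random
#' subsample of pairs is scored instead.
#'
#' @param x a [genotype_matrix()] with at least two SNPs.
#' @param r2_threshold threshold in `(0, 1]`.
#' @param max_pairs pair-count cap before subsampling.
#' @param seed RNG seed for the subsample.
#' @return fraction in `[0, 1]`.
#' @export
ld_pair_fraction <- function(x, r2_threshold = 0.1, max_pairs = 1e5,
                             seed = 1) {
  J <- n_variants(x)
  if (J < 2) stop("need at least two SNPs")
  G <- impute_means(x$G)
  n_pairs <- J * (J - 1) / 2
  if (n_pairs <= max_pairs) {
    r2 <- suppressWarnings(cor(G))^2
    r2[is.na(r2)] <- 0
    r2[r2 > 1 - 1e-12] <- 1  # exact-duplicate pairs, despite rounding
    vals <- r2[upper.tri(r2)]
  } else {
    vals <- with_seed(seed, {
      a <- sample.int(J, max_pairs, replace = TRUE)
      b <- sample.int(J, max_pairs, replace = TRUE)
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      r <- vapply(seq_along(a), function(i)
        suppressWarnings(cor(G[, a[i]], G[, b[i]])), numeric(1))
      r[is.na(r)] <- 0
      r2s <- r^2
      r2s[r2s > 1 - 1e-12] <- 1
      r2s
    })
  }
  mean(vals < r2_threshold)
}

#' Full QC pass
#'
#' Applies the fixed filter order: per-SNP missingness, per-individual
#' missingness, minor allele frequency, LD pruning. Deterministic given the
#' input and thresholds.
#'
#' @param x a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] set.
#' @return filtered `genotype_matrix`; attribute `qc_report` is a data frame
#'   of removed markers/samples with reason codes.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  y <- filter_missingness(x, thresholds$max_snp_missing,
                          thresholds$max_ind_missing)
  report <- rbind(
    qc_rows(attr(y, "removed_snps"), "marker", "snp_missingness"),
    qc_rows(attr(y, "removed_samples"), "sample", "individual_missingness"))
  z <- filter_maf(y, thresholds$min_maf)
  report <- rbind(report, qc_rows(attr(z, "removed"), "marker", "low_maf"))
  out <- ld_prune(z, thresholds$ld_r2, thresholds$ld_window)
  report <- rbind(report, qc_rows(attr(out, "removed"), "marker", "high_ld"))
  attr(out, "removed") <- NULL
  attr(out, "qc_report") <- report
  out
}

qc_rows <- function(ids, what, reason) {
  if (length(ids) == 0)
    return(data.frame(id = character(0), type = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  data.frame(id = ids, type = what, reason = reason, stringsAsFactors = FALSE)
}

#' Write a QC report
#'
#' @param x output of [qc_filter()].
#' @param path TSV destination.
#' @export
write_qc_report <- function(x, path) {
  report <- attr(x, "qc_report")
  if (is.null(report)) stop("no qc_report attribute; run qc_filter() first")
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
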