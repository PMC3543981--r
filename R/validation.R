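#' Identity-by-state distance matrix
#'
#' Pairwise dissimilarity `D_ij = 1 - mean over jointly observed SNPs of
#' (2 - |g_i - g_j|) / 2`, i.e. one minus the mean fraction of shared
#' alleles; equals `mean(|g_i - g_j|) / 2`, bounded in `[0, 1]`.
#'
#' @param x a [genotype_matrix()]; every pair of samples must share at least
#'   one observed SNP.
#' @return object of class `distance_matrix`: fields `samples` and `D`
#'   (symmetric, zero diagonal).
#' @export
ibs_distance_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  J <- n_variants(x)
  # dist() rescales pairwise sums by J / (shared observed count), which is
  # exactly the pairwise-complete mean the IBS definition requires
  D <- as.matrix(dist(x$G, method = "manhattan")) / (2 * J)
  if (anyNA(D)) {
    bad <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("samples ", x$samples[bad[1]], " and ", x$samples[bad[2]],
         " share no observed SNPs")
  }
  dimnames(D) <- list(x$samples, x$samples)
  structure(list(samples = x$samples, D = D), class = "distance_matrix")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  D <- as.matrix(D)
  samples <- rownames(D)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(D)))
  structure(list(samples = samples, D = D), class = "distance_matrix")
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared-distance matrix, eigendecomposes, and returns
#' coordinates `eigenvector * sqrt(eigenvalue)` for the top `m` positive
#' eigenvalues, with per-axis fractions of the total positive-eigenvalue
#' variance.
#'
#' @param D a `distance_matrix` (or plain symmetric matrix).
#' @param m number of axes (`>= 1`).
#' @return object of class `pcoa_result`: `coords` (n x m), `varexp`
#'   (length m, non-increasing), `eig` (all eigenvalues).
#' @export
pcoa <- function(D, m = 2) {
  D <- as_dist_matrix(D)
  n <- nrow(D$D)
  stopifnot(m >= 1)
  res <- suppressWarnings(cmdscale(as.dist(D$D), k = min(m, n - 1),
                                   eig = TRUE))
  pos <- res$eig[res$eig > 1e-12]
  if (length(pos) == 0) stop("no positive eigenvalues: degenerate distances")
  m_eff <- min(m, length(pos), ncol(res$points))
  coords <- res$points[, seq_len(m_eff), drop = FALSE]
  rownames(coords) <- D$samples
  structure(list(coords = coords,
                 varexp = pos[seq_len(m_eff)] / sum(pos),
                 eig = res$eig),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coords), "points,", ncol(x$coords), "axes\n")
  cat("  variance explained:", paste(sprintf("%.1f%%", 100 * x$varexp),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Hudson-style pairwise Fst between panel populations
#'
#' Per-SNP numerator `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) -
#' p2 (1 - p2) / (n2 - 1)` and denominator `p1 (1 - p2) + p2 (1 - p1)`,
#' combined across SNPs as a ratio of sums. `n1`, `n2` are allele counts at
#' the SNP.
#'
#' @param panel a [reference_panel()] with at least two members per
#'   population.
#' @return K x K symmetric matrix with zero diagonal.
#' @export
pairwise_fst <- function(panel) {
  stopifnot(inherits(panel, "reference_panel"))
  pops <- panel$populations
  tab <- table(panel$labels)
  if (any(tab[pops] < 2)) stop("every population needs >= 2 members")
  G <- panel$genotypes$G
  p <- lapply(pops, function(k) {
    sub <- G[panel$labels == k, , drop = FALSE]
    list(p = colMeans(sub, na.rm = TRUE) / 2,
         n = 2 * colSums(!is.na(sub)))
  })
  names(p) <- pops
  K <- length(pops)
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    p1 <- p[[a]]$p; n1 <- p[[a]]$n
    p2 <- p[[b]]$p; n2 <- p[[b]]$n
    ok <- n1 > 2 & n2 > 2 & !is.na(p1) & !is.na(p2)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    use <- ok & den > 0
    if (!any(use))
      stop("Fst undefined for ", pops[a], " vs ", pops[b],
           ": no polymorphic markers")
    out[a, b] <- out[b, a] <- sum(num[use]) / sum(den[use])
  }
  out
}

#' Permutation distance-variance test
#'
#' Quantifies how much of the total variance in a dissimilarity matrix is
#' explained by a grouping factor (R-squared from squared distances) and
#' attaches a permutation p-value from a pseudo-F statistic; computed via a
#' one-factor PERMANOVA (vegan). The p-value is
#' `(1 + number of permuted F >= observed F) / (n_perm + 1)`.
#'
#' @param D a `distance_matrix` (or symmetric matrix).
#' @param labels grouping factor, at least two distinct groups.
#' @param n_perm number of permutations (`>= 99`).
#' @param seed RNG seed for the permutations.
#' @return list with `R2`, `p`, `F`.
#' @export
distance_variance_test <- function(D, labels, n_perm = 999, seed = NULL) {
  D <- as_dist_matrix(D)
  labels <- as.character(labels)
  if (length(labels) != nrow(D$D))
    stop("one label per sample required")
  if (length(unique(labels)) < 2)
    stop("need at least two distinct groups")
  if (n_perm < 99) stop("n_perm must be >= 99")
  dat <- data.frame(grp = factor(labels))
  fit <- with_seed(seed,
    vegan::adonis2(as.dist(D$D) ~ grp, data = dat, permutations = n_perm))
  list(R2 = fit$R2[1], p = fit$`Pr(>F)`[1], F = fit$F[1])
}

#' Leave-one-out panel resampling
#'
#' Each panel member in turn is treated as a target of unknown ancestry and
#' scored by a supervised fit against the remaining members. The default fit
#' options use reference-mode frequencies: removing one individual barely
#' moves the frequency estimates, and the mode keeps the n passes cheap.
#'
#' @param panel a [reference_panel()]; every population needs `>= 2`
#'   members.
#' @param opts [fit_opts()] for each supervised fit.
#' @param denoise additionally run the full two-step procedure (bootstrap
#'   plus denoising) for each held-out member and report the refined
#'   proportions; substantially slower.
#' @param n_reps,seed bootstrap parameters used when `denoise = TRUE`.
#' @return an `admixture_estimate` covering every panel member, with the
#'   documented labels in attribute `labels` and the per-member
#'   own-population proportion in attribute `own_proportion`.
#' @export
leave_one_out <- function(panel, opts = fit_opts(freq_mode = "reference"),
                          denoise = FALSE, n_reps = 100, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  tab <- table(panel$labels)
  if (any(tab < 2))
    stop("singleton population(s) cannot be held out: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  n <- n_samples(panel$genotypes)
  K <- length(panel$populations)
  Q <- matrix(NA_real_, n, K)
  # collapse the panel to per-population allele counts once; holding out
  # member i just subtracts that member's contribution from its own
  # population's counts, which is an exact leave-one-out
  if (denoise) {
    for (i in seq_len(n)) {
      rest <- subset_panel(panel, samples = setdiff(seq_len(n), i))
      target <- subset_genotypes(panel$genotypes, i)
      res <- estimate_ancestry(rest, target, opts, n_reps = n_reps,
                               seed = seed + i, boot_opts = opts)
      Q[i, ] <- res$denoised$q_refined
    }
    est <- new_admixture_estimate(panel$genotypes$samples,
                                  panel$populations, Q, NA_real_,
                                  NA_integer_, TRUE, NULL)
    attr(est, "labels") <- panel$labels
    attr(est, "own_proportion") <-
      Q[cbind(seq_len(n), match(panel$labels, panel$populations))]
    return(est)
  }
  counts <- reference_counts(panel)
  pop_idx <- match(panel$labels, panel$populations)
  G <- panel$genotypes$G
  for (i in seq_len(n)) {
    g <- G[i, ]
    obs <- !is.na(g)
    alt_i <- counts$alt
    tot_i <- counts$tot
    alt_i[pop_idx[i], obs] <- alt_i[pop_idx[i], obs] - g[obs]
    tot_i[pop_idx[i], obs] <- tot_i[pop_idx[i], obs] - 2
    gt <- matrix(g, 1, length(g))
    n_obs <- sum(obs)
    fit <- if (opts$freq_mode == "joint") {
      fit_run(gt, matrix(1 / K, 1, K),
              (alt_i + opts$pseudocount) / (tot_i + 2 * opts$pseudocount),
              alt = alt_i, tot = tot_i, update_F = TRUE,
              accel = opts$accel,
              tol_abs = opts$tol * (n_obs + sum(tot_i) / 2),
              max_iter = opts$max_iter)
    } else {
      fit_run(gt, matrix(1 / K, 1, K),
              (alt_i + opts$pseudocount) / (tot_i + 2 * opts$pseudocount),
              update_F = FALSE, accel = opts$accel,
              tol_abs = opts$tol * n_obs, max_iter = opts$max_iter,
              tol_pg = opts$tol)
    }
    Q[i, ] <- fit$Q
  }
  est <- new_admixture_estimate(panel$genotypes$samples, panel$populations,
                                Q, NA_real_, NA_integer_, TRUE, NULL)
  attr(est, "labels") <- panel$labels
  attr(est, "own_proportion") <-
    Q[cbind(seq_len(n), match(panel$labels, panel$populations))]
  est
}

#' Standard error versus marker count
#'
#' Subsamples the panel's markers without replacement to each requested
#' count, re-runs the bootstrap, and reports the mean standard error per
#' population, tracing how estimate uncertainty decays as markers are added.
#'
#' @param panel a [reference_panel()].
#' @param targets a [genotype_matrix()] aligned to the panel.
#' @param marker_counts vector of marker counts, each `<=` the panel's J.
#' @param opts [fit_opts()] for the bootstrap fits.
#' @param n_reps,block_len bootstrap parameters (see [bootstrap_se()]).
#' @param seed RNG seed driving both the subsampling and the bootstraps.
#' @return data frame with columns `n_markers`, `population`, `mean_se`.
#' @export
se_vs_marker_count <- function(panel, targets, marker_counts,
                               opts = fit_opts(freq_mode = "reference"),
                               n_reps = 200, block_len = 1, seed = 1) {
  J <- n_variants(panel$genotypes)
  if (any(marker_counts > J))
    stop("marker count exceeds available markers (", J, ")")
  if (any(marker_counts < 2)) stop("marker counts must be >= 2")
  out <- list()
  for (ci in seq_along(marker_counts)) {
    count <- marker_counts[ci]
    idx <- if (count == J) seq_len(J) else
      with_seed(seed + ci, sort(sample.int(J, count)))
    sub_panel <- panel
    sub_panel$genotypes <- subset_genotypes(panel$genotypes,
                                            variants = idx)
    sub_targets <- subset_genotypes(targets, variants = idx)
    sub_opts <- opts
    if (opts$freq_mode == "fixed")
      sub_opts$freq <- allele_freq(
        align_freq(opts$freq, panel$populations)$F[, idx, drop = FALSE],
        panel$populations)
    bs <- bootstrap_se(sub_panel, sub_targets, sub_opts, n_reps = n_reps,
                       block_len = block_len, seed = seed)
    out[[ci]] <- data.frame(n_markers = count,
                            population = panel$populations,
                            mean_se = colMeans(bs$SE),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trio consistency deviation
#'
#' Under Mendelian inheritance a child's admixture proportions should equal
#' the average of the parents'; the elementwise absolute deviation from that
#' average measures estimation error.
#'
#' @param q_child,q_father,q_mother length-K proportion vectors over the
#'   same populations.
#' @return length-K vector of absolute deviations.
#' @export
trio_deviation <- function(q_child, q_father, q_mother) {
  if (length(q_child) != length(q_father) ||
      length(q_child) != length(q_mother))
    stop("q vectors must have equal length")
  abs(q_child - (q_father + q_mother) / 2)
}
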