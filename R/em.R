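FREQ_EPS <- 1e-6

#' Population allele frequency matrix
#'
#' K x J matrix of alt-allele frequencies, one row per ancestral population,
#' clamped to the open unit interval so the binomial log-likelihood stays
#' finite.
#'
#' @param F numeric K x J matrix of alt-allele frequencies.
#' @param populations K population names.
#' @return object of class `allele_freq` with fields `F`, `populations`.
#' @export
allele_freq <- function(F, populations) {
  F <- as.matrix(F)
  populations <- as.character(populations)
  if (nrow(F) != length(populations))
    stop("one population name per frequency row required")
  if (anyDuplicated(populations)) stop("duplicate population names")
  F <- pmin(pmax(F, FREQ_EPS), 1 - FREQ_EPS)
  rownames(F) <- populations
  structure(list(F = F, populations = populations), class = "allele_freq")
}

#' @export
print.allele_freq <- function(x, ...) {
  cat("allele_freq:", length(x$populations), "populations x", ncol(x$F),
      "markers\n")
  invisible(x)
}

#' Fit options for the admixture EM
#'
#' @param tol convergence tolerance on the absolute change in log-likelihood
#'   between iterations, expressed per observed genotype (the absolute
#'   threshold is `tol * number of observed genotype entries`).
#' @param max_iter iteration cap.
#' @param seed RNG seed for random initializations (unsupervised fits).
#' @param freq_mode how ancestral allele frequencies are handled in
#'   supervised fits: `"joint"` re-estimates them jointly over reference and
#'   target individuals with the reference memberships fixed (the default,
#'   mirroring supervised ADMIXTURE); `"reference"` fixes them at the
#'   pseudocount-smoothed reference sample frequencies and iterates only the
#'   target proportions; `"fixed"` uses the frequencies supplied in `freq`.
#' @param freq an [allele_freq()] for `freq_mode = "fixed"`.
#' @param pseudocount added to the alt-allele count (and twice to the total)
#'   when computing reference frequencies, guarding fixation.
#' @param accel accelerate the EM map with monotonicity-safeguarded SQUAREM
#'   extrapolation (an extrapolated step is kept only when it improves the
#'   log-likelihood, otherwise the plain double EM step is used, so the
#'   ascent property is preserved exactly). `FALSE` runs plain EM.
#' @return a list of class `fit_opts`.
#' @export
fit_opts <- function(tol = 1e-8, max_iter = 5000, seed = NULL,
                     freq_mode = c("joint", "reference", "fixed"),
                     freq = NULL, pseudocount = 0.5, accel = TRUE) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(tol > 0, max_iter >= 1)
  if (freq_mode == "fixed" && is.null(freq))
    stop("freq_mode = 'fixed' requires `freq`")
  structure(list(tol = tol, max_iter = as.integer(max_iter), seed = seed,
                 freq_mode = freq_mode, freq = freq,
                 pseudocount = pseudocount, accel = isTRUE(accel)),
            class = "fit_opts")
}

#' Binomial admixture log-likelihood
#'
#' `L = sum over observed (i, j) of g_ij log p_ij + (2 - g_ij) log(1 - p_ij)`
#' with `p_ij = sum_k q_ik f_kj` (binomial coefficient omitted). Missing
#' genotypes contribute zero.
#'
#' @param G genotype matrix (n x J, entries 0/1/2/NA) or a
#'   [genotype_matrix()].
#' @param Q n x K matrix of admixture proportions (rows on the simplex).
#' @param F an [allele_freq()] or a K x J frequency matrix.
#' @return the log-likelihood (finite real).
#' @export
loglikelihood <- function(G, Q, F) {
  G <- as_G(G)
  F <- as_F(F)
  Q <- as.matrix(Q)
  if (nrow(G) != nrow(Q) || ncol(G) != ncol(F) || ncol(Q) != nrow(F))
    stop("dimension mismatch between G, Q and F")
  P <- pmin(pmax(Q %*% F, FREQ_EPS), 1 - FREQ_EPS)
  obs <- !is.na(G)
  sum(G[obs] * log(P[obs]) + (2 - G[obs]) * log(1 - P[obs]))
}

as_G <- function(G) {
  if (inherits(G, "genotype_matrix")) G$G else as.matrix(G)
}
as_F <- function(F) {
  if (inherits(F, "allele_freq")) F$F else
    pmin(pmax(as.matrix(F), FREQ_EPS), 1 - FREQ_EPS)
}

#' One EM block update
#'
#' Performs a single EM update of the admixture proportions (and optionally
#' the allele frequencies) from the current parameter values. Rows listed in
#' `fixed_q_rows` are held fixed (supervised reference individuals). The
#' log-likelihood is guaranteed not to decrease.
#'
#' @inheritParams loglikelihood
#' @param fixed_q_rows integer indices of Q rows to hold fixed.
#' @param fixed_F if `TRUE` the frequencies are not updated.
#' @return list with updated `Q`, `F` (an [allele_freq()] if one was passed),
#'   and `loglik` of the updated parameters.
#' @export
em_step <- function(G, Q, F, fixed_q_rows = integer(0), fixed_F = FALSE) {
  res <- em_run(G, Q, F, fixed_q_rows = fixed_q_rows, fixed_F = fixed_F,
                tol_abs = 0, max_iter = 1)
  list(Q = res$Q, F = res$F, loglik = res$loglik)
}

# Low-level driver around the general compiled EM loop (arbitrary fixed
# rows, per-iteration trace). tol_abs is the absolute log-likelihood change
# threshold.
em_run <- function(G, Q, F, fixed_q_rows = integer(0), fixed_F = FALSE,
                   tol_abs, max_iter) {
  Gm <- as_G(G)
  pops <- if (inherits(F, "allele_freq")) F$populations else rownames(F)
  Fm <- as_F(F)
  Q <- as.matrix(Q)
  free <- setdiff(seq_len(nrow(Q)), fixed_q_rows)
  res <- admix_em_cpp(Gm, Q, Fm, as.integer(free - 1L), !fixed_F,
                      tol_abs, as.integer(max_iter), FREQ_EPS)
  Fout <- if (is.null(pops)) res$F else allele_freq(res$F, pops)
  list(Q = res$Q, F = Fout, loglik = res$loglik, trace = res$trace,
       n_iter = res$n_iter, converged = res$converged)
}

# Production fitting loop: free target rows plus (optionally) reference
# individuals folded in exactly through their per-population allele counts.
# Fixed-frequency accelerated fits decompose over individuals and go
# through the per-row loop (tol_pg is the per-observed-genotype tolerance
# the row loop scales by each individual's own marker count).
fit_run <- function(Gt, Q, F, alt = NULL, tot = NULL, update_F = TRUE,
                    accel = TRUE, tol_abs, max_iter, tol_pg = NULL) {
  pops <- if (inherits(F, "allele_freq")) F$populations else rownames(F)
  Fm <- as_F(F)
  if (!update_F && accel && !is.null(tol_pg)) {
    res <- admix_fit_rows_cpp(as_G(Gt), as.matrix(Q), Fm, tol_pg,
                              as.integer(max_iter), FREQ_EPS)
    res$F <- Fm
    res$trace <- NULL
  } else {
    empty <- matrix(numeric(0), 0, 0)
    res <- admix_fit_cpp(as_G(Gt), as.matrix(Q), Fm,
                         if (is.null(alt)) empty else alt,
                         if (is.null(tot)) empty else tot,
                         update_F, accel, tol_abs, as.integer(max_iter),
                         FREQ_EPS)
  }
  Fout <- if (is.null(pops)) res$F else allele_freq(res$F, pops)
  list(Q = res$Q, F = Fout, loglik = res$loglik, trace = res$trace,
       n_iter = res$n_iter, converged = res$converged)
}

# Per-population reference allele counts: alt-allele sums and observed
# allele totals (2 x observed genotypes), K x J each.
reference_counts <- function(panel) {
  G <- panel$genotypes$G
  alt <- t(vapply(panel$populations, function(pop)
    colSums(G[panel$labels == pop, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(G))))
  tot <- t(vapply(panel$populations, function(pop)
    2 * colSums(!is.na(G[panel$labels == pop, , drop = FALSE])),
    numeric(ncol(G))))
  list(alt = alt, tot = tot)
}

#' Reference-panel allele frequencies
#'
#' Per-population alt-allele frequencies computed from reference genotype
#' counts with pseudocount smoothing:
#' `(alt count + pseudocount) / (2 n_obs + 2 pseudocount)`.
#'
#' @param panel a [reference_panel()].
#' @param pseudocount smoothing constant (default 0.5).
#' @return an [allele_freq()].
#' @export
reference_frequencies <- function(panel, pseudocount = 0.5) {
  stopifnot(inherits(panel, "reference_panel"))
  G <- panel$genotypes$G
  F <- t(vapply(panel$populations, function(pop) {
    rows <- panel$labels == pop
    sub <- G[rows, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    nobs <- colSums(!is.na(sub))
    (alt + pseudocount) / (2 * nobs + 2 * pseudocount)
  }, numeric(ncol(G))))
  allele_freq(F, panel$populations)
}

new_admixture_estimate <- function(samples, populations, Q, loglik, n_iter,
                                   converged, freq) {
  Q <- as.matrix(Q)
  dimnames(Q) <- list(samples, populations)
  structure(list(samples = samples, populations = populations, Q = Q,
                 loglik = loglik, n_iter = n_iter, converged = converged,
                 freq = freq),
            class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat("admixture_estimate:", length(x$samples), "individuals x",
      length(x$populations), "populations\n")
  cat(sprintf("  loglik %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  cat("  mean proportions:\n")
  print(round(colMeans(x$Q), 4))
  invisible(x)
}

#' Supervised admixture estimation
#'
#' Maximum-likelihood admixture proportions for target individuals against a
#' labeled reference panel. Reference individuals' proportion rows are fixed
#' at the indicator vectors of their population labels; target rows (and,
#' depending on `opts$freq_mode`, the population allele frequencies) are
#' iterated by EM to convergence. Target rows start from the uniform 1/K
#' vector unless a warm start is supplied.
#'
#' @param panel a [reference_panel()].
#' @param targets a [genotype_matrix()] with the same variant list as the
#'   panel (aligned alleles).
#' @param opts a [fit_opts()] set.
#' @param Q0 optional warm start: target proportion matrix (rows on the
#'   simplex, columns in panel population order).
#' @return an `admixture_estimate` for the target rows only; field `freq`
#'   holds the fitted (or fixed) [allele_freq()].
#' @export
fit_supervised <- function(panel, targets, opts = fit_opts(), Q0 = NULL) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(targets, "genotype_matrix"))
  check_same_variants(panel$genotypes, targets)
  K <- length(panel$populations)
  if (K == 0) stop("panel has no populations")
  n_t <- n_samples(targets)
  Qt <- if (is.null(Q0)) matrix(1 / K, n_t, K) else {
    stopifnot(nrow(Q0) == n_t, ncol(Q0) == K)
    as.matrix(Q0)
  }
  n_obs <- sum(!is.na(targets$G))

  if (opts$freq_mode == "joint") {
    counts <- reference_counts(panel)
    F0 <- reference_frequencies(panel, opts$pseudocount)
    n_obs <- n_obs + sum(!is.na(panel$genotypes$G))
    res <- fit_run(targets$G, Qt, F0, alt = counts$alt, tot = counts$tot,
                   update_F = TRUE, accel = opts$accel,
                   tol_abs = opts$tol * n_obs, max_iter = opts$max_iter)
    # final block-coordinate ascent pass: with the joint tolerance dominated
    # by the reference block, target rows can retain slack of the same
    # order as the small proportions the denoising rule inspects;
    # re-solving each row exactly at the fitted frequencies removes it
    # (the likelihood only increases)
    if (opts$accel && n_t > 0) {
      polish <- fit_run(targets$G, res$Q, res$F, update_F = FALSE,
                        accel = TRUE, tol_abs = 0,
                        max_iter = opts$max_iter, tol_pg = opts$tol)
      Fm <- res$F$F
      res$Q <- polish$Q
      res$loglik <- polish$loglik +
        sum(counts$alt * log(Fm) + (counts$tot - counts$alt) * log(1 - Fm))
    }
  } else {
    F0 <- if (opts$freq_mode == "fixed") {
      align_freq(opts$freq, panel$populations)
    } else {
      reference_frequencies(panel, opts$pseudocount)
    }
    res <- fit_run(targets$G, Qt, F0, update_F = FALSE,
                   accel = opts$accel, tol_abs = opts$tol * n_obs,
                   max_iter = opts$max_iter, tol_pg = opts$tol)
  }
  new_admixture_estimate(targets$samples, panel$populations, res$Q,
                         res$loglik, res$n_iter, res$converged, res$F)
}

align_freq <- function(freq, populations) {
  stopifnot(inherits(freq, "allele_freq"))
  idx <- match(populations, freq$populations)
  if (anyNA(idx))
    stop("freq lacks population(s): ",
         paste(populations[is.na(idx)], collapse = ", "))
  allele_freq(freq$F[idx, , drop = FALSE], populations)
}

indicator_Q <- function(labels, populations) {
  Q <- matrix(0, length(labels), length(populations))
  Q[cbind(seq_along(labels), match(labels, populations))] <- 1
  Q
}

check_same_variants <- function(a, b) {
  va <- a$variants; vb <- b$variants
  same <- nrow(va) == nrow(vb) &&
    all(va$chrom == vb$chrom) && all(va$pos == vb$pos) &&
    all(va$ref == vb$ref) && all(va$alt == vb$alt)
  if (!same)
    stop("panel and targets must share an identical, allele-aligned ",
         "variant list (use merge_intersect() first)")
}

#' Unsupervised admixture estimation
#'
#' Plain EM fit of the K-population admixture model with no rows fixed.
#' Proportions are initialized from seeded flat-Dirichlet draws and
#' frequencies from perturbed pooled sample frequencies.
#'
#' @param x a [genotype_matrix()].
#' @param K number of clusters (`>= 1`, `<=` sample count).
#' @param opts a [fit_opts()] set; `opts$seed` drives the initialization.
#' @return an `admixture_estimate` with anonymous populations
#'   `pop1 ... popK`; field `freq` holds the fitted frequencies.
#' @export
fit_unsupervised <- function(x, K, opts = fit_opts()) {
  stopifnot(inherits(x, "genotype_matrix"), K >= 1)
  n <- n_samples(x)
  if (n < K) stop("need at least K individuals")
  J <- n_variants(x)
  pooled <- pmin(pmax(allele_frequencies(x), 0.05), 0.95)
  init <- with_seed(opts$seed, {
    A <- matrix(rgamma(n * K, 1), n, K)
    Q0 <- A / rowSums(A)
    F0 <- t(vapply(seq_len(K), function(k)
      pmin(pmax(pooled + runif(J, -0.1, 0.1), FREQ_EPS), 1 - FREQ_EPS),
      numeric(J)))
    list(Q0 = Q0, F0 = F0)
  })
  n_obs <- sum(!is.na(x$G))
  res <- fit_run(x$G, init$Q0, allele_freq(init$F0, paste0("pop", 1:K)),
                 update_F = TRUE, accel = opts$accel,
                 tol_abs = opts$tol * n_obs, max_iter = opts$max_iter)
  new_admixture_estimate(x$samples, paste0("pop", 1:K), res$Q, res$loglik,
                         res$n_iter, res$converged, res$F)
}

#' Write Q / P style matrices
#'
#' `write_Q()` writes admixture proportions one row per sample with K
#' six-decimal columns; `write_freq()` writes allele frequencies one row per
#' marker. With `named = TRUE` a header of population names (and a leading
#' sample/marker ID column) is included.
#'
#' @param est an `admixture_estimate`.
#' @param path destination.
#' @param named include header and ID column.
#' @export
write_Q <- function(est, path, named = TRUE) {
  Q <- matrix(sprintf("%.6f", est$Q), nrow(est$Q), ncol(est$Q))
  if (named) {
    tab <- data.frame(sample = est$samples, Q, stringsAsFactors = FALSE)
    names(tab) <- c("sample", est$populations)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(Q, path, sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_Q
#' @param freq an [allele_freq()].
#' @export
write_freq <- function(freq, path, named = TRUE) {
  P <- matrix(sprintf("%.6f", t(freq$F)), ncol(freq$F), nrow(freq$F))
  if (named) {
    tab <- as.data.frame(P, stringsAsFactors = FALSE)
    names(tab) <- freq$populations
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(P, path, sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
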