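#' Moving-block bootstrap standard errors of admixture proportions
#'
#' Resamples markers with replacement in contiguous blocks of `block_len`
#' markers (moving blocks over the marker order within each chromosome, back
#' to the original marker count), re-runs the supervised fit on every
#' replicate, and returns the across-replicate sample standard deviation of
#' each admixture proportion. Replicate fits warm-start from the point
#' estimate. With `block_len = 1` (the default, appropriate for LD-pruned
#' panels) this is the ordinary marker bootstrap.
#'
#' @param panel a [reference_panel()].
#' @param targets a [genotype_matrix()] aligned to the panel.
#' @param opts a [fit_opts()] set used for the replicate fits. The default
#'   uses `freq_mode = "reference"`: each replicate recomputes the reference
#'   sample frequencies on the resampled markers and iterates only the
#'   target proportions, so the standard errors reflect marker-resampling
#'   variability of the frequency-anchored estimator.
#' @param n_reps number of bootstrap replicates (`>= 2`).
#' @param block_len markers per block; must satisfy
#'   `1 <= block_len < markers on every chromosome` (a single whole-genome
#'   block is degenerate and rejected).
#' @param seed RNG seed for the block resampling.
#' @param point optional precomputed point estimate (an
#'   `admixture_estimate` from [fit_supervised()] with the same `opts`);
#'   computed if missing.
#' @return object of class `bootstrap_result` with fields `SE` (n x K),
#'   `n_reps`, `block_len`, `seed` and the `point` estimate used for
#'   warm starts.
#' @export
bootstrap_se <- function(panel, targets,
                         opts = fit_opts(freq_mode = "reference"),
                         n_reps = 200, block_len = 1, seed = NULL,
                         point = NULL) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(targets, "genotype_matrix"))
  check_same_variants(panel$genotypes, targets)
  if (n_reps < 2) stop("n_reps must be >= 2")
  J <- n_variants(targets)
  if (block_len < 1) stop("block_len must be >= 1")
  if (J < block_len) stop("block_len exceeds the marker count")
  if (block_len >= J)
    stop("block_len must be smaller than the marker count: a single ",
         "whole-genome block admits no resampling variability")
  chroms <- targets$variants$chrom
  for (ch in unique(chroms)) {
    Jc <- sum(chroms == ch)
    if (block_len > Jc)
      stop("block_len exceeds the marker count on chromosome ", ch)
  }
  if (is.null(point)) point <- fit_supervised(panel, targets, opts)

  K <- length(panel$populations)
  n_t <- n_samples(targets)
  # collapse the reference once: replicates only need resampled columns of
  # the per-population allele counts and of the target genotypes
  counts <- reference_counts(panel)
  Ffix <- if (opts$freq_mode == "fixed")
    align_freq(opts$freq, panel$populations)$F else NULL
  Gt <- targets$G
  n_obs <- sum(!is.na(Gt))
  reps <- array(NA_real_, c(n_t, K, n_reps))
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      idx <- block_resample_indices(chroms, block_len)
      Gb <- Gt[, idx, drop = FALSE]
      if (opts$freq_mode == "joint") {
        alt_b <- counts$alt[, idx, drop = FALSE]
        tot_b <- counts$tot[, idx, drop = FALSE]
        F0 <- (alt_b + opts$pseudocount) /
          (tot_b + 2 * opts$pseudocount)
        fit_b <- fit_run(Gb, point$Q, F0, alt = alt_b, tot = tot_b,
                         update_F = TRUE, accel = opts$accel,
                         tol_abs = opts$tol * (n_obs + sum(tot_b) / 2),
                         max_iter = opts$max_iter)
      } else {
        F0 <- if (is.null(Ffix)) {
          (counts$alt[, idx, drop = FALSE] + opts$pseudocount) /
            (counts$tot[, idx, drop = FALSE] + 2 * opts$pseudocount)
        } else Ffix[, idx, drop = FALSE]
        fit_b <- fit_run(Gb, point$Q, F0, update_F = FALSE,
                         accel = opts$accel, tol_abs = opts$tol * n_obs,
                         max_iter = opts$max_iter, tol_pg = opts$tol)
      }
      reps[, , b] <- fit_b$Q
    }
  })
  SE <- apply(reps, c(1, 2), sd)
  dimnames(SE) <- dimnames(point$Q)
  structure(list(SE = SE, n_reps = n_reps, block_len = block_len,
                 seed = seed, point = point),
            class = "bootstrap_result")
}

# Moving-block resampling indices: within each chromosome, draw block start
# positions uniformly with replacement among all complete blocks, concatenate
# and truncate to the chromosome's marker count.
block_resample_indices <- function(chroms, block_len) {
  out <- integer(0)
  for (ch in unique(chroms)) {
    cols <- which(chroms == ch)
    Jc <- length(cols)
    if (block_len == 1) {
      out <- c(out, cols[sample.int(Jc, Jc, replace = TRUE)])
    } else {
      n_blocks <- ceiling(Jc / block_len)
      starts <- sample.int(Jc - block_len + 1, n_blocks, replace = TRUE)
      pick <- as.vector(vapply(starts, function(s)
        s + seq_len(block_len) - 1L, integer(block_len)))
      out <- c(out, cols[pick[seq_len(Jc)]])
    }
  }
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap_result:", nrow(x$SE), "individuals x", ncol(x$SE),
      "populations;", x$n_reps, "replicates, block length", x$block_len, "\n")
  cat("  mean SE per population:\n")
  print(round(colMeans(x$SE), 4))
  invisible(x)
}

#' Write bootstrap SEs as TSV
#'
#' @param x a `bootstrap_result`.
#' @param path destination.
#' @export
write_se <- function(x, path) {
  tab <- data.frame(sample = rownames(x$SE), x$SE, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
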