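#' Populations with significant evidence of contribution
#'
#' Implements the retention rule of the denoising step: a population is kept
#' when its estimated proportion minus twice its bootstrap standard error is
#' strictly positive (i.e. the approximate 95\% lower confidence bound
#' excludes zero). If no population survives, the single largest component is
#' retained (lowest index on ties) so the refined fit is always defined.
#'
#' @param q length-K proportion vector (simplex row).
#' @param se length-K non-negative standard error vector.
#' @return integer indices of the retained populations.
#' @examples
#' retain_populations(c(0.5, 0.5, 0, 0, 0, 0), rep(0.01, 6))  # 1:2
#' @export
retain_populations <- function(q, se) {
  if (length(q) != length(se)) stop("q and se must have equal length")
  if (any(se < 0)) stop("standard errors must be non-negative")
  kept <- which(q - 2 * se > 0)
  if (length(kept) == 0) kept <- which.max(q)
  kept
}

#' Denoising second pass
#'
#' For each target individual, populations whose first-pass proportion minus
#' twice its bootstrap standard error is non-positive are excluded, and the
#' supervised fit is re-run with the reference panel restricted to the
#' retained populations. Targets sharing the same retained set are refit in
#' one supervised run (set `group = FALSE` for strict per-individual runs).
#' Refined proportions are written into full-K rows with exact zeros on the
#' excluded populations.
#'
#' @param panel a [reference_panel()].
#' @param targets a [genotype_matrix()] aligned to the panel.
#' @param first_pass `admixture_estimate` from [fit_supervised()].
#' @param ses `bootstrap_result` from [bootstrap_se()], aligned with
#'   `first_pass`.
#' @param opts [fit_opts()] for the refining fits (frequencies re-estimated
#'   per the mode, default joint).
#' @param group refit targets with identical retained sets together.
#' @return object of class `denoised_estimate` with fields `samples`,
#'   `populations`, `retained` (list of population-name vectors),
#'   `q_refined`, `q_initial`, `se_initial`.
#' @export
denoise_estimates <- function(panel, targets, first_pass, ses,
                              opts = fit_opts(), group = TRUE) {
  stopifnot(inherits(first_pass, "admixture_estimate"),
            inherits(ses, "bootstrap_result"))
  if (!identical(dim(first_pass$Q), dim(ses$SE)))
    stop("first_pass and ses are not aligned")
  if (!identical(first_pass$samples, targets$samples))
    stop("first_pass and targets are not aligned")
  K <- length(first_pass$populations)
  n <- length(first_pass$samples)

  kept <- lapply(seq_len(n), function(i)
    retain_populations(first_pass$Q[i, ], ses$SE[i, ]))
  key <- vapply(kept, function(k) paste(k, collapse = ","), character(1))
  if (!group) key <- paste(seq_len(n), key)

  q_refined <- matrix(0, n, K,
                      dimnames = list(first_pass$samples,
                                      first_pass$populations))
  for (grp in unique(key)) {
    rows <- which(key == grp)
    pops_idx <- kept[[rows[1]]]
    pops <- first_pass$populations[pops_idx]
    sub_panel <- subset_panel(panel, populations = pops)
    sub_targets <- subset_genotypes(targets, samples = rows)
    # warm-start each refit at the first-pass estimate restricted to the
    # retained support (renormalized); same optimum, far fewer iterations
    Q0 <- first_pass$Q[rows, pops_idx, drop = FALSE]
    Q0 <- pmax(Q0, 1e-6)
    Q0 <- Q0 / rowSums(Q0)
    fit <- fit_supervised(sub_panel, sub_targets, opts, Q0 = Q0)
    q_refined[rows, pops_idx] <- fit$Q
  }

  structure(list(samples = first_pass$samples,
                 populations = first_pass$populations,
                 retained = lapply(kept, function(k)
                   first_pass$populations[k]),
                 q_refined = q_refined,
                 q_initial = first_pass$Q,
                 se_initial = ses$SE),
            class = "denoised_estimate")
}

#' @export
print.denoised_estimate <- function(x, ...) {
  cat("denoised_estimate:", length(x$samples), "individuals x",
      length(x$populations), "populations\n")
  n_kept <- vapply(x$retained, length, 1L)
  cat("  retained populations per individual:",
      paste(range(n_kept), collapse = "-"), "\n")
  cat("  mean refined proportions:\n")
  print(round(colMeans(x$q_refined), 4))
  invisible(x)
}

#' Write denoised estimates as TSV
#'
#' Columns: sample, the K refined proportions, the K first-pass standard
#' errors, and the retained-set string.
#'
#' @param x a `denoised_estimate`.
#' @param path destination.
#' @export
write_denoised <- function(x, path) {
  tab <- data.frame(sample = x$samples,
                    x$q_refined,
                    x$se_initial,
                    retained = vapply(x$retained, paste, character(1),
                                      collapse = ","),
                    check.names = FALSE)
  names(tab) <- c("sample", x$populations,
                  paste0("se_", x$populations), "retained")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-step ancestry estimation pipeline
#'
#' Convenience wrapper running the full procedure: supervised first-pass
#' fit, moving-block bootstrap standard errors, and the denoising second
#' pass.
#'
#' @inheritParams bootstrap_se
#' @param denoise run the denoising second pass (default `TRUE`).
#' @param boot_opts [fit_opts()] for the bootstrap replicate fits.
#' @return list with components `first_pass` (`admixture_estimate`),
#'   `se` (`bootstrap_result`) and, when `denoise` is `TRUE`, `denoised`
#'   (`denoised_estimate`).
#' @export
estimate_ancestry <- function(panel, targets, opts = fit_opts(),
                              n_reps = 200, block_len = 1, seed = NULL,
                              denoise = TRUE,
                              boot_opts = fit_opts(freq_mode = "reference")) {
  first <- fit_supervised(panel, targets, opts)
  se <- bootstrap_se(panel, targets, boot_opts, n_reps = n_reps,
                     block_len = block_len, seed = seed)
  out <- list(first_pass = first, se = se)
  if (denoise)
    out$denoised <- denoise_estimates(panel, targets, first, se, opts)
  out
}
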