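COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Merge genotype datasets by marker intersection
#'
#' Restricts a list of genotype matrices to the markers typed in common in
#' all of them (keyed on chromosome and position) and concatenates the
#' samples. Allele coding is aligned to the first dataset's ref/alt
#' orientation:
#' \itemize{
#'   \item same ref/alt: genotypes kept as is;
#'   \item ref/alt swapped: genotypes recoded `g -> 2 - g`;
#'   \item opposite-strand complement (optionally swapped): strand-flipped
#'     and recoded as needed;
#'   \item strand-ambiguous sites (A/T or C/G) whose orientation cannot be
#'     resolved are dropped by default (see `keep_ambiguous`);
#'   \item any other allele mismatch: site dropped.
#' }
#' Dropped-site counts are reported via `message()` and attached as attribute
#' `n_dropped`.
#'
#' @param datasets list of two or more [genotype_matrix()] objects.
#' @param keep_ambiguous keep strand-ambiguous (A/T, C/G) sites, assuming
#'   all datasets report the same strand (default `FALSE`: dropped).
#' @return a [genotype_matrix()] with the concatenated samples and the
#'   intersected, allele-aligned markers.
#' @export
merge_intersect <- function(datasets, keep_ambiguous = FALSE) {
  if (!is.list(datasets) || length(datasets) < 2)
    stop("need at least two datasets to merge")
  lapply(datasets, function(d) stopifnot(inherits(d, "genotype_matrix")))
  all_samples <- unlist(lapply(datasets, `[[`, "samples"))
  if (anyDuplicated(all_samples))
    stop("duplicate sample IDs across datasets: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))

  keys <- lapply(datasets, function(d)
    paste(d$variants$chrom, d$variants$pos, sep = ":"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) stop("no markers in common among the datasets")

  ref_set <- datasets[[1]]
  idx1 <- match(shared, keys[[1]])
  v1 <- ref_set$variants[idx1, , drop = FALSE]

  aligned <- vector("list", length(datasets))
  aligned[[1]] <- ref_set$G[, idx1, drop = FALSE]
  keep <- rep(TRUE, length(shared))
  n_ambiguous <- 0L
  n_mismatch <- 0L

  is_ambiguous <- function(ref, alt) ref == COMPLEMENT[alt]

  for (d in seq_along(datasets)[-1]) {
    idx <- match(shared, keys[[d]])
    v <- datasets[[d]]$variants[idx, , drop = FALSE]
    G <- datasets[[d]]$G[, idx, drop = FALSE]
    same <- v$ref == v1$ref & v$alt == v1$alt
    swap <- v$ref == v1$alt & v$alt == v1$ref
    flip <- COMPLEMENT[v$ref] == v1$ref & COMPLEMENT[v$alt] == v1$alt
    flip_swap <- COMPLEMENT[v$ref] == v1$alt & COMPLEMENT[v$alt] == v1$ref
    ambig <- is_ambiguous(v1$ref, v1$alt) | is_ambiguous(v$ref, v$alt)
    if (!keep_ambiguous) {
      drop_ambig <- ambig & (same | swap | flip | flip_swap)
      # same-strand identical coding of an ambiguous site is still
      # unresolvable in general: a strand flip mimics an allele swap
      n_ambiguous <- n_ambiguous + sum(drop_ambig & keep)
      keep <- keep & !drop_ambig
    } else {
      # trust reported strand: resolve by allele identity only
      flip[ambig] <- FALSE
      flip_swap[ambig] <- FALSE
    }
    recode <- swap | flip_swap
    ok <- same | swap | flip | flip_swap
    n_mismatch <- n_mismatch + sum(!ok & keep)
    keep <- keep & ok
    G[, recode] <- 2 - G[, recode]
    aligned[[d]] <- G
  }

  if (!any(keep)) stop("no markers left after allele alignment")
  if (n_ambiguous > 0)
    message("merge_intersect: dropped ", n_ambiguous,
            " strand-ambiguous site(s)")
  if (n_mismatch > 0)
    message("merge_intersect: dropped ", n_mismatch,
            " allele-incompatible site(s)")

  out <- genotype_matrix(
    do.call(rbind, lapply(aligned, function(G) G[, keep, drop = FALSE])),
    all_samples, v1[keep, , drop = FALSE])
  attr(out, "n_dropped") <- n_ambiguous + n_mismatch
  out
}
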