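#' Genotype matrix container
#'
#' Holds diploid biallelic SNP genotypes as alt-allele counts (0, 1, 2, or
#' `NA` for missing) for `n` samples at `J` variants, together with per-variant
#' metadata. This is the central container consumed by QC, model fitting and
#' the validation battery.
#'
#' @param G integer/numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample identifiers (row order).
#' @param variants data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`; alleles must be single nucleotides in `A/C/G/T` and differ.
#' @return An object of class `genotype_matrix` with fields `G`, `samples`,
#'   `variants`.
#' @examples
#' v <- data.frame(chrom = "1", pos = 1:2, id = c("s1", "s2"),
#'                 ref = "A", alt = "G")
#' gm <- genotype_matrix(rbind(c(0, 1), c(2, NA)), c("a", "b"), v)
#' n_samples(gm); n_variants(gm)
#' @export
genotype_matrix <- function(G, samples, variants) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  samples <- as.character(samples)
  variants <- validate_variants(variants)
  if (nrow(G) != length(samples))
    stop("row count of G (", nrow(G), ") does not match number of samples (",
         length(samples), ")")
  if (ncol(G) != nrow(variants))
    stop("column count of G (", ncol(G), ") does not match number of variants (",
         nrow(variants), ")")
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  bad <- !(is.na(G) | G %in% c(0, 1, 2))
  if (any(bad))
    stop("genotypes must be 0, 1, 2 or NA; found e.g. ", G[which(bad)[1]])
  dimnames(G) <- list(samples, variants$id)
  structure(list(G = G, samples = samples, variants = variants),
            class = "genotype_matrix")
}

validate_variants <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0)
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  variants <- variants[, need, drop = FALSE]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$id <- as.character(variants$id)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1)) stop("variant positions must be >= 1")
    ok <- variants$ref %in% c("A", "C", "G", "T") &
      variants$alt %in% c("A", "C", "G", "T") &
      variants$ref != variants$alt
    if (!all(ok))
      stop("invalid alleles at variant(s): ",
           paste(utils::head(variants$id[!ok], 5), collapse = ", "))
  }
  rownames(variants) <- NULL
  variants
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname genotype_matrix
#' @export
n_variants <- function(x) nrow(x$variants)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_variants(x), "variants\n")
  miss <- mean(is.na(x$G))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples sample indices or IDs to keep (default all).
#' @param variants variant column indices to keep (default all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(x$samples) else samples
  if (is.character(si)) si <- match(si, x$samples)
  vi <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  genotype_matrix(x$G[si, vi, drop = FALSE], x$samples[si],
                  x$variants[vi, , drop = FALSE])
}

#' Resample variant columns of a genotype matrix
#'
#' Unlike [subset_genotypes()] this allows repeated columns (bootstrap
#' replicates); variant IDs are made unique.
#' @keywords internal
resample_variants <- function(x, idx) {
  v <- x$variants[idx, , drop = FALSE]
  v$id <- make.unique(v$id)
  genotype_matrix(x$G[, idx, drop = FALSE], x$samples, v)
}

#' Labeled reference panel
#'
#' A [genotype_matrix()] in which every individual carries a population label
#' from a named set of K populations; reference individuals are assumed to
#' derive 100\% of their ancestry from their labeled population.
#'
#' @param genotypes a `genotype_matrix`.
#' @param labels character vector of population labels, one per sample.
#' @param populations ordered vector of the K distinct population names;
#'   defaults to the unique labels in order of first appearance.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(genotypes, labels,
                            populations = unique(labels)) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  labels <- as.character(labels)
  populations <- as.character(populations)
  if (length(labels) != n_samples(genotypes))
    stop("one label per sample required")
  if (anyDuplicated(populations)) stop("duplicate population names")
  if (!all(labels %in% populations))
    stop("labels not in population set: ",
         paste(unique(setdiff(labels, populations)), collapse = ", "))
  if (!all(populations %in% labels))
    stop("population(s) with no members: ",
         paste(setdiff(populations, labels), collapse = ", "))
  structure(list(genotypes = genotypes, labels = labels,
                 populations = populations),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", n_samples(x$genotypes), "individuals,",
      length(x$populations), "populations,", n_variants(x$genotypes),
      "variants\n")
  print(table(factor(x$labels, levels = x$populations)))
  invisible(x)
}

#' Subset a reference panel
#'
#' @param panel a `reference_panel`.
#' @param populations populations to keep (default all).
#' @param samples sample IDs/indices to keep (default all); applied after the
#'   population restriction.
#' @param variants variant indices to keep (default all).
#' @return a `reference_panel`.
#' @export
subset_panel <- function(panel, populations = NULL, samples = NULL,
                         variants = NULL) {
  keep <- rep(TRUE, n_samples(panel$genotypes))
  if (!is.null(populations)) keep <- panel$labels %in% populations
  if (!is.null(samples)) {
    si <- samples
    if (is.character(si)) si <- match(si, panel$genotypes$samples)
    in_s <- rep(FALSE, length(keep)); in_s[si] <- TRUE
    keep <- keep & in_s
  }
  pops <- if (is.null(populations)) panel$populations else
    panel$populations[panel$populations %in% populations]
  reference_panel(subset_genotypes(panel$genotypes, which(keep), variants),
                  panel$labels[keep], pops)
}

#' Pooled or per-population alt-allele frequencies
#'
#' @param x a `genotype_matrix`.
#' @return numeric vector of alt-allele frequencies over non-missing
#'   genotypes (NaN for all-missing columns).
#' @export
allele_frequencies <- function(x) {
  colMeans(x$G, na.rm = TRUE) / 2
}
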