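#' Read genotypes from standard formats
#'
#' Reads diploid biallelic SNP genotypes into a [genotype_matrix()].
#' Supported dialects:
#' \describe{
#'   \item{`vcf`}{VCF 4.x with a GT FORMAT field. Multi-allelic and non-SNP
#'     records are skipped; the skipped count is reported via `message()` and
#'     attached as attribute `n_skipped`.}
#'   \item{`plink`}{PLINK binary fileset (`.bed`/`.bim`/`.fam`, SNP-major).
#'     `path` may be the `.bed` file or the common prefix. Genotypes count
#'     copies of the `.bim` A1 allele (A1 = alt, A2 = ref).}
#'   \item{`table`}{A minimal tab-separated dialect: a header row with
#'     `sample` followed by one field per variant, then one row per sample
#'     with entries `0`, `1`, `2` or `NA`. Variant header fields are either a
#'     bare marker ID (positional metadata is synthesized) or the lossless
#'     form `id|chrom|pos|ref|alt` written by [write_genotypes()].}
#' }
#'
#' @param path input file (or PLINK prefix).
#' @param format one of `"vcf"`, `"plink"`, `"table"`.
#' @return a [genotype_matrix()]; attribute `n_skipped` gives the number of
#'   unusable (multi-allelic / non-SNP) records dropped.
#' @export
read_genotypes <- function(path, format = c("table", "vcf", "plink")) {
  format <- match.arg(format)
  switch(format,
         table = read_genotypes_table(path),
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path))
}

#' Write genotypes
#'
#' Writes a [genotype_matrix()] so that [read_genotypes()] with the same
#' format reproduces it exactly. Missing genotypes are encoded per dialect
#' (`./.` in VCF, `NA` in the table dialect, code `01` in PLINK bed).
#'
#' @param x a `genotype_matrix`.
#' @param path output file (or PLINK prefix).
#' @param format one of `"table"`, `"vcf"`, `"plink"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("table", "vcf", "plink")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "genotype_matrix"))
  switch(format,
         table = write_genotypes_table(x, path),
         vcf = write_genotypes_vcf(x, path),
         plink = write_genotypes_plink(x, path))
  invisible(path)
}

# ---- table dialect ---------------------------------------------------------

read_genotypes_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[1] != "sample")
    stop("table dialect requires a header starting with 'sample': ", path)
  ids <- header[-1]
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = c("character", rep("numeric",
                                                    length(ids))))
  variants <- parse_table_variant_ids(ids)
  gm <- genotype_matrix(as.matrix(tab[, -1, drop = FALSE]), tab$sample,
                        variants)
  if (n_variants(gm) == 0) stop("no usable variants in ", path)
  gm
}

parse_table_variant_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  full <- vapply(parts, length, 1L) == 5L
  variants <- data.frame(chrom = "1", pos = seq_along(ids), id = ids,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (any(full)) {
    m <- do.call(rbind, parts[full])
    variants$id[full] <- m[, 1]
    variants$chrom[full] <- m[, 2]
    variants$pos[full] <- as.integer(m[, 3])
    variants$ref[full] <- m[, 4]
    variants$alt[full] <- m[, 5]
  }
  variants
}

write_genotypes_table <- function(x, path) {
  v <- x$variants
  ids <- paste(v$id, v$chrom, v$pos, v$ref, v$alt, sep = "|")
  G <- x$G
  storage.mode(G) <- "integer"
  tab <- data.frame(sample = x$samples, G, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab) <- c("sample", ids)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- VCF -------------------------------------------------------------------

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ok <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message("read_genotypes: skipped ", n_skipped,
            " multi-allelic or non-SNP record(s)")
  if (!any(ok)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[ok, , drop = FALSE]
  counts <- apply(gt, 2, function(col) {
    al <- strsplit(gsub("|", "/", col, fixed = TRUE), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) == 0 || any(is.na(a)) || any(a == "."))
        return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  })
  counts <- matrix(counts, nrow = sum(ok),
                   dimnames = list(NULL, colnames(gt)))
  fix <- fix[ok, , drop = FALSE]
  rownames(fix) <- NULL
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, ":", fix$POS), fix$ID)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = id, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(counts), colnames(gt), variants)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

write_genotypes_vcf <- function(x, path) {
  v <- x$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t")), con)
  if (n_variants(x) > 0) {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = n_variants(x), ncol = n_samples(x))
    obs <- !is.na(t(x$G))
    gt[obs] <- code[as.character(t(x$G)[obs])]
    lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
}

# ---- PLINK bed/bim/fam -----------------------------------------------------

plink_prefix <- function(path) sub("\\.bed$", "", path)

read_genotypes_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("cannot read file: ", f)
  fam_tab <- read.table(fam, stringsAsFactors = FALSE)
  samples <- as.character(fam_tab[[2]])
  bim_tab <- read.table(bim, stringsAsFactors = FALSE,
                        col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  ok <- bim_tab$a1 %in% c("A", "C", "G", "T") &
    bim_tab$a2 %in% c("A", "C", "G", "T") & bim_tab$a1 != bim_tab$a2
  n <- length(samples)
  J <- nrow(bim_tab)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * J)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed)
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  # 2-bit codes, little-endian within each byte:
  # 00 = hom A1 (g = 2), 01 = missing, 10 = het, 11 = hom A2 (g = 0)
  decode <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  bits <- as.integer(body)
  codes <- matrix(NA_real_, nrow = n, ncol = J)
  for (shift in 0:3) {
    two_bits <- bitwAnd(bitwShiftR(bits, 2L * shift), 3L)
    m <- matrix(two_bits, nrow = bpv, ncol = J)
    rows <- seq(shift + 1, n, by = 4)
    if (length(rows) > 0)
      codes[rows, ] <- decode[as.character(m[seq_along(rows), ])]
  }
  gm <- genotype_matrix(codes[, ok, drop = FALSE], samples,
                        data.frame(chrom = as.character(bim_tab$chrom[ok]),
                                   pos = bim_tab$pos[ok], id = bim_tab$id[ok],
                                   ref = bim_tab$a2[ok], alt = bim_tab$a1[ok],
                                   stringsAsFactors = FALSE))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message("read_genotypes: skipped ", n_skipped, " non-SNP bim record(s)")
  if (n_variants(gm) == 0) stop("no usable variants in ", bed)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

write_genotypes_plink <- function(x, path) {
  prefix <- plink_prefix(path)
  v <- x$variants
  write.table(data.frame(x$samples, x$samples, 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(v$chrom, v$id, 0, v$pos, v$alt, v$ref),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- n_samples(x)
  J <- n_variants(x)
  bpv <- ceiling(n / 4)
  encode <- function(g) {
    if (is.na(g)) 1L else if (g == 2) 0L else if (g == 1) 2L else 3L
  }
  out <- raw(3 + bpv * J)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pos <- 4L
  for (j in seq_len(J)) {
    codes <- vapply(x$G[, j], encode, integer(1))
    length(codes) <- bpv * 4  # pad with NA -> treated as 0 below
    codes[is.na(codes)] <- 0L
    m <- matrix(codes, nrow = 4)
    bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    out[pos:(pos + bpv - 1)] <- as.raw(bytes)
    pos <- pos + bpv
  }
  writeBin(out, paste0(prefix, ".bed"))
}

# ---- population label files ------------------------------------------------

#' Read/write population label files
#'
#' Two-column tab-separated files with header `sample` and `population`.
#'
#' @param path file path.
#' @return `read_labels`: named character vector of population labels
#'   (names are sample IDs).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character")
  if (!all(c("sample", "population") %in% names(tab)))
    stop("label file needs 'sample' and 'population' columns: ", path)
  stats::setNames(tab$population, tab$sample)
}

#' @rdname read_labels
#' @param labels named character vector (names = sample IDs).
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(sample = names(labels), population = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
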