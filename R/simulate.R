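#' Default continental population names and differentiation parameters
#'
#' The default six-population setting emulates a continental reference
#' panel. Per-population Balding-Nichols drift parameters are calibrated so
#' that expected pairwise Hudson Fst, `(F_k + F_l) / 2`, matches the scale
#' of differentiation observed between continental groups (e.g. the
#' European/Native-American analogue pair lands near 0.16-0.17 and the
#' European/Central-Asian pair is the least differentiated).
#'
#' @keywords internal
#' @name sim-defaults
NULL

DEFAULT_POPULATIONS <- c("Europe", "Africa", "America", "EastAsia",
                         "Oceania", "CentralAsia")
DEFAULT_FST <- c(Europe = 0.083, Africa = 0.248, America = 0.238,
                 EastAsia = 0.088, Oceania = 0.343, CentralAsia = 0.028)
# continental panel composition of the reference panel being emulated
DEFAULT_N_REF <- c(Europe = 1335, Africa = 366, America = 47,
                   EastAsia = 453, Oceania = 16, CentralAsia = 296)

#' Simulation specification
#'
#' Bundles the parameters of a synthetic study: K differentiated populations
#' at configurable drift, a labeled reference panel, and admixed target
#' cohorts drawn from the binomial admixture genotype model.
#'
#' @param K number of populations.
#' @param J number of unlinked SNPs.
#' @param fst per-population Balding-Nichols drift parameters in `(0, 1)`;
#'   expected pairwise Fst between populations k and l is about
#'   `(fst[k] + fst[l]) / 2`. Defaults to the continental calibration for
#'   `K = 6`, otherwise an evenly spaced ladder on `[0.05, 0.3]`.
#' @param n_ref reference individuals per population: a scalar or a
#'   length-K vector. The `K = 6` default mirrors the continental
#'   composition of the emulated reference panel (1335 European, 366
#'   African, 47 Native American, 453 East Asian, 16 Oceanic, 296 Central
#'   Asian); other K default to 50 per population.
#' @param targets list of target cohorts, each `list(n = count, q = length-K
#'   proportion vector)`.
#' @param populations population names.
#' @param seed RNG seed making the whole study reproducible.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(K = 6, J = 16443, fst = NULL, n_ref = NULL,
                            targets = list(), populations = NULL,
                            seed = 1) {
  if (is.null(populations))
    populations <- if (K == 6) DEFAULT_POPULATIONS else paste0("pop", 1:K)
  if (is.null(fst))
    fst <- if (K == 6) unname(DEFAULT_FST) else
      seq(0.05, 0.3, length.out = K)
  if (is.null(n_ref))
    n_ref <- if (K == 6) unname(DEFAULT_N_REF) else 50
  if (length(n_ref) == 1) n_ref <- rep(n_ref, K)
  stopifnot(length(populations) == K, length(fst) == K, J >= 1,
            length(n_ref) == K, all(n_ref >= 1))
  if (any(fst <= 0 | fst >= 1)) stop("fst parameters must lie in (0, 1)")
  for (tg in targets) {
    stopifnot(is.numeric(tg$n), tg$n >= 1, length(tg$q) == K)
    if (abs(sum(tg$q) - 1) > 1e-8 || any(tg$q < 0))
      stop("target q vectors must lie on the simplex")
  }
  structure(list(K = K, J = as.integer(J), fst = fst,
                 n_ref = as.integer(n_ref), targets = targets,
                 populations = populations, seed = seed),
            class = "simulation_spec")
}

#' Balding-Nichols population allele frequencies
#'
#' Ancestral frequencies are drawn uniformly on `[0.05, 0.95]`; population
#' frequencies follow `Beta(p (1 - F_k) / F_k, (1 - p) (1 - F_k) / F_k)`
#' independently per population, clamped to the open unit interval.
#'
#' @param spec a [simulation_spec()], or `NULL` to use the remaining
#'   arguments directly.
#' @param K,J,fst,populations,seed used when `spec` is `NULL`.
#' @return an [allele_freq()]; the ancestral frequencies are attached as
#'   attribute `ancestral`.
#' @export
simulate_frequencies <- function(spec = NULL, K = 6, J = 1000, fst = NULL,
                                 populations = NULL, seed = 1) {
  if (is.null(spec))
    spec <- simulation_spec(K = K, J = J, fst = fst,
                            populations = populations, seed = seed)
  if (any(spec$fst <= 0 | spec$fst >= 1))
    stop("fst parameters must lie in (0, 1)")
  with_seed(spec$seed, {
    p <- runif(spec$J, 0.05, 0.95)
    F <- t(vapply(seq_len(spec$K), function(k) {
      Fk <- spec$fst[k]
      rbeta(spec$J, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
    }, numeric(spec$J)))
    out <- allele_freq(F, spec$populations)
    attr(out, "ancestral") <- p
    out
  })
}

#' Simulate genotypes under the binomial admixture model
#'
#' `g_ij ~ Binomial(2, sum_k q_ik f_kj)`, independently across unlinked
#' sites.
#'
#' @param Q n x K admixture proportion matrix (rows on the simplex).
#' @param freq an [allele_freq()].
#' @param seed RNG seed.
#' @param missing_rate fraction of entries set missing at random.
#' @param sample_prefix prefix for generated sample IDs.
#' @return a [genotype_matrix()] (variants on chromosome "1" at positions
#'   `1..J`, alleles A/G).
#' @export
simulate_genotypes <- function(Q, freq, seed = NULL, missing_rate = 0,
                               sample_prefix = "ind") {
  Q <- as.matrix(Q)
  F <- as_F(freq)
  stopifnot(ncol(Q) == nrow(F))
  n <- nrow(Q); J <- ncol(F)
  P <- Q %*% F
  with_seed(seed, {
    G <- matrix(rbinom(n * J, 2, as.vector(P)), n, J)
    if (missing_rate > 0)
      G[runif(n * J) < missing_rate] <- NA
    samples <- if (!is.null(rownames(Q))) rownames(Q) else
      paste0(sample_prefix, seq_len(n))
    genotype_matrix(G, samples, default_variants(J))
  })
}

default_variants <- function(J) {
  data.frame(chrom = "1", pos = seq_len(J), id = paste0("snp", seq_len(J)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Simulate a labeled reference panel
#'
#' Draws `n_ref` unadmixed individuals per population (indicator proportion
#' vectors) from the model frequencies.
#'
#' @param spec a [simulation_spec()].
#' @param freq optional precomputed [allele_freq()] (defaults to
#'   [simulate_frequencies()] on `spec`).
#' @return a [reference_panel()]; the generating frequencies are attached
#'   as attribute `freq`.
#' @export
simulate_reference_panel <- function(spec, freq = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(freq)) freq <- simulate_frequencies(spec)
  labels <- rep(spec$populations, times = spec$n_ref)
  Q <- indicator_Q(labels, spec$populations)
  rownames(Q) <- paste0("ref_", labels, "_",
                        unlist(lapply(spec$n_ref, seq_len)))
  gm <- simulate_genotypes(Q, freq, seed = spec$seed + 1000L)
  panel <- reference_panel(gm, labels, spec$populations)
  attr(panel, "freq") <- freq
  panel
}

#' Simulate a full study: panel plus admixed target cohorts
#'
#' The reference panel is drawn from the Balding-Nichols population
#' frequencies. Target genotypes are drawn, by default, from the allele
#' frequencies *estimated from the simulated panel* (`target_freq =
#' "panel"`): this mirrors the study protocol in which source-population
#' frequencies for the admixture simulation are taken from the reference
#' panel itself, so the generating and fitting frequencies agree up to the
#' joint re-estimation. `target_freq = "model"` instead draws targets from
#' the underlying Balding-Nichols frequencies, adding the panel's
#' frequency-estimation noise as genuine model mismatch.
#'
#' @param spec a [simulation_spec()] with a non-empty `targets` list.
#' @param target_freq `"panel"` or `"model"` (see above).
#' @return list with `panel` (a [reference_panel()]), `targets` (a
#'   [genotype_matrix()]), `truth` (true proportion matrix for the targets)
#'   and `freq` (the model [allele_freq()]).
#' @export
simulate_study <- function(spec, target_freq = c("panel", "model")) {
  stopifnot(inherits(spec, "simulation_spec"))
  target_freq <- match.arg(target_freq)
  freq <- simulate_frequencies(spec)
  panel <- simulate_reference_panel(spec, freq)
  truth <- do.call(rbind, lapply(spec$targets, function(tg)
    matrix(tg$q, tg$n, spec$K, byrow = TRUE)))
  if (is.null(truth)) truth <- matrix(numeric(0), 0, spec$K)
  colnames(truth) <- spec$populations
  if (nrow(truth) > 0)
    rownames(truth) <- paste0("target_", seq_len(nrow(truth)))
  gen_freq <- if (target_freq == "panel")
    reference_frequencies(panel) else freq
  targets <- if (nrow(truth) > 0)
    simulate_genotypes(truth, gen_freq, seed = spec$seed + 2000L,
                       sample_prefix = "target_") else NULL
  list(panel = panel, targets = targets, truth = truth, freq = freq)
}

#' Simulate a child's genotypes from two parents
#'
#' At each site one allele is drawn uniformly from each parent's two allele
#' copies, independently across sites (unlinked approximation); a missing
#' parental genotype makes the child's genotype missing at that site.
#'
#' @param g_father,g_mother genotype vectors (0/1/2/NA) of equal length.
#' @param seed RNG seed.
#' @return genotype vector of the child.
#' @export
simulate_offspring <- function(g_father, g_mother, seed = NULL) {
  if (length(g_father) != length(g_mother))
    stop("parental genotype vectors must have equal length")
  with_seed(seed, {
    J <- length(g_father)
    pf <- g_father / 2
    pm <- g_mother / 2
    miss <- is.na(pf) | is.na(pm)
    pf[is.na(pf)] <- 0
    pm[is.na(pm)] <- 0
    child <- rbinom(J, 1, pf) + rbinom(J, 1, pm)
    child[miss] <- NA
    as.numeric(child)
  })
}

#' Write a simulated study to disk
#'
#' Writes the panel genotypes (table dialect), panel labels, target
#' genotypes and the true proportion table, for downstream scoring.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(study$panel$genotypes,
                  file.path(dir, "panel_genotypes.tsv"), "table")
  write_labels(setNames(study$panel$labels,
                        study$panel$genotypes$samples),
               file.path(dir, "panel_labels.tsv"))
  if (!is.null(study$targets)) {
    write_genotypes(study$targets, file.path(dir, "target_genotypes.tsv"),
                    "table")
    truth <- data.frame(sample = rownames(study$truth), study$truth,
                        check.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a simulation spec from YAML
#'
#' Fields mirror [simulation_spec()]; `targets` is a sequence of mappings
#' with `n` and `q`.
#'
#' @param path YAML file.
#' @return a [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("K", "J", "fst", "n_ref", "populations",
                                  "seed"))]
  if (!is.null(y$targets))
    args$targets <- lapply(y$targets, function(tg) {
      nval <- tg[["n"]]
      if (is.null(nval)) {
        # YAML 1.1 resolves a bare `n` key to boolean FALSE
        hit <- which(names(tg) %in% c("FALSE", "count"))
        if (length(hit) > 0) nval <- tg[[hit[1]]]
      }
      list(n = nval, q = as.numeric(tg$q))
    })
  do.call(simulation_spec, args)
}
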