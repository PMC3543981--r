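# Shared fixture builders. Everything is generated in code; no stored data.

make_variants <- function(J, chrom = "1", ref = "A", alt = "G") {
  data.frame(chrom = rep(chrom, J), pos = seq_len(J),
             id = sprintf("snp%d", seq_len(J)), ref = rep(ref, J),
             alt = rep(alt, J), stringsAsFactors = FALSE)
}

make_gm <- function(G, samples = NULL, variants = NULL) {
  G <- as.matrix(G)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(G)))
  if (is.null(variants)) variants <- make_variants(ncol(G))
  genotype_matrix(G, samples, variants)
}

# small two-population panel + targets for fast end-to-end checks
small_study <- function(K = 2, J = 1000, n_ref = 50, n_targets = 20,
                        q = NULL, fst = NULL, seed = 11) {
  if (is.null(q)) q <- rep(1 / K, K)
  targets <- if (n_targets > 0) list(list(n = n_targets, q = q)) else list()
  simulate_study(simulation_spec(
    K = K, J = J, fst = fst, n_ref = n_ref, targets = targets,
    populations = paste0("pop", seq_len(K)), seed = seed))
}

expect_simplex_rows <- function(Q, tol = 1e-9) {
  expect_true(all(Q >= -1e-12))
  expect_true(all(abs(rowSums(Q) - 1) < tol))
}
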