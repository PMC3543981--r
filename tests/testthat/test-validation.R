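test_that("IBS distances match their closed forms", {
  gm <- make_gm(rbind(rep(0, 10), rep(0, 10), rep(2, 10), rep(1, 10)))
  D <- ibs_distance_matrix(gm)$D
  expect_equal(D[1, 2], 0)             # identical rows
  expect_equal(D[1, 3], 1)             # opposite homozygotes
  expect_equal(D[1, 4], 0.5)           # one shared allele per site
  expect_equal(D[3, 4], 0.5)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("IBS handles missingness pairwise and errors on zero overlap", {
  G <- rbind(c(0, 2, NA, NA), c(0, 0, 1, NA), c(NA, NA, NA, 1))
  gm <- make_gm(G)
  # samples 1-2 share sites 1-2: |0-0| + |2-0| = 2 over 2 sites -> 0.5
  expect_equal(ibs_distance_matrix(subset_genotypes(gm, 1:2))$D[1, 2],
               0.5)
  expect_error(ibs_distance_matrix(gm), "share no observed")
})

test_that("IBS distance satisfies the triangle inequality on random triples", {
  set.seed(71)
  for (case in 1:25) {
    gm <- make_gm(matrix(sample(0:2, 3 * 30, TRUE), 3, 30))
    D <- ibs_distance_matrix(gm)$D
    expect_lte(D[1, 2], D[1, 3] + D[3, 2] + 1e-12)
  }
})

test_that("classical-scaling PCoA reproduces exact geometries", {
  # two points at distance d
  D2 <- matrix(c(0, 3, 3, 0), 2)
  p2 <- pcoa(D2, m = 1)
  expect_equal(unname(abs(diff(p2$coords[, 1]))), 3, tolerance = 1e-10)
  expect_equal(unname(p2$varexp), 1)
  # three equidistant points: two equal axes at half the variance each
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  p3 <- pcoa(D3, m = 2)
  expect_equal(unname(p3$varexp), c(0.5, 0.5), tolerance = 1e-10)
  # random planar configuration is recovered to numerical precision
  set.seed(72)
  X <- matrix(rnorm(20), 10, 2)
  DX <- as.matrix(dist(X))
  pX <- pcoa(DX, m = 2)
  expect_equal(as.matrix(dist(pX$coords)), DX, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pX$varexp) < 1e-12))
  expect_error(pcoa(matrix(0, 3, 3)), "positive eigenvalue")
})

test_that("Hudson Fst hits its fixed points and recovers simulation targets", {
  set.seed(73)
  # identical composition: Fst ~ 0
  G <- matrix(sample(0:2, 40 * 400, TRUE), 40, 400)
  panel0 <- reference_panel(make_gm(rbind(G[1:20, ], G[1:20, ]),
                                    samples = paste0("s", 1:40)),
                            rep(c("A", "B"), each = 20))
  f0 <- pairwise_fst(panel0)
  expect_lt(abs(f0["A", "B"]), 2 / sqrt(400))
  # fixed differences everywhere: Fst = 1
  panel1 <- reference_panel(make_gm(rbind(matrix(0, 4, 50),
                                          matrix(2, 4, 50))),
                            rep(c("A", "B"), each = 4))
  expect_equal(pairwise_fst(panel1)["A", "B"], 1)
  # monomorphic pair is undefined
  panelm <- reference_panel(make_gm(matrix(0, 6, 20)),
                            rep(c("A", "B"), each = 3))
  expect_error(pairwise_fst(panelm), "polymorphic|undefined")
  expect_error(pairwise_fst(
    reference_panel(make_gm(matrix(0:2, 3, 4)), c("A", "A", "B"))),
    ">= 2")

  # Balding-Nichols recovery at target 0.15 (n = 100/pop, J = 10^4)
  spec <- simulation_spec(K = 2, J = 10000, fst = c(0.15, 0.15),
                          n_ref = 100, populations = c("P1", "P2"),
                          seed = 19)
  panel <- simulate_reference_panel(spec)
  est <- pairwise_fst(panel)["P1", "P2"]
  expect_lt(abs(est - 0.15), 0.01)
})

test_that("distance-variance test separates structure from noise", {
  set.seed(74)
  # two tight, well-separated clusters: minimal attainable p
  X <- rbind(matrix(rnorm(20, 0, 0.05), 10), matrix(rnorm(20, 5, 0.05), 10))
  D <- as.matrix(dist(X))
  labels <- rep(c("a", "b"), each = 10)
  res <- distance_variance_test(D, labels, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$R2, 0.9)
  expect_error(distance_variance_test(D, rep("a", 20)), "two distinct")
  expect_error(distance_variance_test(D, labels, n_perm = 10), "n_perm")
  # determinism under a seed
  res2 <- distance_variance_test(D, labels, n_perm = 199, seed = 1)
  expect_identical(res$p, res2$p)
})

test_that("distance-variance p-values are calibrated under the null", {
  set.seed(75)
  pvals <- vapply(1:200, function(i) {
    X <- matrix(rnorm(24), 12, 2)
    labels <- sample(rep(c("a", "b"), 6))
    distance_variance_test(as.matrix(dist(X)), labels, n_perm = 99,
                           seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("leave-one-out recovers documented ancestry on a clean panel", {
  set.seed(76)
  spec <- simulation_spec(K = 3, J = 2500, fst = c(0.12, 0.18, 0.25),
                          n_ref = 25,
                          populations = c("P1", "P2", "P3"), seed = 29)
  panel <- simulate_reference_panel(spec)
  loo <- leave_one_out(panel)
  own <- attr(loo, "own_proportion")
  expect_gte(mean(own > 0.9), 0.95)
  # spike in one deliberately admixed member: it is flagged
  freq <- attr(panel, "freq")
  mix <- simulate_genotypes(matrix(c(0.5, 0.5, 0), 1), freq, seed = 30,
                            sample_prefix = "mix")
  panel2 <- reference_panel(admixstep:::merge_rows(panel$genotypes, mix),
                            c(panel$labels, "P1"))
  loo2 <- leave_one_out(panel2)
  expect_lt(attr(loo2, "own_proportion")[76], 0.9)
  # singleton populations cannot be held out
  spec1 <- simulation_spec(K = 2, J = 100, fst = c(0.1, 0.1), n_ref = 1,
                           populations = c("X", "Y"), seed = 1)
  expect_error(leave_one_out(simulate_reference_panel(spec1)),
               "singleton")
})

test_that("leave-one-out with denoising refines held-out estimates", {
  set.seed(80)
  spec <- simulation_spec(K = 2, J = 600, fst = c(0.2, 0.2), n_ref = 6,
                          populations = c("P1", "P2"), seed = 55)
  panel <- simulate_reference_panel(spec)
  loo <- leave_one_out(panel, denoise = TRUE, n_reps = 25, seed = 3)
  expect_simplex_rows(loo$Q)
  expect_gt(mean(attr(loo, "own_proportion")), 0.9)
  # refined rows carry exact zeros on dropped populations
  expect_true(any(loo$Q == 0))
})

test_that("leave-one-out gives even odds between identical populations", {
  set.seed(77)
  freq <- simulate_frequencies(K = 1, J = 800, fst = 0.2, seed = 41)
  G <- simulate_genotypes(matrix(1, 30, 1), freq, seed = 42)
  panel <- reference_panel(G, rep(c("A", "B"), each = 15))
  loo <- leave_one_out(panel)
  expect_lt(abs(mean(attr(loo, "own_proportion")) - 0.5), 0.15)
})

test_that("SE-vs-marker-count: exact at full J and ~ -1/2 log-log slope under fixed F", {
  set.seed(78)
  spec <- simulation_spec(K = 2, J = 3200, fst = c(0.15, 0.15), n_ref = 30,
                          targets = list(list(n = 4, q = c(0.5, 0.5))),
                          populations = c("P1", "P2"), seed = 51)
  study <- simulate_study(spec)
  opts_fix <- fit_opts(freq_mode = "fixed", freq = study$freq)
  counts <- c(200, 400, 800, 1600, 3200)
  tab <- se_vs_marker_count(study$panel, study$targets, counts,
                            opts = opts_fix, n_reps = 80, seed = 61)
  expect_identical(names(tab), c("n_markers", "population", "mean_se"))
  # count == J reproduces a direct bootstrap with the same seed
  direct <- bootstrap_se(study$panel, study$targets, opts_fix,
                         n_reps = 80, seed = 61)
  expect_equal(tab$mean_se[tab$n_markers == 3200],
               unname(colMeans(direct$SE)), tolerance = 1e-12)
  # information accumulates like 1/sqrt(J)
  m <- tapply(tab$mean_se, tab$n_markers, mean)
  slope <- coef(lm(log(m) ~ log(as.numeric(names(m)))))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  expect_error(se_vs_marker_count(study$panel, study$targets, 10000),
               "exceeds")
})

test_that("trio deviations are elementwise and zero at the parental mean", {
  expect_equal(trio_deviation(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)),
               c(0, 0))
  expect_equal(trio_deviation(c(0.6, 0.4), c(0.5, 0.5), c(0.5, 0.5)),
               c(0.1, 0.1))
  expect_error(trio_deviation(c(0.5, 0.5), c(1, 0, 0), c(0.5, 0.5)),
               "length")
})

test_that("simulated trios deviate from the parental mean at the 1e-2 scale", {
  set.seed(79)
  spec <- simulation_spec(K = 4, J = 4000, fst = rep(0.15, 4), n_ref = 40,
                          targets = list(list(n = 20,
                                              q = c(0.46, 0.05, 0.46,
                                                    0.03))),
                          populations = paste0("P", 1:4), seed = 71)
  study <- simulate_study(spec)
  G <- study$targets$G
  opts <- fit_opts(freq_mode = "reference")
  devs <- matrix(NA_real_, 10, 4)
  for (tr in 1:10) {
    gf <- G[2 * tr - 1, ]; gm_ <- G[2 * tr, ]
    gc <- simulate_offspring(gf, gm_, seed = 80 + tr)
    trio <- make_gm(rbind(gf, gm_, gc),
                    samples = c("f", "m", "c"),
                    variants = study$targets$variants)
    fit <- fit_supervised(study$panel, trio, opts)
    devs[tr, ] <- trio_deviation(fit$Q[3, ], fit$Q[1, ], fit$Q[2, ])
  }
  expect_lt(mean(devs), 0.05)
  expect_gt(mean(devs), 0.0005)
})
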