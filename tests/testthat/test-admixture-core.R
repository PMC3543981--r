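test_that("log-likelihood matches closed forms", {
  # 1 individual, 1 SNP, g = 1, K = 1, f = 0.5: ln .5 + ln .5
  expect_equal(loglikelihood(matrix(1), matrix(1), matrix(0.5)),
               log(0.5) + log(0.5), tolerance = 1e-10)
  # g = 2 at p = 0.9: 2 ln 0.9
  expect_equal(loglikelihood(matrix(2), matrix(1), matrix(0.9)),
               2 * log(0.9), tolerance = 1e-10)
  # mixture: q = (.5, .5), f_1 = (.2, .8), f_2 = (.1, .3), g = (1, 0)
  # p = (.5, .2) -> ln .5 + ln .5 + 2 ln .8
  F <- rbind(c(0.2, 0.1), c(0.8, 0.3))
  ll <- loglikelihood(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1), F)
  expect_equal(ll, log(0.5) + log(0.5) + 2 * log(0.8), tolerance = 1e-9)
  # missing genotypes contribute zero
  ll_na <- loglikelihood(matrix(c(1, NA), 1), matrix(c(0.5, 0.5), 1), F)
  expect_equal(ll_na, log(0.5) + log(0.5), tolerance = 1e-9)
  expect_error(loglikelihood(matrix(1), matrix(c(1, 0), 1), matrix(0.5)),
               "dimension")
})

test_that("em_step: K = 1 fixes q at 1; supervised F converges to the sample frequency", {
  G <- matrix(c(0, 1, 2), 3, 1)
  st <- em_step(G, matrix(1, 3, 1), matrix(0.3, 1, 1))
  expect_equal(unname(st$Q), matrix(1, 3, 1))
  # all q rows fixed; one population observing genotypes 0,1,2 at a SNP:
  # the frequency MLE is 3/6 = 0.5
  F <- matrix(0.17, 1, 1)
  for (i in 1:200) {
    st <- em_step(G, matrix(1, 3, 1), F, fixed_q_rows = 1:3)
    F <- st$F
  }
  expect_equal(unname(F), matrix(0.5), tolerance = 1e-6)
})

test_that("EM is monotone and simplex-conserving on random instances", {
  set.seed(21)
  for (case in 1:100) {
    n <- sample(2:4, 1); J <- sample(3:8, 1); K <- sample(2:3, 1)
    G <- matrix(sample(c(0:2, NA), n * J, TRUE,
                       prob = c(.3, .3, .3, .1)), n, J)
    if (all(is.na(G))) G[1] <- 1
    Q <- matrix(rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
    F <- matrix(runif(K * J, 0.05, 0.95), K, J)
    res <- admixstep:::em_run(G, Q, F, tol_abs = 1e-10, max_iter = 40)
    expect_true(all(diff(res$trace) > -1e-8))
    expect_simplex_rows(res$Q)
  }
})

test_that("accelerated fits are also monotone (safeguarded extrapolation)", {
  set.seed(22)
  study <- small_study(K = 3, J = 300, n_ref = 25, n_targets = 8,
                       q = c(0.5, 0.3, 0.2))
  counts <- admixstep:::reference_counts(study$panel)
  F0 <- reference_frequencies(study$panel)$F
  res <- admixstep:::admix_fit_cpp(study$targets$G,
                                   matrix(1 / 3, 8, 3), F0,
                                   counts$alt, counts$tot,
                                   TRUE, TRUE, 1e-6, 500, 1e-6)
  expect_true(all(diff(res$trace) > -1e-8))
  expect_simplex_rows(res$Q)
})

test_that("EM optimum matches a grid-search oracle (n = 1, K = 2, fixed F)", {
  set.seed(23)
  for (case in 1:12) {
    J <- sample(5:20, 1)
    F <- matrix(runif(2 * J, 0.05, 0.95), 2, J)
    q_true <- runif(1)
    g <- rbinom(J, 2, as.vector(q_true * F[1, ] + (1 - q_true) * F[2, ]))
    # independent oracle: dense grid on the 1-simplex
    grid <- seq(0, 1, by = 1e-4)
    ll <- vapply(grid, function(q)
      loglikelihood(matrix(as.numeric(g), 1), matrix(c(q, 1 - q), 1), F),
      numeric(1))
    q_star <- grid[which.max(ll)]

    freq <- allele_freq(F, c("A", "B"))
    panel <- reference_panel(
      make_gm(matrix(sample(0:2, 2 * J, TRUE), 2, J)), c("A", "B"))
    fit <- fit_supervised(panel, make_gm(matrix(as.numeric(g), 1, J),
                                         samples = "t"),
                          fit_opts(freq_mode = "fixed", freq = freq))
    expect_lt(abs(fit$Q[1, "A"] - q_star), 1e-3)
  }
})

test_that("supervised fits recover reference copies and respect K = 1", {
  set.seed(24)
  study <- small_study(K = 2, J = 3000, n_ref = 50, n_targets = 0,
                       fst = c(0.15, 0.15))
  panel <- study$panel
  # verbatim copies of reference individuals score > 0.95 on their own pop
  idx <- c(1:5, 51:55)
  targets <- subset_genotypes(panel$genotypes, idx)
  targets$samples <- paste0("copy_", targets$samples)
  rownames(targets$G) <- targets$samples
  fit <- fit_supervised(panel, targets)
  own <- fit$Q[cbind(1:10, rep(1:2, each = 5))]
  expect_gt(mean(own), 0.95)
  # K = 1: q = 1, loglik equals the closed form at the fitted frequencies
  p1 <- subset_panel(panel, populations = "pop1")
  t1 <- subset_genotypes(targets, 1:3)
  f1 <- fit_supervised(p1, t1)
  expect_equal(unname(f1$Q), matrix(1, 3, 1))
  expect_equal(f1$loglik,
               loglikelihood(rbind(p1$genotypes$G, t1$G),
                             matrix(1, n_samples(p1$genotypes) + 3, 1),
                             f1$freq),
               tolerance = 1e-6)
  expect_error(fit_supervised(panel, subset_genotypes(targets, 1:2,
                                                      variants = 1:100)),
               "variant")
})

test_that("label permutation only permutes the output", {
  set.seed(25)
  study <- small_study(K = 3, J = 500, n_ref = 30, n_targets = 6,
                       q = c(0.6, 0.3, 0.1))
  panel <- study$panel
  fit <- fit_supervised(panel, study$targets)
  perm <- c(3, 1, 2)
  panel_p <- panel
  panel_p$populations <- panel$populations[perm]
  fit_p <- fit_supervised(panel_p, study$targets)
  expect_equal(fit_p$Q[, panel$populations], fit$Q[, panel$populations],
               tolerance = 1e-6)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("unsupervised clustering separates two differentiated populations", {
  set.seed(26)
  study <- small_study(K = 2, J = 2000, n_ref = 50, n_targets = 0,
                       fst = c(0.2, 0.2))
  gm <- study$panel$genotypes
  truth <- study$panel$labels
  fit <- fit_unsupervised(gm, 2, fit_opts(seed = 5))
  assign <- apply(fit$Q, 1, which.max)
  agree <- max(mean((assign == 1) == (truth == "pop1")),
               mean((assign == 2) == (truth == "pop1")))
  expect_gte(agree, 0.98)
  # K = 1 degenerates to pooled sample frequencies
  f1 <- fit_unsupervised(gm, 1, fit_opts(seed = 5))
  expect_equal(as.vector(f1$freq$F),
               unname(pmin(pmax(allele_frequencies(gm), 1e-6), 1 - 1e-6)),
               tolerance = 0.02)
  # two seeds land on (essentially) the same solution
  fit_b <- fit_unsupervised(gm, 2, fit_opts(seed = 99))
  reorder <- if (cor(fit$Q[, 1], fit_b$Q[, 1]) > 0) 1:2 else 2:1
  expect_lt(mean(abs(fit$Q - fit_b$Q[, reorder])), 0.01)
})

test_that("known-frequency fits are unbiased within Monte-Carlo error", {
  set.seed(27)
  K <- 3; J <- 4000; n <- 60
  freq <- simulate_frequencies(K = K, J = J, fst = c(0.1, 0.2, 0.3),
                               seed = 31)
  q_true <- c(0.5, 0.3, 0.2)
  Q <- matrix(q_true, n, K, byrow = TRUE)
  gm <- simulate_genotypes(Q, freq, seed = 32)
  panel <- reference_panel(make_gm(matrix(sample(0:2, K * J, TRUE), K, J),
                                   samples = paste0("r", 1:K)),
                          freq$populations)
  fit <- fit_supervised(panel, gm,
                        fit_opts(freq_mode = "fixed", freq = freq))
  bias <- colMeans(fit$Q) - q_true
  mc <- 2 * apply(fit$Q, 2, sd) / sqrt(n)
  expect_true(all(abs(bias) < pmax(mc, 0.005)))
})

test_that("Q and frequency writers produce the documented layouts", {
  set.seed(28)
  study <- small_study(K = 2, J = 50, n_ref = 10, n_targets = 3)
  fit <- fit_supervised(study$panel, study$targets)
  qp <- withr::local_tempfile(fileext = ".tsv")
  write_Q(fit, qp)
  tab <- read.table(qp, header = TRUE, sep = "\t")
  expect_identical(names(tab), c("sample", "pop1", "pop2"))
  expect_equal(nrow(tab), 3)
  write_Q(fit, qp, named = FALSE)
  raw <- read.table(qp)
  expect_equal(dim(raw), c(3, 2))
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_freq(fit$freq, fp)
  ftab <- read.table(fp, header = TRUE, sep = "\t")
  expect_equal(dim(ftab), c(50, 2))
})
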