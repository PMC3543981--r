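test_that("unsupervised seeding admits clean cohorts and excludes admixed spike-ins", {
  set.seed(61)
  K <- 3
  spec <- simulation_spec(K = K, J = 2500, fst = rep(0.18, K), n_ref = 30,
                          targets = list(list(n = 10,
                                              q = c(0.5, 0.5, 0))),
                          populations = c("A", "B", "C"), seed = 7)
  study <- simulate_study(spec, target_freq = "model")
  # spike the 50/50 admixed individuals in, documented (wrongly) as pop A
  gm <- admixstep:::merge_rows(study$panel$genotypes, study$targets)
  labels <- c(study$panel$labels, rep("A", 10))
  res <- unsupervised_seed_stage(gm, labels, threshold = 0.9,
                                 opts = fit_opts(seed = 3))
  expect_true(all(study$targets$samples %in% res$report$sample))
  expect_false(any(study$targets$samples %in%
                     res$panel$genotypes$samples))
  # clean individuals admitted with their documented labels
  expect_gte(n_samples(res$panel$genotypes), 85)
  admitted <- res$panel$genotypes$samples
  expect_identical(res$panel$labels,
                   labels[match(admitted, gm$samples)])
  # conservation: admitted + excluded = candidates
  expect_equal(n_samples(res$panel$genotypes) + nrow(res$report),
               n_samples(gm))
  # threshold 0 admits everyone
  res0 <- unsupervised_seed_stage(gm, labels, threshold = 1e-12,
                                  opts = fit_opts(seed = 3))
  expect_equal(nrow(res0$report), 0)
})

test_that("seed stage validates K against the documented labels", {
  gm <- make_gm(matrix(sample(0:2, 60, TRUE), 6, 10))
  expect_error(unsupervised_seed_stage(gm, rep(c("A", "B"), 3), K = 3),
               "labels")
})

test_that("anchored expansion admits same-source candidates, excludes admixed ones", {
  set.seed(62)
  K <- 3
  freq <- simulate_frequencies(K = K, J = 3000, fst = c(0.15, 0.2, 0.15),
                               populations = c("A", "B", "NEW"), seed = 8)
  ref_q <- admixstep:::indicator_Q(rep(c("A", "B"), each = 30),
                                   c("A", "B", "NEW"))
  panel_gm <- simulate_genotypes(ref_q, freq, seed = 9,
                                 sample_prefix = "ref")
  current <- reference_panel(panel_gm, rep(c("A", "B"), each = 30))
  # anchors + clean candidates drawn from NEW; 6 candidates 20% admixed
  cand_q <- rbind(admixstep:::indicator_Q(rep("NEW", 14),
                                          c("A", "B", "NEW")),
                  matrix(rep(c(0.2, 0, 0.8), 6), 6, 3, byrow = TRUE))
  cand_gm <- simulate_genotypes(cand_q, freq, seed = 10,
                                sample_prefix = "cand")
  res <- anchored_expansion(current, cand_gm,
                            anchors = cand_gm$samples[1:4],
                            new_population = "NEW",
                            opts = fit_opts(seed = 2))
  admitted_new <- res$panel$genotypes$samples[res$panel$labels == "NEW"]
  expect_true(all(cand_gm$samples[1:14] %in% admitted_new))
  expect_true(all(cand_gm$samples[15:20] %in% res$report$sample))
  expect_true(all(res$report$own_proportion < 0.9))
  expect_error(anchored_expansion(current, cand_gm, cand_gm$samples[1],
                                  "A"), "already")
  expect_error(anchored_expansion(current, cand_gm, character(0), "NEW"),
               "anchors")
})

test_that("build_panel runs a multi-stage recipe and is stable on rerun", {
  set.seed(63)
  pops <- c("A", "B", "C", "NEW")
  freq <- simulate_frequencies(K = 4, J = 2500,
                               fst = c(0.2, 0.25, 0.2, 0.25),
                               populations = pops, seed = 12)
  n_per <- 25
  Q <- rbind(admixstep:::indicator_Q(rep(c("A", "B", "C"), each = n_per),
                                     pops),
             admixstep:::indicator_Q(rep("NEW", n_per), pops),
             matrix(rep(c(0.5, 0.5, 0, 0), 5), 5, 4, byrow = TRUE))
  gm <- simulate_genotypes(Q, freq, seed = 13, sample_prefix = "ind")
  ids <- gm$samples
  seed_ids <- ids[1:(3 * n_per)]
  new_ids <- ids[(3 * n_per + 1):(4 * n_per)]
  admixed_ids <- ids[(4 * n_per + 1):(4 * n_per + 5)]
  labels <- setNames(c(rep(c("A", "B", "C"), each = n_per),
                       rep("NEW", n_per), rep("A", 5)), ids)
  recipe <- panel_recipe(list(
    list(kind = "unsupervised_seed",
         samples = c(seed_ids, admixed_ids)),
    list(kind = "anchored_expansion", new_population = "NEW",
         anchors = new_ids[1:4], candidates = new_ids[-(1:4)])),
    threshold = 0.9)
  res <- build_panel(gm, labels, recipe, fit_opts(seed = 21))
  expect_setequal(unique(res$panel$labels), pops)
  # the spiked-in admixed individuals are exactly the seed-stage exclusions
  expect_true(all(admixed_ids %in% res$report$sample))
  expect_gte(n_samples(res$panel$genotypes), 3 * n_per + n_per - 8)
  # every documented candidate is either admitted or reported
  expect_equal(n_samples(res$panel$genotypes) + nrow(res$report),
               4 * n_per + 5)

  # idempotence: rebuilding from the admitted panel excludes no one new
  admitted <- res$panel$genotypes$samples
  labels2 <- setNames(res$panel$labels, admitted)
  new_admitted <- admitted[labels2 == "NEW"]
  recipe2 <- panel_recipe(list(
    list(kind = "unsupervised_seed",
         samples = admitted[labels2 != "NEW"]),
    list(kind = "anchored_expansion", new_population = "NEW",
         anchors = new_admitted[1:4],
         candidates = setdiff(new_admitted, new_admitted[1:4]))),
    threshold = 0.9)
  res2 <- build_panel(gm, labels2, recipe2, fit_opts(seed = 22))
  expect_equal(nrow(res2$report), 0)

  # single-stage recipe equals the stage function
  r1 <- build_panel(gm, labels,
                    panel_recipe(list(list(kind = "unsupervised_seed",
                                           samples = seed_ids))),
                    fit_opts(seed = 21))
  r2 <- unsupervised_seed_stage(subset_genotypes(gm, seed_ids),
                                labels[seed_ids],
                                opts = fit_opts(seed = 21))
  expect_identical(r1$panel$genotypes$samples,
                   r2$panel$genotypes$samples)
})

test_that("recipes round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("threshold: 0.85",
               "stages:",
               "  - kind: unsupervised_seed",
               "    samples: [a, b, c]",
               "  - kind: anchored_expansion",
               "    new_population: X",
               "    anchors: [d]",
               "    candidates: [e, f]"), path)
  r <- read_panel_recipe(path)
  expect_s3_class(r, "panel_recipe")
  expect_equal(r$threshold, 0.85)
  expect_equal(r$stages[[2]]$anchors, "d")
  expect_error(panel_recipe(list(list(kind = "bogus"))), "unknown")
})
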