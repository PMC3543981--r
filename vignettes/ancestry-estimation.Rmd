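---
title: "Two-step supervised ancestry estimation: model, denoising rule, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step supervised ancestry estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given dense biallelic SNP genotypes for a person of unknown origin and a
reference panel of individuals with documented ancestry from K continental
populations, we want the *admixture proportions* `q = (q_1, ..., q_K)`:
the fraction of the person's genome derived from each ancestral population.
Unsupervised clustering answers a different question (how do these samples
group?); here the populations are fixed in advance by the panel, which makes
the estimates comparable across studies and interpretable in terms of known
world populations.

## The likelihood model

Each allele copy at SNP `j` of individual `i` originates in population `k`
with probability `q_ik` and is then the alternate allele with probability
`f_kj`, the population allele frequency. Marginally the genotype
(alt-allele count) is

    g_ij ~ Binomial(2, p_ij),    p_ij = sum_k q_ik f_kj,

and, for unlinked markers, the log-likelihood is

    L(Q, F) = sum_{i,j observed} [ g_ij log p_ij + (2 - g_ij) log(1 - p_ij) ].

`fit_supervised()` maximizes `L` with the reference individuals' rows of `Q`
pinned at indicator vectors of their documented labels. By default the
frequencies `F` are re-estimated jointly over reference and target
individuals (`freq_mode = "joint"`, the semantics of supervised analysis in
the standard tools); `freq_mode = "reference"` instead fixes `F` at the
pseudocount-smoothed reference sample frequencies, and `freq_mode = "fixed"`
takes frequencies supplied by the caller (used by the simulation tests,
where the generating frequencies are known).

## Optimization

The engine is the classic EM block update (`em_step()`): with
responsibilities computed from the current `(Q, F)`, the M-step updates are

    q'_ik = q_ik / (2 J_i) * sum_j [ g_ij f_kj / p_ij + (2 - g_ij)(1 - f_kj)/(1 - p_ij) ]
    f'_kj = A_kj / (A_kj + B_kj)

with `A`, `B` the expected alt/ref allele counts attributed to population
`k`. The likelihood never decreases, which the test suite asserts directly.

Three numerical choices matter in practice:

* **Safeguarded acceleration.** Plain EM converges linearly and can need
  thousands of sweeps at panel scale. `fit_opts(accel = TRUE)` (the
  default) applies SQUAREM-style extrapolation to the EM map; an
  extrapolated step is accepted only when it improves the likelihood,
  otherwise the plain double EM step is used, so monotonicity is preserved
  exactly. `accel = FALSE` gives plain EM.
* **Exact per-individual solves when F is fixed.** With frequencies held
  fixed, the problem separates by individual and each subproblem —
  maximizing a concave function over the K-simplex — is solved by an
  active-set projected Newton method to first-order (KKT) optimality.
  This matters because EM-style multiplicative updates crawl sublinearly
  into boundary components: a likelihood-change stopping rule can leave
  errors of order 1e-2 in exactly the small proportions the denoising rule
  inspects. Supervised joint fits end with one such exact per-row pass at
  the fitted frequencies (a block-coordinate ascent step).
* **Tolerances and clamps.** Convergence is declared when the
  log-likelihood change per sweep falls below `tol` per observed genotype
  (default `1e-8`; iteration cap 5000). Frequencies are clamped to
  `[1e-6, 1 - 1e-6]` to guard the log domain; proportions pinned at the
  boundary are exact zeros. Supervised target rows start from the uniform
  vector (deterministic); unsupervised runs draw flat-Dirichlet rows and
  perturbed pooled frequencies from a caller-supplied seed.

## Bootstrap standard errors

`bootstrap_se()` quantifies the sampling uncertainty of each `q_ik` by a
moving-block bootstrap over markers: blocks of `block_len` contiguous
markers (within chromosomes) are resampled with replacement back to the
original marker count and the supervised fit is re-run; the standard error
is the across-replicate standard deviation (denominator `n_reps - 1`).
Defaults: `n_reps = 200` (the conventional bootstrap count of the standard
tools) and `block_len = 1` — appropriate for LD-pruned panels where markers
are nearly independent; linked data should use a block length on the scale
of the local correlation. Replicate fits warm-start from the point estimate
and, by default, fix frequencies at the replicate's reference counts, so
the errors reflect marker-resampling variability of the frequency-anchored
estimator. A single whole-genome block is rejected (no resampling
variability). Identical seeds give bit-identical results.

## The denoising second pass

Finite panels and marker sets leave every estimate with noise, so a person
of entirely European ancestry will typically show small spurious
proportions elsewhere. The second pass implements the published rule:
population `k` is retained for individual `i` exactly when

    q_ik - 2 * SE_ik > 0,

i.e. when the approximate 95% lower confidence bound excludes zero; the
supervised fit is then re-run with the reference panel restricted to the
retained populations, and excluded populations are written as exact zeros.
Two guards: if no population survives, the single largest component is kept
(lowest index on ties) — the rule's degenerate case, never reached on
realistic data; and targets with identical retained sets are refit in one
grouped run (exactly equivalent under fixed frequencies, and equivalent up
to convergence tolerance under joint re-estimation; `group = FALSE` forces
per-individual runs). Refits warm-start from the first-pass estimates
restricted to the retained support. No multiple-testing correction is
applied across the K tests, matching the published procedure. Bootstrap
errors are not recomputed after denoising by default.

A property worth stating: denoising never removes an individual's largest
component, and on simulated admixed targets it weakly improves mean
absolute error — both are asserted in the test suite. The rule is a
hard threshold on a noisy statistic, so a few individuals in a large cohort
will genuinely retain a spurious population whose estimate is an upper-tail
noise event; the residual mean spurious ancestry after denoising scales
with the tail mass beyond two standard errors.

## Stepwise reference-panel construction

`build_panel()` reproduces the construction strategy for the panel itself:

1. an **unsupervised seed stage** clusters cohorts of documented origin
   into K groups; clusters are mapped to documented labels by the optimal
   assignment (exhaustive over label permutations of the label-by-cluster
   mean-proportion matrix, erroring if the optimum is not unique), and an
   individual is admitted when its proportion on its mapped cluster is at
   least the threshold (default 0.9; individuals *below* the threshold are
   removed, so the boundary is admitted);
2. **anchored expansion stages** add one population each: a few anchor
   individuals are assigned fixed membership in the new population, a
   supervised fit scores the remaining candidates, and candidates are
   admitted when their new-population proportion strictly exceeds the
   threshold (here the published wording demands strictly greater, and the
   two boundaries are kept distinct deliberately).

The recipe (stage order, anchors, thresholds) is always explicit — order of
inclusion genuinely affects the result, so nothing is inferred. Every
candidate ends up either in the panel or in the exclusion report with its
own-cluster proportion.

## Validation battery

* `ibs_distance_matrix()`: `D_ij = mean_j |g_i - g_j| / 2` over jointly
  observed SNPs — one minus the mean fraction of shared alleles, a metric
  on genotype vectors bounded in [0, 1].
* `pcoa()`: classical scaling (double-centered squared distances,
  eigendecomposition); exact on Euclidean inputs, with per-axis variance
  fractions from the positive eigenvalues.
* `pairwise_fst()`: Hudson's estimator combined as a ratio of sums across
  SNPs — chosen for its insensitivity to unequal sample sizes and its
  clean simulation oracle.
* `distance_variance_test()`: a one-factor permutation pseudo-F on the
  distance matrix (R-squared of the grouping plus a permutation p-value),
  the same contract as regression-based distance-variance analyses.
* `leave_one_out()`: each panel member re-scored with itself removed —
  implemented exactly by subtracting the member from its population's
  allele counts — to check that documented ancestry is recapitulated.
* `se_vs_marker_count()`: bootstrap errors on random marker subsets,
  tracing how uncertainty decays as markers accumulate (slope -1/2 on the
  log-log scale for independent markers with known frequencies).
* `trio_deviation()`: a child's estimates against the parental average,
  an internal consistency check requiring no ground truth.

## The simulator and what it does (not) emulate

`simulate_study()` builds a fully synthetic study: population allele
frequencies follow the Balding–Nichols model — ancestral frequencies
uniform on [0.05, 0.95], population frequencies Beta-distributed around
them with per-population drift parameter `F_k`, giving expected pairwise
Hudson Fst of about `(F_k + F_l)/2` — and genotypes are binomial draws from
the admixture model. The K = 6 defaults are calibrated to the published
continental differentiation: drift parameters (0.083, 0.248, 0.238, 0.088,
0.343, 0.028) for the European, African, Native-American, East-Asian,
Oceanic and Central-Asian analogues, the least-squares fit to the published
pairwise Fst matrix (placing, e.g., the European–Native-American pair near
0.16 and making the Central-Asian analogue the hardest to separate from
Europe), and per-population panel sizes (1335, 366, 47, 453, 16, 296)
matching the documented continental composition of the emulated panel.

Target cohorts are drawn, by default, from the allele frequencies
*estimated from the simulated panel* rather than from the underlying model
frequencies (`target_freq = "panel"`): the study being emulated obtained
its source-population frequencies from the reference panel itself, so its
generating and fitting frequencies coincide. The `"model"` option draws
targets from the true Balding–Nichols frequencies instead, which adds the
panel's frequency-estimation noise as genuine model mismatch — useful for
stress-testing, but not the emulated protocol.

What the simulator does **not** reproduce: linkage disequilibrium (markers
are independent, consistent with the LD-pruned regime the estimator is
meant for), SNP ascertainment and array MAF spectra, within-continent
substructure, genotyping error, and the higher moments of real continental
allele-frequency differences — Balding–Nichols matches pairwise Fst but
real populations carry more (or less) per-marker discriminating information
at the same Fst. Passing tests therefore demonstrate correctness of the
machinery and calibration under the stated model, not performance
guarantees on any particular genotyping platform.

## Problem sizes used by the tests

The quantitative acceptance checks run two full studies at the emulated
scale (K = 6, J = 16,443 markers, 2,513 panel members, 100 targets,
200 bootstrap replicates): a two-way 0.5/0.5 European/Native-American
cohort and a three-way 0.2/0.05/0.75 European/Native-American/African
cohort. Property checks (EM monotonicity, oracle agreement, leave-one-out
recovery at J = 5,000 and 50 per population, Fst recovery at J = 10,000 and
100 per population, error-scaling slopes) use smaller sizes chosen so each
property is measured with comfortable statistical margin.

## Known limitations

* Global ancestry only; no local (per-region) ancestry, though restricting
  the marker set to a region is mechanically possible.
* The reference panel defines the resolution: proportions are relative to
  the K panel populations, and ancestry from an unrepresented population is
  absorbed by its nearest represented relatives.
* The retention rule tests each population marginally at two standard
  errors; in large cohorts a predictable few percent of true-zero
  components survive as upper-tail noise events.
* Bootstrap errors condition on the observed individual and panel; they
  measure marker-sampling variability, not panel-composition uncertainty.

## A minimal session

```{r example}
library(admixstep)

spec <- simulation_spec(K = 6, J = 16443,
                        targets = list(list(n = 100,
                                            q = c(0.5, 0, 0.5, 0, 0, 0))),
                        seed = 1)
study <- simulate_study(spec)
res <- estimate_ancestry(study$panel, study$targets,
                         n_reps = 200, seed = 2)
colMeans(res$denoised$q_refined)
```
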