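#' Panel-building recipe
#'
#' An ordered list of construction stages. Each stage is a list with a
#' `kind` field:
#' \describe{
#'   \item{`unsupervised_seed`}{fields `samples` (IDs of the candidate
#'     cohorts, with documented labels) and optionally `K` (defaults to the
#'     number of distinct documented labels among them).}
#'   \item{`anchored_expansion`}{fields `new_population`, `anchors`
#'     (sample IDs given fixed membership in the new population) and
#'     `candidates` (sample IDs to score for admission).}
#' }
#' Stage-level `threshold` overrides the recipe default.
#'
#' @param stages list of stage lists.
#' @param threshold admission threshold in `(0, 1)` (default 0.9).
#' @return list of class `panel_recipe`.
#' @export
panel_recipe <- function(stages, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1, length(stages) >= 1)
  for (s in stages) {
    if (!s$kind %in% c("unsupervised_seed", "anchored_expansion"))
      stop("unknown stage kind: ", s$kind)
    if (s$kind == "anchored_expansion" &&
        (is.null(s$anchors) || length(s$anchors) == 0))
      stop("anchored_expansion stages need non-empty anchors")
  }
  structure(list(stages = stages, threshold = threshold),
            class = "panel_recipe")
}

#' Read a panel recipe from YAML
#'
#' The YAML document mirrors [panel_recipe()]: a top-level `threshold` and a
#' `stages` sequence.
#'
#' @param path YAML file.
#' @return a `panel_recipe`.
#' @export
read_panel_recipe <- function(path) {
  y <- yaml::read_yaml(path)
  panel_recipe(y$stages,
               threshold = if (is.null(y$threshold)) 0.9 else y$threshold)
}

exclusion_report <- function(sample = character(0), stage = integer(0),
                             own_proportion = numeric(0),
                             reason = character(0)) {
  n <- length(sample)
  data.frame(sample = sample,
             stage = rep_len(as.integer(stage), n),
             own_proportion = rep_len(as.numeric(own_proportion), n),
             reason = rep_len(as.character(reason), n),
             stringsAsFactors = FALSE)
}

#' Unsupervised seeding stage
#'
#' Clusters candidate cohorts carrying documented labels into K groups by
#' unsupervised EM, maps clusters to documented labels by the optimal
#' assignment (exhaustive over label-to-cluster permutations on the K x K
#' matrix of label-wise mean proportions), and admits an individual when its
#' proportion on its mapped cluster is at least `threshold` (the seed stage
#' removes individuals *below* the threshold, so the boundary itself is
#' admitted).
#'
#' @param genotypes a [genotype_matrix()] of the candidate cohorts.
#' @param labels documented population label per sample.
#' @param K number of clusters; must equal the number of distinct labels.
#' @param threshold admission threshold in `(0, 1)`.
#' @param opts [fit_opts()] for the unsupervised fit (seed the
#'   initialization via `opts$seed`).
#' @return list with `panel` (a [reference_panel()] of the admitted
#'   individuals) and `report` (exclusion report data frame).
#' @export
unsupervised_seed_stage <- function(genotypes, labels, K = NULL,
                                    threshold = 0.9, opts = fit_opts()) {
  labels <- as.character(labels)
  pops <- unique(labels)
  if (is.null(K)) K <- length(pops)
  if (K != length(pops))
    stop("K (", K, ") must equal the number of documented labels (",
         length(pops), ")")
  fit <- fit_unsupervised(genotypes, K, opts)
  meanQ <- t(vapply(pops, function(p)
    colMeans(fit$Q[labels == p, , drop = FALSE]), numeric(K)))
  mapping <- assign_clusters(meanQ)  # cluster index per documented label
  own <- fit$Q[cbind(seq_along(labels), mapping[match(labels, pops)])]
  admit <- own >= threshold
  report <- exclusion_report(genotypes$samples[!admit], 1L, own[!admit],
                             "below_threshold")
  if (!any(admit)) stop("seed stage admitted no individuals")
  panel <- reference_panel(subset_genotypes(genotypes, which(admit)),
                           labels[admit], pops[pops %in% labels[admit]])
  list(panel = panel, report = report)
}

# Optimal label -> cluster assignment maximizing the total own-label mean
# proportion; exhaustive over permutations (K is small). Errors when the
# optimum is not unique (ambiguous cluster identity).
assign_clusters <- function(meanQ) {
  K <- nrow(meanQ)
  if (K > 8) stop("exhaustive assignment supports K <= 8")
  perms <- permutations_of(K)
  scores <- vapply(perms, function(p)
    sum(meanQ[cbind(seq_len(K), p)]), numeric(1))
  best <- which.max(scores)
  ties <- sum(abs(scores - scores[best]) < 1e-12)
  if (ties > 1)
    stop("ambiguous cluster-to-label mapping (", ties,
         " equally good assignments); mean proportions:\n",
         paste(utils::capture.output(print(round(meanQ, 3))), collapse = "\n"))
  perms[[best]]
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(K - 1))
    for (pos in seq_len(K))
      out[[length(out) + 1]] <- append(p, K, after = pos - 1)
  out
}

#' Anchored supervised expansion stage
#'
#' Adds a new population to an existing panel: a small set of anchor
#' individuals is assigned fixed membership in the new population, a
#' supervised fit scores the remaining candidates, and a candidate is
#' admitted when its proportion on the new population strictly exceeds
#' `threshold`.
#'
#' @param current the [reference_panel()] built so far.
#' @param candidates a [genotype_matrix()] holding anchors and candidates
#'   (variant list aligned with the panel).
#' @param anchors sample IDs within `candidates` anchoring the new
#'   population.
#' @param new_population name of the population being added (must not exist
#'   in `current`).
#' @param threshold admission threshold in `(0, 1)`.
#' @param opts [fit_opts()] for the supervised fit.
#' @return list with `panel` (expanded) and `report` (exclusions).
#' @export
anchored_expansion <- function(current, candidates, anchors, new_population,
                               threshold = 0.9, opts = fit_opts()) {
  stopifnot(inherits(current, "reference_panel"),
            inherits(candidates, "genotype_matrix"))
  if (new_population %in% current$populations)
    stop("population already in panel: ", new_population)
  if (length(anchors) == 0) stop("anchors must be non-empty")
  if (!all(anchors %in% candidates$samples))
    stop("anchor(s) absent from candidates: ",
         paste(setdiff(anchors, candidates$samples), collapse = ", "))
  anchor_gm <- subset_genotypes(candidates, anchors)
  rest_ids <- setdiff(candidates$samples, anchors)
  pops <- c(current$populations, new_population)
  panel2 <- reference_panel(
    merge_rows(current$genotypes, anchor_gm),
    c(current$labels, rep(new_population, length(anchors))), pops)
  if (length(rest_ids) == 0)
    return(list(panel = panel2, report = exclusion_report()))
  rest <- subset_genotypes(candidates, rest_ids)
  fit <- fit_supervised(panel2, rest, opts)
  q_new <- fit$Q[, new_population]
  admit <- q_new > threshold
  report <- exclusion_report(rest_ids[!admit], NA_integer_, q_new[!admit],
                             "below_threshold")
  panel3 <- reference_panel(
    merge_rows(panel2$genotypes, subset_genotypes(rest, which(admit))),
    c(panel2$labels, rep(new_population, sum(admit))), pops)
  list(panel = panel3, report = report)
}

# Row-concatenate two genotype matrices sharing a variant list.
merge_rows <- function(a, b) {
  check_same_variants(a, b)
  genotype_matrix(rbind(a$G, b$G), c(a$samples, b$samples), a$variants)
}

#' Stepwise panel construction
#'
#' Executes a [panel_recipe()] stage by stage, threading the growing panel:
#' an initial unsupervised seeding of well-differentiated groups, followed by
#' anchored supervised expansions adding one population each. Every
#' candidate ends up either in the panel or in the exclusion report.
#'
#' @param data a [genotype_matrix()] holding every individual referenced by
#'   the recipe.
#' @param labels named character vector of documented population labels
#'   (names = sample IDs); needed for `unsupervised_seed` stages.
#' @param recipe a [panel_recipe()].
#' @param opts [fit_opts()] passed to each stage's fit.
#' @return list with `panel` (final [reference_panel()]) and `report`
#'   (exclusion report across stages, with the stage index).
#' @export
build_panel <- function(data, labels, recipe, opts = fit_opts()) {
  stopifnot(inherits(data, "genotype_matrix"),
            inherits(recipe, "panel_recipe"))
  panel <- NULL
  report <- exclusion_report()
  for (si in seq_along(recipe$stages)) {
    st <- recipe$stages[[si]]
    thr <- if (is.null(st$threshold)) recipe$threshold else st$threshold
    if (st$kind == "unsupervised_seed") {
      if (si != 1 || !is.null(panel))
        stop("unsupervised_seed must be the first stage")
      ids <- st$samples
      lab <- labels[ids]
      if (anyNA(lab))
        stop("documented labels missing for: ",
             paste(ids[is.na(lab)], collapse = ", "))
      res <- unsupervised_seed_stage(subset_genotypes(data, ids), lab,
                                     K = st$K, threshold = thr, opts = opts)
    } else {
      if (is.null(panel)) stop("anchored_expansion before any seed stage")
      cand_ids <- unique(c(st$anchors, st$candidates))
      res <- anchored_expansion(panel, subset_genotypes(data, cand_ids),
                                st$anchors, st$new_population,
                                threshold = thr, opts = opts)
    }
    panel <- res$panel
    if (nrow(res$report) > 0) {
      res$report$stage <- si
      report <- rbind(report, res$report)
    }
  }
  list(panel = panel, report = report)
}

#' Write a panel's labels and exclusion report
#'
#' @param result output of [build_panel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(setNames(result$panel$labels,
                        result$panel$genotypes$samples),
               file.path(dir, "panel_labels.tsv"))
  write.table(result$report, file.path(dir, "exclusions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
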