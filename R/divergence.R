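#' Ancestral-plasticity and evolved-divergence log-fold changes
#'
#' Over the candidate genes, computes the two common-garden contrasts whose
#' correlation is the core test of plasticity-led divergence:
#' ancestral plasticity = forest 32-degree mean minus forest 25-degree mean;
#' evolved divergence = urban 32-degree mean minus forest 32-degree mean
#' (all log2-CPM group means). The forest common-garden lineage stands proxy
#' for the ancestral pre-urban state.
#'
#' @param norm normalized expression matrix, genes x samples.
#' @param samples sample metadata.
#' @param candidate_ids candidate gene ids.
#' @return list with `gene_id`, `ancestral_lfc`, `evolved_lfc`.
#' @export
plasticity_divergence_lfcs <- function(norm, samples, candidate_ids) {
  sub <- norm[candidate_ids, , drop = FALSE]
  anc <- group_lfc(sub, samples, cg_group("forest", "day25"),
                   cg_group("forest", "day32"))
  evo <- group_lfc(sub, samples, cg_group("forest", "day32"),
                   cg_group("urban", "day32"))
  list(gene_id = candidate_ids, ancestral_lfc = anc$lfc, evolved_lfc = evo$lfc)
}

#' Spearman rank correlation with mid-rank ties
#'
#' rho is the Pearson correlation of mid-ranks (ties share their average
#' rank); the two-sided p-value uses the t approximation on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  assert_that(length(x) == length(y), "length mismatch")
  assert_that(length(x) >= 3, "need at least 3 observations")
  assert_that(stats::var(x) > 0 && stats::var(y) > 0,
              "rho undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Matrix-randomization null for the plasticity-divergence correlation
#'
#' The ancestral and evolved contrasts share the forest 32-degree group, so
#' even pure noise yields a negative correlation (regression toward the
#' mean). The null distribution absorbs that artifact: in each permutation
#' every gene's expression values are independently permuted across the
#' common-garden samples (destroying the gene-group association while
#' preserving each gene's value multiset), both log-fold-change vectors and
#' Spearman's rho are recomputed, and the observed rho is compared against
#' the null. The one-sided empirical p uses the add-one rule,
#' `p = (1 + #[null <= observed]) / (n_perm + 1)`.
#'
#' @param norm_cg normalized expression of the candidate genes restricted to
#'   common-garden samples (genes x samples).
#' @param samples_cg metadata rows for those samples.
#' @param observed_rho the observed correlation on the same matrix.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative `"less"` (more negative than artifact, default),
#'   `"greater"`, or `"two.sided"`.
#' @return list of class `"randomization_null"`: null_rhos, limits (2.5th
#'   and 97.5th percentiles), empirical_p, n_perm, seed.
#' @export
randomization_null_test <- function(norm_cg, samples_cg, observed_rho,
                                    n_perm = 1000, seed = 1,
                                    alternative = c("less", "greater",
                                                    "two.sided")) {
  assert_that(n_perm >= 1, "n_perm must be >= 1", config = TRUE)
  alternative <- match.arg(alternative)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  m <- ncol(norm_cg)
  ia <- resolve_group(samples_cg, cg_group("forest", "day25"), "forest25")
  ib <- resolve_group(samples_cg, cg_group("forest", "day32"), "forest32")
  iu <- resolve_group(samples_cg, cg_group("urban", "day32"), "urban32")
  assert_that(any(ia) && any(ib) && any(iu),
              "common-garden groups (forest25/forest32/urban32) required")
  null_rhos <- vapply(seq_len(n_perm), function(i) {
    perm <- t(apply(norm_cg, 1, sample, size = m))
    anc <- rowMeans(perm[, ib, drop = FALSE]) -
      rowMeans(perm[, ia, drop = FALSE])
    evo <- rowMeans(perm[, iu, drop = FALSE]) -
      rowMeans(perm[, ib, drop = FALSE])
    stats::cor(rank(anc), rank(evo))
  }, numeric(1))
  empirical_p <- switch(alternative,
    less = (1 + sum(null_rhos <= observed_rho)) / (n_perm + 1),
    greater = (1 + sum(null_rhos >= observed_rho)) / (n_perm + 1),
    two.sided = (1 + sum(abs(null_rhos) >= abs(observed_rho))) /
      (n_perm + 1))
  structure(list(
    observed_rho = observed_rho,
    null_rhos = null_rhos,
    limits = stats::quantile(null_rhos, c(0.025, 0.975), names = FALSE),
    empirical_p = empirical_p,
    alternative = alternative,
    n_perm = n_perm, seed = seed), class = "randomization_null")
}

#' @export
print.randomization_null <- function(x, ...) {
  cat(sprintf(
    "randomization null (%d perms): observed rho = %.3f, null 95%% limits [%.3f, %.3f], empirical p (%s) = %.4f\n",
    x$n_perm, x$observed_rho, x$limits[1], x$limits[2], x$alternative,
    x$empirical_p))
  invisible(x)
}
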