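#' Gene significance against CT_MAX
#'
#' Signed Pearson correlation of each gene's normalized expression with the
#' CT_MAX phenotype, with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom. The sign is retained: positive regulators are
#' genes whose expression rises with heat tolerance, negative regulators the
#' reverse.
#'
#' @param norm normalized expression matrix, genes x samples.
#' @param ctmax numeric CT_MAX vector aligned with the columns of `norm`.
#' @return data.frame with gene_id, gs, p.
#' @export
gene_significance <- function(norm, ctmax) {
  assert_that(length(ctmax) == ncol(norm),
              "ctmax length must equal the number of samples")
  n <- length(ctmax)
  assert_that(n >= 3, "need at least 3 samples")
  assert_that(stats::var(ctmax) > 0, "CT_MAX has zero variance")
  gs <- as.numeric(stats::cor(t(norm), ctmax))
  tstat <- gs * sqrt((n - 2) / pmax(1 - gs^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(gene_id = rownames(norm), gs = gs, p = p,
             stringsAsFactors = FALSE)
}

#' Candidate selection at within-module FDR
#'
#' Benjamini-Hochberg adjustment applied separately within each co-expression
#' module (unassigned genes, label 0, form their own group). A gene is a
#' candidate when its within-module q-value is below `alpha`; candidates are
#' classed as positive or negative regulators by the sign of their gene
#' significance.
#'
#' @param gs_table output of [gene_significance()].
#' @param labels integer module labels named by gene (or aligned vector).
#' @param alpha FDR level (default 0.05).
#' @return `gs_table` with columns module, q, candidate, regulator_class.
#' @export
select_candidates <- function(gs_table, labels, alpha = 0.05) {
  if (!is.null(names(labels))) labels <- labels[gs_table$gene_id]
  assert_that(length(labels) == nrow(gs_table) && !anyNA(labels),
              "every gene needs a module label")
  gs_table$module <- as.integer(labels)
  gs_table$q <- NA_real_
  for (m in unique(gs_table$module)) {
    idx <- gs_table$module == m
    gs_table$q[idx] <- stats::p.adjust(gs_table$p[idx], method = "BH")
  }
  gs_table$candidate <- gs_table$q < alpha
  gs_table$regulator_class <- ifelse(gs_table$candidate,
                                     ifelse(gs_table$gs > 0, "positive",
                                            "negative"), NA_character_)
  gs_table
}

#' Cross-subset validation of gene significance
#'
#' Compares candidate-gene GS computed on two disjoint sample subsets (e.g.
#' wild-caught vs common-garden): ordinary least squares fit of one subset's
#' GS on the other (adjusted and plain R-squared), Spearman rank correlation,
#' paired t-tests of GS between subsets split by regulator class, and
#' per-class OLS R-squared.
#'
#' @param gs_full GS table with regulator classes (from
#'   [select_candidates()]).
#' @param gs_a,gs_b GS tables computed on the two subsets.
#' @param candidate_ids genes to compare.
#' @return list of class `"gs_validation"`.
#' @export
validate_gs_subsets <- function(gs_full, gs_a, gs_b, candidate_ids) {
  shared <- Reduce(intersect, list(candidate_ids, gs_a$gene_id, gs_b$gene_id))
  assert_that(length(shared) >= 3, "fewer than 3 shared candidates")
  a <- gs_a$gs[match(shared, gs_a$gene_id)]
  b <- gs_b$gs[match(shared, gs_b$gene_id)]
  cls <- gs_full$regulator_class[match(shared, gs_full$gene_id)]

  fit <- stats::lm(b ~ a)
  sp <- spearman_correlation(a, b)
  per_class <- lapply(stats::setNames(nm = c("positive", "negative")),
                      function(k) {
    idx <- which(cls == k)
    if (length(idx) < 3) return(NULL)
    f <- summary(stats::lm(b[idx] ~ a[idx]))
    d <- a[idx] - b[idx]
    tt <- if (stats::sd(d) == 0) {
      ## identical (or uniformly shifted) GS vectors: degenerate paired t
      list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
           parameter = length(d) - 1,
           p.value = if (mean(d) == 0) 1 else 0)
    } else {
      stats::t.test(a[idx], b[idx], paired = TRUE)
    }
    list(n = length(idx), r_squared = f$r.squared,
         adj_r_squared = f$adj.r.squared,
         p_lm = stats::coef(f)[2, 4],
         paired_t = unname(tt$statistic), paired_df = unname(tt$parameter),
         paired_p = tt$p.value)
  })
  structure(list(
    n = length(shared),
    r_squared = summary(fit)$r.squared,
    adj_r_squared = summary(fit)$adj.r.squared,
    lm_p = stats::coef(summary(fit))[2, 4],
    spearman_rho = sp$rho, spearman_p = sp$p,
    per_class = per_class), class = "gs_validation")
}

#' @export
print.gs_validation <- function(x, ...) {
  cat("GS cross-subset validation over", x$n, "candidates\n")
  cat(sprintf("  OLS R^2 = %.3f (adj %.3f), p = %.3g\n", x$r_squared,
              x$adj_r_squared, x$lm_p))
  cat(sprintf("  Spearman rho = %.3f, p = %.3g\n", x$spearman_rho,
              x$spearman_p))
  for (k in names(x$per_class)) {
    pc <- x$per_class[[k]]
    if (is.null(pc)) next
    cat(sprintf("  %s regulators (n=%d): R^2 = %.3f, paired t = %.2f (p = %.3g)\n",
                k, pc$n, pc$r_squared, pc$paired_t, pc$paired_p))
  }
  invisible(x)
}
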