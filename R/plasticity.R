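#' Classify heat-induced plasticity of one gene
#'
#' Decision rule: a positive regulator (expression positively correlated with
#' CT_MAX) whose expression rises from 25 to 32 degrees shows adaptive
#' plasticity, as does a negative regulator whose expression falls; the
#' opposite pairings are maladaptive. Log-fold changes within `epsilon` of
#' zero are called indeterminate (with the default epsilon of 0 only an
#' exact zero is indeterminate).
#'
#' @param regulator_class `"positive"` or `"negative"`.
#' @param lfc_25_to_32 log2 fold change, 32-degree group minus 25-degree.
#' @param epsilon half-width of the indeterminate band around zero.
#' @return `"adaptive"`, `"maladaptive"` or `"indeterminate"` (vectorized).
#' @export
classify_gene <- function(regulator_class, lfc_25_to_32, epsilon = 0) {
  assert_that(all(regulator_class %in% c("positive", "negative")),
              "regulator_class must be positive/negative (candidates only)")
  reg_sign <- ifelse(regulator_class == "positive", 1, -1)
  out <- rep("indeterminate", length(lfc_25_to_32))
  det <- abs(lfc_25_to_32) > epsilon
  out[det] <- ifelse(sign(lfc_25_to_32[det]) == reg_sign[det],
                     "adaptive", "maladaptive")
  out
}

#' Classify a candidate cohort per lineage
#'
#' Applies [classify_gene()] to every candidate for both lineages, using the
#' common-garden 25-vs-32 degree log-fold change of each lineage against the
#' regulator classes derived from the full-cohort gene significance.
#'
#' @param gs_table GS table with candidate flags ([select_candidates()]).
#' @param lfc_forest,lfc_urban per-lineage common-garden LFC tables
#'   ([group_lfc()], 32-degree minus 25-degree).
#' @param epsilon indeterminate band (default 0).
#' @return data.frame of class `"plasticity_calls"`: one row per
#'   (gene, lineage) with regulator_class, lfc_25_to_32 and call. Summary
#'   counts by lineage/call and by lineage/class/direction are attached as
#'   attribute `"summary"`.
#' @export
classify_cohort <- function(gs_table, lfc_forest, lfc_urban, epsilon = 0) {
  cand <- gs_table[which(gs_table$candidate), ]
  assert_that(nrow(cand) > 0, "no candidate genes to classify")
  tables <- list(forest = lfc_forest, urban = lfc_urban)
  rows <- lapply(names(tables), function(lin) {
    lfc_tab <- tables[[lin]]
    miss <- setdiff(cand$gene_id, lfc_tab$gene_id)
    assert_that(length(miss) == 0, "candidates absent from ", lin,
                " LFC table: ", paste(utils::head(miss, 5), collapse = ", "))
    lfc <- lfc_tab$lfc[match(cand$gene_id, lfc_tab$gene_id)]
    data.frame(gene_id = cand$gene_id, lineage = lin,
               regulator_class = cand$regulator_class,
               lfc_25_to_32 = lfc,
               call = classify_gene(cand$regulator_class, lfc, epsilon),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  attr(calls, "summary") <- summarize_calls(calls)
  class(calls) <- c("plasticity_calls", "data.frame")
  calls
}

summarize_calls <- function(calls) {
  by_call <- as.data.frame(table(lineage = calls$lineage, call = calls$call),
                           stringsAsFactors = FALSE)
  direction <- ifelse(calls$lfc_25_to_32 > 0, "up",
                      ifelse(calls$lfc_25_to_32 < 0, "down", "flat"))
  by_dir <- as.data.frame(table(lineage = calls$lineage,
                                regulator_class = calls$regulator_class,
                                direction = direction),
                          stringsAsFactors = FALSE)
  det <- calls$call != "indeterminate"
  prop <- vapply(split(calls$call[det] == "maladaptive", calls$lineage[det]),
                 mean, numeric(1))
  list(by_call = by_call, by_class_direction = by_dir,
       maladaptive_proportion = prop,
       n_indeterminate = sum(!det))
}

#' Proportion tests on plasticity calls
#'
#' Within each lineage, an exact binomial test of the maladaptive count
#' against 0.5; between lineages, an exact binomial test of the urban
#' adaptive count against the forest adaptive proportion, plus the
#' two-sample equality-of-proportions test with continuity correction.
#' Indeterminate calls are excluded (their count is reported).
#'
#' @param calls a `"plasticity_calls"` table.
#' @return list of class `"plasticity_tests"`.
#' @export
plasticity_proportion_tests <- function(calls) {
  det <- calls[calls$call != "indeterminate", ]
  assert_that(nrow(det) > 0, "no determinate calls")
  within <- lapply(split(det, det$lineage), function(d) {
    k <- sum(d$call == "maladaptive")
    n <- nrow(d)
    bt <- stats::binom.test(k, n, p = 0.5)
    list(n = n, maladaptive = k, proportion = k / n, p = bt$p.value)
  })
  between <- NULL
  if (all(c("forest", "urban") %in% det$lineage)) {
    f <- det[det$lineage == "forest", ]
    u <- det[det$lineage == "urban", ]
    p_forest_adaptive <- mean(f$call == "adaptive")
    bt <- stats::binom.test(sum(u$call == "adaptive"), nrow(u),
                            p = max(min(p_forest_adaptive, 1 - 1e-12),
                                    1e-12))
    pt <- suppressWarnings(
      stats::prop.test(c(sum(f$call == "maladaptive"),
                         sum(u$call == "maladaptive")),
                       c(nrow(f), nrow(u)), correct = TRUE))
    between <- list(
      forest_adaptive_prop = p_forest_adaptive,
      urban_adaptive_prop = mean(u$call == "adaptive"),
      exact_binomial_p = bt$p.value,
      prop_chisq = unname(pt$statistic), prop_df = unname(pt$parameter),
      prop_p = pt$p.value)
  }
  structure(list(within = within, between = between,
                 n_indeterminate = sum(calls$call == "indeterminate")),
            class = "plasticity_tests")
}

#' Welch test of plasticity magnitude between lineages
#'
#' Compares the absolute common-garden 25-to-32 degree log-fold changes of
#' candidate genes between forest and urban lineages by Welch's two-sample
#' t-test (an attenuated urban response gives smaller urban magnitudes).
#' With zero variance in both groups the t statistic degenerates; the guard
#' returns p = 0 (means differ) or p = 1 (means equal) with a warning.
#'
#' @param lfc_forest,lfc_urban per-lineage LFC tables.
#' @param candidate_ids genes to compare.
#' @return list with t, df, p and group means/SDs.
#' @export
plasticity_magnitude_test <- function(lfc_forest, lfc_urban, candidate_ids) {
  f <- abs(lfc_forest$lfc[match(candidate_ids, lfc_forest$gene_id)])
  u <- abs(lfc_urban$lfc[match(candidate_ids, lfc_urban$gene_id)])
  assert_that(!anyNA(f) && !anyNA(u), "candidates missing from LFC tables")
  assert_that(length(f) >= 2 && length(u) >= 2, "need >= 2 genes per group")
  if (stats::sd(f) == 0 && stats::sd(u) == 0) {
    warning("zero variance in both groups; degenerate Welch test")
    eq <- isTRUE(all.equal(mean(f), mean(u)))
    return(list(t = if (eq) 0 else Inf * sign(mean(f) - mean(u)),
                df = NA_real_, p = if (eq) 1 else 0,
                mean_forest = mean(f), mean_urban = mean(u),
                sd_forest = 0, sd_urban = 0))
  }
  tt <- stats::t.test(f, u)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_forest = mean(f), mean_urban = mean(u),
       sd_forest = stats::sd(f), sd_urban = stats::sd(u))
}

#' @export
print.plasticity_tests <- function(x, ...) {
  for (lin in names(x$within)) {
    w <- x$within[[lin]]
    cat(sprintf("%s: %d/%d maladaptive (%.1f%%), binomial p = %.3g\n",
                lin, w$maladaptive, w$n, 100 * w$proportion, w$p))
  }
  if (!is.null(x$between)) {
    b <- x$between
    cat(sprintf(
      "between lineages: adaptive %.1f%% (forest) vs %.1f%% (urban); exact binomial p = %.3g; prop chi^2 = %.2f, p = %.3g\n",
      100 * b$forest_adaptive_prop, 100 * b$urban_adaptive_prop,
      b$exact_binomial_p, b$prop_chisq, b$prop_p))
  }
  if (x$n_indeterminate > 0) {
    cat("indeterminate calls excluded:", x$n_indeterminate, "\n")
  }
  invisible(x)
}
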