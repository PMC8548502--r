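#' Hardy-Weinberg deviation scan with set comparison
#'
#' Per SNP and per population: chi-squared goodness of fit (1 df) of the
#' observed genotype counts (AA, Aa, aa) against Hardy-Weinberg expectations
#' computed from the population allele frequency; a SNP is deviant at
#' p < `alpha`. SNPs with an expected cell count below 5 are flagged
#' `low_count` but still computed. When the variant table carries set
#' labels, the candidate-vs-background deviant proportions are compared per
#' population by the two-sample equality-of-proportions test with continuity
#' correction.
#'
#' @param variants a `variant_table`.
#' @param pops named list of sample-id vectors, one per population.
#' @param alpha deviance threshold (default 0.05).
#' @param candidate_sets set labels treated as candidate (default the
#'   adaptive/maladaptive classes).
#' @return list of class `"hwe_scan"`: `table` (per SNP x population rows)
#'   and `comparison` (per-population proportion tests, or NULL).
#' @export
hwe_scan <- function(variants, pops, alpha = 0.05,
                     candidate_sets = c("adaptive", "maladaptive")) {
  geno <- variants$geno
  info <- variants$info
  tabs <- lapply(names(pops), function(pn) {
    g <- geno[, resolve_samples(geno, pops[[pn]]), drop = FALSE]
    n0 <- rowSums(g == 0, na.rm = TRUE)
    n1 <- rowSums(g == 1, na.rm = TRUE)
    n2 <- rowSums(g == 2, na.rm = TRUE)
    n <- n0 + n1 + n2
    res <- hwe_chisq(n0, n1, n2)
    data.frame(snp_id = info$snp_id, population = pn,
               n_AA = n0, n_Aa = n1, n_aa = n2,
               chi2 = res$chi2, p = res$p,
               deviant = !is.na(res$p) & res$p < alpha,
               low_count = res$low_count,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, tabs)
  comparison <- NULL
  if (!is.null(info$set)) {
    cand <- info$set %in% candidate_sets
    bg <- info$set == "background"
    comparison <- lapply(stats::setNames(nm = names(pops)), function(pn) {
      d <- table[table$population == pn, ]
      kc <- sum(d$deviant[cand], na.rm = TRUE)
      kb <- sum(d$deviant[bg], na.rm = TRUE)
      nc <- sum(cand & !is.na(d$p)); nb <- sum(bg & !is.na(d$p))
      if (nc == 0 || nb == 0) return(NULL)
      pt <- suppressWarnings(stats::prop.test(c(kc, kb), c(nc, nb),
                                              correct = TRUE))
      list(candidate_deviant = kc, candidate_n = nc,
           background_deviant = kb, background_n = nb,
           candidate_proportion = kc / nc,
           background_proportion = kb / nb,
           chisq = unname(pt$statistic), df = unname(pt$parameter),
           p = pt$p.value)
    })
  }
  structure(list(table = table, comparison = comparison, alpha = alpha),
            class = "hwe_scan")
}

## Vectorized 1-df chi-squared HWE goodness of fit from genotype counts.
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * pmax(n, 1))
  e_AA <- n * p^2
  e_Aa <- n * 2 * p * (1 - p)
  e_aa <- n * (1 - p)^2
  chi2 <- ifelse(n > 0 & p > 0 & p < 1,
                 (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa,
                 NA_real_)
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  low <- !is.na(chi2) & (pmin(e_AA, e_Aa, e_aa) < 5)
  list(chi2 = chi2, p = pval, low_count = low)
}

#' Functional-class enrichment of a SNP set against the background
#'
#' Compares the proportion of SNPs of a functional class (nonsynonymous or
#' noncoding) in a focal set against the transcriptome-wide background set
#' with the two-sample equality-of-proportions test with continuity
#' correction, plus a Wilson 95% confidence interval on the focal
#' proportion.
#'
#' @param variants a `variant_table` with `fclass` labels.
#' @param focal_idx,background_idx row indexes (or logical masks).
#' @param class `"nonsynonymous"` or `"noncoding"` (any label present).
#' @return list with proportions, chi-squared, p and the Wilson CI.
#' @export
annotation_class_enrichment <- function(variants, focal_idx, background_idx,
                                        class) {
  fclass <- variants$info$fclass
  assert_that(!is.null(fclass), "variant table carries no functional classes")
  f <- fclass[focal_idx]; b <- fclass[background_idx]
  assert_that(length(f) > 0 && length(b) > 0, "empty SNP set")
  kf <- sum(f == class); kb <- sum(b == class)
  pt <- suppressWarnings(stats::prop.test(c(kf, kb),
                                          c(length(f), length(b)),
                                          correct = TRUE))
  ci <- wilson_ci(kf, length(f))
  list(class = class,
       focal_count = kf, focal_n = length(f),
       focal_proportion = kf / length(f),
       background_proportion = kb / length(b),
       chisq = unname(pt$statistic), df = unname(pt$parameter),
       p = pt$p.value,
       focal_ci = ci)
}
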