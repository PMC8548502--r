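#' Filter biallelic SNPs on quality, allele frequency and missingness
#'
#' Retains SNPs with quality >= `min_qual`, minor allele frequency >=
#' `min_maf` (computed from non-missing genotypes across all samples) and a
#' missing-genotype fraction strictly below `max_missing`. A per-criterion
#' removal report is attached as attribute `"filter_report"` (a SNP failing
#' several criteria is counted under each).
#'
#' @param variants a `variant_table`.
#' @param min_qual,min_maf,max_missing filter thresholds.
#' @return the filtered `variant_table`.
#' @export
filter_variants <- function(variants, min_qual = 20, min_maf = 0.05,
                            max_missing = 0.20) {
  info <- variants$info
  geno <- variants$geno
  n_called <- rowSums(!is.na(geno))
  miss <- (ncol(geno) - n_called) / ncol(geno)
  af <- rowSums(geno, na.rm = TRUE) / (2 * pmax(n_called, 1))
  maf <- pmin(af, 1 - af)
  pass_qual <- info$qual >= min_qual
  pass_maf <- maf >= min_maf & n_called > 0
  pass_miss <- miss < max_missing
  keep <- pass_qual & pass_maf & pass_miss
  if (!any(keep)) warning("no SNPs survive filtering")
  out <- structure(list(info = info[keep, , drop = FALSE],
                        geno = geno[keep, , drop = FALSE]),
                   class = "variant_table")
  attr(out, "filter_report") <- c(
    input = nrow(info), retained = sum(keep),
    fail_quality = sum(!pass_qual), fail_maf = sum(!pass_maf),
    fail_missing = sum(!pass_miss))
  out
}

#' Per-SNP Weir-Cockerham FST with optional kernel smoothing
#'
#' Two-population variance-components estimator theta (the single-locus
#' Weir & Cockerham 1984 form, the AMOVA-family estimator), computed per SNP
#' from allele frequencies, sample sizes and observed heterozygosity of the
#' two populations; individuals with a missing genotype are dropped per SNP.
#' Negative estimates are retained (clamping would bias set means). Theta is
#' undefined (NA) where a population has no called genotypes at the SNP,
#' fewer than three individuals are called in total, or the locus is
#' monomorphic overall.
#'
#' When `sigma_bp` is given, a smoothed track is added: the Gaussian-kernel
#' weighted mean of theta over SNPs on the same scaffold,
#' `smoothed_i = sum_j w_ij theta_j / sum_j w_ij`,
#' `w_ij = exp(-d_ij^2 / (2 sigma^2))` (weights truncated at 4 sigma).
#'
#' @param variants a `variant_table`.
#' @param pop_a,pop_b sample id vectors (or logical indexes over columns).
#' @param sigma_bp Gaussian kernel sd in bp, or NULL for no smoothing.
#' @return data.frame of class `"fst_scan"`: snp_id, scaffold, pos, theta,
#'   and smoothed (if requested), plus the per-set labels carried over.
#' @export
weir_cockerham_fst <- function(variants, pop_a, pop_b, sigma_bp = NULL) {
  geno <- variants$geno
  ga <- geno[, resolve_samples(geno, pop_a), drop = FALSE]
  gb <- geno[, resolve_samples(geno, pop_b), drop = FALSE]
  assert_that(ncol(ga) >= 2 && ncol(gb) >= 2,
              "each population needs >= 2 samples")
  theta <- wc_theta_components(ga, gb)$theta
  out <- data.frame(snp_id = variants$info$snp_id,
                    scaffold = variants$info$scaffold,
                    pos = variants$info$pos, theta = theta,
                    stringsAsFactors = FALSE)
  if (!is.null(variants$info$set)) out$set <- variants$info$set
  if (!is.null(variants$info$gene_id)) out$gene_id <- variants$info$gene_id
  if (!is.null(sigma_bp)) {
    out$smoothed <- kernel_smooth_by_scaffold(out$scaffold, out$pos,
                                              out$theta, sigma_bp)
  }
  class(out) <- c("fst_scan", "data.frame")
  out
}

## Weir & Cockerham (1984) a, b, c components for two populations,
## vectorized over SNPs. Returns per-SNP theta and the components (the
## multi-locus ratio-of-sums estimator is sum(a)/sum(a+b+c)).
wc_theta_components <- function(ga, gb) {
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(ga == 1, na.rm = TRUE) / n1
  h2 <- rowSums(gb == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  denom <- a + b + c_
  ## theta is undefined when a population has no called genotypes, when the
  ## overall sample is too small for the nbar - 1 correction, or when the
  ## locus is monomorphic across both populations (zero denominator)
  theta <- ifelse(n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3 &
                    abs(denom) > .Machine$double.eps,
                  a / denom, NA_real_)
  list(theta = theta, a = a, b = b, c = c_)
}

resolve_samples <- function(geno, spec) {
  if (is.logical(spec)) return(which(spec))
  idx <- match(spec, colnames(geno))
  assert_that(!anyNA(idx), "unknown sample id(s): ",
              paste(utils::head(spec[is.na(idx)], 5), collapse = ", "))
  idx
}

## Gaussian-kernel weighted mean along each scaffold; weights truncated at
## 4 sigma. sigma -> 0 returns the raw values, sigma -> Inf the scaffold
## mean.
kernel_smooth_by_scaffold <- function(scaffold, pos, value, sigma_bp) {
  out <- rep(NA_real_, length(value))
  if (sigma_bp <= 0) return(value)
  for (sc in unique(scaffold)) {
    idx <- which(scaffold == sc & !is.na(value))
    if (!length(idx)) next
    p <- pos[idx]; v <- value[idx]
    ord <- order(p); p <- p[ord]; v <- v[ord]
    res <- numeric(length(p))
    win <- 4 * sigma_bp
    lo <- findInterval(p - win, p) + 1L
    hi <- findInterval(p + win, p)
    for (i in seq_along(p)) {
      j <- lo[i]:hi[i]
      w <- exp(-(p[j] - p[i])^2 / (2 * sigma_bp^2))
      res[i] <- sum(w * v[j]) / sum(w)
    }
    out[idx[ord]] <- res
  }
  ## SNPs with undefined theta keep NA in the smoothed track
  out
}

#' Multi-locus Weir-Cockerham FST (ratio of sums)
#'
#' @param variants a `variant_table`.
#' @param pop_a,pop_b sample sets as in [weir_cockerham_fst()].
#' @return a single FST estimate, `sum(a) / sum(a + b + c)` over SNPs.
#' @export
fst_overall <- function(variants, pop_a, pop_b) {
  geno <- variants$geno
  ga <- geno[, resolve_samples(geno, pop_a), drop = FALSE]
  gb <- geno[, resolve_samples(geno, pop_b), drop = FALSE]
  comp <- wc_theta_components(ga, gb)
  ok <- !is.na(comp$theta)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' FST outlier enrichment of a SNP set against the background
#'
#' The outlier threshold is the (1 - alpha) empirical quantile (type-7
#' interpolation) of the background theta distribution; the proportion of
#' focal-set SNPs beyond it is compared to the background's own outlier
#' proportion with the two-sample equality-of-proportions test with
#' continuity correction.
#'
#' @param scan an `"fst_scan"` data.frame.
#' @param set_idx,background_idx row indexes (or logical masks) into `scan`.
#' @param alpha empirical tail probability defining outliers (default 0.05).
#' @return list with threshold, proportions, chi-squared statistic and p.
#' @export
fst_outlier_enrichment <- function(scan, set_idx, background_idx,
                                   alpha = 0.05) {
  th_set <- scan$theta[set_idx]; th_set <- th_set[!is.na(th_set)]
  th_bg <- scan$theta[background_idx]; th_bg <- th_bg[!is.na(th_bg)]
  assert_that(length(th_set) > 0, "empty focal set")
  assert_that(length(th_bg) >= 100, "background needs >= 100 SNPs")
  threshold <- stats::quantile(th_bg, 1 - alpha, type = 7, names = FALSE)
  k_set <- sum(th_set > threshold); n_set <- length(th_set)
  k_bg <- sum(th_bg > threshold); n_bg <- length(th_bg)
  pt <- suppressWarnings(stats::prop.test(c(k_set, k_bg), c(n_set, n_bg),
                                          correct = TRUE))
  list(threshold = threshold, alpha = alpha,
       set_outliers = k_set, set_n = n_set,
       set_proportion = k_set / n_set,
       background_proportion = k_bg / n_bg,
       chisq = unname(pt$statistic), df = unname(pt$parameter),
       p = pt$p.value)
}

#' Welch contrast of mean FST between two SNP sets
#'
#' @param scan an `"fst_scan"` data.frame.
#' @param set_a_idx,set_b_idx row indexes (set A is conventionally the
#'   maladaptive class, set B the adaptive class).
#' @return list with t, df, p and per-set mean +/- SE.
#' @export
mean_fst_contrast <- function(scan, set_a_idx, set_b_idx) {
  a <- scan$theta[set_a_idx]; a <- a[!is.na(a)]
  b <- scan$theta[set_b_idx]; b <- b[!is.na(b)]
  assert_that(length(a) >= 2 && length(b) >= 2, "need >= 2 SNPs per set")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("zero variance in both sets; degenerate Welch test")
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b),
                se_a = 0, se_b = 0, n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b),
       se_a = stats::sd(a) / sqrt(length(a)),
       se_b = stats::sd(b) / sqrt(length(b)),
       n_a = length(a), n_b = length(b))
}
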