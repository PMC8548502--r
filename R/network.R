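#' Choose the soft-threshold power for the weighted network
#'
#' Scans candidate powers and returns the smallest whose scale-free topology
#' fit reaches `target_fit`. The fit is the R-squared of the regression of
#' log10 frequency on log10 mean connectivity over at least 10 connectivity
#' bins (the conventional scale-free fit index for weighted co-expression
#' networks). If no power reaches the target, the power maximizing the fit
#' is returned with a warning.
#'
#' @param norm normalized expression matrix, genes x samples.
#' @param candidate_powers integer powers to scan.
#' @param target_fit required scale-free fit R-squared.
#' @param n_bins connectivity bins used for the fit.
#' @return integer power; the full scan is attached as attribute `"fits"`.
#' @export
choose_soft_power <- function(norm, candidate_powers = 1:20,
                              target_fit = 0.8, n_bins = 10) {
  assert_that(nrow(norm) >= 3, "need at least 3 genes")
  v <- apply(norm, 1, stats::var)
  assert_that(all(v > 0), "constant-expression gene(s) present: ",
              paste(utils::head(rownames(norm)[v == 0], 5), collapse = ", "),
              "; filter before network construction")
  cmat <- abs(stats::cor(t(norm)))
  fits <- vapply(candidate_powers, function(beta) {
    a <- cmat^beta
    k <- rowSums(a) - 1
    scale_free_fit(k, n_bins)
  }, numeric(1))
  ok <- which(fits >= target_fit)
  if (length(ok)) {
    beta <- candidate_powers[ok[1]]
  } else {
    beta <- candidate_powers[which.max(fits)]
    warning("no candidate power reaches scale-free fit ", target_fit,
            "; returning power ", beta, " (fit ",
            signif(max(fits), 3), ")")
  }
  structure(beta, fits = stats::setNames(fits, candidate_powers))
}

## R^2 of log10(freq) ~ log10(mean k) over connectivity bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(0)
  breaks <- unique(stats::quantile(k, seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(0)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin))
  kmean <- tapply(k, bin, mean)
  keep <- freq > 0 & kmean > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  summary(fit)$r.squared
}

#' Unsigned adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^beta` (unsigned, Pearson) and the
#' standard topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u` distinct from both `i` and `j` and connectivity
#' `k_i = sum_{u != i} a_iu`. Both matrices have unit diagonal and entries in
#' `[0, 1]`. The signed gene-trait correlation is kept separately by
#' [gene_significance()]; module detection itself is unsigned.
#'
#' @param norm normalized expression matrix, genes x samples.
#' @param beta soft-threshold power (>= 1).
#' @param max_genes guard against accidental huge dense matrices; raise
#'   explicitly to override.
#' @return list with `adjacency`, `tom`, `beta`.
#' @export
build_adjacency_tom <- function(norm, beta, max_genes = 20000) {
  assert_that(beta >= 1, "beta must be >= 1", config = TRUE)
  assert_that(nrow(norm) <= max_genes,
              "n_genes = ", nrow(norm), " exceeds max_genes = ", max_genes,
              "; pass a larger max_genes to override", config = TRUE)
  v <- apply(norm, 1, stats::var)
  assert_that(all(v > 0), "zero-variance gene(s): ",
              paste(utils::head(rownames(norm)[v == 0], 5), collapse = ", "))
  a <- abs(stats::cor(t(norm)))^beta
  diag(a) <- 1
  tom <- tom_from_adjacency(a)
  list(adjacency = a, tom = tom, beta = as.integer(beta))
}

## TOM via one matrix product: (A %*% A)_ij counts u = i and u = j terms,
## each contributing a_ij (unit diagonal), so the off-diagonal shared-
## neighbour sum is (A %*% A)_ij - 2 a_ij.
tom_from_adjacency <- function(a) {
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by dynamic tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`;
#' branches are obtained by cutting the tree at `cut_height`, and branches
#' smaller than `min_module_size` are left unassigned (label 0). Assigned
#' labels are contiguous integers ordered by decreasing module size.
#'
#' @param tom topological overlap matrix.
#' @param min_module_size smallest branch kept as a module.
#' @param cut_height static cut height on the 1 - TOM dendrogram.
#' @return integer label vector named by gene.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  assert_that(min_module_size >= 2, "min_module_size must be >= 2",
              config = TRUE)
  dendro <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(dendro, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  }
  stats::setNames(labels, rownames(tom))
}

#' Module eigengenes with correlated-module merging
#'
#' The eigengene of a module is the unit-norm first principal component of
#' the gene-standardized module expression across samples, sign-oriented to
#' correlate non-negatively with the module's average standardized profile.
#' Pairs of modules whose eigengene correlation satisfies
#' `r^2 >= merge_r2` are merged iteratively (most correlated pair first),
#' recomputing eigengenes after every merge, until no pair qualifies.
#' Merged labels are relabelled contiguously by decreasing size.
#'
#' @param norm normalized expression matrix, genes x samples.
#' @param labels integer module labels (0 = unassigned).
#' @param merge_r2 squared-correlation merge threshold.
#' @return list with `labels` (post-merge), `eigengenes` (modules x samples),
#'   and `merge_history` (list of merged label pairs).
#' @export
compute_eigengenes_and_merge <- function(norm, labels, merge_r2 = 0.75) {
  assert_that(any(labels > 0), "no non-zero modules to summarize")
  labels <- stats::setNames(as.integer(labels), names(labels))
  history <- list()
  repeat {
    egs <- eigengene_matrix(norm, labels)
    if (nrow(egs) < 2) break
    cc <- stats::cor(t(egs))
    diag(cc) <- 0
    r2 <- cc^2
    if (max(r2) < merge_r2) break
    pair <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    m1 <- as.integer(rownames(egs)[pair[1]])
    m2 <- as.integer(rownames(egs)[pair[2]])
    labels[labels == m2] <- m1
    history[[length(history) + 1L]] <- c(kept = m1, merged = m2,
                                         r2 = max(r2))
  }
  ## contiguous relabel by decreasing size
  tab <- table(labels[labels > 0])
  ord <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))])
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  egs <- eigengene_matrix(norm, new)
  list(labels = new, eigengenes = egs, merge_history = history)
}

eigengene_matrix <- function(norm, labels) {
  mods <- sort(unique(labels[labels > 0]))
  egs <- matrix(NA_real_, length(mods), ncol(norm),
                dimnames = list(mods, colnames(norm)))
  for (i in seq_along(mods)) {
    egs[i, ] <- module_eigengene(norm[labels == mods[i], , drop = FALSE])
  }
  egs
}

## Unit-norm first left singular vector of the samples x genes standardized
## matrix, oriented along the average standardized profile. A single-gene
## module yields its own standardized profile (unit norm).
module_eigengene <- function(x) {
  xs <- t(scale(t(x)))  # standardize each gene across samples
  if (nrow(xs) == 1) {
    e <- xs[1, ]
    return(e / sqrt(sum(e^2)))
  }
  sv <- svd(t(xs), nu = 1, nv = 0)
  e <- sv$u[, 1]
  avg <- colMeans(xs)
  if (sum(e * avg) < 0) e <- -e
  e
}
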