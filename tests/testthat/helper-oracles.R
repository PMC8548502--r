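# Independent oracles used across the suite. These deliberately recompute
# the target statistics by a different route (explicit loops, enumeration,
# textbook closed forms) than the package implementation.

## Topological overlap by literal triple loop over shared neighbours.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

## Weir-Cockerham theta via the allele-copy nested ANOVA (mean squares),
## two populations, dosage vectors with NAs allowed.
wc_oracle <- function(ga, gb) {
  pops <- list(ga[!is.na(ga)], gb[!is.na(gb)])
  ns <- vapply(pops, length, integer(1))
  ybar_ij <- lapply(pops, function(g) g / 2)
  p_i <- vapply(ybar_ij, mean, numeric(1))
  ntot <- sum(ns)
  r <- 2
  pbar <- sum(ns * p_i) / ntot
  ssg <- sum(vapply(pops, function(g) sum(g == 1) * 0.5, numeric(1)))
  ssi <- 2 * sum(mapply(function(y, p) sum((y - p)^2), ybar_ij, p_i))
  ssp <- 2 * sum(ns * (p_i - pbar)^2)
  msg <- ssg / ntot
  msi <- ssi / sum(ns - 1)
  msp <- ssp / (r - 1)
  nc <- (ntot - sum(ns^2) / ntot) / (r - 1)
  s_p <- (msp - msi) / (2 * nc)
  s_i <- (msi - msg) / 2
  denom <- s_p + s_i + msg
  if (abs(denom) < .Machine$double.eps) return(NA_real_)
  s_p / denom
}

## Welch two-sample t from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

## Mid-rank Spearman by enumeration: average the rank vectors over every
## tie-breaking order (the mid-rank vector is exactly that average), then
## take the Pearson correlation of the averaged ranks.
spearman_enumeration_oracle <- function(x, y) {
  rank_orders <- function(v) {
    ord <- order(v)
    ranks_base <- seq_along(v)
    groups <- split(seq_along(v)[ord], v[ord])
    perms <- function(k) {
      if (k == 1) return(list(1L))
      out <- list()
      for (p in perms(k - 1)) {
        for (pos in seq_len(k)) out[[length(out) + 1L]] <- append(p, k, pos - 1)
      }
      out
    }
    res <- list(integer(length(v)))
    start <- 0L
    for (g in groups) {
      k <- length(g)
      new <- list()
      for (r in res) {
        for (p in perms(k)) {
          r2 <- r
          r2[g] <- start + unlist(p)
          new[[length(new) + 1L]] <- r2
        }
      }
      res <- new
      start <- start + k
    }
    res
  }
  avg_rank <- function(v) {
    rs <- rank_orders(v)
    Reduce(`+`, rs) / length(rs)
  }
  cor(avg_rank(x), avg_rank(y))
}

## Two-proportion chi-squared with continuity correction (textbook form).
prop_chisq_oracle <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  num <- (abs(x1 / n1 - x2 / n2) - 0.5 * (1 / n1 + 1 / n2))^2
  chi2 <- num / (p * (1 - p) * (1 / n1 + 1 / n2))
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

## Wrap a dosage matrix as a variant_table for popgen tests.
toy_variant_table <- function(geno, pos = NULL, qual = 50,
                              gene_id = NULL, fclass = NULL, set = NULL) {
  n_snps <- nrow(geno)
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("snp%03d", seq_len(n_snps))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
  }
  info <- data.frame(snp_id = rownames(geno), scaffold = "scaffold_1",
                     pos = pos %||% seq_len(n_snps),
                     qual = rep_len(qual, n_snps), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  if (!is.null(gene_id)) info$gene_id <- rep_len(gene_id, n_snps)
  if (!is.null(fclass)) info$fclass <- rep_len(fclass, n_snps)
  if (!is.null(set)) info$set <- rep_len(set, n_snps)
  structure(list(info = info, geno = geno), class = "variant_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Small expression matrix with two planted correlation blocks.
planted_block_matrix <- function(n_per_block = 50, n_samples = 60,
                                 within_cor = 0.9, seed = 1) {
  set.seed(seed)
  blocks <- lapply(1:2, function(b) {
    f <- rnorm(n_samples)
    t(sapply(seq_len(n_per_block), function(i) {
      sqrt(within_cor) * f + sqrt(1 - within_cor) * rnorm(n_samples)
    }))
  })
  x <- do.call(rbind, blocks)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("S%03d", seq_len(n_samples))
  list(x = x, labels = rep(1:2, each = n_per_block))
}
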