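#' Simulate biallelic SNP genotypes with planted habitat divergence
#'
#' Places genes on one synthetic scaffold (tiled at the configured spacing),
#' scatters SNPs uniformly within each gene span, and draws genotypes under a
#' two-level allele-frequency model: an ancestral frequency per SNP
#' (Uniform(0.1, 0.9)) and Balding-Nichols Beta-distributed habitat-specific
#' frequencies around it, with divergence parameter equal to the planted FST
#' of the SNP's set (background / adaptive / maladaptive, derived from the
#' planted plasticity direction of the host gene). Within-gene linkage
#' disequilibrium is induced by a latent Gaussian autoregression along each
#' haplotype (two haplotypes per animal, so genotypes are in Hardy-Weinberg
#' proportions within each population); candidate genes use a slower-decaying
#' autocorrelation, planting elevated local LD. Functional classes
#' (nonsynonymous / synonymous / noncoding) are planted per set, and
#' genotypes are masked at the configured missingness rate.
#'
#' With a planted divergence of 1 the two habitats are fixed for alternate
#' alleles (the Balding-Nichols limit).
#'
#' @param cfg a [sim_config()] object.
#' @param truth planted truth from [simulate_expression()].
#' @param samples sample metadata from [simulate_expression()].
#' @return a `variant_table`: list with `info` (data.frame: snp_id, scaffold,
#'   pos, qual, ref, alt, gene_id, fclass, set) and `geno` (integer matrix,
#'   SNPs x samples, alt-allele dosage 0/1/2 with NA for missing).
#' @export
simulate_variants <- function(cfg, truth, samples) {
  validate_sim_config(cfg)
  assert_that(all(cfg$planted_fst >= 0 & cfg$planted_fst <= 1),
              "planted_fst outside [0, 1]", config = TRUE)
  set.seed(cfg$seed + 1L, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  n_genes <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  gene_start <- (seq_len(n_genes) - 1) * cfg$gene_spacing_bp + 1
  gene_end <- gene_start + cfg$gene_span_bp - 1

  ## per-gene SNP allocation and set labels ------------------------------
  per_gene <- as.integer(stats::rmultinom(1, cfg$n_snps, rep(1, n_genes)))
  gene_set <- rep("background", n_genes)
  if (length(truth$candidate_idx)) {
    malad <- truth$forest_norm_direction != truth$regulator_sign
    gene_set[truth$candidate_idx] <- ifelse(malad, "maladaptive", "adaptive")
  }

  n_samples <- nrow(samples)
  pop <- paste(samples$municipality, samples$habitat, sep = ":")
  geno <- matrix(NA_integer_, cfg$n_snps, n_samples)
  info_rows <- vector("list", n_genes)
  offset <- 0L

  for (g in which(per_gene > 0)) {
    k <- per_gene[g]
    pos <- sort(sample.int(cfg$gene_span_bp, k)) + gene_start[g] - 1L
    fst <- unname(cfg$planted_fst[gene_set[g]])
    p_anc <- stats::runif(k, 0.1, 0.9)

    ## habitat-specific frequencies per municipality (Balding-Nichols)
    q <- matrix(NA_real_, k, n_samples)
    for (mun in unique(samples$municipality)) {
      for (hab in c("forest", "urban")) {
        idx <- samples$municipality == mun & samples$habitat == hab
        if (!any(idx)) next
        if (fst == 0) {
          qf <- p_anc
        } else if (fst == 1) {
          qf <- if (hab == "forest") rep(0, k) else rep(1, k)
        } else {
          shape <- (1 - fst) / fst
          qf <- stats::rbeta(k, p_anc * shape, (1 - p_anc) * shape)
        }
        q[, idx] <- qf
      }
    }

    ## haplotypes with latent AR(1) along the gene span
    rho <- unname(cfg$ld_rho[if (gene_set[g] == "background") "background"
                             else "candidate"])
    z <- matrix(stats::rnorm(2 * n_samples * k), 2 * n_samples, k)
    if (k > 1) {
      phi <- rho^(diff(pos) / 1000)
      for (j in 2:k) {
        z[, j] <- phi[j - 1] * z[, j - 1] +
          sqrt(1 - phi[j - 1]^2) * z[, j]
      }
    }
    thr <- stats::qnorm(pmin(pmax(q, 0), 1))  # threshold per SNP x sample
    thr_h <- thr[, rep(seq_len(n_samples), each = 2), drop = FALSE]
    alleles <- (t(z) < thr_h) * 1L
    g_dos <- alleles[, seq(1, 2 * n_samples, by = 2), drop = FALSE] +
      alleles[, seq(2, 2 * n_samples, by = 2), drop = FALSE]

    rows <- offset + seq_len(k)
    geno[rows, ] <- g_dos
    info_rows[[g]] <- data.frame(
      scaffold = "scaffold_1", pos = pos, gene_id = gene_ids[g],
      set = gene_set[g], stringsAsFactors = FALSE)
    offset <- offset + k
  }

  info <- do.call(rbind, info_rows)
  n_snps <- nrow(info)
  info$snp_id <- sprintf("snp%06d", seq_len(n_snps))
  info$qual <- round(stats::runif(n_snps, 30, 60), 1)
  info$ref <- "A"
  info$alt <- "G"

  fclass <- character(n_snps)
  for (s in names(cfg$class_prop)) {
    idx <- info$set == s
    if (any(idx)) {
      pr <- cfg$class_prop[[s]]
      fclass[idx] <- sample(names(pr), sum(idx), replace = TRUE, prob = pr)
    }
  }
  info$fclass <- fclass
  info <- info[, c("snp_id", "scaffold", "pos", "qual", "ref", "alt",
                   "gene_id", "fclass", "set")]

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < cfg$missing_rate
    geno[mask] <- NA_integer_
  }
  dimnames(geno) <- list(info$snp_id, samples$sample_id)

  structure(list(info = info, geno = geno), class = "variant_table")
}

#' Gene coordinate table for the synthetic scaffold
#'
#' @param cfg a [sim_config()] object.
#' @return data.frame with gene_id and 1-based inclusive start/end.
#' @export
gene_coordinates <- function(cfg) {
  start <- (seq_len(cfg$n_genes) - 1) * cfg$gene_spacing_bp + 1
  data.frame(gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
             scaffold = "scaffold_1", start = start,
             end = start + cfg$gene_span_bp - 1, stringsAsFactors = FALSE)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$info), "SNPs x", ncol(x$geno), "samples\n")
  cat("  sets:", paste(sprintf("%s=%d", names(table(x$info$set)),
                               table(x$info$set)), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}
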