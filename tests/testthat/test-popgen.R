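test_that("variant filtering enforces the three thresholds exactly", {
  ## 10 SNPs, 10 samples: plant one quality violation, one MAF violation,
  ## one missingness violation
  set.seed(60)
  geno <- matrix(rbinom(100, 2, 0.5), 10, 10)
  geno[2, ] <- c(0L, rep(0L, 8), 1L)        # MAF = 0.05 exactly -> retained
  geno[3, ] <- rep(0L, 10); geno[3, 1] <- 1L  # MAF = 0.05 on 10 samples
  geno[4, ] <- c(rep(NA, 2), rbinom(8, 2, 0.5))  # 20% missing -> removed
  geno[5, ] <- c(rep(NA, 1), rbinom(9, 2, 0.5))  # 10% missing -> kept
  geno[6, ] <- rep(c(0L, 1L), 5)
  qual <- rep(50, 10); qual[7] <- 19.9      # removed
  qual[8] <- 20                              # boundary inclusive -> kept
  vt <- toy_variant_table(geno, qual = qual)
  ## force SNP 9 below the MAF floor
  vt$geno[9, ] <- c(1L, rep(0L, 9)) * 0L
  vt$geno[9, 1] <- 0L                        # monomorphic: MAF 0 -> removed
  out <- filter_variants(vt, min_qual = 20, min_maf = 0.05,
                         max_missing = 0.20)
  kept <- out$info$snp_id
  expect_false("snp004" %in% kept)  # missing rate 0.20 not < 0.20
  expect_true("snp005" %in% kept)
  expect_false("snp007" %in% kept)  # quality 19.9 < 20
  expect_true("snp008" %in% kept)   # quality 20 retained
  expect_false("snp009" %in% kept)  # MAF below floor
  expect_true(all(c("snp002", "snp003") %in% kept))  # MAF 0.05 inclusive
  rep_ <- attr(out, "filter_report")
  expect_equal(unname(rep_["input"]), 10)
  expect_equal(unname(rep_["retained"]), length(kept))
})

test_that("Weir-Cockerham theta: no divergence, fixation, and the oracle", {
  ## frequency-matched populations at HWE: theta near 0
  set.seed(61)
  p <- runif(200, 0.2, 0.8)
  ga <- sapply(p, function(q) rbinom(40, 2, q))
  gb <- sapply(p, function(q) rbinom(40, 2, q))
  geno <- cbind(t(ga), t(gb))
  storage.mode(geno) <- "integer"
  colnames(geno) <- sprintf("S%03d", 1:80)
  vt <- toy_variant_table(geno)
  scan <- weir_cockerham_fst(vt, sprintf("S%03d", 1:40),
                             sprintf("S%03d", 41:80))
  expect_lt(abs(mean(scan$theta, na.rm = TRUE)), 0.02)

  ## fixed difference -> theta = 1
  fix <- matrix(c(rep(0L, 5), rep(2L, 5)), 1)
  colnames(fix) <- sprintf("S%03d", 1:10)
  vfix <- toy_variant_table(fix)
  expect_equal(weir_cockerham_fst(vfix, sprintf("S%03d", 1:5),
                                  sprintf("S%03d", 6:10))$theta, 1)

  ## toy tables against the allele-copy ANOVA oracle
  set.seed(62)
  for (i in 1:200) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    g <- c(sample(0:2, na, TRUE), sample(0:2, nb, TRUE))
    if (sd(g) == 0) next
    m <- matrix(as.integer(g), 1)
    colnames(m) <- sprintf("S%03d", seq_len(na + nb))
    th <- weir_cockerham_fst(toy_variant_table(m),
                             sprintf("S%03d", 1:na),
                             sprintf("S%03d", na + 1:nb))$theta
    orc <- wc_oracle(g[1:na], g[na + 1:nb])
    if (is.na(orc)) expect_true(is.na(th)) else
      expect_equal(th, orc, tolerance = 1e-10)
  }
})

test_that("missing genotypes are dropped per SNP in theta", {
  g <- matrix(c(0L, 0L, NA, 2L, 2L, 2L,
                0L, 1L, 1L, NA, NA, 2L), 2, byrow = TRUE)
  colnames(g) <- sprintf("S%03d", 1:6)
  vt <- toy_variant_table(g)
  scan <- weir_cockerham_fst(vt, sprintf("S%03d", 1:3),
                             sprintf("S%03d", 4:6))
  expect_equal(scan$theta[1], wc_oracle(c(0L, 0L, NA), c(2L, 2L, 2L)),
               tolerance = 1e-10)
  expect_equal(scan$theta[2], wc_oracle(c(0L, 1L, 1L), c(NA, NA, 2L)),
               tolerance = 1e-10)
})

test_that("kernel smoothing limits: sigma to 0 and to infinity", {
  set.seed(63)
  n <- 50
  geno <- matrix(rbinom(n * 20, 2, 0.4), n, 20)
  colnames(geno) <- sprintf("S%03d", 1:20)
  pos <- sort(sample.int(1e6, n))
  vt <- toy_variant_table(geno, pos = pos)
  scan0 <- weir_cockerham_fst(vt, sprintf("S%03d", 1:10),
                              sprintf("S%03d", 11:20), sigma_bp = 1e-9)
  ok <- !is.na(scan0$theta)
  expect_equal(scan0$smoothed[ok], scan0$theta[ok], tolerance = 1e-6)
  scan_inf <- weir_cockerham_fst(vt, sprintf("S%03d", 1:10),
                                 sprintf("S%03d", 11:20), sigma_bp = 1e12)
  expect_equal(scan_inf$smoothed[ok],
               rep(mean(scan_inf$theta, na.rm = TRUE), sum(ok)),
               tolerance = 1e-6)
})

test_that("outlier enrichment calibrates on the null and saturates", {
  set.seed(64)
  theta <- rnorm(2000, 0.02, 0.01)
  scan <- data.frame(theta = theta)
  ## a set drawn from the background: proportion near alpha
  enr <- fst_outlier_enrichment(scan, sample.int(2000, 400), 1:2000,
                                alpha = 0.05)
  expect_lt(abs(enr$set_proportion - 0.05),
            0.05 + 2.6 * sqrt(0.05 * 0.95 / 400))
  expect_gt(enr$p, 0.001)
  ## all focal theta above the background maximum
  scan2 <- data.frame(theta = c(theta, rep(max(theta) + 1, 200)))
  enr2 <- fst_outlier_enrichment(scan2, 2001:2200, 1:2000)
  expect_equal(enr2$set_proportion, 1)
  expect_lt(enr2$p, 1e-10)
  expect_error(fst_outlier_enrichment(scan, integer(0), 1:2000), "empty")
  expect_error(fst_outlier_enrichment(scan, 1:10, 1:50), ">= 100")
})

test_that("mean FST contrast matches the Welch closed form", {
  set.seed(65)
  a <- rnorm(30, 0.12, 0.05); b <- rnorm(25, 0.06, 0.05)
  scan <- data.frame(theta = c(a, b))
  res <- mean_fst_contrast(scan, 1:30, 31:55)
  orc <- welch_oracle(a, b)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  same <- mean_fst_contrast(scan, 1:30, 1:30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("LD pairs: duplicated SNPs, window boundaries, bin convention", {
  set.seed(66)
  base <- rbinom(20, 2, 0.5)
  geno <- rbind(base, base, rbinom(20, 2, 0.5))
  storage.mode(geno) <- "integer"
  colnames(geno) <- sprintf("S%03d", 1:20)
  rownames(geno) <- sprintf("snp%03d", 1:3)
  ## positions: two duplicates 100 bp apart in one window; third in another
  vt <- toy_variant_table(geno, pos = c(4899L, 4999L, 15001L))
  pairs <- pairwise_ld(vt, window_bp = 10000)
  expect_equal(nrow(pairs), 1)      # cross-window pair not emitted
  expect_equal(pairs$r2, 1)         # identical dosage columns
  expect_equal(pairs$distance, 100)
  expect_equal(pairs$distance_bin, 0)
  ## bin convention: 999 -> bin 0; 1000 -> bin 1
  vt2 <- toy_variant_table(geno[c(1, 2), ], pos = c(1L, 1000L))
  p2 <- pairwise_ld(vt2)
  expect_equal(p2$distance_bin, 0)   # distance 999
  vt3 <- toy_variant_table(geno[c(1, 2), ], pos = c(1L, 1001L))
  expect_equal(pairwise_ld(vt3)$distance_bin, 1)  # distance 1000
})

test_that("r2 matches the hand-computed squared correlation", {
  gA <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L)
  gB <- c(0L, 1L, 1L, 0L, 2L, 2L, 0L, 0L)
  geno <- rbind(gA, gB)
  colnames(geno) <- sprintf("S%03d", 1:8)
  vt <- toy_variant_table(geno, pos = c(100L, 200L))
  pairs <- pairwise_ld(vt)
  expect_equal(pairs$r2, cor(gA, gB)^2, tolerance = 1e-12)
  ## invariance to allele-coding swap at one SNP
  vt_swap <- toy_variant_table(rbind(gA, 2L - gB),
                               pos = c(100L, 200L))
  expect_equal(pairwise_ld(vt_swap)$r2, pairs$r2, tolerance = 1e-12)
})

test_that("monomorphic-within-complete-pairs SNPs are skipped with count", {
  geno <- rbind(c(0L, 0L, 0L, NA), c(0L, 1L, 2L, 1L))
  colnames(geno) <- sprintf("S%03d", 1:4)
  vt <- toy_variant_table(geno, pos = c(10L, 20L))
  pairs <- pairwise_ld(vt)
  expect_equal(nrow(pairs), 0)
  expect_equal(attr(pairs, "n_skipped"), 1L)
})

test_that("LD set comparison: relabelled identical tables give p near 1", {
  set.seed(67)
  n <- 60
  pairs <- data.frame(
    window_id = "w", snp_i = "a", snp_j = "b", pos_i = 1L, pos_j = 2L,
    distance = rep(500L, 2 * n), r2 = rep(runif(n), 2),
    distance_bin = 0L,
    gene_id = c(rep(sprintf("gf%02d", 1:15), each = 4),
                rep(sprintf("gb%02d", 1:15), each = 4)),
    set = rep(c("maladaptive", "background"), each = n),
    stringsAsFactors = FALSE)
  cmp <- ld_set_comparison(pairs, n_perm = 200, seed = 3)
  expect_equal(cmp$observed_diff, 0, tolerance = 1e-12)
  expect_gt(cmp$empirical_p, 0.95)
  expect_error(ld_set_comparison(pairs, n_perm = 0), "n_perm")
})

test_that("planted candidate LD elevation is detected", {
  hits <- 0
  for (i in 1:10) {
    cfg <- sim_config(n_genes = 150, n_candidates = 40, n_snps = 1200,
                      wild_n = list(M = c(forest = 25, urban = 25)),
                      cg_n = NULL, missing_rate = 0,
                      ld_rho = c(background = 0.3, candidate = 0.95),
                      planted_fst = c(background = 0.02, adaptive = 0.02,
                                      maladaptive = 0.02),
                      seed = 300 + i)
    ds <- simulate_expression(cfg)
    vt <- simulate_variants(cfg, ds$truth, ds$samples)
    pairs <- pairwise_ld(vt)
    cmp <- ld_set_comparison(pairs, n_perm = 200, seed = i)
    if (cmp$empirical_p <= 0.05 && cmp$observed_diff > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("HWE chi-squared matches the worked example and flags deviants", {
  res <- plastisel:::hwe_chisq(25, 50, 25)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  res2 <- plastisel:::hwe_chisq(30, 40, 30)
  expect_equal(res2$chi2, 4.0, tolerance = 1e-12)
  expect_equal(res2$p, pchisq(4, 1, lower.tail = FALSE))
  ## low expected count flagged but computed
  res3 <- plastisel:::hwe_chisq(1, 2, 6)
  expect_true(res3$low_count)
  expect_false(is.na(res3$chi2))
})

test_that("hwe_scan compares candidate and background deviant rates", {
  set.seed(68)
  n <- 400
  ## candidates: strong heterozygote deficit; background: HWE draws
  p <- runif(n, 0.3, 0.7)
  bg <- t(sapply(p[1:200], function(q) rbinom(30, 2, q)))
  cand <- t(sapply(p[201:400], function(q) {
    2L * rbinom(30, 1, q)  # no hets at all
  }))
  geno <- rbind(bg, cand)
  storage.mode(geno) <- "integer"
  colnames(geno) <- sprintf("S%03d", 1:30)
  rownames(geno) <- sprintf("snp%03d", 1:n)
  vt <- toy_variant_table(geno,
                          set = rep(c("background", "maladaptive"),
                                    each = 200))
  scan <- hwe_scan(vt, pops = list(all = sprintf("S%03d", 1:30)))
  cmp <- scan$comparison$all
  expect_gt(cmp$candidate_proportion, cmp$background_proportion)
  expect_lt(cmp$p, 1e-10)
  ## identical deviant proportions -> p ~ 1
  vt2 <- toy_variant_table(rbind(bg, bg),
                           set = rep(c("background", "maladaptive"),
                                     each = 200))
  cmp2 <- hwe_scan(vt2, pops = list(all = sprintf("S%03d", 1:30)))
  expect_gt(cmp2$comparison$all$p, 0.99)
})

test_that("class enrichment matches the continuity-corrected closed form", {
  fclass <- c(rep("nonsynonymous", 40), rep("noncoding", 60),
              rep("nonsynonymous", 20), rep("noncoding", 80))
  geno <- matrix(rep(c(0L, 1L, 2L, 1L), 50), 200, 4)
  colnames(geno) <- sprintf("S%03d", 1:4)
  vt <- toy_variant_table(geno, fclass = fclass)
  res <- annotation_class_enrichment(vt, 1:100, 101:200, "nonsynonymous")
  orc <- prop_chisq_oracle(40, 100, 20, 100)
  expect_equal(res$chisq, orc$chi2, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_equal(res$focal_proportion, 0.4)
  ci <- res$focal_ci
  expect_true(ci["lower"] < 0.4 && 0.4 < ci["upper"])
  ## equal proportions -> chi^2 ~ 0, p ~ 1
  res2 <- annotation_class_enrichment(vt, 1:100, 1:100, "noncoding")
  expect_lt(res2$chisq, 1e-10)
  expect_gt(res2$p, 0.99)
})

test_that("planted noncoding enrichment is recovered from the generator", {
  hits <- 0
  for (i in 1:10) {
    cfg <- sim_config(n_genes = 200, n_candidates = 60, n_snps = 2500,
                      wild_n = list(M = c(forest = 10, urban = 10)),
                      cg_n = NULL, forest_malad_frac = 1, seed = 400 + i)
    ds <- simulate_expression(cfg)
    vt <- simulate_variants(cfg, ds$truth, ds$samples)
    malad <- which(vt$info$set == "maladaptive")
    bg <- which(vt$info$set == "background")
    if (length(malad) < 300) next
    res <- annotation_class_enrichment(vt, malad, bg, "noncoding")
    if (res$p < 0.001 &&
          res$focal_proportion > res$background_proportion) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
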