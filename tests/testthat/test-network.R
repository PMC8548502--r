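test_that("adjacency endpoints: |cor| 1 -> 1, cor 0 -> 0", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(-1, -2, -3, -4))
  colnames(x) <- paste0("s", 1:4)
  net <- build_adjacency_tom(x + matrix(rnorm(12, sd = 1e-9), 3), beta = 6)
  expect_equal(net$adjacency["g1", "g2"], 1, tolerance = 1e-6)
  expect_equal(net$adjacency["g1", "g3"], 1, tolerance = 1e-6)  # |cor| = 1
  y <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  colnames(y) <- paste0("s", 1:4)
  net0 <- build_adjacency_tom(y, beta = 6)
  expect_equal(net0$adjacency["g1", "g2"], 0)
})

test_that("TOM matches the hand-evaluated 3-gene formula", {
  a <- matrix(c(1, .5, .2,
                .5, 1, .8,
                .2, .8, 1), 3, 3, byrow = TRUE)
  tom <- plastisel:::tom_from_adjacency(a)
  ## hand evaluation: l_12 = a13 * a32 = .2 * .8 = .16;
  ## k = (.7, 1.3, 1.0); tom_12 = (.16 + .5)/(min(.7, 1.3) + 1 - .5)
  expect_equal(tom[1, 2], (.16 + .5) / (.7 + 1 - .5), tolerance = 1e-12)
  expect_equal(tom[1, 3], (.5 * .8 + .2) / (.7 + 1 - .2), tolerance = 1e-12)
  expect_equal(tom[2, 3], (.5 * .2 + .8) / (1.0 + 1 - .8), tolerance = 1e-12)
  expect_equal(tom, t(tom))
  expect_equal(diag(tom), rep(1, 3))
})

test_that("TOM equals the triple-loop oracle on random instances", {
  set.seed(7)
  for (n in c(5, 12, 20)) {
    x <- matrix(rnorm(n * 15), n, 15)
    a <- abs(cor(t(x)))^4
    diag(a) <- 1
    expect_equal(unname(plastisel:::tom_from_adjacency(a)), tom_oracle(a),
                 tolerance = 1e-12)
  }
})

test_that("module detection recovers planted blocks", {
  pb <- planted_block_matrix(n_per_block = 50, within_cor = 0.9, seed = 4)
  net <- build_adjacency_tom(pb$x, beta = 6)
  labels <- detect_modules(net$tom, min_module_size = 30)
  expect_equal(length(unique(labels[labels > 0])), 2)
  ## agreement up to label permutation
  tab <- table(labels, pb$labels)
  expect_gte(sum(apply(tab, 2, max)) / length(labels), 0.98)
})

test_that("small branches fall to label 0; oversized threshold unassigns all", {
  pb <- planted_block_matrix(n_per_block = 10, within_cor = 0.9, seed = 5)
  net <- build_adjacency_tom(pb$x, beta = 6)
  labels <- detect_modules(net$tom, min_module_size = 30)
  expect_true(all(labels == 0))
  set.seed(6)
  noise <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
  netn <- build_adjacency_tom(noise, beta = 6)
  expect_true(all(detect_modules(netn$tom, min_module_size = 41) == 0))
})

test_that("eigengene of identical genes is their standardized profile", {
  set.seed(8)
  prof <- rnorm(20)
  x <- matrix(rep(prof, each = 5), 5, 20, byrow = FALSE)
  x <- t(replicate(5, prof)) + matrix(rnorm(100, sd = 1e-8), 5)
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:20)
  labels <- setNames(rep(1L, 5), rownames(x))
  res <- compute_eigengenes_and_merge(x, labels)
  e <- res$eigengenes[1, ]
  z <- scale(prof)[, 1]; z <- z / sqrt(sum(z^2))
  expect_gt(abs(cor(e, z)), 0.999999)
  expect_gt(cor(e, prof), 0)   # sign-oriented along the profile
  expect_equal(sum(e^2), 1, tolerance = 1e-8)
})

test_that("duplicate modules merge; weakly correlated modules do not", {
  set.seed(9)
  f1 <- rnorm(40)
  dup <- rbind(t(replicate(10, f1 + rnorm(40, sd = .1))),
               t(replicate(10, f1 + rnorm(40, sd = .1))))
  rownames(dup) <- paste0("g", 1:20); colnames(dup) <- paste0("s", 1:40)
  labels <- setNames(rep(1:2, each = 10), rownames(dup))
  merged <- compute_eigengenes_and_merge(dup, labels, merge_r2 = 0.75)
  expect_equal(length(unique(merged$labels)), 1)
  expect_equal(length(merged$merge_history), 1)

  ## two module factors correlated at r = 0.5 (r^2 = 0.25 < 0.75): kept
  f2 <- 0.5 * f1 + sqrt(1 - 0.25) * rnorm(40)
  sep <- rbind(t(replicate(10, f1 + rnorm(40, sd = .05))),
               t(replicate(10, f2 + rnorm(40, sd = .05))))
  rownames(sep) <- paste0("g", 1:20); colnames(sep) <- paste0("s", 1:40)
  merged2 <- compute_eigengenes_and_merge(sep, labels, merge_r2 = 0.75)
  expect_equal(length(unique(merged2$labels)), 2)
})

test_that("gene significance is the signed Pearson correlation", {
  ct <- c(36, 38, 39, 40, 42)
  x <- rbind(match = ct, anti = -ct,
             hand = c(2, 1, 4, 3, 6))
  colnames(x) <- paste0("s", 1:5)
  x <- x + matrix(rnorm(15, sd = 1e-9), 3)  # avoid exactly +/-1 edge
  gs <- gene_significance(x, ct)
  expect_equal(gs$gs[1], 1, tolerance = 1e-6)
  expect_equal(gs$gs[2], -1, tolerance = 1e-6)
  expect_equal(gs$gs[3], cor(c(2, 1, 4, 3, 6), ct), tolerance = 1e-6)
  expect_lt(gs$p[1], 1e-6)
  ## closed-form Pearson for x=(1..5), y=(2,1,4,3,6)
  r <- cor(1:5, c(2, 1, 4, 3, 6))
  gs2 <- gene_significance(rbind(g = c(2, 1, 4, 3, 6)) +
                             rbind(rnorm(5, sd = 1e-10)), 1:5)
  expect_equal(gs2$gs, r, tolerance = 1e-6)
})

test_that("GS is invariant to affine rescaling of a gene", {
  set.seed(10)
  x <- matrix(rnorm(50), 5, 10)
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:10)
  ct <- rnorm(10, 39, 1.5)
  g1 <- gene_significance(x, ct)
  x[2, ] <- 7 * x[2, ] + 3
  g2 <- gene_significance(x, ct)
  expect_equal(g1$gs, g2$gs)
})

test_that("within-module BH selection follows the worked example", {
  p <- c(rep(0.001, 10), rep(0.9, 90))
  gs <- data.frame(gene_id = paste0("g", 1:100),
                   gs = rep(0.5, 100), p = p)
  labels <- setNames(rep(1L, 100), gs$gene_id)
  sel <- select_candidates(gs, labels, alpha = 0.05)
  expect_equal(sum(sel$candidate), 10)
  expect_equal(sel$q[1], 0.001 * 100 / 10)   # BH arithmetic: q = 0.01
  expect_true(all(which(sel$candidate) <= 10))
  ## all p = 1 -> nothing selected
  gs1 <- transform(gs, p = 1)
  expect_equal(sum(select_candidates(gs1, labels)$candidate), 0)
  ## q monotone nondecreasing in p within a module
  set.seed(11)
  gs2 <- data.frame(gene_id = paste0("g", 1:50), gs = 0.1,
                    p = runif(50))
  sel2 <- select_candidates(gs2, setNames(rep(1L, 50), gs2$gene_id))
  ord <- order(sel2$p)
  expect_true(all(diff(sel2$q[ord]) >= -1e-12))
})

test_that("BH runs separately within modules", {
  ## BH arithmetic within each module vs pooled across all genes
  gs <- data.frame(gene_id = paste0("g", 1:4),
                   gs = 0.5, p = c(0.01, 0.8, 0.02, 0.9))
  labels <- setNames(c(1L, 1L, 2L, 2L), gs$gene_id)
  sel <- select_candidates(gs, labels)
  expect_equal(sel$q, c(0.02, 0.8, 0.04, 0.9))
  labels2 <- setNames(c(1L, 1L, 1L, 1L), gs$gene_id)
  sel2 <- select_candidates(gs, labels2)
  expect_equal(sel2$q, c(0.04, 0.9, 0.04, 0.9))
  expect_false(isTRUE(all.equal(sel$q, sel2$q)))
})

test_that("soft power selection: degenerate tie returns smallest power", {
  set.seed(12)
  f <- rnorm(30)
  x <- rbind(t(replicate(25, f + rnorm(30, sd = 1e-6))),
             t(replicate(25, -f + rnorm(30, sd = 1e-6))))
  rownames(x) <- paste0("g", 1:50); colnames(x) <- paste0("s", 1:30)
  ## all |cor| ~ 1: fit is identical (degenerate) across powers
  beta <- suppressWarnings(choose_soft_power(x, candidate_powers = 1:6))
  fits <- attr(beta, "fits")
  expect_equal(as.integer(beta),
               as.integer(names(fits)[fits >= max(fits) - 1e-9][1]))
  ## determinism on fixed input
  beta2 <- suppressWarnings(choose_soft_power(x, candidate_powers = 1:6))
  expect_equal(as.integer(beta), as.integer(beta2))
})

test_that("selected power matches the exhaustive fit scan", {
  set.seed(13)
  n <- 120
  ## heavy-tailed connectivity: a few hub factors with many followers
  hubs <- matrix(rnorm(4 * 40), 4, 40)
  x <- matrix(rnorm(n * 40, sd = 1), n, 40)
  sizes <- c(60, 30, 20, 10)
  idx <- rep(1:4, sizes)
  x <- x * 0.6 + hubs[idx, ]
  rownames(x) <- paste0("g", 1:n); colnames(x) <- paste0("s", 1:40)
  beta <- suppressWarnings(choose_soft_power(x, candidate_powers = 1:10,
                                             target_fit = 0.8))
  fits <- attr(beta, "fits")
  ok <- which(fits >= 0.8)
  expected <- if (length(ok)) as.integer(names(fits)[ok[1]]) else
    as.integer(names(which.max(fits)))
  expect_equal(as.integer(beta), expected)
})

test_that("constant-expression genes are refused", {
  x <- rbind(g1 = rep(1, 10), g2 = rnorm(10))
  colnames(x) <- paste0("s", 1:10)
  expect_error(build_adjacency_tom(x, beta = 6), "g1")
  expect_error(choose_soft_power(rbind(x, g3 = rnorm(10))), "constant")
})

test_that("cross-subset GS validation behaves on constructed cases", {
  gs_full <- data.frame(gene_id = paste0("g", 1:20),
                        gs = rep(c(0.5, -0.5), 10), p = 0.001,
                        regulator_class = rep(c("positive", "negative"), 10))
  a <- seq(-0.9, 0.9, length.out = 20)
  gs_a <- data.frame(gene_id = gs_full$gene_id, gs = a)
  ## identical vectors
  v1 <- suppressWarnings(
    validate_gs_subsets(gs_full, gs_a, gs_a, gs_full$gene_id))
  expect_equal(v1$r_squared, 1)
  expect_equal(v1$spearman_rho, 1)
  expect_equal(v1$per_class$positive$paired_t, 0, tolerance = 1e-8)
  ## affine positive transform: R^2 = 1, rho = 1, paired t nonzero
  gs_b <- transform(gs_a, gs = 2 * gs + 1)
  v2 <- suppressWarnings(
    validate_gs_subsets(gs_full, gs_a, gs_b, gs_full$gene_id))
  expect_equal(v2$r_squared, 1)
  expect_equal(v2$spearman_rho, 1)
  expect_gt(abs(v2$per_class$positive$paired_t), 2)
  expect_error(validate_gs_subsets(gs_full, gs_a, gs_b, paste0("g", 1:2)),
               "fewer than 3")
})

test_that("wild/common-garden split shares planted GS signal", {
  ## the subset-validation R^2 should be significantly positive when both
  ## subsets inherit the same planted coupling
  hits <- 0
  for (rep_i in 1:5) {
    cfg <- sim_config(n_genes = 150, n_candidates = 60, n_snps = 0,
                      wild_n = list(M = c(forest = 25, urban = 25)),
                      cg_n = list(forest = c(day25 = 8, day32 = 8),
                                  urban = c(day25 = 8, day32 = 8)),
                      gs_coupling = 0.8, seed = 100 + rep_i)
    ds <- simulate_expression(cfg)
    norm <- normalize_counts(ds$counts)
    wild <- ds$samples$rearing == "wild"
    gs_full <- gene_significance(norm, ds$samples$ctmax_C)
    gs_full$regulator_class <- ifelse(gs_full$gs > 0, "positive", "negative")
    gs_w <- gene_significance(norm[, wild], ds$samples$ctmax_C[wild])
    gs_c <- gene_significance(norm[, !wild], ds$samples$ctmax_C[!wild])
    v <- validate_gs_subsets(gs_full, gs_w, gs_c,
                             ds$truth$candidate_gene_ids)
    if (v$lm_p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
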