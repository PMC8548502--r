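#' Pipeline configuration
#'
#' Assembles simulator settings (or input file paths) and stage parameters
#' into the single configuration consumed by [run_pipeline()]. Every stage
#' default follows the analysis conventions of the study design: candidate
#' FDR 0.05 within modules, eigengene merge at r^2 = 0.75, 1000-permutation
#' randomization null, SNP filters quality >= 20 / MAF >= 5% / missing <
#' 20%, 10 kb LD windows with 1 kb bins, and outlier alpha 0.05.
#'
#' @param sim a [sim_config()] object, or NULL when reading inputs from
#'   `paths`.
#' @param paths named list of input files (`counts`, `metadata`, `vcf`) used
#'   when `sim` is NULL; the directory layout of [write_dataset()].
#' @param beta soft-threshold power; NULL selects it via
#'   [choose_soft_power()].
#' @param min_module_size,cut_height module-detection parameters.
#' @param merge_r2 eigengene merge threshold.
#' @param gs_alpha candidate FDR level.
#' @param epsilon indeterminate band for plasticity calls.
#' @param n_perm permutations for the randomization null and LD contrast.
#' @param min_qual,min_maf,max_missing SNP filters.
#' @param sigma_bp FST smoothing kernel sd (bp); NULL disables. The 5 Mb
#'   convention of genome-scale scans is a deliberate flag; on the compact
#'   synthetic scaffold a 50 kb kernel is the exercisable default.
#' @param window_bp,bin_bp LD window and distance-bin sizes.
#' @param outlier_alpha empirical tail for FST outliers.
#' @param seed master seed for every stochastic stage.
#' @param out_dir directory for stage outputs, or NULL to skip writing.
#' @return list of class `"plastisel_config"`.
#' @export
plastisel_config <- function(sim = sim_config(), paths = NULL,
                             beta = 6, min_module_size = 30,
                             cut_height = 0.99, merge_r2 = 0.75,
                             gs_alpha = 0.05, epsilon = 0,
                             n_perm = 1000,
                             min_qual = 20, min_maf = 0.05,
                             max_missing = 0.20,
                             sigma_bp = 50000,
                             window_bp = 10000, bin_bp = 1000,
                             outlier_alpha = 0.05,
                             seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  assert_that(!is.null(cfg$sim) || !is.null(cfg$paths),
              "either a simulate block or input paths must be given",
              config = TRUE)
  for (a in c("gs_alpha", "outlier_alpha")) {
    assert_that(cfg[[a]] > 0 && cfg[[a]] < 1, a, " must lie in (0, 1)",
                config = TRUE)
  }
  class(cfg) <- "plastisel_config"
  cfg
}

#' Run the full inference pipeline
#'
#' Executes, in order: data simulation (or loading), library-size
#' normalization, co-expression network construction with module detection
#' and eigengene merging, gene-significance screening with within-module FDR
#' candidate selection, per-lineage adaptive/maladaptive plasticity
#' classification with proportion and magnitude tests, the
#' ancestral-plasticity vs evolved-divergence Spearman correlation with its
#' matrix-randomization null, and the population-genomic battery (SNP
#' filtering, per-municipality Weir-Cockerham FST with outlier enrichment
#' and mean contrasts, LD decay comparison, Hardy-Weinberg scans, and
#' functional-class enrichment). Reruns with the same configuration and seed
#' reproduce the report.
#'
#' @param config a [plastisel_config()] object.
#' @param quiet suppress per-stage progress messages.
#' @return list of class `"plastisel_report"`; stage objects are kept in
#'   `$stages`, headline statistics in the top level.
#' @export
run_pipeline <- function(config = plastisel_config(), quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[plastisel] ", ...)

  ## stage 1: data -------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    say("simulate: ", sim$n_genes, " genes, ", sim$n_snps, " SNPs, seed ",
        config$seed)
    ds <- simulate_expression(sim)
    variants <- simulate_variants(sim, ds$truth, ds$samples)
    truth <- ds$truth
  } else {
    say("load inputs")
    ds <- read_dataset(config$paths$dir %||% dirname(config$paths$counts))
    variants <- ds$variants
    truth <- ds$truth
  }
  samples <- validate_samples(ds$samples)
  counts <- drop_zero_genes(ds$counts)

  ## stage 2: normalize --------------------------------------------------
  norm <- normalize_counts(counts)

  ## stage 3: network ----------------------------------------------------
  beta <- config$beta %||% choose_soft_power(norm)
  say("network: beta = ", beta)
  net <- build_adjacency_tom(norm, beta)
  labels0 <- detect_modules(net$tom, config$min_module_size,
                            config$cut_height)
  merged <- if (any(labels0 > 0)) {
    compute_eigengenes_and_merge(norm, labels0, config$merge_r2)
  } else {
    ## no branch reached the minimum module size: everything unassigned
    list(labels = labels0, eigengenes = NULL, merge_history = list())
  }
  say("modules: ", length(unique(merged$labels[merged$labels > 0])),
      " (unassigned: ", sum(merged$labels == 0), " genes)")

  ## stage 4: gene significance ------------------------------------------
  gs <- gene_significance(norm, samples$ctmax_C)
  gs <- select_candidates(gs, merged$labels, config$gs_alpha)
  candidate_ids <- gs$gene_id[gs$candidate]
  say("candidates: ", length(candidate_ids), " at q < ", config$gs_alpha)

  ## stage 5: plasticity classification ----------------------------------
  lfc_forest <- group_lfc(norm, samples, cg_group("forest", "day25"),
                          cg_group("forest", "day32"))
  lfc_urban <- group_lfc(norm, samples, cg_group("urban", "day25"),
                         cg_group("urban", "day32"))
  calls <- classify_cohort(gs, lfc_forest, lfc_urban, config$epsilon)
  prop_tests <- plasticity_proportion_tests(calls)
  magnitude <- plasticity_magnitude_test(lfc_forest, lfc_urban,
                                         candidate_ids)

  ## stage 6: plasticity vs divergence -----------------------------------
  lfcs <- plasticity_divergence_lfcs(norm, samples, candidate_ids)
  sp <- spearman_correlation(lfcs$ancestral_lfc, lfcs$evolved_lfc)
  cg_idx <- samples$rearing == "common_garden"
  null <- randomization_null_test(norm[candidate_ids, cg_idx, drop = FALSE],
                                  samples[cg_idx, ], sp$rho,
                                  n_perm = config$n_perm,
                                  seed = config$seed)
  say(sprintf("rho = %.3f, empirical p = %.4f", sp$rho, null$empirical_p))

  ## stage 7: population genomics ----------------------------------------
  popgen <- NULL
  if (!is.null(variants)) {
    variants <- annotate_sets_from_calls(variants, gs, calls)
    filtered <- filter_variants(variants, config$min_qual, config$min_maf,
                                config$max_missing)
    say("variants: ", nrow(filtered$info), " of ", nrow(variants$info),
        " SNPs pass filters")
    popgen <- popgen_battery(filtered, samples, config)
  }

  report <- structure(list(
    n_genes = nrow(counts), n_samples = nrow(samples),
    beta = as.integer(beta),
    n_modules = length(unique(merged$labels[merged$labels > 0])),
    n_candidates = length(candidate_ids),
    maladaptive_proportion = attr(calls, "summary")$maladaptive_proportion,
    plasticity_tests = prop_tests,
    magnitude_test = magnitude,
    rho = sp$rho, rho_p = sp$p,
    null_limits = null$limits, empirical_p = null$empirical_p,
    popgen = popgen,
    stages = list(samples = samples, norm = norm, labels = merged$labels,
                  eigengenes = merged$eigengenes, gs = gs, calls = calls,
                  lfc_forest = lfc_forest, lfc_urban = lfc_urban,
                  divergence_lfcs = lfcs, null = null,
                  variants = if (!is.null(variants)) variants else NULL,
                  truth = truth),
    seed = config$seed,
    config_hash = fnv1a_hash(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "plastisel_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

## Attach estimated plasticity-set labels to SNPs: a SNP inherits the forest
## call of its host gene (adaptive / maladaptive), candidate genes without a
## determinate forest call are candidate_unclassified, everything else is
## background.
annotate_sets_from_calls <- function(variants, gs, calls) {
  forest <- calls[calls$lineage == "forest", ]
  call_of <- stats::setNames(forest$call, forest$gene_id)
  gene <- variants$info$gene_id
  set <- rep("background", length(gene))
  is_cand <- gene %in% gs$gene_id[gs$candidate]
  cl <- call_of[gene[is_cand]]
  set[is_cand] <- ifelse(is.na(cl) | cl == "indeterminate",
                         "candidate_unclassified", cl)
  variants$info$set <- set
  variants
}

popgen_battery <- function(filtered, samples, config) {
  info <- filtered$info
  idx_adapt <- which(info$set == "adaptive")
  idx_malad <- which(info$set == "maladaptive")
  idx_bg <- which(info$set == "background")

  per_mun <- list()
  for (mun in unique(samples$municipality)) {
    ids_f <- samples$sample_id[samples$municipality == mun &
                                 samples$habitat == "forest"]
    ids_u <- samples$sample_id[samples$municipality == mun &
                                 samples$habitat == "urban"]
    if (length(ids_f) < 2 || length(ids_u) < 2) next
    scan <- weir_cockerham_fst(filtered, ids_f, ids_u,
                               sigma_bp = config$sigma_bp)
    enr <- lapply(list(adaptive = idx_adapt, maladaptive = idx_malad),
                  function(idx) {
                    if (length(idx) == 0) return(NULL)
                    fst_outlier_enrichment(scan, idx, idx_bg,
                                           config$outlier_alpha)
                  })
    contrast <- if (length(idx_malad) >= 2 && length(idx_adapt) >= 2) {
      mean_fst_contrast(scan, idx_malad, idx_adapt)
    }
    per_mun[[mun]] <- list(
      scan = scan,
      mean_theta = c(
        background = mean(scan$theta[idx_bg], na.rm = TRUE),
        adaptive = mean(scan$theta[idx_adapt], na.rm = TRUE),
        maladaptive = mean(scan$theta[idx_malad], na.rm = TRUE)),
      outlier_enrichment = enr,
      mean_contrast = contrast)
  }

  pairs <- pairwise_ld(filtered, config$window_bp, config$bin_bp)
  ld_cmp <- tryCatch(
    ld_set_comparison(pairs, n_perm = config$n_perm, seed = config$seed),
    error = function(e) NULL)

  pops <- split(samples$sample_id, samples$municipality)
  hwe <- hwe_scan(filtered, pops)

  enrich <- list(
    adaptive_nonsynonymous = if (length(idx_adapt))
      annotation_class_enrichment(filtered, idx_adapt, idx_bg,
                                  "nonsynonymous"),
    maladaptive_nonsynonymous = if (length(idx_malad))
      annotation_class_enrichment(filtered, idx_malad, idx_bg,
                                  "nonsynonymous"),
    adaptive_noncoding = if (length(idx_adapt))
      annotation_class_enrichment(filtered, idx_adapt, idx_bg, "noncoding"),
    maladaptive_noncoding = if (length(idx_malad))
      annotation_class_enrichment(filtered, idx_malad, idx_bg, "noncoding"))

  list(filter_report = attr(filtered, "filter_report"),
       per_municipality = per_mun,
       ld = ld_cmp,
       hwe_comparison = if (!is.null(hwe$comparison)) hwe$comparison,
       class_enrichment = enrich)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$stages
  utils::write.table(s$gs, file.path(out_dir, "gene_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(s$calls),
                     file.path(out_dir, "plasticity_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_json <- report[setdiff(names(report), "stages")]
  summary_json$popgen <- lapply(summary_json$popgen, function(x) x)
  if (!is.null(summary_json$popgen$per_municipality)) {
    summary_json$popgen$per_municipality <-
      lapply(summary_json$popgen$per_municipality,
             function(m) m[setdiff(names(m), "scan")])
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.plastisel_report <- function(x, ...) {
  cat("plastisel pipeline report (seed ", x$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  cat(sprintf("  %d genes x %d samples; %d modules (beta = %d)\n",
              x$n_genes, x$n_samples, x$n_modules, x$beta))
  cat(sprintf("  candidates: %d\n", x$n_candidates))
  mp <- x$maladaptive_proportion
  cat(sprintf("  maladaptive plasticity: forest %.1f%%, urban %.1f%%\n",
              100 * mp["forest"], 100 * mp["urban"]))
  cat(sprintf(
    "  ancestral vs evolved rho = %.3f (null 95%% [%.3f, %.3f], empirical p = %.4f)\n",
    x$rho, x$null_limits[1], x$null_limits[2], x$empirical_p))
  if (!is.null(x$popgen)) {
    for (mun in names(x$popgen$per_municipality)) {
      m <- x$popgen$per_municipality[[mun]]
      cat(sprintf(
        "  %s: mean FST bg %.3f / adaptive %.3f / maladaptive %.3f\n",
        mun, m$mean_theta["background"], m$mean_theta["adaptive"],
        m$mean_theta["maladaptive"]))
    }
    if (!is.null(x$popgen$ld)) {
      cat(sprintf("  LD contrast: diff = %.4f, empirical p = %.4f\n",
                  x$popgen$ld$observed_diff, x$popgen$ld$empirical_p))
    }
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
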