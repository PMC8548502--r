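#' Simulate the expression study: samples, counts, planted truth
#'
#' Draws sample metadata (wild-caught animals across municipality pairs plus a
#' common-garden colony), a CT_MAX phenotype per animal, and a gene-by-sample
#' negative-binomial count matrix with planted structure:
#' \itemize{
#'   \item latent co-expression modules shared by all genes;
#'   \item candidate genes whose log-mean expression is coupled to the
#'     animal's standardized CT_MAX with sign equal to the planted regulator
#'     sign;
#'   \item a 25-to-32 degree reaction norm for candidate genes whose forest
#'     direction predominantly opposes the regulator sign (maladaptive
#'     ancestral plasticity) and whose urban direction is attenuated and
#'     possibly reversed.
#' }
#' The night (15 degree) and 25-degree day treatments share the baseline;
#' the reaction norm displaces the 32-degree treatment only.
#'
#' @param cfg a [sim_config()] object.
#' @return list with elements `samples` (data.frame: sample_id, municipality,
#'   habitat, rearing, treatment, ctmax_C), `counts` (integer matrix, genes x
#'   samples), and `truth` (planted ground truth: candidate ids, regulator
#'   signs, per-lineage norm directions, module assignment, seed).
#' @export
simulate_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  samples <- build_sample_metadata(cfg)
  n_samples <- nrow(samples)
  n_genes <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n_genes))

  ## planted truth -------------------------------------------------------
  cand_idx <- sort(sample.int(n_genes, cfg$n_candidates))
  regulator_sign <- sample(c(-1, 1), cfg$n_candidates, replace = TRUE)
  malad <- stats::runif(cfg$n_candidates) < cfg$forest_malad_frac
  forest_dir <- ifelse(malad, -regulator_sign, regulator_sign)
  reversed <- stats::runif(cfg$n_candidates) < cfg$urban_reversal_prob
  urban_dir <- ifelse(reversed, -forest_dir, forest_dir)
  module <- sample.int(cfg$n_modules, n_genes, replace = TRUE)

  truth <- list(
    candidate_gene_ids = gene_ids[cand_idx],
    candidate_idx = cand_idx,
    regulator_sign = stats::setNames(regulator_sign, gene_ids[cand_idx]),
    forest_norm_direction = stats::setNames(forest_dir, gene_ids[cand_idx]),
    urban_norm_direction = stats::setNames(urban_dir, gene_ids[cand_idx]),
    module = stats::setNames(module, gene_ids),
    urban_attenuation = cfg$urban_attenuation,
    urban_reversal_prob = cfg$urban_reversal_prob,
    forest_malad_frac = cfg$forest_malad_frac,
    planted_fst = cfg$planted_fst,
    class_prop = cfg$class_prop,
    seed = cfg$seed)

  ## log2-scale expression offsets ---------------------------------------
  z <- as.numeric(scale(samples$ctmax_C))
  eta <- matrix(stats::rnorm(n_genes * n_samples, sd = cfg$noise_sd),
                n_genes, n_samples)

  fac <- matrix(stats::rnorm(cfg$n_modules * n_samples), cfg$n_modules,
                n_samples)
  loading <- cfg$module_sd * stats::runif(n_genes, 0.7, 1) *
    sample(c(-1, 1), n_genes, replace = TRUE)
  eta <- eta + loading * fac[module, , drop = FALSE]

  if (cfg$n_candidates > 0) {
    eta[cand_idx, ] <- eta[cand_idx, ] +
      cfg$gs_coupling * outer(regulator_sign, z)
    hot <- samples$treatment == "day32"
    if (any(hot)) {
      dir_by_hab <- cbind(forest = forest_dir, urban = urban_dir)
      mag <- c(forest = cfg$lfc_mag,
               urban = cfg$lfc_mag * cfg$urban_attenuation)
      hab_hot <- samples$habitat[hot]
      shift <- dir_by_hab[, hab_hot, drop = FALSE] *
        rep(mag[hab_hot], each = cfg$n_candidates)
      eta[cand_idx, hot] <- eta[cand_idx, hot] + shift
    }
  }

  ## negative-binomial counts --------------------------------------------
  base2 <- pmax(stats::rnorm(n_genes, cfg$base_log2_mean, cfg$base_log2_sd), 0)
  phi <- stats::rlnorm(n_genes, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  sfac <- stats::rlnorm(n_samples, 0, cfg$libsize_sdlog)
  mu <- 2^(base2 + eta) * rep(sfac, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                  size = rep(1 / phi, n_samples)),
                   n_genes, n_samples,
                   dimnames = list(gene_ids, samples$sample_id))

  list(samples = samples, counts = counts, truth = truth)
}

build_sample_metadata <- function(cfg) {
  rows <- list()
  for (mun in names(cfg$wild_n)) {
    for (hab in c("forest", "urban")) {
      n <- cfg$wild_n[[mun]][[hab]]
      treatment <- sample(rep_len(c("night15", "day25", "day32"), n))
      rows[[length(rows) + 1L]] <- data.frame(
        municipality = mun, habitat = hab, rearing = "wild",
        treatment = treatment, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cfg$cg_n)) {
    for (hab in names(cfg$cg_n)) {
      for (trt in names(cfg$cg_n[[hab]])) {
        n <- cfg$cg_n[[hab]][[trt]]
        rows[[length(rows) + 1L]] <- data.frame(
          municipality = cfg$cg_municipality, habitat = hab,
          rearing = "common_garden", treatment = rep(trt, n),
          stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, rows)
  samples <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(samples))),
                   samples, stringsAsFactors = FALSE)
  sd_i <- ifelse(samples$rearing == "common_garden",
                 cfg$ctmax_sd_cg %||% cfg$ctmax_sd, cfg$ctmax_sd)
  samples$ctmax_C <- round(rtruncnorm(nrow(samples), cfg$ctmax_mean,
                                      sd_i, cfg$ctmax_range[1],
                                      cfg$ctmax_range[2]), 2)
  rownames(samples) <- NULL
  samples
}

#' Validate a sample-metadata table
#'
#' Checks the invariants the pipeline relies on: unique sample ids, known
#' factor levels, common-garden animals restricted to the day treatments,
#' and CT_MAX inside the physiologically plausible 30-50 degree band.
#'
#' @param samples sample metadata data.frame.
#' @return the table, invisibly; errors on violation.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "municipality", "habitat", "rearing", "treatment",
            "ctmax_C")
  assert_that(all(need %in% names(samples)),
              "metadata must contain columns: ", paste(need, collapse = ", "))
  assert_that(!anyDuplicated(samples$sample_id), "sample_id must be unique")
  assert_that(all(samples$habitat %in% c("forest", "urban")),
              "habitat must be forest/urban")
  assert_that(all(samples$rearing %in% c("wild", "common_garden")),
              "rearing must be wild/common_garden")
  assert_that(all(samples$treatment %in% c("night15", "day25", "day32")),
              "treatment must be night15/day25/day32")
  cg <- samples$rearing == "common_garden"
  assert_that(all(samples$treatment[cg] %in% c("day25", "day32")),
              "common-garden samples admit only day25/day32 treatments")
  ct <- samples$ctmax_C[!is.na(samples$ctmax_C)]
  assert_that(all(ct >= 30 & ct <= 50), "ctmax_C must lie in [30, 50]")
  invisible(samples)
}
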