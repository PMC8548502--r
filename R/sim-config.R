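#' Synthetic-data generator configuration
#'
#' Builds the configuration object consumed by [simulate_expression()] and
#' [simulate_variants()]. Defaults emulate the study design the package
#' targets: 114 wild-caught lizards from four urban-forest municipality pairs
#' plus 16 common-garden animals from one municipality, three acclimation
#' treatments, CT_MAX (critical thermal maximum, the heat-tolerance phenotype)
#' between 35 and 43 degrees C, negative-binomial RNA-seq counts with a
#' modular co-expression structure, candidate genes coupled to CT_MAX, forest
#' reaction norms predominantly opposing the CT_MAX-favouring direction, and
#' biallelic SNPs with Balding-Nichols habitat divergence plus elevated local
#' linkage disequilibrium at candidate genes.
#'
#' @param n_genes number of genes in the count matrix.
#' @param n_candidates number of genes coupled to CT_MAX (planted candidates).
#' @param n_modules number of latent co-expression modules.
#' @param wild_n named list, one entry per municipality, each a named vector
#'   `c(forest = , urban = )` of wild sample sizes. The defaults sum to 114
#'   wild animals; together with the 16 common-garden animals the Mayaguez
#'   totals reach the study's per-municipality sequencing sizes (19 forest /
#'   18 urban).
#' @param cg_n common-garden sample sizes: named list with `forest` and
#'   `urban` entries, each `c(day25 = , day32 = )`. `NULL` omits the common
#'   garden. The default follows the study's 16-animal design
#'   (forest 3 at 25 degrees / 4 at 32; urban 5 / 4); the alternative split
#'   (forest 4/3) can be selected here.
#' @param cg_municipality municipality of origin of the common-garden colony.
#' @param ctmax_mean,ctmax_sd,ctmax_range truncated-normal parameters for
#'   CT_MAX in degrees C.
#' @param ctmax_sd_cg CT_MAX sd for common-garden animals; shared rearing
#'   conditions remove most environmental variance in heat tolerance, so the
#'   default is half the wild sd.
#' @param base_log2_mean,base_log2_sd per-gene baseline expression
#'   (log2 scale) distribution.
#' @param dispersion_meanlog,dispersion_sdlog lognormal parameters of the
#'   gene-wise negative-binomial dispersion.
#' @param libsize_sdlog lognormal sd of per-sample library-size factors.
#' @param module_sd sd of the latent module factor effect (log2 units).
#' @param gs_coupling expression change (log2 units) per standard deviation
#'   of CT_MAX for candidate genes; 0 disables the coupling (null generator).
#' @param lfc_mag magnitude (log2 units) of the forest 25-to-32 degree
#'   reaction norm of candidate genes.
#' @param forest_malad_frac probability that a candidate's forest reaction
#'   norm opposes its regulator sign (i.e. is maladaptive).
#' @param urban_attenuation multiplicative attenuation of the urban reaction
#'   norm relative to forest, in `[0, 1]`.
#' @param urban_reversal_prob probability that the urban norm direction flips
#'   relative to the forest norm.
#' @param noise_sd extra per-observation log2 noise.
#' @param n_snps total SNP count, allocated uniformly across genes.
#' @param gene_spacing_bp,gene_span_bp genes are tiled on one synthetic
#'   scaffold at `gene_spacing_bp` spacing and span `gene_span_bp`.
#' @param planted_fst named vector of Balding-Nichols divergence parameters
#'   for the `background`, `adaptive` and `maladaptive` SNP sets.
#' @param class_prop named list of functional-class probabilities
#'   (`nonsynonymous`, `synonymous`, `noncoding`) per SNP set.
#' @param ld_rho named vector `c(background = , candidate = )`: latent
#'   haplotype autocorrelation per kb driving within-gene LD.
#' @param missing_rate genotype missingness rate.
#' @param seed integer seed; every draw in the generator flows from it.
#'
#' @return a list of class `"plastisel_sim_config"`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_candidates = 600,
                       n_modules = 7,
                       wild_n = list(
                         Aguadilla = c(forest = 11, urban = 16),
                         Arecibo   = c(forest = 18, urban = 16),
                         Mayaguez  = c(forest = 12, urban = 9),
                         SanJuan   = c(forest = 11, urban = 21)),
                       cg_n = list(forest = c(day25 = 3, day32 = 4),
                                   urban  = c(day25 = 5, day32 = 4)),
                       cg_municipality = "Mayaguez",
                       ctmax_mean = 39, ctmax_sd = 1.5,
                       ctmax_sd_cg = 0.75,
                       ctmax_range = c(35, 43),
                       base_log2_mean = 5, base_log2_sd = 1.5,
                       dispersion_meanlog = log(0.1), dispersion_sdlog = 0.5,
                       libsize_sdlog = 0.15,
                       module_sd = 1.1,
                       gs_coupling = 0.8,
                       lfc_mag = 2.5,
                       forest_malad_frac = 0.8,
                       urban_attenuation = 0.5,
                       urban_reversal_prob = 0.5,
                       noise_sd = 0.4,
                       n_snps = 20000,
                       gene_spacing_bp = 1e5,
                       gene_span_bp = 1e4,
                       planted_fst = c(background = 0.02,
                                       adaptive = 0.06,
                                       maladaptive = 0.12),
                       class_prop = list(
                         background  = c(nonsynonymous = 0.25,
                                         synonymous = 0.25, noncoding = 0.50),
                         adaptive    = c(nonsynonymous = 0.45,
                                         synonymous = 0.15, noncoding = 0.40),
                         maladaptive = c(nonsynonymous = 0.15,
                                         synonymous = 0.15, noncoding = 0.70)),
                       ld_rho = c(background = 0.5, candidate = 0.9),
                       missing_rate = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "plastisel_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_genes >= 1 && cfg$n_candidates >= 0,
              "n_genes and n_candidates must be positive", config = TRUE)
  assert_that(cfg$n_candidates <= cfg$n_genes,
              "n_candidates (", cfg$n_candidates,
              ") exceeds n_genes (", cfg$n_genes, ")", config = TRUE)
  sizes <- unlist(cfg$wild_n)
  assert_that(all(sizes > 0), "wild sample sizes must be positive",
              config = TRUE)
  if (!is.null(cfg$cg_n)) {
    assert_that(all(unlist(cfg$cg_n) > 0),
                "common-garden sample sizes must be positive", config = TRUE)
    assert_that(all(names(cfg$cg_n) %in% c("forest", "urban")),
                "cg_n entries must be named forest/urban", config = TRUE)
  }
  assert_that(all(cfg$planted_fst >= 0 & cfg$planted_fst <= 1),
              "planted_fst values must lie in [0, 1]", config = TRUE)
  assert_that(cfg$urban_attenuation >= 0 && cfg$urban_attenuation <= 1,
              "urban_attenuation must lie in [0, 1]", config = TRUE)
  assert_that(cfg$forest_malad_frac >= 0 && cfg$forest_malad_frac <= 1 &&
                cfg$urban_reversal_prob >= 0 && cfg$urban_reversal_prob <= 1,
              "probabilities must lie in [0, 1]", config = TRUE)
  assert_that(cfg$n_snps >= 0 && cfg$missing_rate >= 0 &&
                cfg$missing_rate < 1,
              "n_snps must be nonnegative and missing_rate in [0, 1)",
              config = TRUE)
  for (p in cfg$class_prop) {
    assert_that(abs(sum(p) - 1) < 1e-8 &&
                  all(c("nonsynonymous", "synonymous", "noncoding") %in%
                        names(p)),
                "class_prop entries must be named probabilities summing to 1",
                config = TRUE)
  }
  invisible(cfg)
}
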