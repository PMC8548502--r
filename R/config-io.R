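#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain a `simulate:` block (fields of [sim_config()])
#' and any stage parameter of [plastisel_config()]; unspecified fields keep
#' their defaults. Used by the command-line wrapper.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a `"plastisel_config"` object.
#' @export
plastisel_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate %||% list()
  ## nested numeric lists arrive as lists; coerce sample-size blocks
  for (f in c("wild_n", "cg_n")) {
    if (!is.null(sim_args[[f]])) {
      sim_args[[f]] <- lapply(sim_args[[f]], function(v) unlist(v))
    }
  }
  for (f in c("planted_fst", "ld_rho")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  if (!is.null(sim_args$class_prop)) {
    sim_args$class_prop <- lapply(sim_args$class_prop, unlist)
  }
  sim <- do.call(sim_config, sim_args)
  stage_args <- y[setdiff(names(y), "simulate")]
  cfg <- do.call(plastisel_config, c(list(sim = sim), stage_args))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
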