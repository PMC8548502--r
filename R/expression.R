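#' Library-size normalization to log2 counts-per-million
#'
#' value = log2(count / library_size * 1e6 + prior_count), where the library
#' size is the sample's column sum. The prior count is added after CPM
#' scaling, so a zero count maps to log2(prior_count) (0 for the default
#' prior of 1) regardless of library size, and normalization is strictly
#' increasing in the raw count within a sample.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @param prior_count pseudo-count added on the CPM scale (default 1).
#' @return real matrix of log2-CPM values, same dimnames.
#' @export
normalize_counts <- function(counts, prior_count = 1) {
  assert_that(is.matrix(counts) && all(counts >= 0, na.rm = TRUE),
              "counts must be a nonnegative matrix")
  libsize <- colSums(counts)
  bad <- libsize <= 0
  assert_that(!any(bad), "zero library size for sample(s): ",
              paste(colnames(counts)[bad], collapse = ", "))
  log2(sweep(counts, 2, libsize, "/") * 1e6 + prior_count)
}

#' Drop genes with zero counts in every sample
#'
#' Zero-variance rows break correlation-based network construction; they are
#' removed here with a warning stating how many were dropped.
#'
#' @param counts count matrix.
#' @return the filtered matrix.
#' @export
drop_zero_genes <- function(counts) {
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero counts dropped before ",
            "network construction")
    counts <- counts[!zero, , drop = FALSE]
  }
  counts
}

#' Group-wise log fold change of normalized expression
#'
#' Per-gene difference of group means of log2-CPM, group B minus group A, so
#' a positive value means higher expression in group B. No dispersion
#' shrinkage is applied: the statistic is the plain average log-fold change.
#'
#' @param norm normalized (log2-CPM) matrix, genes x samples.
#' @param samples sample metadata; rows must match `colnames(norm)`.
#' @param group_a,group_b either logical vectors over samples, character
#'   vectors of sample ids, or named lists of metadata equality clauses, e.g.
#'   `list(rearing = "common_garden", habitat = "forest",
#'   treatment = "day32")`.
#' @return data.frame with `gene_id` and `lfc` (log2 units); group
#'   definitions kept in attributes `group_a` / `group_b`.
#' @export
group_lfc <- function(norm, samples, group_a, group_b) {
  ia <- resolve_group(samples, group_a, "group_a")
  ib <- resolve_group(samples, group_b, "group_b")
  assert_that(any(ia), "group_a selects no samples (",
              deparse1(group_a), ")")
  assert_that(any(ib), "group_b selects no samples (",
              deparse1(group_b), ")")
  assert_that(!any(ia & ib), "groups overlap: ",
              paste(samples$sample_id[ia & ib], collapse = ", "))
  lfc <- rowMeans(norm[, ib, drop = FALSE]) -
    rowMeans(norm[, ia, drop = FALSE])
  out <- data.frame(gene_id = rownames(norm), lfc = unname(lfc),
                    stringsAsFactors = FALSE)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "n_a") <- sum(ia)
  attr(out, "n_b") <- sum(ib)
  out
}

## Turn a group specification into a logical index over samples.
resolve_group <- function(samples, spec, label) {
  if (is.logical(spec)) {
    assert_that(length(spec) == nrow(samples),
                label, ": logical index length mismatch")
    return(spec)
  }
  if (is.character(spec)) return(samples$sample_id %in% spec)
  if (is.list(spec)) {
    idx <- rep(TRUE, nrow(samples))
    for (field in names(spec)) {
      assert_that(field %in% names(samples),
                  label, ": unknown metadata field '", field, "'")
      idx <- idx & samples[[field]] %in% spec[[field]]
    }
    return(idx)
  }
  stop_validation(label, ": unsupported group specification")
}

## Canonical common-garden group predicates used across stages.
cg_group <- function(habitat, treatment) {
  list(rearing = "common_garden", habitat = habitat, treatment = treatment)
}
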