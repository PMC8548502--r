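#' Write a simulated dataset to disk
#'
#' Emits the standard file set: counts TSV (genes x samples, header row =
#' sample ids), metadata TSV, VCF v4.2 (one record per SNP, GT genotypes,
#' INFO tags GENE/FCLASS/SET), BED gene map (0-based half-open spans) and
#' truth JSON. [read_dataset()] round-trips the tables exactly.
#'
#' @param samples sample metadata data.frame.
#' @param counts gene x sample count matrix.
#' @param variants `variant_table` or NULL.
#' @param truth planted-truth list or NULL.
#' @param out_dir output directory (created if absent).
#' @param gene_coords gene coordinate data.frame for the BED map (optional).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(samples, counts, variants = NULL, truth = NULL,
                          out_dir, gene_coords = NULL) {
  assert_that(identical(colnames(counts), samples$sample_id),
              "count matrix columns must match metadata sample ids")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "cannot create output directory ", out_dir)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"))

  cts <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(cts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(variants)) {
    paths["vcf"] <- file.path(out_dir, "variants.vcf")
    write_vcf(variants, paths["vcf"])
  }
  if (!is.null(gene_coords)) {
    paths["bed"] <- file.path(out_dir, "genes.bed")
    bed <- data.frame(gene_coords$scaffold, gene_coords$start - 1L,
                      gene_coords$end, gene_coords$gene_id)
    utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}

## Plain-text VCF v4.2 formatter. vcfR is used for reading; its writer only
## emits gzip output, and these fixtures must stay plain text.
write_vcf <- function(variants, path) {
  info <- variants$info
  geno <- variants$geno
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=plastisel",
    "##contig=<ID=scaffold_1>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Host gene id\">",
    paste0("##INFO=<ID=FCLASS,Number=1,Type=String,Description=",
           "\"Functional class\">"),
    paste0("##INFO=<ID=SET,Number=1,Type=String,Description=",
           "\"Plasticity SNP set\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(geno), ncol(geno))
  ok <- !is.na(geno)
  gt[ok] <- gt_code[geno[ok] + 1L]
  body <- paste(info$scaffold, info$pos, info$snp_id, info$ref, info$alt,
                info$qual, "PASS",
                sprintf("GENE=%s;FCLASS=%s;SET=%s", info$gene_id,
                        info$fclass, info$set),
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing counts.tsv, metadata.tsv and optionally
#'   variants.vcf / truth.json.
#' @return list with `samples`, `counts`, and (when present) `variants`,
#'   `truth`.
#' @export
read_dataset <- function(dir) {
  counts_df <- utils::read.table(file.path(dir, "counts.tsv"), header = TRUE,
                                 sep = "\t", check.names = FALSE,
                                 stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene_id
  storage.mode(counts) <- "integer"
  samples <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  out <- list(samples = samples, counts = counts)
  vcf_path <- file.path(dir, "variants.vcf")
  if (file.exists(vcf_path)) out$variants <- read_vcf(vcf_path)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    out$truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  out
}

#' Read a VCF into a `variant_table`
#'
#' Parses with vcfR and converts GT fields to alt-allele dosages. INFO tags
#' GENE/FCLASS/SET are attached when present.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a `variant_table` (see [simulate_variants()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- data.frame(
    snp_id = fix$ID, scaffold = fix$CHROM, pos = as.integer(fix$POS),
    qual = as.numeric(fix$QUAL), ref = fix$REF, alt = fix$ALT,
    stringsAsFactors = FALSE)
  for (tag in c("GENE", "FCLASS", "SET")) {
    val <- vcfR::extract.info(v, element = tag)
    if (!all(is.na(val))) {
      info[[c(GENE = "gene_id", FCLASS = "fclass", SET = "set")[tag]]] <- val
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(info$snp_id, colnames(gt)))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  rownames(info) <- NULL
  structure(list(info = info, geno = dos), class = "variant_table")
}
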