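# Small in-code fixtures shared across test files.

toy_expr <- function(values, genes = NULL, samples = NULL,
                     platform = "rnaseq_log2tpm") {
  m <- as.matrix(values)
  if (!is.null(genes)) rownames(m) <- genes
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (!is.null(samples)) colnames(m) <- samples
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  expression_matrix(m, platform = platform)
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_clinical <- function(time, status, sample = paste0("P", seq_along(time))) {
  clinical_table(data.frame(sample = sample, time = time, status = status,
                            stringsAsFactors = FALSE))
}

# MAF builder: one record per row of the arguments (recycled).
toy_maf <- function(sample, gene, ref = "C", alt = "A", vtype = "SNP",
                    vclass = "Missense_Mutation", chrom = "1",
                    pos = seq_along(sample)) {
  maf_table(data.frame(
    Hugo_Symbol = gene, Tumor_Sample_Barcode = sample,
    Variant_Classification = vclass, Variant_Type = vtype,
    Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
    Chromosome = chrom, Start_Position = pos, stringsAsFactors = FALSE))
}

# YAML config for CLI-driven runs at reduced size.
cli_yaml <- function(path, outdir, seed = 3L) {
  yaml::write_yaml(list(
    n_ne_lines = 15L, n_nonne_lines = 30L, n_genes = 400L,
    n_signature_genes = 40L, n_immune_genes = 40L, n_bulk = 120L,
    n_mut_genes = 60L, seed = seed, outdir = outdir), path)
  path
}

# A small, fast simulation config used where the full-size defaults are
# not the point of the test.
small_sim <- function(seed = 1L, ...) {
  sim_config(n_ne_lines = 15L, n_nonne_lines = 30L, n_genes = 400L,
             n_signature_genes = 40L, n_immune_genes = 40L, n_bulk = 120L,
             n_mut_genes = 60L, seed = seed, ...)
}
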