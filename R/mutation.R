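#' Read a MAF (Mutation Annotation Format) table
#'
#' TCGA-dialect tab-separated MAF. Required columns:
#' `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`,
#' `Variant_Type`, `Reference_Allele`, `Tumor_Seq_Allele2`, `Chromosome`,
#' `Start_Position`. Coordinates are 1-based inclusive and chromosome
#' strings pass through verbatim.
#'
#' @param path MAF file path (comment lines starting with `#` are skipped).
#' @return data.frame of class `maf_table`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  maf_table(df)
}

#' @rdname read_maf
#' @param df data.frame with the required MAF columns.
#' @export
maf_table <- function(df) {
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
           "Variant_Type", "Reference_Allele", "Tumor_Seq_Allele2",
           "Chromosome", "Start_Position")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("MAF missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!nzchar(df$Reference_Allele)) || any(!nzchar(df$Tumor_Seq_Allele2)))
    stop("empty allele fields in MAF", call. = FALSE)
  snp <- df$Variant_Type == "SNP"
  if (any(snp & (nchar(df$Reference_Allele) != 1L |
                 nchar(df$Tumor_Seq_Allele2) != 1L)))
    stop("SNP records must have single-base ref/alt alleles", call. = FALSE)
  class(df) <- c("maf_table", "data.frame")
  df
}

#' Write a MAF table
#' @param maf a `maf_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tumour mutation burden (variants per exome megabase)
#'
#' Number of the sample's variant records divided by 38 Mb of exome. All
#' record types count by default; `exclude_silent = TRUE` drops
#' `Silent` classifications from the numerator.
#'
#' @param maf a `maf_table`.
#' @param sample sample barcode; must be present in the MAF (a sample with
#'   zero remaining variants after filtering scores 0).
#' @param exclude_silent drop silent variants from the count.
#' @param exome_mb exome size in megabases (default 38).
#' @return TMB in variants/Mb.
#' @export
tmb <- function(maf, sample, exclude_silent = FALSE, exome_mb = 38) {
  if (!sample %in% maf$Tumor_Sample_Barcode)
    stop("sample '", sample, "' not present in MAF", call. = FALSE)
  rec <- maf[maf$Tumor_Sample_Barcode == sample, , drop = FALSE]
  if (exclude_silent)
    rec <- rec[rec$Variant_Classification != "Silent", , drop = FALSE]
  nrow(rec) / exome_mb
}

#' TMB for every sample in a MAF
#' @inheritParams tmb
#' @return data.frame with columns `sample`, `n_variants`, `tmb`.
#' @export
tmb_all <- function(maf, exclude_silent = FALSE, exome_mb = 38) {
  rec <- maf
  if (exclude_silent)
    rec <- rec[rec$Variant_Classification != "Silent", , drop = FALSE]
  counts <- table(factor(rec$Tumor_Sample_Barcode,
                         levels = unique(maf$Tumor_Sample_Barcode)))
  data.frame(sample = names(counts), n_variants = as.integer(counts),
             tmb = as.integer(counts) / exome_mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
TI_CLASSES <- c("C>T", "T>C")

#' Single-nucleotide substitution classes and Ti/Tv
#'
#' Collapses SNP substitutions to the six pyrimidine-reference classes
#' (C>A, C>G, C>T, T>A, T>C, T>G; purine-reference records are
#' complemented). Transitions are C>T and T>C; the other four classes are
#' transversions. Records with ref == alt are rejected with a warning.
#'
#' @param maf a `maf_table`.
#' @return list with `counts` (named six-class totals), `ti`, `tv`
#'   (overall counts), and `per_sample` (data.frame of per-sample class
#'   fractions plus `ti_frac`, `tv_frac`, which sum to 1).
#' @export
snv_classes <- function(maf) {
  snp <- maf[maf$Variant_Type == "SNP", , drop = FALSE]
  ref <- toupper(snp$Reference_Allele)
  alt <- toupper(snp$Tumor_Seq_Allele2)
  bad <- ref == alt
  if (any(bad)) {
    warning(sum(bad), " SNP record(s) with ref == alt rejected", call. = FALSE)
    snp <- snp[!bad, , drop = FALSE]; ref <- ref[!bad]; alt <- alt[!bad]
  }
  flip <- ref %in% c("A", "G")
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  cls <- factor(paste0(ref, ">", alt),
                levels = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  counts <- table(cls)
  ti <- sum(counts[TI_CLASSES])
  tv <- sum(counts) - ti
  tab <- table(snp$Tumor_Sample_Barcode, cls)
  tot <- rowSums(tab)
  frac <- sweep(as.matrix(tab), 1L, pmax(tot, 1L), "/")
  per_sample <- data.frame(sample = rownames(tab), as.data.frame.matrix(frac),
                           check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  per_sample$ti_frac <- rowSums(frac[, TI_CLASSES, drop = FALSE])
  per_sample$tv_frac <- 1 - per_sample$ti_frac
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       ti = as.integer(ti), tv = as.integer(tv), per_sample = per_sample)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided conditional p-value (sum over tables with the observed
#' margins whose hypergeometric probability does not exceed the observed
#' table's). The reported odds ratio is the cross-product ratio, with 0.5
#' added to every cell for display only when any cell is zero.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("all-zero 2x2 table", call. = FALSE)
  p <- stats::fisher.test(matrix(cells, 2L, byrow = TRUE))$p.value
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = min(p, 1))
}

# gene x sample logical mutation matrix
mutation_matrix <- function(maf, samples = unique(maf$Tumor_Sample_Barcode)) {
  genes <- unique(maf$Hugo_Symbol)
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- maf$Tumor_Sample_Barcode %in% samples
  idx <- cbind(match(maf$Hugo_Symbol[keep], genes),
               match(maf$Tumor_Sample_Barcode[keep], samples))
  m[idx] <- TRUE
  m
}

#' Differentially mutated genes between two groups
#'
#' Per gene, a 2x2 Fisher test of mutated/wild-type sample counts across
#' the two groups; genes with p below `alpha` are flagged. P-values are
#' unadjusted by default (matching the common 0.05 screening rule); set
#' `adjust = TRUE` for BH correction of the flag.
#'
#' @param maf a `maf_table`.
#' @param groups named character/factor: group label per sample barcode
#'   (two groups, each >= 2 samples). Samples absent from the MAF count as
#'   wild-type for every gene.
#' @param alpha significance threshold (default 0.05).
#' @param adjust apply BH before flagging.
#' @return data.frame: `gene`, mutated counts and frequencies per group,
#'   `odds_ratio`, `p_value`, `fdr`, `flagged`.
#' @export
differential_mutation <- function(maf, groups, alpha = 0.05, adjust = FALSE) {
  groups <- stats::setNames(as.character(groups), names(groups))
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  m <- mutation_matrix(maf, samples = names(groups))
  n1 <- sum(groups == lv[1]); n2 <- sum(groups == lv[2])
  mut1 <- rowSums(m[, groups == lv[1], drop = FALSE])
  mut2 <- rowSums(m[, groups == lv[2], drop = FALSE])
  keep <- (mut1 + mut2) > 0L            # genes never mutated are skipped
  res <- data.frame(gene = rownames(m)[keep],
                    mut1 = mut1[keep], n1 = n1, freq1 = mut1[keep] / n1,
                    mut2 = mut2[keep], n2 = n2, freq2 = mut2[keep] / n2,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(res)[2:7] <- c(paste0("mut_", lv[1]), paste0("n_", lv[1]),
                       paste0("freq_", lv[1]), paste0("mut_", lv[2]),
                       paste0("n_", lv[2]), paste0("freq_", lv[2]))
  for (i in seq_len(nrow(res))) {
    ft <- fisher_exact_2x2(res[[2]][i], n1 - res[[2]][i],
                           res[[5]][i], n2 - res[[5]][i])
    res$odds_ratio[i] <- ft$odds_ratio
    res$p_value[i] <- ft$p_value
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$flagged <- (if (adjust) res$fdr else res$p_value) < alpha
  res[order(res$p_value), , drop = FALSE]
}

#' Pairwise co-occurrence / mutual exclusivity of mutated genes
#'
#' For the top-N most frequently mutated genes, tests every unordered pair
#' with Fisher's exact test on joint mutation status; a pair is labelled
#' `co_occurrence` when the odds ratio exceeds 1 and `exclusivity`
#' otherwise.
#'
#' @param maf a `maf_table`.
#' @param top_n number of most frequently mutated genes to consider
#'   (default 25; capped at the available gene count with a warning).
#' @return data.frame: `gene1`, `gene2`, `both`, `only1`, `only2`,
#'   `neither`, `odds_ratio`, `p_value`, `label`.
#' @export
interactions <- function(maf, top_n = 25L) {
  m <- mutation_matrix(maf)
  if (nrow(m) < 2L) stop("need >= 2 mutated genes", call. = FALSE)
  if (top_n > nrow(m)) {
    warning("top_n capped at ", nrow(m), " available genes", call. = FALSE)
    top_n <- nrow(m)
  }
  freq <- rowSums(m)
  sel <- names(sort(freq, decreasing = TRUE))[seq_len(top_n)]
  pairs <- utils::combn(sel, 2L)
  out <- data.frame(gene1 = pairs[1, ], gene2 = pairs[2, ],
                    both = NA_integer_, only1 = NA_integer_,
                    only2 = NA_integer_, neither = NA_integer_,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    label = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g1 <- m[pairs[1, i], ]; g2 <- m[pairs[2, i], ]
    a <- sum(g1 & g2); b <- sum(g1 & !g2)
    cc <- sum(!g1 & g2); d <- sum(!g1 & !g2)
    ft <- fisher_exact_2x2(a, b, cc, d)
    out$both[i] <- a; out$only1[i] <- b; out$only2[i] <- cc; out$neither[i] <- d
    out$odds_ratio[i] <- ft$odds_ratio
    out$p_value[i] <- ft$p_value
    out$label[i] <- if (ft$odds_ratio > 1) "co_occurrence" else "exclusivity"
  }
  out[order(out$p_value), , drop = FALSE]
}
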