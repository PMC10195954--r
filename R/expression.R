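#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric gene-by-sample matrix carrying a
#' platform tag and a normalization flag, the two pieces of provenance the
#' scoring pipeline needs to enforce its preconditions (RNA-seq values are
#' log2(TPM+1)-transformed, microarray values are min-max scaled per gene).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes character vector of unique gene symbols (defaults to rownames).
#' @param samples character vector of unique sample IDs (defaults to colnames).
#' @param platform one of `"rnaseq_tpm"`, `"rnaseq_log2tpm"`,
#'   `"microarray_raw"`, `"microarray_norm"`.
#' @param normalized logical; whether a per-gene normalization has been applied.
#'
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   attributes `platform` and `normalized`.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values),
                              platform = c("rnaseq_tpm", "rnaseq_log2tpm",
                                           "microarray_raw", "microarray_norm"),
                              normalized = FALSE) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes) || is.null(samples))
    stop("expression_matrix() requires gene and sample labels", call. = FALSE)
  if (length(genes) != nrow(values) || length(samples) != ncol(values))
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)])[1:min(3, sum(duplicated(genes)))],
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample IDs", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  dimnames(values) <- list(as.character(genes), as.character(samples))
  structure(values, platform = platform, normalized = isTRUE(normalized),
            class = c("expression_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples | platform=%s | normalized=%s\n",
              nrow(x), ncol(x), attr(x, "platform"), attr(x, "normalized")))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to test.
#' @export
is_expression_matrix <- function(x) inherits(x, "expression_matrix")

# Rebuild the class/attributes after a plain-matrix operation.
restamp <- function(values, template, platform = attr(template, "platform"),
                    normalized = attr(template, "normalized")) {
  expression_matrix(values, platform = platform, normalized = normalized)
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header holds sample IDs. Duplicate gene rows are collapsed by
#' keeping the row with the highest mean expression (the usual convention
#' when several probes or transcript rows map to one symbol).
#'
#' @param path file path.
#' @param platform platform tag to stamp on the result (see
#'   [expression_matrix()]).
#' @param impute_missing if `TRUE`, missing cells are imputed with the
#'   gene-wise median; the default is to fail on any missing value.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, platform = "rnaseq_tpm", impute_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file has no data rows/sample columns: ", path, call. = FALSE)
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], names(vals)[j], col[bad[1]]), call. = FALSE)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyNA(m)) {
    if (!impute_missing)
      stop("missing values in expression matrix; use impute_missing = TRUE ",
           "for gene-wise median imputation", call. = FALSE)
    for (i in which(rowSums(is.na(m)) > 0L)) {
      med <- stats::median(m[i, ], na.rm = TRUE)
      if (is.na(med)) stop("gene '", genes[i], "' entirely missing", call. = FALSE)
      m[i, is.na(m[i, ])] <- med
    }
  }
  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    # keep, per symbol, the row with the largest mean
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    m <- m[sort(keep), , drop = FALSE]
  }
  expression_matrix(m, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' @param mat an [expression_matrix()].
#' @param path output path; first column is named `gene`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2(TPM + 1) transform
#'
#' @param mat an [expression_matrix()] with platform `rnaseq_tpm` and
#'   non-negative values.
#' @return The transformed matrix, platform `rnaseq_log2tpm`.
#' @export
log2_tpm <- function(mat) {
  stopifnot(is_expression_matrix(mat))
  if (attr(mat, "platform") != "rnaseq_tpm")
    stop("log2_tpm() expects platform 'rnaseq_tpm', got '",
         attr(mat, "platform"), "'", call. = FALSE)
  if (any(mat < 0))
    stop("negative TPM values are not allowed", call. = FALSE)
  restamp(log2(unclass(mat) + 1), mat, platform = "rnaseq_log2tpm")
}

#' Per-gene min-max scaling to [0, 1]
#'
#' Applies X' = (X - Xmin) / (Xmax - Xmin) gene-wise across samples, the
#' standard harmonization for log-transformed microarray intensities.
#' Constant gene rows (Xmax == Xmin) are set to 0 with a warning.
#'
#' @param mat an [expression_matrix()] with platform `microarray_raw`.
#' @return Matrix with every non-constant gene row spanning [0, 1];
#'   platform `microarray_norm`, `normalized = TRUE`.
#' @export
minmax_01 <- function(mat) {
  stopifnot(is_expression_matrix(mat))
  if (attr(mat, "platform") != "microarray_raw")
    stop("minmax_01() expects platform 'microarray_raw', got '",
         attr(mat, "platform"), "'", call. = FALSE)
  v <- unclass(mat)
  lo <- apply(v, 1L, min)
  hi <- apply(v, 1L, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene row(s) set to 0 in minmax_01()",
            call. = FALSE)
    rng[flat] <- 1
  }
  out <- (v - lo) / rng
  out[flat, ] <- 0
  restamp(out, mat, platform = "microarray_norm", normalized = TRUE)
}

#' Restrict matrices to their common genes
#'
#' Cross-cohort harmonization step: every matrix is subset to the sorted
#' intersection of all gene lists, in identical order.
#'
#' @param mats list of two or more [expression_matrix()] objects.
#' @return List of matrices, all on the same sorted common gene vector.
#' @export
intersect_genes <- function(mats) {
  if (!is.list(mats) || length(mats) < 2L)
    stop("intersect_genes() needs a list of >= 2 matrices", call. = FALSE)
  stopifnot(all(vapply(mats, is_expression_matrix, logical(1))))
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L)
    stop("no genes common to all matrices", call. = FALSE)
  common <- sort(common)
  lapply(mats, function(m) restamp(unclass(m)[common, , drop = FALSE], m))
}

#' Subset an expression matrix by sample IDs
#'
#' @param mat an [expression_matrix()].
#' @param samples character vector of sample IDs to keep (order preserved).
#' @return The subset matrix with provenance attributes intact.
#' @export
subset_samples <- function(mat, samples) {
  stopifnot(is_expression_matrix(mat))
  miss <- setdiff(samples, colnames(mat))
  if (length(miss))
    stop("sample(s) not in matrix: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  restamp(unclass(mat)[, samples, drop = FALSE], mat)
}

#' Mean-center each gene row
#'
#' Subtracts the per-gene mean across the columns of the given matrix. In
#' the index workflow the full cell-line panel is centered before the
#' one-class trainer sees the neuroendocrine columns.
#'
#' @param mat an [expression_matrix()].
#' @return Centered matrix (same platform tag).
#' @export
center_genes <- function(mat) {
  stopifnot(is_expression_matrix(mat))
  restamp(unclass(mat) - rowMeans(mat), mat)
}
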