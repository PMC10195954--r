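#' Score samples against a trained weight vector
#'
#' Per sample, computes the Spearman correlation (average-rank ties)
#' between the model weights and the sample's expression profile over the
#' genes shared by the two; this rank correlation is the raw
#' neuroendocrine-differentiation score. Genes in the weight vector absent
#' from the matrix are dropped and counted in `n_common_genes`.
#'
#' @param weights a `weight_vector` (see [train_oclr()] / [read_weights()]).
#' @param mat an [expression_matrix()] to score.
#' @return data.frame of class `nedi_scores` with columns `sample`, `rho`,
#'   `index` (NA until [normalize_index()]), `stratum` (NA until
#'   [stratify_median()]), `n_common_genes`.
#' @export
score_samples <- function(weights, mat) {
  stopifnot(inherits(weights, "weight_vector"), is_expression_matrix(mat))
  common <- intersect(weights$gene, rownames(mat))
  if (length(common) < 2L)
    stop("fewer than 2 genes shared between weight vector and matrix",
         call. = FALSE)
  w <- weights$weight[match(common, weights$gene)]
  sub <- unclass(mat)[common, , drop = FALSE]
  rw <- rank(w)                          # average-rank ties
  rho <- vapply(seq_len(ncol(sub)), function(j) {
    x <- sub[, j]
    if (max(x) == min(x))
      stop("zero-variance expression profile for sample '",
           colnames(sub)[j], "'; Spearman undefined", call. = FALSE)
    stats::cor(rw, rank(x))
  }, numeric(1))
  structure(data.frame(sample = colnames(mat), rho = rho, index = NA_real_,
                       stratum = NA_character_,
                       n_common_genes = length(common),
                       stringsAsFactors = FALSE),
            class = c("nedi_scores", "data.frame"))
}

#' Map raw scores to the [0, 1] NED index
#'
#' Linear cohort-relative transform `(rho - min) / (max - min)`: the
#' cohort minimum maps to 0 and the maximum to 1, preserving the rank
#' order of the raw correlations. Because the map is cohort-relative,
#' indices are comparable within a cohort but not across cohorts.
#'
#' @param scores a `nedi_scores` data.frame from [score_samples()].
#' @return The same data.frame with `index` filled in.
#' @export
normalize_index <- function(scores) {
  stopifnot(inherits(scores, "nedi_scores"))
  r <- scores$rho
  if (length(r) < 2L || max(r) == min(r))
    stop("degenerate cohort: need >= 2 samples with distinct scores",
         call. = FALSE)
  scores$index <- (r - min(r)) / (max(r) - min(r))
  scores
}

#' Split a cohort at the median index
#'
#' `stratum` is `"high"` iff `index > median(index)`, else `"low"`; a
#' sample sitting exactly at the median is labelled low (deterministic
#' tie rule).
#'
#' @param scores a `nedi_scores` data.frame with indices present.
#' @return The same data.frame with `stratum` filled in.
#' @export
stratify_median <- function(scores) {
  stopifnot(inherits(scores, "nedi_scores"))
  if (anyNA(scores$index))
    stop("indices missing; call normalize_index() first", call. = FALSE)
  med <- stats::median(scores$index)
  scores$stratum <- ifelse(scores$index > med, "high", "low")
  message(sprintf("stratified: %d low, %d high (median index %.4f)",
                  sum(scores$stratum == "low"), sum(scores$stratum == "high"),
                  med))
  scores
}

#' Correlation with a two-sided p-value
#'
#' Pearson or Spearman coefficient with the usual t-approximation p-value,
#' as used for index-versus-burden and index-versus-signature associations.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate` and `p_value`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input; correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Write / read per-sample score tables
#'
#' @param scores a `nedi_scores` data.frame.
#' @param path TSV path (columns sample, rho, index, stratum,
#'   n_common_genes).
#' @return `path` (write) or the restored data.frame (read).
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  structure(df, class = c("nedi_scores", "data.frame"))
}
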