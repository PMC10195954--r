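#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average-rank ties) and
#' walked in descending order. The enrichment score of a set G is
#' \deqn{ES(G) = \sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)]}
#' with \eqn{P_{in}} the weighted (rank^alpha) cumulative fraction of set
#' genes encountered and \eqn{P_{out}} the cumulative fraction of non-set
#' genes. Scores depend on ranks only, so any strictly monotone transform
#' of a sample's expression leaves them unchanged.
#'
#' @param mat an [expression_matrix()].
#' @param sets a `gene_set_collection` (see [read_gmt()]).
#' @param alpha rank-weight exponent; 0.25 is the canonical ssGSEA value.
#' @param normalize if `TRUE` (default) all scores are divided by the
#'   range (max - min) of the full score matrix, the usual cohort
#'   normalization.
#' @return numeric sets-by-samples matrix of class `enrichment_matrix`
#'   with attributes `alpha` and `normalized`.
#' @export
ssgsea <- function(mat, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(is_expression_matrix(mat), alpha >= 0)
  genes <- rownames(mat)
  N <- length(genes)
  masks <- lapply(sets, function(g) genes %in% g)
  sizes <- vapply(masks, sum, integer(1))
  if (any(sizes == 0L)) {
    warning("dropping ", sum(sizes == 0L),
            " gene set(s) with zero overlap: ",
            paste(names(sets)[sizes == 0L], collapse = ", "), call. = FALSE)
    masks <- masks[sizes > 0L]
    if (length(masks) == 0L) stop("no gene set overlaps the matrix", call. = FALSE)
  }
  if (any(vapply(masks, sum, integer(1)) == N))
    stop("a gene set covers every gene in the matrix; ",
         "the miss-penalty is undefined", call. = FALSE)
  es <- matrix(NA_real_, length(masks), ncol(mat),
               dimnames = list(names(masks), colnames(mat)))
  v <- unclass(mat)
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    nu <- rank(x)                        # ascending rank, ties averaged
    ord <- order(x, decreasing = TRUE)
    wts <- nu[ord]^alpha
    for (k in seq_along(masks)) {
      inset <- masks[[k]][ord]
      m <- sum(inset)
      p_in <- cumsum(wts * inset) / sum(wts[inset])
      p_out <- cumsum(!inset) / (N - m)
      es[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  structure(es, alpha = alpha, normalized = isTRUE(normalize),
            class = c("enrichment_matrix", "matrix", "array"))
}

#' ESTIMATE-style stromal / immune / combined scores
#'
#' Stromal and immune scores are the ssGSEA scores of the two signature
#' sets; the combined (estimate) score is their sum, tracking overall
#' non-tumour infiltration.
#'
#' @param mat an [expression_matrix()].
#' @param stromal_set,immune_set character vectors of signature genes.
#' @inheritParams ssgsea
#' @return data.frame with columns `sample`, `stromal`, `immune`,
#'   `estimate`.
#' @export
estimate_scores <- function(mat, stromal_set, immune_set, alpha = 0.25,
                            normalize = TRUE) {
  sets <- gene_set_collection(list(stromal = stromal_set, immune = immune_set))
  es <- ssgsea(mat, sets, alpha = alpha, normalize = normalize)
  if (nrow(es) < 2L)
    stop("both signature sets must overlap the matrix", call. = FALSE)
  data.frame(sample = colnames(es),
             stromal = es["stromal", ],
             immune = es["immune", ],
             estimate = es["stromal", ] + es["immune", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Preranked GSEA (weighted Kolmogorov-Smirnov running sum)
#'
#' Classic preranked enrichment with weight exponent 1: walking the
#' ranking in decreasing order, set genes advance the running sum in
#' proportion to |rank statistic| and non-set genes retreat it uniformly;
#' ES is the signed extremum. The null is built by resampling random gene
#' sets of equal size from the ranking, NES = ES divided by the mean
#' |null ES| of the same sign, and p-values are BH-adjusted across sets.
#'
#' @param ranking named numeric vector (gene-level statistic); names
#'   must be unique.
#' @param sets a `gene_set_collection`.
#' @param n_perm number of null gene-set draws (>= 100).
#' @param seed integer RNG seed; identical inputs and seed reproduce
#'   identical p-values.
#' @return data.frame with columns `set`, `size`, `ES`, `NES`, `p_value`,
#'   `padj`.
#' @export
gsea_preranked <- function(ranking, sets, n_perm = 1000L, seed = 1L) {
  stopifnot(is.numeric(ranking), !is.null(names(ranking)),
            !anyDuplicated(names(ranking)), n_perm >= 100)
  ord <- order(ranking, decreasing = TRUE)
  r <- ranking[ord]
  genes <- names(r)
  N <- length(r)
  absr <- abs(r)

  es_for_idx <- function(idx) {          # idx: positions (in ranked order) of set genes
    hit <- logical(N); hit[idx] <- TRUE
    inc <- ifelse(hit, absr / sum(absr[idx]), -1 / (N - length(idx)))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }

  keep <- vapply(sets, function(g) sum(genes %in% g) >= 2L, logical(1))
  if (any(!keep))
    warning("dropping ", sum(!keep), " set(s) with overlap < 2: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no scoreable gene sets", call. = FALSE)

  out <- data.frame(set = names(sets), size = NA_integer_, ES = NA_real_,
                    NES = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  set.seed(seed)
  null_cache <- list()                   # one null ensemble per set size
  for (i in seq_along(sets)) {
    idx <- which(genes %in% sets[[i]])
    k <- length(idx)
    es <- es_for_idx(idx)
    key <- as.character(k)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- vapply(seq_len(n_perm), function(b)
        es_for_idx(sample.int(N, k)), numeric(1))
    nulls <- null_cache[[key]]
    same <- nulls[sign(nulls) == sign(es)]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(nulls))
    out$size[i] <- k
    out$ES[i] <- es
    out$NES[i] <- if (denom > 0) es / denom else 0
    out$p_value[i] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Per-gene two-group differential expression (Welch t)
#'
#' Vectorized Welch t-test per gene with Benjamini-Hochberg FDR. `log2FC`
#' is mean(group 2) - mean(group 1) on the (assumed log-scale) input, with
#' group 1 the first factor level.
#'
#' @param mat an [expression_matrix()] (log-scale values).
#' @param groups factor/character of length `ncol(mat)` with exactly two
#'   levels, each represented by >= 2 samples.
#' @return data.frame with columns `gene`, `log2FC`, `t`, `p_value`, `fdr`,
#'   ordered as the input genes.
#' @export
differential_expression <- function(mat, groups) {
  stopifnot(is_expression_matrix(mat))
  groups <- factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(mat))
    stop("groups must label every column with exactly two levels", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  v <- unclass(mat)
  g1 <- v[, groups == levels(groups)[1], drop = FALSE]
  g2 <- v[, groups == levels(groups)[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: both variances zero
  flat <- se2 == 0
  tstat[flat] <- 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p[flat & m1 != m2] <- 0
  tstat[flat & m1 != m2] <- sign(m2 - m1)[flat & m1 != m2] * Inf
  data.frame(gene = rownames(v), log2FC = m2 - m1, t = tstat, p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export the top-k up- and down-regulated genes
#'
#' Selects the k genes with the largest and smallest t statistics, the
#' lists used downstream for connectivity-map style compound queries.
#'
#' @param de a [differential_expression()] result.
#' @param k list length (default 150).
#' @return list with character vectors `up` and `down`.
#' @export
top_k_export <- function(de, k = 150L) {
  if (k > nrow(de))
    stop("k (", k, ") exceeds the number of genes (", nrow(de), ")",
         call. = FALSE)
  ord <- order(de$t, decreasing = TRUE)
  list(up = de$gene[ord[seq_len(k)]],
       down = de$gene[rev(ord)[seq_len(k)]])
}
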