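#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Genes are de-duplicated within each set.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `source` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d (< 3 tab-separated fields)", i),
           call. = FALSE)
    nms[i] <- parts[1]
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("GMT set '%s' (line %d) has no genes", parts[1], i),
           call. = FALSE)
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(sets) <- nms
  gene_set_collection(sets, source = path)
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors.
#' @param source free-text provenance.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))) || anyDuplicated(names(sets)))
    stop("gene sets must have unique non-empty names", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene set after de-duplication", call. = FALSE)
  structure(sets, source = source, class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection` or named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical/survival TSV
#'
#' Requires columns `sample`, `time` (days) and `status` (0 = censored,
#' 1 = event); extra covariate columns pass through. Rows with non-positive
#' time are dropped with a message.
#'
#' @param path TSV path.
#' @return data.frame of class `clinical_table`, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample", "time", "status")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  clinical_table(df)
}

#' @rdname read_clinical
#' @param df data.frame with at least `sample`, `time`, `status`.
#' @export
clinical_table <- function(df) {
  df$sample <- as.character(df$sample)
  df$time <- as.numeric(df$time)
  df$status <- as.integer(df$status)
  bad <- !is.finite(df$time) | df$time <= 0
  if (any(bad)) {
    message(sum(bad), " clinical row(s) with non-positive/missing time dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid clinical rows", call. = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in clinical table", call. = FALSE)
  if (!all(df$status %in% c(0L, 1L))) stop("status must be 0/1", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}
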