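#' Validate a sample-by-taxon abundance table
#'
#' Abundance tables are stored as integer matrices with taxa as rows and
#' samples as columns (the orientation used by the TSV writers). Counts must
#' be non-negative integers and row/column names unique.
#'
#' @param x matrix of counts (taxa x samples).
#' @param require_nonzero_samples error when a sample has zero total count.
#' @return the validated integer matrix, invisibly unchanged.
#' @export
validate_abundance <- function(x, require_nonzero_samples = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_pcg("abundance table must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_pcg("abundance table must have taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop_pcg("duplicate taxon ids: ",
             paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop_pcg("duplicate sample ids: ",
             paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyNA(x) || any(x < 0)) stop_pcg("counts must be non-negative and non-missing")
  if (any(x != round(x))) stop_pcg("counts must be integers")
  if (require_nonzero_samples && any(colSums(x) == 0)) {
    bad <- colnames(x)[colSums(x) == 0]
    stop_pcg("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  storage.mode(x) <- "integer"
  invisible(x)
}

# Drop taxa never observed (post-generation trimming).
trim_zero_taxa <- function(x) x[rowSums(x) > 0L, , drop = FALSE]

#' Read an abundance table from TSV
#'
#' Expects a header row of sample ids, a first column of taxon ids, and
#' integer counts. Rejects (with the offending line or cell named) ragged
#' rows, duplicate taxa, and non-integer or negative cells rather than
#' coercing.
#'
#' @param path file path.
#' @return integer matrix, taxa as rows, samples as columns.
#' @export
read_abundance_tsv <- function(path) {
  if (!file.exists(path)) stop_pcg("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop_pcg(path, ": need a header and at least one taxon row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1L]])
  widths <- lengths(fields)
  if (any(widths != ncol_expected)) {
    stop_pcg(path, ": ragged row at line ",
             paste(which(widths != ncol_expected), collapse = ", "))
  }
  samples <- fields[[1L]][-1L]
  taxa <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(taxa)) {
    stop_pcg(path, ": duplicate taxon id at line ",
             paste(1L + which(duplicated(taxa)), collapse = ", "))
  }
  cells <- lapply(fields[-1L], function(f) f[-1L])
  num <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_along(num)) {
    v <- num[[i]]
    if (anyNA(v)) stop_pcg(path, ": non-numeric count at line ", i + 1L)
    if (any(v < 0)) stop_pcg(path, ": negative count at line ", i + 1L,
                             " (taxon ", taxa[i], ")")
    if (any(v != round(v))) stop_pcg(path, ": non-integer count at line ", i + 1L)
  }
  x <- do.call(rbind, num)
  dimnames(x) <- list(taxa, samples)
  validate_abundance(x)
}

#' Write an abundance table to TSV
#'
#' @param x integer matrix, taxa as rows, samples as columns.
#' @param path output file path.
#' @export
write_abundance_tsv <- function(x, path) {
  validate_abundance(x)
  header <- paste(c("taxon", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], x[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
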