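#' Construct a count table
#'
#' A count table is a nonnegative integer gene-by-sample matrix with per-gene
#' spike-in flags (ERCC species are sequenced alongside plant genes but are
#' handled separately by every normalization).
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param spike optional logical vector per gene; derived from gene-id
#'   prefixes when `NULL`.
#' @return list of class \code{"count_table"} with elements \code{counts}
#'   (integer matrix) and \code{spike} (named logical).
#' @export
count_table <- function(counts, spike = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative")
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"  # avoid integer overflow in sums
  if (is.null(spike)) {
    spike <- grepl("^ERCC-", toupper(rownames(counts)))
  }
  stopifnot(length(spike) == nrow(counts))
  names(spike) <- rownames(counts)
  structure(list(counts = counts, spike = spike), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$spike), "spike species )\n")
  invisible(x)
}

#' Read count data
#'
#' `read_counts_matrix` reads a merged matrix TSV (first column gene ids, one
#' column per sample). `read_counts_htseq` reads one or more two-column
#' per-sample files in HTSeq-count format; the special counters appended by
#' HTSeq (rows whose id starts with `__`, e.g. `__no_feature`) are dropped,
#' with their totals reported in the `dropped` attribute.
#'
#' @param path TSV file (matrix reader).
#' @param paths named character vector of per-sample files; names become
#'   sample ids (HTSeq reader).
#' @return a [count_table()].
#' @export
read_counts_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  gene_id <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- gene_id
  drop_special(m)
}

#' @rdname read_counts_matrix
#' @export
read_counts_htseq <- function(paths) {
  stopifnot(length(paths) >= 1L, !is.null(names(paths)),
            all(nzchar(names(paths))))
  cols <- lapply(paths, function(p) {
    tab <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    stats::setNames(tab[[2L]], tab[[1L]])
  })
  genes <- names(cols[[1L]])
  for (x in cols[-1L]) {
    if (!identical(names(x), genes)) stop("sample files disagree on gene ids")
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(paths)
  drop_special(m)
}

drop_special <- function(m) {
  special <- grepl("^__", rownames(m))
  dropped <- if (any(special)) colSums(m[special, , drop = FALSE]) else NULL
  if (any(special)) {
    message("dropped ", sum(special), " HTSeq special counter row(s); ",
            "per-sample totals recorded in attr 'dropped'")
  }
  ct <- count_table(m[!special, , drop = FALSE])
  attr(ct, "dropped") <- dropped
  ct
}

#' Read and validate sample metadata
#'
#' @param path TSV with columns \code{sample_id}, \code{organ} (sepal/leaf),
#'   \code{ploidy} (2C/4C/8C), \code{replicate} and optionally
#'   \code{rna_per_dna} (ug total RNA per ug DNA) and \code{spike_mix}.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_meta
#' @param meta a data.frame to validate in place.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "organ", "ploidy", "replicate")
  stopifnot(all(need %in% names(meta)))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  stopifnot(all(meta$organ %in% c("sepal", "leaf")),
            all(meta$ploidy %in% c("2C", "4C", "8C")),
            all(meta$replicate >= 1))
  if (anyDuplicated(meta[, c("organ", "ploidy", "replicate")])) {
    stop("(organ, ploidy, replicate) must be unique")
  }
  if ("rna_per_dna" %in% names(meta)) {
    ok <- is.na(meta$rna_per_dna) | meta$rna_per_dna > 0
    if (!all(ok)) stop("rna_per_dna must be positive where present")
  }
  meta
}
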