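#' Transcripts per million from gene-level counts
#'
#' TPM is computed as reads per kilobase (RPK: read count divided by
#' exon-union gene length in kb), rescaled so each sample's non-spike RPK
#' values sum to one million: \eqn{TPM_g = RPK_g / (\sum RPK / 10^6)}.
#' Spike-in rows are carried through against the same per-sample denominator
#' but are excluded from the denominator sum, so plant TPMs remain comparable
#' between samples with different spike fractions.
#'
#' @param counts a [count_table()].
#' @param lengths named numeric vector of lengths in kb, or an
#'   [annotation_set()] (its \code{length_kb} column is used). Every
#'   non-spike gene must have a positive length; spike species without a
#'   length default to 1 kb (their absolute TPM scale is never interpreted).
#' @return an \code{expression_table}: list with \code{values} (gene x
#'   sample matrix), \code{spike} flags and \code{basis = "tpm"}.
#' @export
compute_tpm <- function(counts, lengths) {
  .expression_from_counts(counts, lengths, basis = "tpm")
}

.get_lengths <- function(counts, lengths) {
  if (inherits(lengths, "annotation_set")) {
    lengths <- stats::setNames(lengths$length_kb, lengths$gene_id)
  }
  gene_id <- rownames(counts$counts)
  len <- lengths[gene_id]
  no_len <- is.na(len) | len <= 0
  if (any(no_len & !counts$spike)) {
    stop("missing/nonpositive length for non-spike gene(s): ",
         paste(utils::head(gene_id[no_len & !counts$spike], 3),
               collapse = ", "))
  }
  len[no_len] <- 1
  stats::setNames(as.numeric(len), gene_id)
}

.expression_from_counts <- function(counts, lengths, basis) {
  stopifnot(inherits(counts, "count_table"))
  len <- .get_lengths(counts, lengths)
  rpk <- counts$counts / len
  plant <- !counts$spike
  if (basis == "tpm") {
    denom <- colSums(rpk[plant, , drop = FALSE])
    if (any(denom <= 0)) {
      stop("all-zero non-spike counts in sample(s): ",
           paste(colnames(counts$counts)[denom <= 0], collapse = ", "))
    }
  } else {
    denom <- colSums(counts$counts[counts$spike, , drop = FALSE])
    if (any(denom <= 0)) {
      stop("zero spike reads in sample(s): ",
           paste(colnames(counts$counts)[denom <= 0], collapse = ", "))
    }
  }
  values <- sweep(rpk, 2L, denom / 1e6, "/")
  structure(list(values = values, spike = counts$spike, basis = basis),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table (basis =", x$basis, "):", nrow(x$values),
      "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' Write / read an expression table as TSV
#'
#' The basis (\code{tpm} or \code{per_genome}) is stored in a one-line
#' \code{# basis=} header comment.
#' @param expr an expression_table.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# basis=", expr$basis), con)
  tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  basis <- sub("^# basis=", "", first)
  if (identical(basis, first)) stop("missing '# basis=' header in ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, skip = 1L,
                           check.names = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  spike <- grepl("^ERCC-", toupper(rownames(values)))
  names(spike) <- rownames(values)
  structure(list(values = values, spike = spike, basis = basis),
            class = "expression_table")
}

#' Replicate-mean expression per cytotype
#'
#' Averages expression across the biological replicates of each cytotype
#' (organ x ploidy combination), giving one column per cytotype.
#'
#' @param expr an expression_table.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param cytotypes optional character vector of "organ_ploidy" labels to
#'   keep, e.g. \code{"sepal_2C"}; all present by default.
#' @return numeric matrix, genes x cytotypes, with the input's basis kept in
#'   attribute \code{"basis"}.
#' @export
mean_expression <- function(expr, meta, cytotypes = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  meta <- validate_sample_meta(meta)
  meta <- meta[meta$sample_id %in% colnames(expr$values), , drop = FALSE]
  grp <- paste(meta$organ, meta$ploidy, sep = "_")
  if (is.null(cytotypes)) cytotypes <- unique(grp)
  missing <- setdiff(cytotypes, grp)
  if (length(missing)) {
    stop("cytotype(s) absent from data: ", paste(missing, collapse = ", "))
  }
  out <- vapply(cytotypes, function(ct) {
    s <- meta$sample_id[grp == ct]
    rowMeans(expr$values[, s, drop = FALSE])
  }, numeric(nrow(expr$values)))
  dimnames(out) <- list(rownames(expr$values), cytotypes)
  attr(out, "basis") <- expr$basis
  out
}

#' Per-gene expression ratios between two cytotypes
#'
#' Forms, for each gene, the ratio of replicate-mean expression in a
#' numerator cytotype over a denominator cytotype (e.g. tetraploid/diploid),
#' attaching the gene's genome, targeting class and interaction tier. Genes
#' whose mean is not above `min_mean` in both cytotypes are excluded (no
#' pseudocount), so all ratios are finite and positive.
#'
#' @param means matrix from [mean_expression()] (or two named vectors via
#'   `meanA`/`meanB`).
#' @param num,den column names (cytotypes) for numerator and denominator.
#' @param ann an [annotation_set()]; genes absent from it are labelled by
#'   prefix classification with targeting unknown.
#' @param min_mean exclusion threshold on both means (default 0: any gene
#'   with zero mean in either cytotype is dropped).
#' @param exclude optional gene ids removed before forming ratios.
#' @return data.frame with columns \code{gene_id, ratio, genome, targeting,
#'   tier, complex_id}.
#' @export
tpm_ratio <- function(means, num, den, ann = NULL, min_mean = 0,
                      exclude = NULL) {
  stopifnot(is.matrix(means), all(c(num, den) %in% colnames(means)))
  a <- means[, num]
  b <- means[, den]
  spike <- grepl("^ERCC-", toupper(rownames(means)))
  keep <- a > min_mean & b > min_mean & !spike
  if (!is.null(exclude)) keep <- keep & !(rownames(means) %in% exclude)
  gene_id <- rownames(means)[keep]
  out <- data.frame(gene_id = gene_id, ratio = a[keep] / b[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(ann)) {
    out$genome <- suppressWarnings(classify_genome(gene_id))
    out$targeting <- ifelse(out$genome == "nuclear", "unknown",
                            "not_applicable")
    out$tier <- "none"
    out$complex_id <- NA_character_
  } else {
    idx <- match(gene_id, ann$gene_id)
    if (anyNA(idx)) {
      stop(sum(is.na(idx)), " ratio gene(s) missing from annotation")
    }
    out$genome <- ann$genome[idx]
    out$targeting <- ann$targeting[idx]
    out$tier <- ann$tier[idx]
    out$complex_id <- ann$complex_id[idx]
  }
  out
}
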