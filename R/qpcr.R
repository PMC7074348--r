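#' Construct a qPCR plate
#'
#' A plate couples well-level quantification cycles (Cq) with gene roles
#' (one or more targets, at least two nuclear reference genes) and sample
#' ploidy metadata. Cq is the cycle at which amplification crosses
#' threshold; template quantity is proportional to efficiency^(-Cq).
#'
#' @param wells data.frame with columns \code{gene_id}, \code{sample_id},
#'   \code{role} ("target"/"reference"), \code{Cq}.
#' @param meta data.frame with columns \code{sample_id}, \code{ploidy},
#'   \code{replicate}.
#' @param efficiency amplification factor per cycle, in (1, 2]; 2 means
#'   perfect doubling.
#' @return list of class \code{"qpcr_plate"}.
#' @export
qpcr_plate <- function(wells, meta, efficiency = 2) {
  stopifnot(all(c("gene_id", "sample_id", "role", "Cq") %in% names(wells)),
            all(c("sample_id", "ploidy", "replicate") %in% names(meta)),
            all(wells$role %in% c("target", "reference")),
            all(wells$Cq > 0), all(is.finite(wells$Cq)))
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  refs <- unique(wells$gene_id[wells$role == "reference"])
  if (length(refs) < 2L) stop("need at least 2 reference genes")
  # every sample must carry every reference
  for (s in unique(wells$sample_id)) {
    have <- wells$gene_id[wells$sample_id == s & wells$role == "reference"]
    if (!all(refs %in% have)) {
      stop("sample ", s, " is missing reference well(s)")
    }
  }
  stopifnot(all(wells$sample_id %in% meta$sample_id))
  structure(list(wells = wells, meta = meta, efficiency = efficiency,
                 references = refs),
            class = "qpcr_plate")
}

#' Read a qPCR plate from TSV
#' @param path wells TSV (gene_id, sample_id, role, Cq) ...
#' @param meta_path ... and sample metadata TSV (sample_id, ploidy,
#'   replicate).
#' @param efficiency see [qpcr_plate()].
#' @export
read_qpcr_plate <- function(path, meta_path, efficiency = 2) {
  qpcr_plate(utils::read.delim(path, stringsAsFactors = FALSE),
             utils::read.delim(meta_path, stringsAsFactors = FALSE),
             efficiency = efficiency)
}

#' Relative copy number by delta-delta-Cq
#'
#' Estimates the fold change of a target locus between two ploidies,
#' normalized to the geometric mean of the reference genes. On the Cq scale
#' the geometric mean of reference quantities is the arithmetic mean of
#' reference Cq values, so per replicate
#' \eqn{\Delta Cq = Cq_{target} - mean(Cq_{refs})}, and for a replicate pair
#' \eqn{fold = efficiency^{-(\Delta Cq_A - \Delta Cq_B)}}. Replicates are
#' paired by replicate index across the two ploidies; with unequal replicate
#' counts the mean-\eqn{\Delta Cq}-per-ploidy form is used (a single fold,
#' SE = NA). The mean fold across pairs and its standard error are returned.
#'
#' @param plate a [qpcr_plate()].
#' @param target target gene id.
#' @param pair character length-2: (numerator ploidy, denominator ploidy),
#'   e.g. \code{c("4C", "2C")} for the tetraploid/diploid fold.
#' @return list with \code{fold}, \code{se}, \code{n} (replicate pairs),
#'   \code{folds} (per pair).
#' @export
relative_copy_number <- function(plate, target, pair = c("4C", "2C")) {
  stopifnot(inherits(plate, "qpcr_plate"), length(pair) == 2L)
  w <- plate$wells
  if (!target %in% w$gene_id[w$role == "target"]) {
    stop("target ", target, " not on plate")
  }
  dcq_for <- function(ploidy) {
    samples <- plate$meta[plate$meta$ploidy == ploidy, , drop = FALSE]
    if (nrow(samples) == 0L) stop("no samples at ploidy ", ploidy)
    samples <- samples[order(samples$replicate), , drop = FALSE]
    vapply(samples$sample_id, function(s) {
      tw <- w$Cq[w$sample_id == s & w$gene_id == target]
      if (length(tw) != 1L) stop("target well missing for sample ", s)
      rw <- w$Cq[w$sample_id == s & w$role == "reference"]
      tw - mean(rw)
    }, numeric(1))
  }
  dA <- dcq_for(pair[1L])
  dB <- dcq_for(pair[2L])
  e <- plate$efficiency
  if (length(dA) == length(dB)) {
    folds <- e^(-(dA - dB))
    se <- if (length(folds) > 1L) {
      stats::sd(folds) / sqrt(length(folds))
    } else NA_real_
    list(fold = mean(folds), se = se, n = length(folds), folds = folds)
  } else {
    fold <- e^(-(mean(dA) - mean(dB)))
    list(fold = fold, se = NA_real_, n = c(length(dA), length(dB)),
         folds = fold)
  }
}
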