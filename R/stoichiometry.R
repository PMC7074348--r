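#' Fraction of nuclear transcription devoted to a targeting class
#'
#' Per sample: summed read counts of nuclear genes in one targeting class
#' divided by summed read counts of all nuclear genes. Organelle-encoded and
#' spike rows are excluded from both sums, so the five class fractions
#' (plastid, mitochondrion, dual, other, unknown) partition 1 exactly.
#'
#' @param counts a [count_table()].
#' @param ann an [annotation_set()] covering the count genes.
#' @param class targeting class label.
#' @param samples optional sample ids (default all).
#' @return named numeric vector of fractions per sample.
#' @export
targeted_fraction <- function(counts, ann, class, samples = NULL) {
  stopifnot(class %in% setdiff(.targeting_levels, "not_applicable"))
  sel <- .sample_sel(counts, samples)
  idx <- match(rownames(counts$counts), ann$gene_id)
  if (anyNA(idx)) stop("count gene(s) missing from annotation")
  nuc <- ann$genome[idx] == "nuclear"
  in_class <- nuc & ann$targeting[idx] == class
  tot <- colSums(counts$counts[nuc, sel, drop = FALSE])
  if (any(tot <= 0)) {
    stop("zero nuclear reads in sample(s): ",
         paste(sel[tot <= 0], collapse = ", "))
  }
  colSums(counts$counts[in_class, sel, drop = FALSE]) / tot
}

.sample_sel <- function(counts, samples) {
  if (is.null(samples)) return(colnames(counts$counts))
  stopifnot(all(samples %in% colnames(counts$counts)))
  samples
}

#' Bulk organelle-to-nuclear transcription ratio
#'
#' Per sample: summed read counts of genes encoded in one organelle genome
#' divided by summed read counts of all nuclear genes.
#'
#' @inheritParams targeted_fraction
#' @param genome \code{"plastid"} or \code{"mitochondrion"}.
#' @return named numeric vector per sample.
#' @export
organelle_nuclear_ratio <- function(counts, ann, genome, samples = NULL) {
  stopifnot(genome %in% c("plastid", "mitochondrion"))
  sel <- .sample_sel(counts, samples)
  idx <- match(rownames(counts$counts), ann$gene_id)
  if (anyNA(idx)) stop("count gene(s) missing from annotation")
  org <- ann$genome[idx] == genome
  nuc <- ann$genome[idx] == "nuclear"
  tot <- colSums(counts$counts[nuc, sel, drop = FALSE])
  if (any(tot <= 0)) {
    stop("zero nuclear reads in sample(s): ",
         paste(sel[tot <= 0], collapse = ", "))
  }
  colSums(counts$counts[org, sel, drop = FALSE]) / tot
}

#' Cytonuclear balance ratio
#'
#' Per sample: summed read counts of organelle-encoded genes divided by
#' summed read counts of the nuclear genes whose products are targeted to
#' that organelle. A balance ratio that is stable across ploidy levels
#' indicates coordinated transcription between the organelle genome and its
#' nuclear support genes. Dual-targeted genes enter the denominator only
#' when `include_dual = TRUE` (the "plus dual" panel variant).
#'
#' @inheritParams organelle_nuclear_ratio
#' @param include_dual include dual-targeted nuclear genes in the
#'   denominator.
#' @return named numeric vector per sample.
#' @export
balance_ratio <- function(counts, ann, genome, include_dual = FALSE,
                          samples = NULL) {
  stopifnot(genome %in% c("plastid", "mitochondrion"))
  sel <- .sample_sel(counts, samples)
  idx <- match(rownames(counts$counts), ann$gene_id)
  if (anyNA(idx)) stop("count gene(s) missing from annotation")
  org <- ann$genome[idx] == genome
  classes <- if (include_dual) c(genome, "dual") else genome
  targ <- ann$genome[idx] == "nuclear" & ann$targeting[idx] %in% classes
  tot <- colSums(counts$counts[targ, sel, drop = FALSE])
  if (any(tot <= 0)) {
    stop("zero targeted nuclear reads in sample(s): ",
         paste(sel[tot <= 0], collapse = ", "))
  }
  colSums(counts$counts[org, sel, drop = FALSE]) / tot
}

#' Per-gene TPM-ratio distributions grouped by genome of origin
#'
#' Like [tpm_ratio()], but the natural grouping downstream is the genome
#' (nuclear / plastid / mitochondrion). An exclusion list supports
#' sensitivity checks that drop individual dominant genes (e.g. the
#' mitochondrial 26S rRNA locus ATMG00020, which can account for over a
#' third of all mitochondrial reads).
#'
#' @inheritParams per_genome_ratio
#' @param expr an expression_table (basis tpm).
#' @param exclude optional gene ids to drop.
#' @return data.frame as [tpm_ratio()] (its \code{genome} column is the
#'   grouping key).
#' @export
genome_tpm_ratios <- function(expr, meta, ann, num, den, min_mean = 0,
                              exclude = NULL) {
  m <- mean_expression(expr, meta, cytotypes = c(num, den))
  tpm_ratio(m, num, den, ann = ann, min_mean = min_mean, exclude = exclude)
}

#' Coefficient of variation of expression ratios by interaction tier
#'
#' Summarizes how constrained each nested gene class is in its dosage
#' response. Classes (nested): \code{other} (non-organelle-targeted nuclear
#' genes), \code{targeted} (all organelle-targeted nuclear genes, any tier),
#' \code{complexed} (tier complexed or direct), \code{direct} (tier direct).
#' CV = sample standard deviation (n-1 denominator) of the per-gene ratios
#' divided by their mean; tighter cytonuclear constraint shows up as a
#' smaller CV.
#'
#' @param ratios data.frame from [tpm_ratio()] (needs columns ratio, genome,
#'   targeting, tier).
#' @return data.frame with columns \code{class}, \code{n_genes}, \code{cv};
#'   classes with fewer than 2 genes are omitted with a warning.
#' @export
cv_by_tier <- function(ratios) {
  nuc <- ratios[ratios$genome == "nuclear", , drop = FALSE]
  targeted <- nuc$targeting %in% c("plastid", "mitochondrion", "dual")
  sets <- list(
    other = nuc$ratio[nuc$targeting == "other"],
    targeted = nuc$ratio[targeted],
    complexed = nuc$ratio[targeted & nuc$tier %in% c("complexed", "direct")],
    direct = nuc$ratio[targeted & nuc$tier == "direct"]
  )
  keep <- vapply(sets, length, integer(1)) >= 2L
  if (!all(keep)) {
    warning("class(es) with <2 genes omitted: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- sets[keep]
  data.frame(class = names(sets),
             n_genes = vapply(sets, length, integer(1)),
             cv = vapply(sets, function(x) stats::sd(x) / mean(x),
                         numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression correlation across the subunits of a chimeric complex
#'
#' Pearson correlation of replicate-mean expression between two cytotypes
#' over the member genes of one protein complex, reported for all members
#' together and separately for the nuclear-encoded and organelle-encoded
#' subunits (when each side has at least 3 quantified members). High r with
#' subunits spanning a wide expression range indicates that all subunits
#' moved by a common factor, i.e. coordinated regulation across genomes.
#'
#' @param means matrix from [mean_expression()].
#' @param num,den cytotype column names.
#' @param members gene ids of the complex subunits.
#' @param ann an [annotation_set()] (for the nuclear/organellar split).
#' @return list with \code{r_all}, \code{n}, \code{r_nuclear},
#'   \code{n_nuclear}, \code{r_organellar}, \code{n_organellar} (subgroup r
#'   is NA when its side has <3 members).
#' @export
complex_correlation <- function(means, num, den, members, ann) {
  stopifnot(all(c(num, den) %in% colnames(means)))
  members <- intersect(members, rownames(means))
  if (length(members) < 3L) stop("need >= 3 quantified complex members")
  x <- means[members, den]
  y <- means[members, num]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate complex: zero expression variance across members")
  }
  genome <- ann$genome[match(members, ann$gene_id)]
  sub_r <- function(sel) {
    if (sum(sel) < 3L || stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[sel], y[sel])
  }
  nuc <- genome == "nuclear"
  list(r_all = stats::cor(x, y), n = length(members),
       r_nuclear = sub_r(nuc), n_nuclear = sum(nuc),
       r_organellar = sub_r(!nuc), n_organellar = sum(!nuc))
}
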