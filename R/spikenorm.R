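#' Transcriptome size: total RNA per unit of genomic DNA
#'
#' The RNA/DNA mass ratio of a co-extraction estimates the size of the total
#' RNA transcriptome per unit of DNA, the quantity that anchors proportional
#' spiking.
#'
#' @param rna_yield,dna_yield masses (ug) from the same co-extraction.
#' @return rna_yield / dna_yield.
#' @export
transcriptome_size <- function(rna_yield, dna_yield) {
  if (any(rna_yield <= 0) || any(dna_yield <= 0)) {
    stop("yields must be positive")
  }
  rna_yield / dna_yield
}

#' Spike-in mass for proportional spiking
#'
#' Spike RNA is added in proportion to the amount of genomic DNA associated
#' in planta with the RNA going into the library:
#' \eqn{spike = k \cdot rna\_mass / (rna\_per\_dna)}. A tissue yielding 19\%
#' more DNA per unit RNA therefore receives 19\% more spike at equal RNA
#' input, which makes downstream spike-normalized read counts proportional
#' to expression per genome copy.
#'
#' @param rna_mass ug of total RNA put into the library.
#' @param rna_per_dna ug RNA per ug DNA for that tissue
#'   ([transcriptome_size()]).
#' @param k proportionality constant (same arbitrary mass unit for all
#'   samples of one experiment).
#' @return spike mass, same units as `k`.
#' @export
spike_mass_for <- function(rna_mass, rna_per_dna, k = 1) {
  if (any(rna_mass <= 0) || any(rna_per_dna <= 0) || any(k <= 0)) {
    stop("all inputs must be positive")
  }
  k * rna_mass / rna_per_dna
}

#' Expression per genome copy via spike normalization
#'
#' Scales plant gene RPK values by the total spike-in read count of the same
#' library: \eqn{v_{g,s} = RPK_{g,s} / (\sum_{spike} c_{.,s}) \times 10^6}.
#' When spike RNA was added in proportion to genomic DNA
#' ([spike_mass_for()]), spike reads measure the DNA (genome copies)
#' underlying each library, so these values are comparable across samples as
#' expression per genome copy (arbitrary units; the 1e6 factor is cosmetic
#' and cancels from every ratio). Gene-length correction is applied before
#' spike scaling so per-gene ratios on this basis are directly comparable to
#' TPM-level ratios.
#'
#' @inheritParams compute_tpm
#' @return an \code{expression_table} with \code{basis = "per_genome"}.
#' @export
per_genome_expression <- function(counts, lengths) {
  .expression_from_counts(counts, lengths, basis = "per_genome")
}

#' Per-genome-copy expression ratios by targeting class
#'
#' Replicate-mean per-genome expression ratios between two ploidies,
#' carrying targeting class; the workhorse behind transcripts-per-genome
#' dosage-response comparisons.
#'
#' @param expr an expression_table with basis \code{per_genome}.
#' @param meta sample metadata.
#' @param ann an [annotation_set()].
#' @param num,den cytotype labels ("organ_ploidy"), numerator/denominator.
#' @param min_mean exclusion threshold as in [tpm_ratio()].
#' @return data.frame as [tpm_ratio()].
#' @export
per_genome_ratio <- function(expr, meta, ann, num, den, min_mean = 0) {
  stopifnot(inherits(expr, "expression_table"),
            identical(expr$basis, "per_genome"))
  m <- mean_expression(expr, meta, cytotypes = c(num, den))
  tpm_ratio(m, num, den, ann = ann, min_mean = min_mean)
}

#' Read a spike design table
#' @param path TSV with columns sample_id, rna_mass, rna_per_dna, spike_mass.
#' @return data.frame; an error if any mass is nonpositive.
#' @export
read_spike_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "rna_mass", "rna_per_dna", "spike_mass")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$rna_mass <= 0) || any(tab$rna_per_dna <= 0) ||
      any(tab$spike_mass <= 0)) {
    stop("spike design masses must be positive")
  }
  tab
}
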