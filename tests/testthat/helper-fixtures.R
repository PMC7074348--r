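# Shared fixtures and independent oracles. Oracles are deliberately naive
# (base-by-base, literal-formula, loop-based) so they cannot share a code
# path with the implementation they check.

# literal transcription of the TPM definition: reads per kilobase, then
# divide each RPK by (sum of non-spike RPK / 1e6)
oracle_tpm <- function(counts, lengths_kb, spike = rep(FALSE, nrow(counts))) {
  out <- counts
  for (s in seq_len(ncol(counts))) {
    rpk <- counts[, s] / lengths_kb
    denom <- sum(rpk[!spike]) / 1e6
    out[, s] <- rpk / denom
  }
  out
}

# base-by-base exon union length in kb
oracle_union_kb <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered) / 1000
}

# minimal Araport11-style GFF3 writer: genes is a list of lists with
# chrom, id and exons = list of per-isoform matrices (start, end)
write_toy_gff <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- if (length(g$exons)) {
      range(unlist(g$exons))
    } else {
      c(g$start, g$end)
    }
    lines <- c(lines, sprintf(
      "%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s", g$chrom, span[1L], span[2L],
      g$id))
    for (i in seq_along(g$exons)) {
      mrna <- sprintf("%s.%d", g$id, i)
      ex <- g$exons[[i]]
      lines <- c(lines, sprintf(
        "%s\ttest\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s", g$chrom,
        min(ex), max(ex), mrna, g$id))
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\ttest\texon\t%d\t%d\t.\t+\t.\tParent=%s", g$chrom,
          ex[k, 1L], ex[k, 2L], mrna))
      }
    }
  }
  writeLines(lines, path)
  path
}

toy_counts <- function(counts, lengths = NULL) {
  ct <- count_table(counts)
  list(ct = ct,
       lengths = lengths %||% stats::setNames(rep(1, nrow(counts)),
                                              rownames(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small/fast variant of the paper-calibrated preset for pipeline tests
fast_params <- function(...) {
  simulation_params(depth = 5e5, ...)
}

# noise-free null world: no dosage effects anywhere; override via ...
null_params <- function(...) {
  defaults <- list(
    dosage_multiplier = c(plastid = 1, mitochondrion = 1, dual = 1,
                          other = 1, unknown = 1),
    organelle_genome_response = c(plastid = 1, mitochondrion = 1),
    coordination_mode = c(plastid = "independent",
                          mitochondrion = "independent"),
    ratio_sd = c(other = 0, unknown = 0, none = 0, complexed = 0,
                 direct = 0),
    org_ratio_sd = 0, dispersion = 0, depth = 2e6)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

meta_for <- function(sim) sim$meta
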