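#' Classify genome of origin from a gene identifier
#'
#' Arabidopsis AGI locus identifiers encode the genome of origin in their
#' prefix: \code{ATCG} loci are plastid(chloroplast)-encoded, \code{ATMG}
#' loci are mitochondria-encoded, \code{AT1G}-\code{AT5G} loci are nuclear,
#' and \code{ERCC-} identifiers are exogenous spike-in species. Matching is
#' case-insensitive.
#'
#' @param gene_id character vector of locus identifiers.
#' @return character vector with elements in
#'   \code{c("nuclear", "plastid", "mitochondrion", "spike")}.
#'   Unrecognized prefixes are classified as \code{"nuclear"} with a warning.
#' @examples
#' classify_genome(c("ATCG00490", "ATMG00020", "AT1G69960", "ERCC-00002"))
#' @export
classify_genome <- function(gene_id) {
  stopifnot(is.character(gene_id), all(nzchar(gene_id)))
  id <- toupper(gene_id)
  out <- rep(NA_character_, length(id))
  out[grepl("^ATCG", id)] <- "plastid"
  out[grepl("^ATMG", id)] <- "mitochondrion"
  out[grepl("^AT[1-5]G", id)] <- "nuclear"
  out[grepl("^ERCC-", id)] <- "spike"
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sum(unknown), " gene id(s) with unrecognized prefix classified ",
            "as nuclear (e.g. ", gene_id[which(unknown)[1L]], ")")
    out[unknown] <- "nuclear"
  }
  out
}

.targeting_levels <- c("plastid", "mitochondrion", "dual", "other",
                       "unknown", "not_applicable")
.tier_levels <- c("none", "complexed", "direct")

#' Construct an annotation set
#'
#' An annotation set is a data frame with one row per gene carrying genome of
#' origin, exon-union length (kb), organelle-targeting class, cytonuclear
#' interaction tier and optional protein-complex membership. Nuclear genes
#' are classified by where their protein product is targeted
#' (plastid / mitochondrion / dual / other / unknown); organelle-encoded and
#' spike-in genes carry \code{targeting = "not_applicable"}. Interaction
#' tiers are nested: genes whose products physically contact
#' organelle-encoded molecules (\code{direct}) are a subset of genes in
#' chimeric complexes or other interactions (\code{complexed}), themselves a
#' subset of organelle-targeted genes.
#'
#' @param gene_id character vector, unique.
#' @param length_kb positive numeric, exon-union length in kilobases.
#' @param genome optional; derived from `gene_id` prefixes when `NULL`.
#' @param targeting,tier,complex_id per-gene classification columns;
#'   defaults: nuclear genes \code{unknown}/\code{none}, others
#'   \code{not_applicable}/\code{none}.
#' @param provenance optional character scalar recorded as an attribute.
#' @return a data.frame of class \code{"annotation_set"} with columns
#'   \code{gene_id, genome, length_kb, targeting, tier, complex_id}.
#' @export
annotation_set <- function(gene_id, length_kb, genome = NULL,
                           targeting = NULL, tier = NULL, complex_id = NULL,
                           provenance = NA_character_) {
  stopifnot(is.character(gene_id), !anyDuplicated(gene_id))
  n <- length(gene_id)
  length_kb <- as.numeric(length_kb)
  stopifnot(length(length_kb) == n, all(is.finite(length_kb)),
            all(length_kb > 0))
  if (is.null(genome)) genome <- classify_genome(gene_id)
  stopifnot(length(genome) == n)
  if (is.null(targeting)) {
    targeting <- ifelse(genome == "nuclear", "unknown", "not_applicable")
  }
  if (is.null(tier)) tier <- rep("none", n)
  if (is.null(complex_id)) complex_id <- rep(NA_character_, n)
  ann <- data.frame(gene_id = gene_id, genome = genome,
                    length_kb = length_kb, targeting = targeting,
                    tier = tier, complex_id = complex_id,
                    stringsAsFactors = FALSE, row.names = NULL)
  validate_annotation(ann)
  attr(ann, "provenance") <- provenance
  class(ann) <- c("annotation_set", "data.frame")
  ann
}

validate_annotation <- function(ann) {
  stopifnot(all(ann$genome %in% c("nuclear", "plastid", "mitochondrion",
                                  "spike")),
            all(ann$targeting %in% .targeting_levels),
            all(ann$tier %in% .tier_levels))
  bad <- ann$genome != "nuclear" & ann$targeting != "not_applicable"
  if (any(bad)) {
    stop("non-nuclear genes must have targeting = not_applicable: ",
         ann$gene_id[which(bad)[1L]])
  }
  bad <- ann$genome == "spike" & ann$tier != "none"
  if (any(bad)) stop("spike genes must have tier = none")
  # tiered interaction only meaningful for organelle-targeted nuclear genes
  bad <- ann$genome == "nuclear" & ann$tier != "none" &
    !(ann$targeting %in% c("plastid", "mitochondrion", "dual"))
  if (any(bad)) {
    stop("interaction tier '", ann$tier[which(bad)[1L]],
         "' requires organelle targeting for nuclear gene ",
         ann$gene_id[which(bad)[1L]])
  }
  invisible(ann)
}

#' Cumulative interaction-tier gene counts
#'
#' Tier membership is nested (direct genes are also complexed; complexed
#' genes are also organelle-targeted), so counts are reported cumulatively.
#'
#' @param ann an annotation_set.
#' @return named integer vector \code{c(targeted, complexed, direct)} over
#'   nuclear genes.
#' @export
tier_counts <- function(ann) {
  nuc <- ann[ann$genome == "nuclear", ]
  targeted <- nuc$targeting %in% c("plastid", "mitochondrion", "dual")
  c(targeted = sum(targeted),
    complexed = sum(targeted & nuc$tier %in% c("complexed", "direct")),
    direct = sum(targeted & nuc$tier == "direct"))
}

#' Gene lengths and chromosomes from a GFF3 annotation
#'
#' Computes, for every gene feature, the exon-union length: the total number
#' of bases covered by at least one exon of any isoform, in kilobases. This
#' is the length convention matching gene-level counting (a read anywhere in
#' any exon is counted for the gene). Genes with no exon features fall back
#' to the gene-span length with a warning. Chromosome names ChrC / ChrM mark
#' the plastid and mitochondrial genomes and are used as a classification
#' fallback for identifiers with unrecognized prefixes.
#'
#' @param path a GFF3 file (Araport11-style: gene/mRNA/exon features with
#'   ID/Parent attributes).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{length_kb}.
#' @export
load_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gene_id <- as.character(genes$ID)
  # map transcript-level features to their parent gene
  tx <- gr[type %in% c("mRNA", "transcript", "tRNA", "rRNA", "ncRNA",
                       "snoRNA", "snRNA", "miRNA")]
  tx2gene <- structure(vapply(tx$Parent, function(p) p[1L], character(1)),
                       names = as.character(tx$ID))
  exons <- gr[type == "exon"]
  exon_parent <- vapply(exons$Parent, function(p) p[1L], character(1))
  # exon Parent may point at a transcript or directly at the gene
  exon_gene <- ifelse(exon_parent %in% names(tx2gene),
                      tx2gene[exon_parent], exon_parent)
  keep <- exon_gene %in% gene_id
  union_bp <- rep(NA_real_, length(gene_id))
  names(union_bp) <- gene_id
  if (any(keep)) {
    by_gene <- GenomicRanges::split(
      IRanges::ranges(exons[keep]), factor(exon_gene[keep]))
    w <- sum(IRanges::width(IRanges::reduce(by_gene)))
    union_bp[names(w)] <- as.numeric(w)
  }
  missing <- is.na(union_bp)
  if (any(missing)) {
    warning(sum(missing), " gene(s) without exon features; using gene-span ",
            "length (e.g. ", gene_id[which(missing)[1L]], ")")
    union_bp[missing] <- as.numeric(GenomicRanges::width(genes)[missing])
  }
  data.frame(gene_id = gene_id,
             chrom = as.character(GenomicRanges::seqnames(genes)),
             length_kb = union_bp / 1000,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an organelle-targeting / interaction-tier table
#'
#' Reads a tab-separated classification table in the style of curated
#' cytonuclear-interaction databases: one row per nuclear gene with its
#' organelle-targeting class, interaction tier and optional complex label.
#'
#' @param path TSV with header columns \code{gene_id}, \code{targeting},
#'   \code{tier} and optionally \code{complex}.
#' @return data.frame with columns gene_id, targeting, tier, complex_id.
#' @export
load_targeting <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  need <- c("gene_id", "targeting", "tier")
  if (!all(need %in% names(tab))) {
    stop("targeting table must have columns gene_id, targeting, tier")
  }
  if (!"complex" %in% names(tab)) tab$complex <- NA_character_
  ok_t <- tab$targeting %in% setdiff(.targeting_levels, "not_applicable")
  if (!all(ok_t)) {
    i <- which(!ok_t)[1L]
    stop("unknown targeting class '", tab$targeting[i], "' at row ", i)
  }
  ok_r <- tab$tier %in% .tier_levels
  if (!all(ok_r)) {
    i <- which(!ok_r)[1L]
    stop("unknown tier '", tab$tier[i], "' at row ", i)
  }
  bad <- tab$tier != "none" &
    !(tab$targeting %in% c("plastid", "mitochondrion", "dual"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("tier '", tab$tier[i], "' with targeting '", tab$targeting[i],
         "' at row ", i, ": interaction tiers require organelle targeting")
  }
  cx <- as.character(tab$complex)
  cx[!nzchar(cx) | is.na(cx)] <- NA_character_
  data.frame(gene_id = tab$gene_id, targeting = tab$targeting,
             tier = tab$tier, complex_id = cx,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble an annotation set from GFF3 lengths and a targeting table
#'
#' Genome of origin comes from the gene-id prefix, with the GFF3 chromosome
#' (ChrC -> plastid, ChrM -> mitochondrion) as fallback for unrecognized
#' prefixes; the prefix wins on conflict. Genes absent from the targeting
#' table default to \code{targeting = "unknown"}, \code{tier = "none"}.
#'
#' @param lengths data.frame from [load_gff3()] (or with the same columns).
#' @param targeting optional data.frame from [load_targeting()].
#' @param provenance optional character scalar.
#' @return an [annotation_set()].
#' @export
build_annotation <- function(lengths, targeting = NULL,
                             provenance = NA_character_) {
  stopifnot(all(c("gene_id", "length_kb") %in% names(lengths)))
  genome <- withCallingHandlers(
    classify_genome(lengths$gene_id),
    warning = function(w) invokeRestart("muffleWarning"))
  if ("chrom" %in% names(lengths)) {
    # fallback for ids whose prefix carries no genome information
    prefix_known <- grepl("^(ATCG|ATMG|AT[1-5]G|ERCC-)",
                          toupper(lengths$gene_id))
    genome[!prefix_known & lengths$chrom == "ChrC"] <- "plastid"
    genome[!prefix_known & lengths$chrom == "ChrM"] <- "mitochondrion"
  }
  targ <- ifelse(genome == "nuclear", "unknown", "not_applicable")
  tier <- rep("none", nrow(lengths))
  cx <- rep(NA_character_, nrow(lengths))
  if (!is.null(targeting)) {
    idx <- match(lengths$gene_id, targeting$gene_id)
    hit <- !is.na(idx) & genome == "nuclear"
    targ[hit] <- targeting$targeting[idx[hit]]
    tier[hit] <- targeting$tier[idx[hit]]
    cx[hit] <- targeting$complex_id[idx[hit]]
  }
  annotation_set(lengths$gene_id, lengths$length_kb, genome = genome,
                 targeting = targ, tier = tier, complex_id = cx,
                 provenance = provenance)
}

#' Write / read an annotation set as TSV (lossless round trip)
#' @param ann an annotation_set.
#' @param path file path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_set(tab$gene_id, tab$length_kb, genome = tab$genome,
                 targeting = tab$targeting, tier = tab$tier,
                 complex_id = as.character(tab$complex_id),
                 provenance = path)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x), "genes\n")
  print(table(genome = x$genome))
  nuc <- x[x$genome == "nuclear", ]
  if (nrow(nuc)) print(table(targeting = nuc$targeting))
  invisible(x)
}
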