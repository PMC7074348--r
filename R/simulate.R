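#' Simulation parameters for the tri-genome experiment generator
#'
#' The defaults constitute the \code{paper_calibrated} preset: a scaled-down
#' Arabidopsis-like world with three genomes of very different gene counts
#' and expression scales, an organelle-targeting / interaction-tier
#' structure over nuclear genes, ploidy-dependent organelle genome copy
#' numbers (plastid 0.76 and mitochondrion 1.01 per nuclear genome at 4C vs
#' 2C), class-specific dosage multipliers, tier-coupled ratio noise (which
#' produces the direct < complexed < targeted < other CV ordering), ERCC
#' spike reads proportional to nuclear genome copies, and gamma-multinomial
#' (negative-binomial-like) counting noise at fixed library size.
#'
#' @param n_nuclear_genes,n_plastid_genes,n_mito_genes,n_spike_species gene
#'   and spike-species counts per genome.
#' @param class_proportions targeting-class mix over nuclear genes (sums to
#'   1).
#' @param tier_proportions interaction-tier mix within organelle-targeted
#'   nuclear genes (sums to 1).
#' @param rate_meanlog,rate_sdlog log-normal base-rate parameters per
#'   genome; organellar rates are per genome copy.
#' @param length_meanlog,length_sdlog log-normal exon-union lengths (kb).
#' @param ploidy_levels subset of \code{c("2C","4C","8C")}, must include
#'   "2C".
#' @param reps_per_ploidy biological replicates per cytotype (3-4 typical).
#' @param organ tissue label for the metadata.
#' @param organelle_copies_2c organelle genome copies per cell in the
#'   diploid.
#' @param organelle_genome_response organelle genome copies per NUCLEAR
#'   genome at 4C relative to 2C (extrapolated log-linearly per further
#'   doubling).
#' @param dosage_multiplier mean 4C/2C per-genome-copy transcription
#'   multiplier per targeting class.
#' @param ratio_sd log-scale sd of the per-gene 4C/2C ratio noise, per
#'   ratio class (\code{other}, \code{unknown}, and tiers \code{none},
#'   \code{complexed}, \code{direct} for targeted genes).
#' @param tier_coupling fraction of the ratio variance shared across each
#'   tier (higher coupling, lower across-gene CV).
#' @param org_ratio_sd log-scale sd of per-gene ratio noise for organellar
#'   genes.
#' @param coordination_mode \code{plastid = "coordinated"} ties total
#'   plastid-genome output to the realized bulk 4C/2C ratio of the nuclear
#'   genes targeted to the plastid (balance ratio stable by construction);
#'   \code{mitochondrion = "boosted"} scales mito-genome output with its
#'   genome copy number times \code{mito_boost}. Either may be
#'   \code{"independent"} (output follows genome copies only).
#' @param mito_boost per-doubling transcriptional boost of the mitochondrial
#'   genome under mode "boosted".
#' @param dispersion gamma (negative-binomial-like) overdispersion; 0 gives
#'   pure multinomial counting noise.
#' @param depth reads per library.
#' @param spike_fraction fraction of diploid-library reads from spikes.
#' @param spike_meanlog,spike_sdlog log-normal abundance spread across spike
#'   species.
#' @param rna_per_dna_2c unit scale (ug RNA per ug DNA) of the diploid
#'   transcriptome size; other ploidies derive from the model's own pools.
#' @param qpcr_noise_sd sd (cycles) of Cq measurement noise
#'   (technical-replicate-averaged).
#' @param qpcr_efficiency amplification factor per cycle.
#' @param complexes named list; each element gives subunit counts per genome
#'   for one chimeric (or all-nuclear) complex, e.g.
#'   \code{list(nuclear = 8, plastid = 4)}.
#' @param seed default RNG seed for the generator.
#' @return validated list of class \code{"simulation_params"}.
#' @export
simulation_params <- function(
    n_nuclear_genes = 6000, n_plastid_genes = 80, n_mito_genes = 120,
    n_spike_species = 92,
    class_proportions = c(plastid = 0.10, mitochondrion = 0.06, dual = 0.02,
                          other = 0.62, unknown = 0.20),
    tier_proportions = c(none = 0.787, complexed = 0.177, direct = 0.036),
    rate_meanlog = c(nuclear = 1.0, plastid = -2.4, mitochondrion = -2.8),
    rate_sdlog = c(nuclear = 1.2, plastid = 1.0, mitochondrion = 1.0),
    length_meanlog = 0.4, length_sdlog = 0.6,
    ploidy_levels = c("2C", "4C"), reps_per_ploidy = 3, organ = "sepal",
    organelle_copies_2c = c(plastid = 500, mitochondrion = 50),
    organelle_genome_response = c(plastid = 0.76, mitochondrion = 1.01),
    dosage_multiplier = c(plastid = 0.85, mitochondrion = 1.05,
                          dual = 0.95, other = 1.10, unknown = 1.10),
    ratio_sd = c(other = 0.55, unknown = 0.55, none = 0.40,
                 complexed = 0.25, direct = 0.02),
    tier_coupling = c(none = 0.3, complexed = 0.6, direct = 0.9),
    org_ratio_sd = 0.05,
    coordination_mode = c(plastid = "coordinated",
                          mitochondrion = "boosted"),
    mito_boost = 1.5,
    dispersion = 0.05, depth = 5e6, spike_fraction = 0.02,
    spike_meanlog = 0, spike_sdlog = 2,
    rna_per_dna_2c = 10,
    qpcr_noise_sd = 0.05, qpcr_efficiency = 2,
    complexes = list(
      RUBISCO = list(nuclear = 4, plastid = 1),
      PSII = list(nuclear = 8, plastid = 4),
      OXPHOS_III = list(nuclear = 9, mitochondrion = 1),
      OXPHOS_II = list(nuclear = 4)),
    seed = 1) {
  p <- as.list(environment())
  validate_params(p)
  class(p) <- "simulation_params"
  p
}

validate_params <- function(p) {
  stopifnot(p$n_nuclear_genes > 0, p$n_plastid_genes > 0,
            p$n_mito_genes > 0, p$n_spike_species > 0,
            p$reps_per_ploidy >= 1, p$depth > 0, p$dispersion >= 0,
            p$spike_fraction > 0, p$spike_fraction < 1,
            p$rna_per_dna_2c > 0, p$qpcr_noise_sd >= 0,
            p$qpcr_efficiency > 1, p$qpcr_efficiency <= 2,
            p$mito_boost > 0, p$org_ratio_sd >= 0)
  if (abs(sum(p$class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1")
  }
  if (abs(sum(p$tier_proportions) - 1) > 1e-8) {
    stop("tier_proportions must sum to 1")
  }
  stopifnot(all(c("plastid", "mitochondrion", "dual", "other", "unknown")
                %in% names(p$class_proportions)),
            all(c("none", "complexed", "direct")
                %in% names(p$tier_proportions)),
            "2C" %in% p$ploidy_levels,
            all(p$ploidy_levels %in% c("2C", "4C", "8C")),
            all(p$organelle_genome_response > 0),
            all(p$dosage_multiplier > 0),
            all(p$tier_coupling >= 0), all(p$tier_coupling <= 1),
            all(p$coordination_mode %in%
                  c("coordinated", "boosted", "independent")))
  invisible(p)
}

# nuclear genome copies relative to diploid (2C -> 1, 4C -> 2, 8C -> 4)
.np <- function(ploidy) c("2C" = 1, "4C" = 2, "8C" = 4)[[ploidy]]

#' Organelle genome copies per cell in the simulated world
#'
#' At ploidy p: diploid baseline x (p/2) nuclear genome copies x
#' per-nuclear-genome response extrapolated per doubling, i.e.
#' \code{copies_2c * np * response^log2(np)}. With a per-genome response of
#' 0.75 at 4C this is exactly 1.5x the diploid per-cell copy number; with a
#' response of 1 it is exactly 2x.
#'
#' @param params a [simulation_params()].
#' @param ploidy "2C", "4C" or "8C".
#' @param genome "plastid" or "mitochondrion".
#' @export
organelle_genomes_per_cell <- function(params, ploidy, genome) {
  np <- .np(ploidy)
  params$organelle_copies_2c[[genome]] *
    np * params$organelle_genome_response[[genome]]^log2(np)
}

# integer allocation of n items to proportions, exact total
.alloc <- function(n, prop) {
  k <- floor(n * prop)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(n * prop - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(k), names(prop))
}

# build the simulated annotation (ids, classes, tiers, complexes, lengths)
.sim_annotation <- function(p) {
  nuc_ids <- sprintf("AT%dG%05d", 1 + (seq_len(p$n_nuclear_genes) - 1) %% 5,
                     10 * seq_len(p$n_nuclear_genes))
  pla_ids <- sprintf("ATCG%05d", 10 * seq_len(p$n_plastid_genes))
  mit_ids <- sprintf("ATMG%05d", 10 * seq_len(p$n_mito_genes))
  spk_ids <- sprintf("ERCC-%05d", seq_len(p$n_spike_species))
  cls_n <- .alloc(p$n_nuclear_genes, p$class_proportions)
  targeting <- rep(names(cls_n), cls_n)
  tier <- rep("none", p$n_nuclear_genes)
  for (cl in c("plastid", "mitochondrion", "dual")) {
    i <- which(targeting == cl)
    tn <- .alloc(length(i), p$tier_proportions)
    tier[i] <- rep(names(tn), tn)
  }
  complex_id <- rep(NA_character_, p$n_nuclear_genes)
  org_complex <- list(plastid = character(0), mitochondrion = character(0))
  for (cx in names(p$complexes)) {
    spec <- p$complexes[[cx]]
    org <- intersect(names(spec), c("plastid", "mitochondrion"))
    chimeric <- length(org) == 1L
    host <- if (chimeric) org else "mitochondrion"  # all-nuclear: mito-side
    want_tier <- if (chimeric) "direct" else "complexed"
    free <- which(targeting == host & tier == want_tier & is.na(complex_id))
    n_nuc <- spec$nuclear %||% 0
    if (length(free) < n_nuc) {
      stop("not enough ", want_tier, " ", host,
           "-targeted genes for complex ", cx)
    }
    complex_id[free[seq_len(n_nuc)]] <- cx
    if (chimeric) {
      n_org <- spec[[org]]
      prev <- length(unlist(org_complex[org]))
      pool <- if (org == "plastid") pla_ids else mit_ids
      if (prev + n_org > length(pool)) stop("too few organellar genes")
      org_complex[[org]] <- c(org_complex[[org]],
                              stats::setNames(rep(cx, n_org),
                                              pool[prev + seq_len(n_org)]))
    }
  }
  gene_id <- c(nuc_ids, pla_ids, mit_ids, spk_ids)
  genome <- rep(c("nuclear", "plastid", "mitochondrion", "spike"),
                c(length(nuc_ids), length(pla_ids), length(mit_ids),
                  length(spk_ids)))
  targ_all <- c(targeting, rep("not_applicable",
                               length(gene_id) - length(nuc_ids)))
  tier_all <- c(tier, rep("none", length(gene_id) - length(nuc_ids)))
  cx_all <- c(complex_id, rep(NA_character_,
                              length(gene_id) - length(nuc_ids)))
  org_cx <- unlist(unname(org_complex))  # keep gene-id names only
  if (length(org_cx)) {
    cx_all[match(names(org_cx), gene_id)] <- unname(org_cx)
  }
  length_kb <- stats::rlnorm(length(gene_id), p$length_meanlog,
                             p$length_sdlog)
  annotation_set(gene_id, length_kb, genome = genome, targeting = targ_all,
                 tier = tier_all, complex_id = cx_all,
                 provenance = "simulated")
}

#' Simulate a tri-genome RNA-seq experiment with ground truth
#'
#' Generative model, per cell: a nuclear gene g contributes
#' \code{np x rate_g x (multiplier_class x e^eps_g)^log2(np)} transcripts
#' (np = nuclear genome copies relative to diploid; eps_g is tier-coupled
#' log-normal ratio noise); an organellar gene contributes per-genome-copy
#' rate x genome copies ([organelle_genomes_per_cell()]) under its
#' coordination mode; spike species contribute abundances proportional to
#' nuclear genome copies (idealized proportional spiking). Read proportions
#' are transcript abundance x length; each library is a single multinomial
#' draw of size \code{depth} over gamma-perturbed proportions (dispersion),
#' so counts sum exactly to depth.
#'
#' @param params a [simulation_params()].
#' @param seed RNG seed (defaults to \code{params$seed}). Same seed, same
#'   params: bit-identical output.
#' @return list of class \code{"cyto_simulation"}: \code{counts}
#'   ([count_table()]), \code{annotation}, \code{meta}, \code{spike_design},
#'   and \code{truth} (per-gene realized 4C/2C expected ratios, per-ploidy
#'   plant pool ratios, expected per-class medians on the TPM and
#'   per-genome-copy scales).
#' @export
simulate_experiment <- function(params, seed = params$seed) {
  validate_params(params)
  set.seed(seed)
  p <- params
  ann <- .sim_annotation(p)
  n <- nrow(ann)
  is_nuc <- ann$genome == "nuclear"
  is_pla <- ann$genome == "plastid"
  is_mit <- ann$genome == "mitochondrion"
  is_spk <- ann$genome == "spike"

  rate <- numeric(n)
  rate[is_nuc] <- stats::rlnorm(sum(is_nuc), p$rate_meanlog[["nuclear"]],
                                p$rate_sdlog[["nuclear"]])
  rate[is_pla] <- stats::rlnorm(sum(is_pla), p$rate_meanlog[["plastid"]],
                                p$rate_sdlog[["plastid"]])
  rate[is_mit] <- stats::rlnorm(sum(is_mit),
                                p$rate_meanlog[["mitochondrion"]],
                                p$rate_sdlog[["mitochondrion"]])
  rate[is_spk] <- stats::rlnorm(sum(is_spk), p$spike_meanlog, p$spike_sdlog)

  # realized per-gene 4C/2C expected ratio R_g (applied as R^log2(np))
  ratio_class <- ifelse(ann$targeting %in%
                          c("plastid", "mitochondrion", "dual"),
                        ann$tier, ann$targeting)
  R <- rep(NA_real_, n)
  shared_z <- stats::setNames(stats::rnorm(3), c("none", "complexed",
                                                 "direct"))
  for (i in which(is_nuc)) {
    cl <- ratio_class[i]
    sd_cl <- p$ratio_sd[[cl]]
    w <- if (cl %in% names(p$tier_coupling)) p$tier_coupling[[cl]] else 0
    eps <- sd_cl * (sqrt(w) * shared_z[[if (w > 0) cl else "none"]] +
                      sqrt(1 - w) * stats::rnorm(1))
    R[i] <- 2 * p$dosage_multiplier[[ann$targeting[i]]] * exp(eps)
  }
  org_eps <- stats::rnorm(sum(is_pla) + sum(is_mit), 0, p$org_ratio_sd)
  # "coordinated": the organelle genome's total output tracks the realized
  # bulk 4C/2C ratio of the nuclear genes targeted to it
  bulk_targeted <- function(cl) {
    sel <- is_nuc & ann$targeting == cl
    sum(rate[sel] * R[sel]) / sum(rate[sel])
  }
  org_R <- function(genome, mode) {
    switch(mode,
      coordinated = bulk_targeted(genome),
      independent = 2 * p$organelle_genome_response[[genome]],
      boosted = 2 * p$organelle_genome_response[[genome]] * p$mito_boost)
  }
  R[is_pla] <- org_R("plastid", p$coordination_mode[["plastid"]]) *
    exp(org_eps[seq_len(sum(is_pla))])
  R[is_mit] <- org_R("mitochondrion",
                     p$coordination_mode[["mitochondrion"]]) *
    exp(org_eps[sum(is_pla) + seq_len(sum(is_mit))])
  R[is_spk] <- 2  # spike pool tracks nuclear genome copies

  base <- rate
  base[is_pla] <- base[is_pla] * p$organelle_copies_2c[["plastid"]]
  base[is_mit] <- base[is_mit] * p$organelle_copies_2c[["mitochondrion"]]
  plant_pool_2c <- sum(base[!is_spk])
  base[is_spk] <- base[is_spk] / sum(base[is_spk]) *
    plant_pool_2c * p$spike_fraction / (1 - p$spike_fraction)

  ploidies <- p$ploidy_levels
  reps <- seq_len(p$reps_per_ploidy)
  meta <- expand.grid(replicate = reps, ploidy = ploidies,
                      stringsAsFactors = FALSE)
  meta$organ <- p$organ
  meta$sample_id <- sprintf("%s_%s_r%d", meta$organ, meta$ploidy,
                            meta$replicate)
  out_per_ploidy <- vapply(ploidies, function(pl) {
    base * R^log2(.np(pl))
  }, numeric(n))
  pool <- colSums(out_per_ploidy[!is_spk, , drop = FALSE])
  meta$rna_per_dna <- p$rna_per_dna_2c *
    (pool[meta$ploidy] / vapply(meta$ploidy, .np, numeric(1))) / pool["2C"]
  meta$spike_mix <- "ERCC92"
  meta <- meta[, c("sample_id", "organ", "ploidy", "replicate",
                   "rna_per_dna", "spike_mix")]

  prob_base <- out_per_ploidy * ann$length_kb  # reads ~ abundance x length
  counts <- matrix(0, n, nrow(meta),
                   dimnames = list(ann$gene_id, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    pr <- prob_base[, meta$ploidy[s]]
    if (p$dispersion > 0) {
      # biological overdispersion affects plant transcripts; spike species
      # are pipetted and keep near-Poisson (multinomial) counting noise
      pr[!is_spk] <- pr[!is_spk] *
        stats::rgamma(sum(!is_spk), shape = 1 / p$dispersion,
                      scale = p$dispersion)
    }
    counts[, s] <- stats::rmultinom(1, size = p$depth, prob = pr)
  }
  ct <- count_table(counts, spike = is_spk)

  spike_design <- data.frame(
    sample_id = meta$sample_id, rna_mass = 1,
    rna_per_dna = meta$rna_per_dna,
    spike_mass = spike_mass_for(1, meta$rna_per_dna, k = p$rna_per_dna_2c),
    stringsAsFactors = FALSE)

  truth <- list(
    params = p, seed = seed,
    ratio_4c_2c = stats::setNames(R, ann$gene_id),
    pool_ratio = pool / pool[["2C"]],
    expected_median = .expected_medians(ann, R, pool)
  )
  structure(list(counts = ct, annotation = ann, meta = meta,
                 spike_design = spike_design, truth = truth),
            class = "cyto_simulation")
}

# realized (noise-free w.r.t. counting) per-class median 4C/2C ratios on the
# TPM and per-nuclear-genome-copy scales
.expected_medians <- function(ann, R, pool) {
  T42 <- pool[["4C"]] / pool[["2C"]]
  nuc <- ann$genome == "nuclear"
  classes <- c("plastid", "mitochondrion", "dual", "other", "unknown")
  med <- vapply(classes, function(cl) {
    stats::median(R[nuc & ann$targeting == cl])
  }, numeric(1))
  list(tpm_ratio = med / T42,
       per_genome_ratio = med / 2,  # spike (nuclear-DNA) ratio is 2 at 4C
       pool_ratio_4c_2c = T42)
}

#' @export
print.cyto_simulation <- function(x, ...) {
  cat("cyto_simulation:", nrow(x$counts$counts), "genes x",
      ncol(x$counts$counts), "libraries; seed", x$truth$seed, "\n")
  invisible(x)
}

#' Simulate a qPCR copy-number plate
#'
#' Template copies per sample: nuclear reference genes scale with nuclear
#' genome copies; the plastid and mitochondrial targets scale with nuclear
#' genome copies times their per-nuclear-genome responses. Cq values follow
#' \code{-log(copies x scale) / log(efficiency) + N(0, qpcr_noise_sd)}.
#' Targets are the loci used for the real assay (plastid RbcL ATCG00490,
#' mitochondrial 26S rRNA ATMG00020) with nuclear references AT2G10940 and
#' AT1G69960.
#'
#' @param params a [simulation_params()].
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @return a [qpcr_plate()].
#' @export
simulate_qpcr <- function(params, seed = params$seed) {
  validate_params(params)
  set.seed(seed)
  p <- params
  genes <- data.frame(
    gene_id = c("ATCG00490", "ATMG00020", "AT2G10940", "AT1G69960"),
    role = c("target", "target", "reference", "reference"),
    base = c(500, 50, 1, 1),  # copies per nuclear genome in the diploid
    genome = c("plastid", "mitochondrion", "nuclear", "nuclear"),
    stringsAsFactors = FALSE)
  meta <- expand.grid(replicate = seq_len(p$reps_per_ploidy),
                      ploidy = p$ploidy_levels, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("gDNA_%s_r%d", meta$ploidy, meta$replicate)
  scale <- 2^-20
  wells <- do.call(rbind, lapply(seq_len(nrow(meta)), function(s) {
    np <- .np(meta$ploidy[s])
    resp <- ifelse(genes$genome == "nuclear", 1,
                   p$organelle_genome_response[genes$genome]^log2(np))
    copies <- genes$base * np * resp
    cq <- -log(copies * scale) / log(p$qpcr_efficiency) +
      stats::rnorm(nrow(genes), 0, p$qpcr_noise_sd)
    data.frame(gene_id = genes$gene_id, sample_id = meta$sample_id[s],
               role = genes$role, Cq = cq, stringsAsFactors = FALSE)
  }))
  qpcr_plate(wells, meta[, c("sample_id", "ploidy", "replicate")],
             efficiency = p$qpcr_efficiency)
}

#' Load a shipped or on-disk simulation preset
#'
#' Presets are flat JSON serializations of [simulation_params()]; the
#' package ships \code{paper_calibrated}, whose copy-number responses
#' (plastid 0.76, mitochondrion 1.01 at 4C/2C) are the only values taken
#' from published measurements -- all other defaults are fixed, documented
#' choices.
#'
#' @param name preset name (file under \code{inst/presets/}) or a path to a
#'   JSON file.
#' @return a [simulation_params()].
#' @export
read_preset <- function(name = "paper_calibrated") {
  path <- if (file.exists(name)) name else {
    system.file("presets", paste0(name, ".json"), package = "cytobalance")
  }
  if (!nzchar(path) || !file.exists(path)) stop("unknown preset: ", name)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cx <- lapply(raw$complexes, function(x) lapply(x, unlist))
  raw$complexes <- NULL
  raw <- lapply(raw, function(x) unlist(x))  # named lists -> named vectors
  raw$complexes <- cx
  do.call(simulation_params, raw)
}

#' Write simulation parameters as a JSON preset
#' @param params a [simulation_params()].
#' @param path output file.
#' @export
write_preset <- function(params, path) {
  # named atomic vectors must become JSON objects, not bare arrays
  prep <- lapply(unclass(params), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(prep, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
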