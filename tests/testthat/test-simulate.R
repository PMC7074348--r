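test_that("parameter validation rejects infeasible settings", {
  expect_error(simulation_params(class_proportions = c(
    plastid = 0.5, mitochondrion = 0.2, dual = 0.1, other = 0.1,
    unknown = 0.2)), "sum to 1")
  expect_error(simulation_params(dispersion = -1))
  expect_error(simulation_params(spike_fraction = 1.5))
  expect_error(simulation_params(ploidy_levels = c("4C")))  # needs 2C
  # complexes need enough direct-tier hosts before any sampling happens
  expect_error(simulate_experiment(simulation_params(n_nuclear_genes = 200)),
               "not enough")
})

test_that("the generator is deterministic in its seed and conserves depth", {
  p <- fast_params()
  a <- simulate_experiment(p, seed = 5)
  b <- simulate_experiment(p, seed = 5)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$ratio_4c_2c, b$truth$ratio_4c_2c)
  c <- simulate_experiment(p, seed = 6)
  expect_false(identical(a$counts$counts, c$counts$counts))
  expect_true(all(colSums(a$counts$counts) == p$depth))
  expect_equal(nrow(a$meta), 2 * p$reps_per_ploidy)
})

test_that("null world: all median ratios are 1 in every class and genome", {
  sim <- simulate_experiment(null_params(), seed = 2)
  tpm <- compute_tpm(sim$counts, sim$annotation)
  m <- mean_expression(tpm, sim$meta)
  r <- tpm_ratio(m, "sepal_4C", "sepal_2C", ann = sim$annotation)
  med_t <- tapply(r$ratio, r$targeting, stats::median)
  med_g <- tapply(r$ratio, r$genome, stats::median)
  expect_true(all(abs(unlist(c(med_t, med_g)) - 1) < 0.03))
})

test_that("per-genome ratios recover the generative dosage multipliers", {
  p <- read_preset("paper_calibrated")   # depth 5e6, dispersion 0.05
  sim <- simulate_experiment(p, seed = 1)
  pg <- per_genome_expression(sim$counts, sim$annotation)
  pr <- per_genome_ratio(pg, sim$meta, sim$annotation,
                         "sepal_4C", "sepal_2C")
  med <- tapply(pr$ratio, pr$targeting, stats::median)
  # classes without a shared tier component: medians hit the configured
  # multipliers directly
  for (cl in c("other", "unknown")) {
    expect_equal(unname(med[cl]), unname(p$dosage_multiplier[cl]),
                 tolerance = 0.05, info = cl)
  }
  # every class median matches the truth record's realized expectation
  truth <- sim$truth$expected_median$per_genome_ratio
  for (cl in names(truth)) {
    expect_equal(unname(med[cl]), unname(truth[cl]), tolerance = 0.05,
                 info = cl)
  }
  # TPM-scale medians match their truth-record counterparts
  tpm <- compute_tpm(sim$counts, sim$annotation)
  mt <- mean_expression(tpm, sim$meta)
  rt <- tpm_ratio(mt, "sepal_4C", "sepal_2C", ann = sim$annotation)
  med_tpm <- tapply(rt$ratio, rt$targeting, stats::median)
  truth_tpm <- sim$truth$expected_median$tpm_ratio
  for (cl in names(truth_tpm)) {
    expect_equal(unname(med_tpm[cl]), unname(truth_tpm[cl]),
                 tolerance = 0.05, info = cl)
  }
})

test_that("organelle genome copies per cell follow the response arithmetic", {
  p <- simulation_params(
    organelle_genome_response = c(plastid = 0.75, mitochondrion = 1.0))
  base_p <- p$organelle_copies_2c[["plastid"]]
  base_m <- p$organelle_copies_2c[["mitochondrion"]]
  expect_identical(organelle_genomes_per_cell(p, "2C", "plastid"), base_p)
  # per-genome response x 2 nuclear genomes: 0.75 -> exactly 1.5-fold/cell
  expect_identical(organelle_genomes_per_cell(p, "4C", "plastid"),
                   1.5 * base_p)
  expect_identical(organelle_genomes_per_cell(p, "4C", "mitochondrion"),
                   2 * base_m)
  # log-linear extrapolation per doubling at 8C
  expect_equal(organelle_genomes_per_cell(p, "8C", "plastid"),
               base_p * 4 * 0.75^2)
})

test_that("paper-calibrated preset reproduces the qualitative compartment
          patterns", {
  sim <- simulate_experiment(read_preset("paper_calibrated"), seed = 3)
  ct <- sim$counts; ann <- sim$annotation
  is4 <- sim$meta$ploidy == "4C"
  pn <- organelle_nuclear_ratio(ct, ann, "plastid")
  mn <- organelle_nuclear_ratio(ct, ann, "mitochondrion")
  expect_lt(mean(pn[is4]), mean(pn[!is4]))   # plastid share drops with WGD
  expect_gt(mean(mn[is4]), mean(mn[!is4]))   # mito share rises
  pb <- balance_ratio(ct, ann, "plastid")
  mb <- balance_ratio(ct, ann, "mitochondrion")
  # plastid balance stable (coordinated); mito balance increases (boosted)
  expect_lt(abs(log(mean(pb[is4]) / mean(pb[!is4]))), log(1.15))
  expect_gt(mean(mb[is4]), mean(mb[!is4]))
  tpm <- compute_tpm(ct, ann)
  r <- genome_tpm_ratios(tpm, sim$meta, ann, "sepal_4C", "sepal_2C")
  med <- tapply(r$ratio, r$genome, stats::median)
  expect_lt(med[["plastid"]], 1)             # plastid TPMs decrease
  # the pattern survives excluding the dominant mitochondrial rRNA analog
  r2 <- genome_tpm_ratios(tpm, sim$meta, ann, "sepal_4C", "sepal_2C",
                          exclude = "ATMG00020")
  expect_lt(tapply(r2$ratio, r2$genome, stats::median)[["plastid"]], 1)
})

test_that("tier CV decreases monotonically in tier coupling", {
  # equal ratio noise everywhere: coupling alone drives the ordering
  # (low dispersion so the counting-noise floor does not mask it)
  p <- simulation_params(
    ratio_sd = c(other = 0.3, unknown = 0.3, none = 0.3, complexed = 0.3,
                 direct = 0.3),
    tier_coupling = c(none = 0, complexed = 0.6, direct = 0.95),
    dispersion = 0.01)
  sim <- simulate_experiment(p, seed = 8)
  tpm <- compute_tpm(sim$counts, sim$annotation)
  m <- mean_expression(tpm, sim$meta)
  r <- tpm_ratio(m, "sepal_4C", "sepal_2C", ann = sim$annotation)
  nuc <- r[r$genome == "nuclear" &
             r$targeting %in% c("plastid", "mitochondrion", "dual"), ]
  cv <- vapply(split(nuc$ratio, nuc$tier),
               function(x) stats::sd(x) / mean(x), numeric(1))
  expect_lt(cv[["direct"]], cv[["complexed"]])
  expect_lt(cv[["complexed"]], cv[["none"]])
})

test_that("spiking metadata is self-consistent with simulated spike reads", {
  sim <- simulate_experiment(fast_params(dispersion = 0), seed = 10)
  ct <- sim$counts$counts
  spike_frac <- colSums(ct[sim$counts$spike, ]) / colSums(ct)
  # spike mass per unit RNA prescribes the spike read share up to counting
  expected <- sim$spike_design$spike_mass / sim$spike_design$rna_mass
  ratio <- (spike_frac / (1 - spike_frac)) / expected
  expect_lt(stats::sd(ratio) / mean(ratio), 0.05)
  # diploid receives more spike per unit RNA whenever its transcriptome
  # (RNA per genome) is smaller
  m <- sim$meta
  expect_equal(unique(m$rna_per_dna[m$ploidy == "2C"]),
               sim$truth$params$rna_per_dna_2c)
})

test_that("simulated qPCR recovers configured responses without bias", {
  p <- simulation_params()
  folds <- vapply(1:60, function(i) {
    relative_copy_number(simulate_qpcr(p, seed = 500 + i),
                         "ATCG00490")$fold
  }, numeric(1))
  se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 0.76), 3 * se + 0.01)
})
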