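# a compact hand-checkable world used across this file
stoich_fixture <- function() {
  genes <- c("AT1G00010", "AT1G00020", "AT2G00010", "AT3G00010",
             "AT4G00010", "ATCG00010", "ATMG00010", "ERCC-00002")
  ann <- annotation_set(
    genes, length_kb = rep(1, 8),
    targeting = c("plastid", "plastid", "mitochondrion", "dual", "other",
                  "not_applicable", "not_applicable", "not_applicable"),
    tier = c("direct", "none", "complexed", "none", "none", "none", "none",
             "none"))
  m <- cbind(s1 = c(150, 100, 200, 50, 500, 500, 120, 30),
             s2 = c(300, 200, 400, 100, 1000, 600, 300, 60))
  rownames(m) <- genes
  list(ann = ann, ct = count_table(m))
}

test_that("targeted_fraction sums counts per class over nuclear genes", {
  fx <- stoich_fixture()
  # nuclear total s1 = 1000; plastid-targeted = 250
  expect_equal(unname(targeted_fraction(fx$ct, fx$ann, "plastid", "s1")),
               0.25)
  expect_equal(unname(targeted_fraction(fx$ct, fx$ann, "unknown", "s1")), 0)
  # partition: the five class fractions sum to 1 in every sample
  classes <- c("plastid", "mitochondrion", "dual", "other", "unknown")
  tot <- Reduce(`+`, lapply(classes,
                            function(cl) targeted_fraction(fx$ct, fx$ann, cl)))
  expect_equal(unname(tot), c(1, 1))
  m0 <- fx$ct$counts; m0[1:5, 1] <- 0L
  expect_error(targeted_fraction(count_table(m0), fx$ann, "plastid"),
               "zero nuclear")
})

test_that("organelle/nuclear and balance ratios match hand sums", {
  fx <- stoich_fixture()
  # plastid 500 / nuclear 10000 = 0.05
  m <- fx$ct$counts * 0L
  m[, ] <- 0L
  m["ATCG00010", "s1"] <- 500L
  m[c("AT1G00010", "AT1G00020", "AT2G00010", "AT3G00010", "AT4G00010"),
    "s1"] <- 2000L
  m[, "s2"] <- 1L
  expect_equal(unname(organelle_nuclear_ratio(count_table(m), fx$ann,
                                              "plastid", "s1")), 0.05)
  # zero organellar counts give 0
  expect_equal(unname(organelle_nuclear_ratio(count_table(m), fx$ann,
                                              "mitochondrion", "s1")), 0)
  # balance: organelle == targeted counts -> exactly 1
  fx2 <- stoich_fixture()
  expect_equal(unname(balance_ratio(fx2$ct, fx2$ann, "plastid", FALSE,
                                    "s1")),
               500 / 250)
  # include_dual adds the dual-targeted gene to the denominator
  expect_equal(unname(balance_ratio(fx2$ct, fx2$ann, "plastid", TRUE,
                                    "s1")),
               500 / 300)
})

test_that("balance = organelle/nuclear divided by targeted fraction", {
  sim <- simulate_experiment(fast_params(), seed = 6)
  for (g in c("plastid", "mitochondrion")) {
    lhs <- balance_ratio(sim$counts, sim$annotation, g)
    rhs <- organelle_nuclear_ratio(sim$counts, sim$annotation, g) /
      targeted_fraction(sim$counts, sim$annotation, g)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("genome_tpm_ratios groups by genome and honors exclusions", {
  sim <- simulate_experiment(null_params(), seed = 12)
  tpm <- compute_tpm(sim$counts, sim$annotation)
  r <- genome_tpm_ratios(tpm, sim$meta, sim$annotation,
                         "sepal_4C", "sepal_2C")
  med <- tapply(r$ratio, r$genome, stats::median)
  for (g in c("nuclear", "plastid", "mitochondrion")) {
    expect_equal(unname(med[g]), 1, tolerance = 0.03, info = g)
  }
  drop <- r$gene_id[r$genome == "mitochondrion"][1L]
  r2 <- genome_tpm_ratios(tpm, sim$meta, sim$annotation,
                          "sepal_4C", "sepal_2C", exclude = drop)
  expect_equal(sum(r2$genome == "mitochondrion"),
               sum(r$genome == "mitochondrion") - 1L)
  expect_equal(sum(r2$genome == "nuclear"), sum(r$genome == "nuclear"))
})

test_that("cv_by_tier computes nested-class CVs with n-1 sd", {
  mk <- function(ratio, targeting, tier) {
    data.frame(gene_id = sprintf("AT1G%05d", seq_along(ratio) * 10),
               ratio = ratio, genome = "nuclear", targeting = targeting,
               tier = tier, complex_id = NA_character_)
  }
  # ratios {1,2,3}: mean 2, sd 1, cv 0.5
  r <- mk(c(1, 2, 3, 5, 5, 5), rep(c("plastid", "other"), each = 3),
          rep("none", 6))
  cv <- suppressWarnings(cv_by_tier(r))
  expect_equal(cv$cv[cv$class == "targeted"], 0.5)
  expect_equal(cv$cv[cv$class == "other"], 0)
  expect_false("direct" %in% cv$class)  # <2 genes, omitted with warning
  expect_warning(cv_by_tier(r), "omitted")
  # scale invariance within a class
  r2 <- r; r2$ratio[r2$targeting == "plastid"] <- r2$ratio[1:3] * 7
  cv2 <- suppressWarnings(cv_by_tier(r2))
  expect_equal(cv2$cv[cv2$class == "targeted"], 0.5)
})

test_that("complex_correlation reports overall and per-genome r", {
  genes <- c(sprintf("AT1G%05d", 1:8 * 10), sprintf("ATCG%05d", 1:4 * 10))
  ann <- annotation_set(genes, rep(1, 12),
                        targeting = c(rep("plastid", 8), rep("not_applicable", 4)),
                        tier = c(rep("direct", 8), rep("none", 4)))
  x <- c(2, 5, 11, 40, 90, 300, 1200, 5000, 30, 800, 2500, 9000)
  means <- cbind(c2 = x, c4 = 0.8 * x)
  rownames(means) <- genes
  cc <- complex_correlation(means, "c4", "c2", genes, ann)
  expect_equal(cc$r_all, 1)
  expect_equal(cc$r_nuclear, 1)
  expect_equal(cc$r_organellar, 1)
  expect_identical(cc$n, 12L)
  # degenerate and undersized complexes
  flat <- means; flat[, ] <- 5
  expect_error(complex_correlation(flat, "c4", "c2", genes, ann),
               "degenerate")
  expect_error(complex_correlation(means, "c4", "c2", genes[1:2], ann),
               ">= 3")
})

test_that("operations agree with a spreadsheet-style recomputation on a
          random 20-gene table", {
  set.seed(77)
  genes <- c(sprintf("AT%dG%05d", rep(1:5, 3), 1:15 * 10),
             sprintf("ATCG%05d", 1:2 * 10), sprintf("ATMG%05d", 1:2 * 10),
             "ERCC-00002")
  targ <- c(sample(c("plastid", "mitochondrion", "dual", "other",
                     "unknown"), 15, replace = TRUE),
            rep("not_applicable", 5))
  ann <- annotation_set(genes, runif(20, 0.2, 4), targeting = targ)
  m <- matrix(rpois(40, 300), 20, 2, dimnames = list(genes, c("x", "y")))
  ct <- count_table(m)
  # brute-force loops
  nuc <- grepl("^AT[1-5]G", genes)
  for (s in c("x", "y")) {
    for (cl in c("plastid", "other")) {
      want <- 0
      for (i in 1:20) if (nuc[i] && targ[i] == cl) want <- want + m[i, s]
      expect_equal(unname(targeted_fraction(ct, ann, cl, s)),
                   want / sum(m[nuc, s]))
    }
    expect_equal(unname(organelle_nuclear_ratio(ct, ann, "plastid", s)),
                 sum(m[grepl("^ATCG", genes), s]) / sum(m[nuc, s]))
    expect_equal(unname(balance_ratio(ct, ann, "mitochondrion", FALSE, s)),
                 sum(m[grepl("^ATMG", genes), s]) /
                   sum(m[nuc & targ == "mitochondrion", s]))
  }
})
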