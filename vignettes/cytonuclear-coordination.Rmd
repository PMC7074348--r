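---
title: "Cytonuclear coordination after genome duplication: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytonuclear coordination after genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobalance)
```

## The question and the quantities

Autopolyploidy multiplies the nuclear genome while leaving the plastid and
mitochondrial genomes untouched, threatening the stoichiometry of chimeric
protein complexes whose subunits are encoded in two genomes. `cytobalance`
measures, from gene-level RNA-seq counts, the three layers at which cells
can compensate:

1. **Organelle genome dosage** — qPCR ΔΔCq copy number of an organellar
   locus relative to the geometric mean of two nuclear reference genes.
2. **Relative transcriptional output** — TPM ratios between ploidies by
   targeting class and genome, bulk compartment ratios, and the *balance
   ratio* (organelle-encoded transcription over the transcription of the
   nuclear genes targeted to that organelle). A balance ratio that does not
   move with ploidy means the two compartments were re-tuned together.
3. **Absolute output per genome copy** — ERCC spike-ins added in proportion
   to the genomic DNA co-extracted with the RNA make summed spike counts a
   yardstick for genome copies, so plant counts divided by spike counts
   compare transcription per gene copy across cytotypes.

## Normalization model

TPM follows the standard RPK-rescaling definition. Two choices are ours and
are deliberately conservative:

* **Spike-in reads are excluded from the TPM denominator.** Samples carry
  different spike fractions by design (spiking is proportional to DNA, not
  RNA), so including them would make plant TPMs incomparable across
  cytotypes. Spike rows are still reported against the same denominator.
* **Ratio distributions use no pseudocount.** A gene enters a ratio only if
  its replicate-mean expression is positive (above `min_mean`, default 0)
  in both cytotypes. Pseudocounts shrink low-expression classes toward 1 by
  different amounts per class, which would bias exactly the class
  comparisons this package exists to make.

Gene length is the exon-union length (bases covered by at least one exon of
any isoform), matching gene-level counting: a read anywhere in any exon is
attributed to the gene. Per-isoform lengths would double-count shared exons.
Intervals are handled by `GenomicRanges::reduce`; a base-by-base oracle in
the test suite pins the arithmetic down.

For per-genome-copy expression, length correction is applied *before* spike
scaling, so a gene's TPM-level and per-genome-level ratios are directly
comparable; the ×10⁶ factor is cosmetic and cancels from every ratio.
"Per genome copy" means per *nuclear* genome copy: the spiking rule tracks
total DNA, which is dominated by and here idealized as the nuclear
complement — the same reference the qPCR normalization uses.

## The statistics battery

All tests are implemented from their defining formulas (mid-ranks,
tie-corrected Kruskal–Wallis H, Dunn's tie-corrected pairwise z with
Benjamini–Hochberg step-up, pooled-variance t with Bonferroni, closed-form
OLS with F = r²(n−2)/(1−r²)) rather than wrapped, and are verified in the
tests against base R and against hand-derived values. Two conventions the
source material leaves open: Dunn's variance term uses the tie-corrected
form popularized by the FSA package, and all p-values are two-sided.
Regression of one expression table on another runs on untransformed means
by default with a `log10(x+1)` option, because heavy-tailed TPM scales can
make a handful of genes carry the fit.

The ΔΔCq estimator normalizes a target's Cq to the *arithmetic* mean of the
reference Cq values — on the quantity scale this is exactly geometric-mean
normalization, and it is numerically stabler than exponentiating first.
Amplification efficiency defaults to 2.0 (perfect doubling) and is exposed;
no standard-curve calibration is modeled. With equal replicate counts,
replicates are paired by index across ploidies and the mean and SE of the
per-pair folds are reported; with unequal counts the mean-ΔCq form is used.

## The simulated world

`simulate_experiment()` draws a scaled-down three-genome transcriptome:
6000 nuclear genes (Arabidopsis expresses ~20000; scaling down keeps the
suite fast while leaving every class ≥ ~40 genes), 80 plastid and 120
mitochondrial genes, 92 spike species. Nuclear targeting classes follow the
published census proportions (~18% organelle-targeted; within those, ~21%
interacting/complexed of which ~3.6% direct — the 4268/910/154 gene counts
scaled). Expected output per cell at ploidy *p* (with *np = p/2* nuclear
genome copies):

* nuclear gene: `np · rate · (multiplier_class · e^ε)^log2(np)`,
* organellar gene: diploid copies × a mode-dependent ratio (below),
* spike species: abundance × `np` (idealized DNA-proportional spiking).

Libraries are single multinomial draws of exactly `depth` reads over
length-weighted, gamma-perturbed proportions — a gamma–multinomial
(negative-binomial-like) scheme whose fixed library size makes the
TPM-sum assertion exact. **Dispersion applies to plant genes only**: spike
species are pipetted, not regulated, and their counting noise in real data
is near-Poisson. (Overdispersing the heavy-tailed spike pool would shake
the summed-spike yardstick by ~±10% per library and destroy the per-genome
recovery property that the generator exists to provide.)

Calibrated values (the only ones taken from published measurements): the
plastid genome response 0.76 and mitochondrial response 1.01 per nuclear
genome at 4C/2C, and the 19% diploid excess of DNA per unit RNA that sets
the spiking worked example. Everything else is a fixed, documented choice:

| parameter | default | why |
|---|---|---|
| `dosage_multiplier` | plastid 0.85, mito 1.05, dual 0.95, other/unknown 1.10 | reproduces the qualitative class ordering (plastid-targeted down, other up, mito intermediate) |
| `ratio_sd` | other/unknown 0.55, tier none 0.40, complexed 0.25, direct 0.02 | decreasing idiosyncratic ratio noise is what "constraint" means; magnitudes chosen so the CV ordering is resolvable above the counting-noise floor √(2·dispersion/reps) ≈ 0.18 |
| `tier_coupling` | none 0.3, complexed 0.6, direct 0.9 | fraction of ratio variance shared across a tier; only the unshared part contributes to the across-gene CV, so CV falls monotonically in coupling |
| `coordination_mode` | plastid `coordinated`, mito `boosted` | plastid genome output tracks the *realized* bulk ratio of plastid-targeted nuclear genes (balance ratio stable by construction); mitochondrial output follows its genome copies times `mito_boost` |
| `mito_boost` | 1.5 | makes the "mito balance ratio rises with ploidy" pattern robust to the ±10% weighting noise of bulk ratios (1.3 left it flaky across seeds) |
| `dispersion`, `depth`, reps | 0.05, 5×10⁶, 3 | typical bulk RNA-seq replicate CV and depth; 3 biological replicates per cytotype |
| `organelle_copies_2c` | plastid 500, mito 50 per diploid cell | order-of-magnitude leaf values |
| `spike_fraction` | 0.02 of diploid reads | typical ERCC spiking target |
| `qpcr_noise_sd` | 0.05 cycles | technical-triplicate-averaged Cq noise. The mean-of-paired-folds estimator is Jensen-biased upward by ≈ ρ(ln E · σ_ΔΔCq)²/2; at 0.05 cycles this is ~0.2%, below the Monte-Carlo SE of a 200-replication recovery run. The published SEs (0.18, 0.25) include plant-to-plant biological copy-number variation, which this generator deliberately omits. |

8C values are log-linear extrapolations per genome doubling
(`factor^log2(np)`); no published 8C copy-number measurements exist to
calibrate them, so octoploid outputs should be read as model extensions,
not emulations.

Four chimeric/homogeneous complexes are wired into the annotation
(RuBisCO 4+1, PSII 8 nuclear + 4 plastid, OXPHOS III 9+1 mito,
OXPHOS II all-nuclear). Complex members sit in the `direct` tier, whose
near-zero idiosyncratic noise is what "coordinated subunits" means; the
organellar subunits inherit the coordinated-mode scaling, so all subunits
move by a common factor and the tetraploid-vs-diploid scatter collapses
onto a line (r > 0.99 at low dispersion).

### What the generator does not emulate

No isoform structure, no library-chemistry differences (poly(A) vs
rRNA-depletion beyond what a per-genome capture scalar could express), no
batch effects, no biological variation in organelle genome copy number
between plants, no organelle DNA contribution to the spike channel, and no
ERCC species-specific capture efficiency. A green recovery test therefore
establishes that the *estimators* are correct on data obeying the stated
model — not that real libraries obey it.

## Recovery semantics (what "±5%" checks)

TPM is a relative scale: if a class is configured with per-genome-copy
multiplier *m*, its median TPM ratio is `2m / T`, where `T` is the realized
whole-transcriptome pool ratio — not *m* itself. The truth record therefore
stores both the realized per-class expectations on the TPM scale and on the
per-genome scale, and the recovery tests assert: (i) spike-normalized
per-genome medians hit the *configured* multipliers directly for classes
without a shared tier component (the shared component is a class-level
random effect that moves a single seed's median legitimately), and (ii) all
class medians on both scales hit the truth record's realized expectations
within ±5% at the preset depth and dispersion.

## Numerical choices and degenerate inputs

Identical-everything groups yield H = 0, p = 1 by convention; zero
within-group variance with unequal means is an error (F undefined), as are
all-zero samples, zero spike totals, missing reference wells, constant-x
regressions and sub-3-member complexes. Ratio antisymmetry,
depth invariance of per-genome values, plate-shift invariance of ΔΔCq, and
the algebraic identity `balance = organelle/nuclear ÷ targeted fraction`
(asserted to 1e-12) anchor the arithmetic. Gene identifiers are classified
by AGI prefix, with the GFF3 chromosome (ChrC/ChrM) as fallback and the
prefix winning on conflict; unrecognized identifiers fall back to "nuclear"
with a warning so that a count table never silently loses genes. HTSeq
special counters (`__no_feature`, ...) are dropped on load with their
totals retained as an attribute.

## Known limitations

Transcript-level coordination is the object of study; protein abundances
may still diverge. The qPCR copy-number model samples two organellar and
two nuclear loci, as in the assay it emulates, and is flagged approximate
for the same reason. Balance ratios computed from bulk counts are
dominated by the most highly expressed genes (the simulator reproduces
this: its mitochondrial rRNA analog can be excluded via the `exclude`
argument exactly as the sensitivity analysis requires). The spec-level
counts 4268/910/154 are database-version-dependent and are emulated as
proportions, not reproduced.
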