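# regencycle

Time-course transcriptome and chromatin analysis of liver regeneration
after partial hepatectomy (PH), for computational biologists studying
synchronised cell-cycle reentry in tissue.

Removal of ~70% of the liver sends the remaining hepatocytes through a
near-synchronous division cycle. A time-course design samples livers in
triplicate at 0, 1, 4, 10, 20, 28, 36, 44, 48, 60, 72 h, 1 and 4 weeks
post-PH, plus sham-operated controls (same surgery, no resection) at 1–48
h. `regencycle` implements the analysis stack such an experiment needs, and
a seeded synthetic-data generator with planted ground truth so that every
stage is testable end to end without the original sequencing data.

## What the package computes

**Transcript sets.** Genes partition into set 1 (undetected), set 2
(detected, stable) and set 3 (detected, changing). Changing is a per-gene
one-way F test across time points on log2(RPKM + 1),

F = (SSB/(J−1)) / (SSW/(N−J)),  p from F(J−1, N−J),

BH-adjusted, called at adjusted p < 1e−7 **and** max |log2 FC vs 0 h| >
0.5.

**PAM clustering.** From-scratch partitioning around medoids
(Kaufman–Rousseeuw BUILD + SWAP, deterministic tie-breaks) on the
dissimilarity d = 1 − Pearson(log2 profiles), with classical silhouettes
s = (b − a)/max(a, b), per-cluster negative-silhouette fractions, and a
silhouette-argmax k-scan.

**Sample trajectories.** PCA (SVD of the gene-centred log2 matrix, no
variance scaling), average-linkage hierarchical clustering on 1 − r with
Newick export, per-gene log2 PH/sham ratio maps at matched hours, and
Spearman correlations between arms over gene sets.

**ChIP quantification.** Fragment-center density (each fragment counts
over the 50 bp around its midpoint, per-million scaled) quantified over
promoter windows (TSS ± 250 bp for Pol II, ± 500 bp for H3K4me3) and
gene bodies (TSS + 500 bp to poly(A) + 2 kb); log2((chip + ε)/(input + ε))
ratios; spike-in scale factors from a 19:1 experimental:spike mix;
representative-transcript selection by maximal promoter Pol II; Post-PH
gene calls (low at 0 h, ≥2-fold elevated later); violin-style
median-trace summaries.

**First-internal-exon anchoring.** For transcribed units with ≥3 exons and
a first internal exon ≤ 2 kb: me3 scoring over 2 kb downstream of the
exon's 5' end, a median split (strictly-above goes up: 9801 distinct
scores split 4900/4901), base-pair-resolution me2/me3 matrices aligned on
the exon's 3' end and sorted by exon length, two-segment change-point
estimation of the me2-to-me3 transition, and an upstream/downstream me2
depletion contrast separating me3-dominant from mixed gene bodies.

## A worked example

```r
library(regencycle)
library(SummarizedExperiment)

cfg <- simulationConfig(n_genes = 2000, seed = 1,
                        class_fractions = c(
                          undetected = 0, stable = 0,
                          setNames(rep(1/7, 7), paste0("changing_", 1:7))))
txs <- simulateAnnotation(cfg)     # 2000 TUs on one synthetic chromosome
se  <- simulateExpression(cfg, txs)

# replicate-mean PH profiles, shape dissimilarity, k-scan
cd <- colData(se); m <- assay(se, "rpkm")
ph <- cd$arm %in% c("control", "PH")
hours <- sort(unique(cd$hours[ph]))
prof <- log2(vapply(hours, function(h)
  rowMeans(m[, ph & cd$hours == h]), numeric(nrow(m))) + 1)
rownames(prof) <- rownames(m)
d <- profileDissimilarity(prof)
scan <- scanK(d, 2:10)
scan$chosen
#> [1] 7
cr <- scan$results[["7"]]
silhouetteScores(cr, d)$average
#> [1] 0.9178942
table(clusterAssignment(cr),
      rowData(se)$archetype_id)   # diagonal: perfect archetype recovery
```

The k-scan's average silhouette peaks at the seven planted temporal
archetypes (0.92 at k = 7 against 0.87 at k = 6 and 0.80 at k = 8), and
the k = 7 assignment reproduces the planted archetype labels exactly
(adjusted Rand index 1): with 13 time points, triplicates and 0.25 log2
units of replicate noise, co-varying profiles of 2 log2 units amplitude
are unambiguous.

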