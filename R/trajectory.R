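#' Principal component analysis of samples
#'
#' Singular value decomposition of the gene-centred log2(RPKM + eps) matrix,
#' treating samples as observations. No unit-variance scaling is applied so
#' that amplitude information is preserved. Variance proportions are
#' sigma_i^2 / sum(sigma^2).
#'
#' @param se expression \code{SummarizedExperiment}; subset to the desired
#'   gene universe (e.g. detected genes) before calling.
#' @param eps RPKM pseudocount (default 1).
#' @param nComponents number of components to keep (default all).
#' @return a \code{\linkS4class{PcaResult}}.
#' @export
pcaSamples <- function(se, eps = 1, nComponents = NULL) {
  m <- log2(SummarizedExperiment::assay(se, "rpkm") + eps)
  if (ncol(m) < 2L) stop("need at least two samples")
  if (!is.null(nComponents) && nComponents > ncol(m))
    stop("fewer samples than requested components")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  varProp <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(if (is.null(nComponents)) ncol(pc$x) else nComponents)
  new("PcaResult", scores = pc$x[, keep, drop = FALSE],
      loadings = pc$rotation[, keep, drop = FALSE],
      varProp = varProp[keep], center = pc$center)
}

#' Replicate-averaged PCA scores per condition
#'
#' Averages sample scores over replicates of each (arm, hours) condition and
#' reports per-condition standard deviations, the display convention for
#' sample-trajectory plots.
#'
#' @param pca a \code{\linkS4class{PcaResult}}.
#' @param design data.frame with \code{arm} and \code{hours} per sample, in
#'   score row order.
#' @param components which components to summarise (default 1:2).
#' @return data.frame with arm, hours and mean/sd per component.
#' @export
averageScores <- function(pca, design, components = 1:2) {
  sc <- pca@scores[, components, drop = FALSE]
  key <- interaction(design$arm, design$hours, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(kk) {
    i <- key == kk
    data.frame(arm = design$arm[i][1], hours = design$hours[i][1],
               t(colMeans(sc[i, , drop = FALSE])),
               t(apply(sc[i, , drop = FALSE], 2, sd)))
  }))
  colnames(out) <- c("arm", "hours",
                     paste0("mean_", colnames(sc)),
                     paste0("sd_", colnames(sc)))
  out[order(out$arm, out$hours), ]
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples using 1 - Pearson correlation of
#' log2(RPKM + eps) profiles and average linkage. Sample order within the
#' input fixes tie-breaking, making the tree deterministic.
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param eps RPKM pseudocount.
#' @param linkage linkage method passed to \code{hclust}.
#' @return an \code{hclust} tree over samples.
#' @export
hclusterSamples <- function(se, eps = 1, linkage = "average") {
  m <- log2(SummarizedExperiment::assay(se, "rpkm") + eps)
  if (ncol(m) < 2L) stop("need at least two samples")
  d <- as.dist(1 - cor(m))
  hclust(d, method = linkage)
}

#' Export a sample dendrogram as Newick
#'
#' @param hc an \code{hclust} tree.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cut a sample dendrogram into groups
#'
#' @param hc an \code{hclust} tree.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cutSampleTree <- function(hc, k) stats::cutree(hc, k = k)

#' Per-gene log2 PH/sham expression ratios at matched hours
#'
#' For each matched hour, log2 of the ratio of replicate-mean RPKM between
#' the PH and sham arms (with pseudocount). Genes whose replicate-mean log2
#' RPKM is below 0 in both arms at that hour are masked (NA), the display
#' rule for ratio maps. Hours missing an arm are skipped with a warning.
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param hours matched hours (default 1, 4, 10, 20, 48).
#' @param eps RPKM pseudocount for the ratio.
#' @return genes x hours matrix of masked log2 ratios.
#' @export
phShamRatio <- function(se, hours = c(1, 4, 10, 20, 48), eps = 0.1) {
  cd <- SummarizedExperiment::colData(se)
  m <- SummarizedExperiment::assay(se, "rpkm")
  cols <- list()
  for (h in hours) {
    ph <- cd$arm == "PH" & cd$hours == h
    sh <- cd$arm == "sham" & cd$hours == h
    if (!any(ph) || !any(sh)) {
      warning("hour ", h, " missing an arm; skipped")
      next
    }
    mp <- rowMeans(m[, ph, drop = FALSE])
    ms <- rowMeans(m[, sh, drop = FALSE])
    r <- log2((mp + eps) / (ms + eps))
    r[log2(pmax(mp, 2^-52)) < 0 & log2(pmax(ms, 2^-52)) < 0] <- NA
    cols[[as.character(h)]] <- r
  }
  if (length(cols) == 0L) stop("no matched hours present")
  do.call(cbind, cols)
}

#' Spearman correlation between arms over a gene set at one hour
#'
#' Rank correlation (average ranks for ties) between the replicate-mean
#' expression of the PH and sham arms across the gene set.
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param geneIds gene ids (at least 3).
#' @param hour matched hour.
#' @return Spearman rho.
#' @export
spearmanArmCorrelation <- function(se, geneIds, hour) {
  if (length(geneIds) < 3L) stop("need at least 3 genes")
  cd <- SummarizedExperiment::colData(se)
  m <- SummarizedExperiment::assay(se, "rpkm")[geneIds, , drop = FALSE]
  ph <- cd$arm == "PH" & cd$hours == hour
  sh <- cd$arm == "sham" & cd$hours == hour
  if (!any(ph) || !any(sh)) stop("hour ", hour, " missing an arm")
  cor(rowMeans(m[, ph, drop = FALSE]), rowMeans(m[, sh, drop = FALSE]),
      method = "spearman")
}
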