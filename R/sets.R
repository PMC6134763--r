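#' Flag detected genes
#'
#' A gene is detected when its log2 RPKM reaches \code{minLog2Rpkm} in at
#' least \code{minSamples} samples.
#'
#' @param se expression \code{SummarizedExperiment} (assay \code{rpkm},
#'   non-negative).
#' @param minLog2Rpkm detection threshold on the log2 RPKM scale (default 0,
#'   i.e. RPKM >= 1).
#' @param minSamples minimal number of samples at or above the threshold.
#' @return named logical vector.
#' @export
detectGenes <- function(se, minLog2Rpkm = 0, minSamples = 1L) {
  m <- SummarizedExperiment::assay(se, "rpkm")
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
  if (any(m < 0)) stop("expression matrix must be non-negative")
  rowSums(m >= 2^minLog2Rpkm) >= minSamples
}

# row-wise one-way F statistic across groups on a numeric matrix.
# Closed-form decomposition: F = (SSB/(J-1)) / (SSW/(N-J)). Groups with a
# single replicate carry no within-group information and are excluded with a
# warning. Degenerate rows (SSW ~ 0) give F = 0 when flat, Inf otherwise.
.rowFtest <- function(y, groups) {
  tab <- table(groups)
  drop <- names(tab)[tab < 2L]
  if (length(drop)) {
    warning("excluding time point(s) with a single replicate: ",
            paste(drop, collapse = ", "))
    keep <- !(as.character(groups) %in% drop)
    y <- y[, keep, drop = FALSE]
    groups <- droplevels(factor(groups)[keep])
  }
  groups <- factor(groups)
  J <- nlevels(groups); N <- ncol(y)
  if (J < 2L) stop("need at least two time points with >= 2 replicates")
  nj <- as.numeric(table(groups))
  gm <- t(vapply(levels(groups), function(g)
    rowMeans(y[, groups == g, drop = FALSE]), numeric(nrow(y))))
  grand <- rowMeans(y)
  ssb <- colSums(nj * (gm - rep(grand, each = J))^2)
  sst <- rowSums((y - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (J - 1); msw <- ssw / (N - J)
  f <- ifelse(msw > 1e-12, msb / msw, ifelse(msb > 1e-12, Inf, 0))
  p <- pf(f, J - 1, N - J, lower.tail = FALSE)
  means <- t(gm)
  colnames(means) <- levels(groups)
  list(F = f, p = p, groupMeans = means, df1 = J - 1, df2 = N - J)
}

#' Classify detected genes into stable and changing sets
#'
#' Per gene, a one-way F statistic across control/PH time points on
#' log2(RPKM + eps), Benjamini-Hochberg adjustment over the detected genes,
#' and the maximal absolute mean log2 fold change of each time point against
#' the 0 h mean. A gene is called changing (set 3) when the adjusted p value
#' is below \code{alpha} and the maximal |log2 FC| exceeds \code{lfc};
#' otherwise it is stable (set 2).
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param detected logical vector (default \code{detectGenes(se)}).
#' @param alpha adjusted-p threshold (default 1e-7).
#' @param lfc log2 fold-change threshold (default 0.5).
#' @param eps RPKM pseudocount before the log2 transform (default 1).
#' @param arms sample arms entering the test (default control + PH; the sham
#'   arm is excluded, configurable).
#' @return \code{DataFrame} over all genes with \code{label}
#'   (\code{set1}/\code{set2}/\code{set3}), \code{F}, \code{p}, \code{padj},
#'   \code{max_abs_lfc}.
#' @export
classifyTranscriptSets <- function(se, detected = detectGenes(se),
                                   alpha = 1e-7, lfc = 0.5, eps = 1,
                                   arms = c("control", "PH")) {
  cd <- SummarizedExperiment::colData(se)
  use <- cd$arm %in% arms
  m <- SummarizedExperiment::assay(se, "rpkm")[, use, drop = FALSE]
  hours <- cd$hours[use]
  if (!any(hours == 0)) stop("0 h reference samples required")
  y <- log2(m[detected, , drop = FALSE] + eps)
  ft <- .rowFtest(y, factor(hours, levels = sort(unique(hours))))
  padj <- p.adjust(ft$p, method = "BH")
  h0 <- which(colnames(ft$groupMeans) == "0")
  if (length(h0) == 0L) stop("0 h time point lost from the F test")
  lfcMat <- ft$groupMeans - ft$groupMeans[, h0]
  maxAbs <- apply(abs(lfcMat), 1, max)
  changing <- padj < alpha & maxAbs > lfc
  out <- DataFrame(label = rep("set1", nrow(m)),
                   F = NA_real_, p = NA_real_, padj = NA_real_,
                   max_abs_lfc = NA_real_, row.names = rownames(m))
  out$label[detected] <- ifelse(changing, "set3", "set2")
  out$F[detected] <- ft$F
  out$p[detected] <- ft$p
  out$padj[detected] <- padj
  out$max_abs_lfc[detected] <- maxAbs
  out
}

#' Map a pathway gene list onto the transcript sets
#'
#' Counts and percentages of a pathway's genes per set (and optionally per
#' changing-set subcluster). Percentages are relative to the full pathway
#' size; \code{pct} is the exact value and \code{pct_rounded} the nearest
#' integer with ties away from zero (matching printed tables). Pathway ids
#' absent from the label universe are counted as unresolved and reported.
#'
#' @param labels named character vector of set labels (the \code{label}
#'   column of \code{classifyTranscriptSets}).
#' @param pathwayGenes character vector of pathway gene ids.
#' @param subclusters optional named vector of subcluster labels for set3
#'   genes (e.g. PAM assignments).
#' @return list with \code{sets} (data.frame: set, count, pct, pct_rounded),
#'   \code{subclusters} (same shape, or NULL), \code{n_pathway},
#'   \code{unresolved}.
#' @export
mapToPathway <- function(labels, pathwayGenes, subclusters = NULL) {
  if (length(pathwayGenes) == 0L) stop("empty pathway gene list")
  nP <- length(pathwayGenes)
  hit <- pathwayGenes %in% names(labels)
  lab <- labels[pathwayGenes[hit]]
  counts <- table(factor(lab, levels = c("set1", "set2", "set3")))
  sets <- data.frame(set = names(counts), count = as.integer(counts),
                     pct = 100 * as.integer(counts) / nP)
  sets$pct_rounded <- roundHalfAway(sets$pct)
  sub <- NULL
  if (!is.null(subclusters)) {
    sl <- subclusters[intersect(pathwayGenes, names(subclusters))]
    ct <- table(sl)
    sub <- data.frame(subcluster = names(ct), count = as.integer(ct),
                      pct = 100 * as.integer(ct) / nP)
    sub$pct_rounded <- roundHalfAway(sub$pct)
  }
  list(sets = sets, subclusters = sub, n_pathway = nP,
       unresolved = sum(!hit))
}

#' Percentage of a count relative to a total, printed-table style
#'
#' @param count,total non-negative counts.
#' @param rounded round to the nearest integer, ties away from zero.
#' @return percentage value.
#' @export
pathwayPercent <- function(count, total, rounded = TRUE) {
  p <- 100 * count / total
  if (rounded) roundHalfAway(p) else p
}

#' Hypergeometric over-representation test
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen number of gene-set members among the term's genes, given
#' the universe; BH adjustment across terms. Terms with no genes in the
#' universe are skipped with a warning.
#'
#' @param geneSet character vector (subset of \code{universe}).
#' @param termToGenes named list mapping term id to gene ids.
#' @param universe character vector of all genes.
#' @return data.frame with \code{term}, \code{k} (hits), \code{K} (term
#'   size in universe), \code{n} (set size), \code{N} (universe size),
#'   \code{p}, \code{q} (BH).
#' @export
overRepresentation <- function(geneSet, termToGenes, universe) {
  if (!all(geneSet %in% universe)) stop("geneSet must be within universe")
  N <- length(universe); n <- length(geneSet)
  sizes <- vapply(termToGenes, function(g) length(intersect(g, universe)),
                  integer(1))
  if (any(sizes == 0L)) {
    warning("skipping term(s) with no genes in universe: ",
            paste(names(termToGenes)[sizes == 0L], collapse = ", "))
    termToGenes <- termToGenes[sizes > 0L]
    sizes <- sizes[sizes > 0L]
  }
  k <- vapply(termToGenes, function(g)
    length(intersect(intersect(g, universe), geneSet)), integer(1))
  # P(X >= k) under Hypergeometric(N, K, n)
  p <- phyper(k - 1, sizes, N - sizes, n, lower.tail = FALSE)
  data.frame(term = names(termToGenes), k = k, K = sizes, n = n, N = N,
             p = unname(p), q = unname(p.adjust(p, "BH")),
             row.names = NULL)
}
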