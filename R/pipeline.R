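#' Pipeline configuration
#'
#' Collects the thresholds and switches used by \code{\link{runPipeline}}.
#' Defaults follow the published constants where they exist (changing-set
#' call at adjusted p < 1e-7 and |log2 FC| > 0.5) and the package defaults
#' elsewhere.
#'
#' @param alpha adjusted-p threshold for the changing set.
#' @param lfc log2 fold-change threshold.
#' @param detectionLog2Rpkm,detectionMinSamples detection rule parameters.
#' @param postPhQuantile,postPhFold Post-PH gene thresholds.
#' @param epsExpression RPKM pseudocount for log transforms.
#' @param epsRatio density pseudocount for ChIP/input ratios.
#' @param metric profile dissimilarity metric.
#' @param kRange candidate cluster numbers for the k-scan.
#' @param chooseK optional explicit k override.
#' @param silhouetteVariant \code{"classical"} or \code{"medoid"}.
#' @param spikeNormalize apply spike-in scaling to ChIP tracks.
#' @param zscoreAxis z-score axis for anchored matrices.
#' @param seed integer seed recorded with every output.
#' @return validated configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(alpha = 1e-7, lfc = 0.5,
                           detectionLog2Rpkm = 0, detectionMinSamples = 1L,
                           postPhQuantile = 0.25, postPhFold = 2,
                           epsExpression = 1, epsRatio = 0.01,
                           metric = "correlation", kRange = 2:10,
                           chooseK = NULL,
                           silhouetteVariant = "classical",
                           spikeNormalize = FALSE,
                           zscoreAxis = "row", seed = 1L) {
  cfg <- list(alpha = alpha, lfc = lfc,
              detectionLog2Rpkm = detectionLog2Rpkm,
              detectionMinSamples = as.integer(detectionMinSamples),
              postPhQuantile = postPhQuantile, postPhFold = postPhFold,
              epsExpression = epsExpression, epsRatio = epsRatio,
              metric = metric, kRange = kRange, chooseK = chooseK,
              silhouetteVariant = silhouetteVariant,
              spikeNormalize = spikeNormalize, zscoreAxis = zscoreAxis,
              seed = as.integer(seed))
  stopifnot(cfg$alpha > 0, cfg$lfc >= 0, cfg$postPhFold > 0,
            cfg$epsExpression > 0, cfg$epsRatio > 0)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a PipelineConfig from YAML
#'
#' @param path YAML file whose keys mirror \code{\link{pipelineConfig}}
#'   arguments.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the expression-side analysis pipeline
#'
#' Stages in dependency order: detection and set classification; PAM
#' clustering of the changing-set PH profiles with silhouette k-scan;
#' sample PCA, hierarchical clustering and PH/sham comparisons; Post-PH
#' gene identification. Optionally, when annotation and ChIP tracks are
#' supplied: promoter/body quantification and the first-internal-exon
#' anchored H3K36me2/me3 analysis. All stage outputs are written as TSV (or
#' Newick) under \code{outdir}, together with a machine-readable
#' \code{summary.json} carrying the seed and configuration echo.
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param outdir output directory.
#' @param config a \code{PipelineConfig}.
#' @param txs optional \code{TxUnitSet} for the chromatin stages.
#' @param tracks optional nested track list
#'   (\code{tracks[[mark]][[hour]]}) as from \code{\link{simulateChip}}.
#' @param anchorTime reference hour for the anchored me2/me3 analysis
#'   (default 60).
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(se, outdir, config = pipelineConfig(),
                        txs = NULL, tracks = NULL, anchorTime = 60) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, name) {
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  cd <- SummarizedExperiment::colData(se)
  m <- SummarizedExperiment::assay(se, "rpkm")

  ## sets
  detected <- detectGenes(se, config$detectionLog2Rpkm,
                          config$detectionMinSamples)
  labels <- classifyTranscriptSets(se, detected, alpha = config$alpha,
                                   lfc = config$lfc,
                                   eps = config$epsExpression)
  wtsv(data.frame(gene_id = rownames(labels), as.data.frame(labels)),
       "set_labels.tsv")
  setSizes <- table(factor(labels$label, c("set1", "set2", "set3")))

  ## clustering of changing genes (replicate-mean PH profiles, log2)
  chg <- rownames(labels)[labels$label == "set3"]
  clusterOut <- NULL
  if (length(chg) >= 3L) {
    phCols <- cd$arm %in% c("control", "PH")
    hours <- sort(unique(cd$hours[phCols]))
    prof <- vapply(hours, function(h)
      rowMeans(m[chg, phCols & cd$hours == h, drop = FALSE]),
      numeric(length(chg)))
    prof <- log2(prof + config$epsExpression)
    rownames(prof) <- chg
    d <- profileDissimilarity(prof, config$metric)
    kr <- config$kRange[config$kRange <= length(chg) - 1L]
    scan <- scanK(d, kr, chooseK = config$chooseK,
                  variant = config$silhouetteVariant)
    cr <- scan$results[[as.character(scan$chosen)]]
    sil <- silhouetteScores(cr, d, config$silhouetteVariant)
    wtsv(scan$table, "k_scan.tsv")
    wtsv(data.frame(gene_id = cr@ids, cluster = cr@assignment,
                    silhouette = unname(sil$widths),
                    is_medoid = seq_along(cr@ids) %in% cr@medoids),
         "clusters.tsv")
    hm <- normalizeForHeatmap(prof, cr, d)
    wtsv(data.frame(gene_id = rownames(hm),
                    cluster = attr(hm, "cluster"), hm,
                    check.names = FALSE), "heatmap_matrix.tsv")
    clusterOut <- list(chosen_k = scan$chosen,
                       avg_silhouette = sil$average,
                       cluster_avg_silhouette = sil$clusterAverage,
                       cluster_sizes = as.integer(table(cr@assignment)),
                       negative_fraction = sil$negativeFraction)
  }

  ## trajectory
  seDet <- se[detected, ]
  pca <- pcaSamples(seDet, eps = config$epsExpression)
  wtsv(data.frame(sample_id = rownames(pca@scores),
                  pca@scores[, 1:min(5, ncol(pca@scores)), drop = FALSE]),
       "pca_scores.tsv")
  hc <- hclusterSamples(seDet, eps = config$epsExpression)
  exportNewick(hc, file.path(outdir, "sample_dendrogram.nwk"))
  ratio <- tryCatch(phShamRatio(se, eps = 0.1), error = function(e) NULL)
  if (!is.null(ratio))
    wtsv(data.frame(gene_id = rownames(m), ratio, check.names = FALSE),
         "ph_sham_ratio.tsv")

  ## Post-PH genes
  pp <- postPhGenes(se, config$postPhQuantile, config$postPhFold,
                    detected = detected)
  writeLines(pp, file.path(outdir, "post_ph_genes.txt"))

  ## chromatin stages
  anchorOut <- NULL
  if (!is.null(txs) && !is.null(tracks) &&
      all(c("h3k36me2", "h3k36me3") %in% names(tracks))) {
    lab <- setNames(labels$label, rownames(labels))
    elig <- eligibleTUs(txs, lab)
    tKey <- as.character(anchorTime)
    me3 <- tracks[["h3k36me3"]][[tKey]]
    me2 <- tracks[["h3k36me2"]][[tKey]]
    if (!is.null(me3) && !is.null(me2) && length(elig$tu_id) >= 2L) {
      if (config$spikeNormalize) {
        me3 <- scaleTrack(me3, spikeInFactor(me3))
        me2 <- scaleTrack(me2, spikeInFactor(me2))
      }
      score <- firstExonMe3Score(txs, me3, elig$tu_id)
      split <- medianSplit(score)
      amU <- buildAnchoredMatrix(txs, me2, split$upper)
      amL <- buildAnchoredMatrix(txs, me2, split$lower)
      contrast <- me2DepletionContrast(amU, amL)
      anchorOut <- list(n_eligible = length(elig$tu_id),
                        excluded = as.list(elig$excluded),
                        upper = length(split$upper),
                        lower = length(split$lower),
                        me2_contrast = contrast)
      wtsv(data.frame(tu_id = names(score), me3_score = unname(score),
                      group = ifelse(names(score) %in% split$upper,
                                     "upper", "lower")),
           "anchor_groups.tsv")
    }
  }

  summary <- list(seed = config$seed,
                  config = unclass(config),
                  n_genes = nrow(m), n_samples = ncol(m),
                  set_sizes = as.list(setSizes),
                  clustering = clusterOut,
                  pca_var_prop = pca@varProp[1:min(5, length(pca@varProp))],
                  n_post_ph = length(pp),
                  anchor = anchorOut)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
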