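#' Simulation configuration for the synthetic liver-regeneration dataset
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults define the emulated study conditions: triplicates on the
#' post-PH/control time grid 0, 1, 4, 10, 20, 28, 36, 44, 48, 60, 72 h,
#' 1 week (168 h) and 4 weeks (672 h), sham surgeries at 1, 4, 10, 20 and
#' 48 h, class proportions mirroring the published undetected / stable /
#' changing split, seven temporal archetypes among changing genes (three
#' decreasing, four increasing, one of which is the 36-72 h proliferation
#' wave), log-normal replicate noise of 0.25 on the log2 scale, a 5%
#' circadian fraction oscillating with a 0.3 log2 amplitude, and a 1/20
#' expected spike-in fragment fraction matching a 19:1 experimental:spike
#' chromatin mix.
#'
#' @param n_genes number of simulated genes.
#' @param class_fractions named proportions for \code{undetected},
#'   \code{stable} and \code{changing_1} .. \code{changing_7}; must sum to 1.
#' @param time_grid_ph,time_grid_sham strictly increasing hour grids; 0 is
#'   allowed only on the PH/control grid.
#' @param n_replicates replicates per condition.
#' @param noise_sd replicate noise sd on the log2 scale (>= 0).
#' @param amplitude archetype amplitude in log2 units.
#' @param circadian_fraction fraction of detected genes with a 24 h sinusoid.
#' @param circadian_amplitude log2 amplitude of the circadian component.
#' @param dormant_fraction fraction of proliferation-archetype genes planted
#'   with a low (dormant) 0 h baseline, i.e. the planted Post-PH genes.
#' @param saa_fraction fraction of stable genes planted as the "Saa-like"
#'   chromatin class (body Pol II without H3K4me3/H3K36me3 but with me2).
#' @param me3_dominant_fraction fraction of transcribed multi-exon TUs whose
#'   gene body past the first internal exon is me3-dominant (me2 depleted)
#'   rather than mixed me2/me3.
#' @param spike_in_fraction expected fraction of fragments assigned to the
#'   spike genome.
#' @param exon_count_range,exon_len_range,intron_len_range integer ranges for
#'   TU structure (bp for lengths).
#' @param long_exon_fraction fraction of first internal exons planted longer
#'   than 2 kb (exercises the length filter of the anchored analysis).
#' @param chrom,chrom_length chromosome name and optional fixed length; when
#'   \code{NULL} the length required to place all TUs with 5 kb flanks is
#'   used.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_genes = 1000L,
                             class_fractions = NULL,
                             time_grid_ph = c(0, 1, 4, 10, 20, 28, 36, 44,
                                              48, 60, 72, 168, 672),
                             time_grid_sham = c(1, 4, 10, 20, 48),
                             n_replicates = 3L,
                             noise_sd = 0.25,
                             amplitude = 2,
                             circadian_fraction = 0.05,
                             circadian_amplitude = 0.3,
                             dormant_fraction = 0.30,
                             saa_fraction = 0.02,
                             me3_dominant_fraction = 0.5,
                             spike_in_fraction = 1 / 20,
                             exon_count_range = c(3L, 9L),
                             exon_len_range = c(100L, 1500L),
                             intron_len_range = c(200L, 2000L),
                             long_exon_fraction = 0.001,
                             chrom = "chrS",
                             chrom_length = NULL,
                             seed = 1L) {
  if (is.null(class_fractions)) {
    # proportions mirroring the published three-set split, changing genes
    # spread evenly over the seven archetypes
    chg <- (1 - 0.6835 - 0.1718) / 7
    class_fractions <- c(undetected = 0.6835, stable = 0.1718,
                         setNames(rep(chg, 7), paste0("changing_", 1:7)))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              class_fractions = class_fractions,
              time_grid_ph = time_grid_ph, time_grid_sham = time_grid_sham,
              n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
              amplitude = amplitude,
              circadian_fraction = circadian_fraction,
              circadian_amplitude = circadian_amplitude,
              dormant_fraction = dormant_fraction,
              saa_fraction = saa_fraction,
              me3_dominant_fraction = me3_dominant_fraction,
              spike_in_fraction = spike_in_fraction,
              exon_count_range = as.integer(exon_count_range),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              long_exon_fraction = long_exon_fraction,
              chrom = chrom, chrom_length = chrom_length,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' Checks the generator invariants: class fractions sum to 1 within 1e-9 and
#' lie in [0, 1]; time grids are strictly increasing and only the PH/control
#' grid may contain 0; the noise sd is non-negative.
#'
#' @param cfg a \code{SimulationConfig}.
#' @return \code{cfg}, invisibly; errors on violation.
#' @export
validateSimulationConfig <- function(cfg) {
  f <- cfg$class_fractions
  need <- c("undetected", "stable", paste0("changing_", 1:7))
  if (!all(need %in% names(f))) stop("class_fractions must name: ",
                                     paste(need, collapse = ", "))
  if (abs(sum(f) - 1) > 1e-9) stop("class_fractions must sum to 1")
  if (any(f < 0 | f > 1)) stop("class_fractions must lie in [0, 1]")
  for (p in c("circadian_fraction", "dormant_fraction", "saa_fraction",
              "me3_dominant_fraction", "spike_in_fraction",
              "long_exon_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (is.unsorted(cfg$time_grid_ph, strictly = TRUE) ||
      is.unsorted(cfg$time_grid_sham, strictly = TRUE))
    stop("time grids must be strictly increasing")
  if (any(cfg$time_grid_sham == 0))
    stop("0 h belongs to the PH/control grid only")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_replicates < 1L) stop("need at least one replicate")
  if (diff(cfg$exon_count_range) < 0 || cfg$exon_count_range[1] < 1L)
    stop("invalid exon_count_range")
  invisible(cfg)
}

#' Temporal archetype templates
#'
#' Seven piecewise-linear templates on the post-PH hour grid, normalised to a
#' peak magnitude of 1 (log2 scale before amplitude scaling): three
#' decreasing (1: early nadir at 4-10 h; 2: broad mid nadir at 20-28 h;
#' 3: late nadir at 60-72 h) and four increasing (4: early peak at 4 h;
#' 5: mid peak at 10 h; 6: peak at 28 h; 7: the proliferation wave peaking at
#' 44-48 h). Archetypes with extrema at or before 20 h (1, 4, 5) are shared
#' with the sham arm; the others are PH-specific.
#'
#' @param hours hours at which to evaluate the templates.
#' @return a 7 x length(hours) matrix of template values in [-1, 1].
#' @export
archetypeTemplates <- function(hours) {
  knots <- list(
    c(0, 0, 1, -0.5, 4, -1, 10, -1, 20, -0.7, 36, -0.4, 48, -0.2, 72, 0, 672, 0),
    c(0, 0, 4, -0.4, 10, -0.7, 20, -1, 28, -1, 36, -0.8, 48, -0.5, 72, -0.2,
      168, 0, 672, 0),
    c(0, 0, 20, 0, 28, -0.3, 44, -0.8, 60, -1, 72, -1, 168, -0.4, 672, 0),
    c(0, 0, 1, 0.5, 4, 1, 10, 0.5, 20, 0.1, 28, 0, 672, 0),
    c(0, 0, 1, 0.1, 4, 0.5, 10, 1, 20, 0.8, 28, 0.3, 36, 0, 672, 0),
    c(0, 0, 10, 0, 20, 0.5, 28, 1, 36, 0.8, 44, 0.4, 48, 0.2, 60, 0, 672, 0),
    c(0, 0, 20, 0, 28, 0.3, 36, 0.8, 44, 1, 48, 1, 60, 0.9, 72, 0.6, 168, 0,
      672, 0))
  do.call(rbind, lapply(knots, function(k) {
    m <- matrix(k, ncol = 2, byrow = TRUE)
    approx(m[, 1], m[, 2], xout = hours, rule = 2)$y
  }))
}

#' Archetypes shared between the sham and PH arms
#'
#' Indices of the archetypes whose extremum falls at or before 20 h; these
#' represent the surgery response common to both arms, while the remaining
#' archetypes (including the proliferation wave) are PH-only.
#'
#' @return integer vector of archetype indices.
#' @export
sharedArchetypes <- function() c(1L, 4L, 5L)

#' Simulate the genome annotation
#'
#' Places \code{n_genes} non-overlapping transcription units on one synthetic
#' chromosome with 5 kb flanks between them, random strand, exon counts and
#' exon/intron lengths drawn uniformly from the configured ranges. A
#' configurable fraction of first internal exons is made longer than 2 kb to
#' exercise the length filter of the anchored analysis. The planted me2-to-me3
#' transition coordinate (the 5' end of the first internal exon) is recorded
#' per TU in the metadata columns \code{transition_bp} and
#' \code{internal_exon_len}.
#'
#' @param cfg a \code{SimulationConfig}.
#' @return a \code{\linkS4class{TxUnitSet}}; the chromosome length is carried
#'   in its \code{seqinfo}.
#' @export
simulateAnnotation <- function(cfg) {
  validateSimulationConfig(cfg)
  set.seed(.subSeed(cfg$seed, "annotation"))
  n <- cfg$n_genes
  ecr <- cfg$exon_count_range; elr <- cfg$exon_len_range
  ilr <- cfg$intron_len_range
  pick <- function(lo, hi, m) lo + sample.int(hi - lo + 1L, m,
                                              replace = TRUE) - 1L
  nex <- pick(ecr[1], ecr[2], n)
  str <- sample(c("+", "-"), n, replace = TRUE)
  flank <- 5000L
  exl <- vector("list", n)
  starts <- integer(n)
  pos <- flank + 1L
  for (i in seq_len(n)) {
    k <- nex[i]
    el <- pick(elr[1], elr[2], k)
    if (k >= 3L && runif(1) < cfg$long_exon_fraction)
      el[2] <- pick(2001L, 4000L, 1L)
    il <- if (k > 1L) pick(ilr[1], ilr[2], k - 1L) else integer(0)
    # genomic blocks in transcription order, then laid out left-to-right;
    # on the minus strand transcription order is right-to-left, so reverse
    lens <- el
    gaps <- il
    if (str[i] == "-") { lens <- rev(lens); gaps <- rev(gaps) }
    s <- pos + c(0L, cumsum(lens + c(gaps, 0L)))[seq_len(k)]
    e <- s + lens - 1L
    exl[[i]] <- IRanges(s, e)
    starts[i] <- pos
    pos <- max(e) + flank + 1L
  }
  required <- pos + flank
  if (!is.null(cfg$chrom_length)) {
    if (cfg$chrom_length < required)
      stop("chromosome too short to place ", n, " TUs: need at least ",
           required, " bp")
    required <- cfg$chrom_length
  }
  si <- Seqinfo(cfg$chrom, seqlengths = as.integer(required))
  gene <- sprintf("g%05d", seq_len(n))
  tuid <- paste0(gene, ".t1")
  exons <- GRangesList(lapply(seq_len(n), function(i)
    GRanges(cfg$chrom, exl[[i]], strand = str[i], seqinfo = si)))
  spans <- unlist(range(exons))
  strand(spans) <- str
  spans$tu_id <- tuid
  spans$gene_id <- gene
  txs <- TxUnitSet(spans, exons)
  # planted transition = 5' end of the first internal exon
  fie <- firstInternalExon(txs)
  m <- match(txIds(txs), fie$tu_id)
  neg <- str == "-"
  tr <- ifelse(neg, end(fie), start(fie))[m]
  txs@units$transition_bp <- as.integer(tr)
  txs@units$internal_exon_len <- as.integer(width(fie)[m])
  validObject(txs)
  txs
}

#' Simulate the expression matrix and ground truth
#'
#' Draws a gene class per gene from the configured class fractions, builds
#' noise-free mean curves (baseline x archetype x circadian components) on
#' the control/PH and sham grids, and emits RPKM values with log-normal
#' replicate noise. Undetected genes are exactly 0 in every sample. Early
#' archetypes are shared between arms; the late and proliferation archetypes
#' are flat in the sham arm. A configured fraction of proliferation-archetype
#' genes is planted with a dormant (low) 0 h baseline; the Post-PH truth flag
#' is computed by applying the Post-PH selection rule to the noise-free
#' curves.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param txs the matching annotation (gene count must equal
#'   \code{cfg$n_genes}).
#' @return a \code{SummarizedExperiment} with assay \code{rpkm}, sample
#'   design in \code{colData} (\code{arm}, \code{hours}, \code{replicate})
#'   and the ground-truth channel in \code{rowData} (\code{gene_class},
#'   \code{archetype_id}, \code{is_circadian}, \code{is_dormant},
#'   \code{is_saa_like}, \code{is_post_ph}, \code{baseline_rpkm}).
#' @export
simulateExpression <- function(cfg, txs) {
  validateSimulationConfig(cfg)
  if (length(unique(geneIds(txs))) != cfg$n_genes)
    stop("annotation gene count does not match cfg$n_genes")
  set.seed(.subSeed(cfg$seed, "expression"))
  n <- cfg$n_genes
  genes <- unique(geneIds(txs))
  classes <- names(cfg$class_fractions)
  cls <- sample(classes, n, replace = TRUE, prob = cfg$class_fractions)
  arch <- rep(NA_integer_, n)
  chg <- grepl("^changing_", cls)
  arch[chg] <- as.integer(sub("changing_", "", cls[chg]))
  detectedClass <- cls != "undetected"
  circ <- detectedClass & runif(n) < cfg$circadian_fraction
  phase <- runif(n, 0, 2 * pi)
  dormant <- !is.na(arch) & arch == 7L & runif(n) < cfg$dormant_fraction
  saa <- cls == "stable" & runif(n) < cfg$saa_fraction
  lb <- pmax(0.5, rnorm(n, mean = 3, sd = 2))        # log2 baseline RPKM
  lb[dormant] <- runif(sum(dormant), -1.3, -0.7)     # dormant: low at 0 h
  baseline <- 2^lb

  tmplPH <- archetypeTemplates(cfg$time_grid_ph)
  tmplSham <- archetypeTemplates(cfg$time_grid_sham)
  tmplSham[setdiff(1:7, sharedArchetypes()), ] <- 0

  # noise-free log2 deviation from baseline, per gene x condition
  devFor <- function(hours, tmpl) {
    d <- matrix(0, n, length(hours))
    idx <- which(!is.na(arch))
    d[idx, ] <- tmpl[arch[idx], , drop = FALSE] * cfg$amplitude
    zt <- 2 + hours  # surgery at Zeitgeber time 2
    cidx <- which(circ)
    if (length(cidx))
      d[cidx, ] <- d[cidx, ] + cfg$circadian_amplitude *
        cos(outer(phase[cidx], 2 * pi * zt / 24, function(p, z) z - p))
    d
  }
  devPH <- devFor(cfg$time_grid_ph, tmplPH)
  devSham <- devFor(cfg$time_grid_sham, tmplSham)

  buildArm <- function(hours, dev, armName) {
    reps <- seq_len(cfg$n_replicates)
    cols <- expand.grid(replicate = reps, hours = hours)
    arm <- if (is.null(armName)) ifelse(cols$hours == 0, "control", "PH")
           else rep(armName, nrow(cols))
    mu <- dev[, match(cols$hours, hours), drop = FALSE]
    noise <- matrix(rnorm(n * nrow(cols), 0, cfg$noise_sd), n)
    rpkm <- baseline * 2^(mu + noise)
    rpkm[cls == "undetected", ] <- 0
    mu0 <- baseline * 2^mu          # noise-free means (replicates identical)
    mu0[cls == "undetected", ] <- 0
    list(rpkm = rpkm, mu = mu0, design = data.frame(
      arm = arm, hours = cols$hours, replicate = cols$replicate))
  }
  ph <- buildArm(cfg$time_grid_ph, devPH, NULL)
  sh <- buildArm(cfg$time_grid_sham, devSham, "sham")
  rpkm <- cbind(ph$rpkm, sh$rpkm)
  design <- rbind(ph$design, sh$design)
  design$sample_id <- paste0(substr(design$arm, 1, 1), design$hours, "r",
                             design$replicate)
  design$sample_id <- sub("^c", "C", sub("^P", "X", sub("^s", "S",
                          design$sample_id)))
  colnames(rpkm) <- design$sample_id
  rownames(rpkm) <- genes

  # truth channel: apply the Post-PH rule to the noise-free curves
  detectedTrue <- apply(cbind(ph$mu, sh$mu), 1, function(x) any(x >= 1))
  mean0 <- ph$mu[, which(cfg$time_grid_ph == 0)[1]]
  post <- cfg$time_grid_ph > 0
  maxPost <- apply(ph$mu[, post, drop = FALSE], 1, max)
  isPostPh <- .postPhRule(mean0, maxPost, detectedTrue,
                          lowQuantile = 0.25, fold = 2, eps = 0.1)

  truth <- DataFrame(gene_class = cls, archetype_id = arch,
                     is_circadian = circ, is_dormant = dormant,
                     is_saa_like = saa, is_post_ph = isPostPh,
                     baseline_rpkm = baseline, circadian_phase = phase,
                     row.names = genes)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm),
    colData = DataFrame(design, row.names = design$sample_id),
    rowData = truth,
    metadata = list(config = cfg))
}

#' Write the simulated expression matrix, design and truth tables as TSV
#'
#' @param se the \code{SummarizedExperiment} from \code{simulateExpression}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeExpressionTSV <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  m <- SummarizedExperiment::assay(se, "rpkm")
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(SummarizedExperiment::colData(se)),
              paths["design"], sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  write.table(data.frame(gene_id = rownames(rd), rd),
              paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read an expression matrix and design table from TSV
#'
#' @param expressionPath TSV with a \code{gene_id} column then one column per
#'   sample (RPKM scale).
#' @param designPath TSV with \code{sample_id}, \code{arm}, \code{hours},
#'   \code{replicate}.
#' @return a \code{SummarizedExperiment} with assay \code{rpkm}.
#' @export
readExpressionTSV <- function(expressionPath, designPath) {
  m <- read.delim(expressionPath, check.names = FALSE)
  rn <- m$gene_id
  m <- as.matrix(m[, setdiff(colnames(m), "gene_id"), drop = FALSE])
  rownames(m) <- rn
  d <- read.delim(designPath)
  d <- d[match(colnames(m), d$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = m),
    colData = DataFrame(d, row.names = d$sample_id))
}
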