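#' Fragment-center density track from fragment intervals
#'
#' Each sequenced fragment contributes one unit of coverage over the 50 bp
#' centred on its midpoint (odd lengths: floored midpoint, window
#' [mid - 25, mid + 25) in 0-based terms). Fragments shorter than 50 bp
#' contribute over their full extent and are counted with a warning. The
#' resulting per-base counts are scaled per million fragments.
#'
#' @param fragments \code{GRanges} of fragment intervals; \code{seqlengths}
#'   must be set (they bound the track).
#' @param mark mark label stored on the track.
#' @param hours time point stored on the track.
#' @param spikeFragments number of fragments that mapped to the spike genome
#'   (recorded, never part of the density).
#' @param normalize scale per million fragments (default) or keep raw counts.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
fragmentCenterDensity <- function(fragments, mark = "chip", hours = 0,
                                  spikeFragments = 0, normalize = TRUE) {
  if (any(width(fragments) < 1L)) stop("fragment end must exceed start")
  sl <- seqlengths(fragments)
  if (any(is.na(sl))) stop("fragments must carry seqlengths")
  short <- width(fragments) < 50L
  if (any(short))
    warning(sum(short), " fragment(s) shorter than 50 bp contribute over ",
            "their full extent")
  n <- length(fragments)
  mid0 <- (start(fragments) - 1L + end(fragments)) %/% 2L
  s <- ifelse(short, start(fragments), mid0 - 24L)
  e <- ifelse(short, end(fragments), mid0 + 25L)
  win <- GRanges(seqnames(fragments),
                 IRanges(pmax(s, 1L),
                         pmin(e, sl[as.character(seqnames(fragments))])),
                 seqinfo = seqinfo(fragments))
  cov <- coverage(win)
  if (normalize && n > 0) cov <- cov * (1e6 / n)
  new("CoverageTrack", mark = mark, hours = as.numeric(hours),
      density = cov, totalFragments = as.numeric(n),
      spikeFragments = as.numeric(spikeFragments))
}

#' Constant-density track (noise-free uniform coverage)
#'
#' @param value density value everywhere.
#' @param seqinfo a \code{Seqinfo} describing the genome.
#' @param mark,hours track labels.
#' @param totalFragments,spikeFragments recorded fragment counts.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
uniformTrack <- function(value, seqinfo, mark = "input", hours = 0,
                         totalFragments = 0, spikeFragments = 0) {
  dens <- RleList(lapply(setNames(seqlengths(seqinfo), seqlevels(seqinfo)),
                         function(L) Rle(value, L)))
  new("CoverageTrack", mark = mark, hours = as.numeric(hours),
      density = dens, totalFragments = as.numeric(totalFragments),
      spikeFragments = as.numeric(spikeFragments))
}

#' Spike-in scale factor
#'
#' Converts the observed spike-genome fragment fraction into a multiplicative
#' scale factor relative to the reference mix (1 part spike to 19 parts
#' experimental chromatin, i.e. a 1/20 reference fraction). Tracks whose
#' spike recovery is higher than the reference are scaled down.
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param referenceSpikeFraction expected spike fraction of the input mix.
#' @return scale factor = reference fraction / observed fraction.
#' @export
spikeInFactor <- function(track, referenceSpikeFraction = 1 / 20) {
  if (track@spikeFragments <= 0)
    stop("spike normalization impossible: zero spike fragments")
  observed <- track@spikeFragments /
    (track@spikeFragments + track@totalFragments)
  referenceSpikeFraction / observed
}

#' Apply a multiplicative scale factor to a track
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param factor scale factor (e.g. from \code{spikeInFactor}).
#' @return the scaled track.
#' @export
scaleTrack <- function(track, factor) {
  track@density <- track@density * factor
  track
}

#' Mean per-base density over genomic windows
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param windows \code{GRanges} of windows (clipped to chromosome bounds).
#' @return numeric vector of mean densities, named like \code{windows}.
#' @export
quantifyWindow <- function(track, windows) {
  if (length(windows) == 0L) return(numeric(0))
  if (any(width(windows) < 1L)) stop("empty quantification window")
  out <- numeric(length(windows))
  for (chr in unique(as.character(seqnames(windows)))) {
    r <- track@density[[chr]]
    if (is.null(r)) stop("chromosome '", chr, "' not in track")
    i <- which(as.character(seqnames(windows)) == chr)
    s <- pmax(start(windows)[i], 1L)
    e <- pmin(end(windows)[i], length(r))
    if (any(s > e)) stop("window entirely outside chromosome bounds")
    out[i] <- viewMeans(Views(r, s, e))
  }
  names(out) <- names(windows)
  out
}

#' log2 ChIP/input ratio with pseudocount
#'
#' @param chip,input densities (same length).
#' @param eps pseudocount in density units; stabilises empty windows.
#' @return log2((chip + eps) / (input + eps)).
#' @export
log2ChipInput <- function(chip, input, eps = 0.01) {
  log2((chip + eps) / (input + eps))
}

#' Identify Post-PH genes from the expression time course
#'
#' A gene qualifies when its mean 0 h RPKM is at or below the given quantile
#' of detected-gene 0 h expression and its maximal post-PH replicate-mean
#' RPKM reaches at least \code{fold} times the 0 h mean (plus a pseudocount).
#' The thresholds are package choices; they are exposed as arguments.
#'
#' @param se expression \code{SummarizedExperiment} (assay \code{rpkm},
#'   colData \code{arm}/\code{hours}).
#' @param lowQuantile quantile of detected-gene 0 h expression defining
#'   "low" (default 0.25).
#' @param fold required fold elevation over the 0 h mean (default 2).
#' @param eps pseudocount in RPKM units.
#' @param detected optional logical vector (defaults to
#'   \code{detectGenes(se)}).
#' @return character vector of qualifying gene ids.
#' @export
postPhGenes <- function(se, lowQuantile = 0.25, fold = 2, eps = 0.1,
                        detected = NULL) {
  cd <- SummarizedExperiment::colData(se)
  if (!any(cd$hours == 0)) stop("no 0 h samples present")
  m <- SummarizedExperiment::assay(se, "rpkm")
  if (is.null(detected)) detected <- detectGenes(se)
  mean0 <- rowMeans(m[, cd$hours == 0, drop = FALSE])
  postCols <- cd$arm == "PH" & cd$hours > 0
  hoursPost <- sort(unique(cd$hours[postCols]))
  means <- vapply(hoursPost, function(h)
    rowMeans(m[, postCols & cd$hours == h, drop = FALSE]),
    numeric(nrow(m)))
  maxPost <- apply(means, 1, max)
  ok <- .postPhRule(mean0, maxPost, detected, lowQuantile, fold, eps)
  rownames(m)[ok]
}

#' Per-window ChIP/input signal table
#'
#' Quantifies one chip track against the matched input over a set of windows
#' and returns a tidy table with the log2 ratio.
#'
#' @param chip,input \code{\linkS4class{CoverageTrack}}s at the same time.
#' @param windows named \code{GRanges} of quantification windows.
#' @param eps ratio pseudocount (density units).
#' @return data.frame with \code{id}, \code{mark}, \code{hours},
#'   \code{chip}, \code{input}, \code{log2_ratio}.
#' @export
markSignal <- function(chip, input, windows, eps = 0.01) {
  cd <- quantifyWindow(chip, windows)
  id <- quantifyWindow(input, windows)
  data.frame(id = names(windows), mark = chip@mark, hours = chip@hours,
             chip = unname(cd), input = unname(id),
             log2_ratio = unname(log2ChipInput(cd, id, eps)))
}

#' Distribution summary of mark signal over a gene set
#'
#' Collapses a mark-signal table (rows = gene x mark x time) into per
#' (mark, time) distribution summaries: median and quartiles of the log2
#' ChIP/input ratios, ready for violin-style display with a median trace.
#'
#' @param signal data.frame as returned by \code{markSignal} (possibly
#'   row-bound over marks and times).
#' @return data.frame with \code{mark}, \code{hours}, \code{n},
#'   \code{median}, \code{q25}, \code{q75}.
#' @export
markDistributionSummary <- function(signal) {
  if (nrow(signal) == 0L) stop("empty signal table")
  sp <- split(signal, list(signal$mark, signal$hours), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    mark = d$mark[1], hours = d$hours[1], n = nrow(d),
    median = median(d$log2_ratio),
    q25 = quantile(d$log2_ratio, 0.25, names = FALSE),
    q75 = quantile(d$log2_ratio, 0.75, names = FALSE))))
  rownames(out) <- NULL
  out[order(out$mark, out$hours), ]
}

#' Onset time of a median signal trace
#'
#' The onset is the first time point at which the median log2 ratio reaches
#' the given fraction of its dynamic range (min + frac * (max - min)).
#'
#' @param summary data.frame from \code{markDistributionSummary}.
#' @param mark mark to extract.
#' @param frac fraction of the dynamic range (default 0.5, half-activation).
#' @return onset hour, or \code{NA} if the trace is flat.
#' @export
medianOnset <- function(summary, mark, frac = 0.5) {
  d <- summary[summary$mark == mark, ]
  d <- d[order(d$hours), ]
  if (nrow(d) == 0L) stop("mark not in summary: ", mark)
  rng <- range(d$median)
  if (diff(rng) < 1e-12) return(NA_real_)
  thr <- rng[1] + frac * diff(rng)
  d$hours[which(d$median >= thr)[1]]
}

#' Flag genes with Pol II but neither H3K4me3 nor H3K36me3
#'
#' Simple classifier for the acute-response chromatin phenotype: genes whose
#' gene-body Pol II log2 ratio lies above the cohort median while both
#' H3K4me3 and H3K36me3 lie below their cohort medians (H3K36me2 presence is
#' not required but typically retained on such genes).
#'
#' @param bodyPolII,k4me3,k36me3 named numeric vectors of log2 ratios over a
#'   common gene cohort.
#' @return character vector of flagged gene ids.
#' @export
polIIOnlyGenes <- function(bodyPolII, k4me3, k36me3) {
  g <- names(bodyPolII)
  stopifnot(identical(g, names(k4me3)), identical(g, names(k36me3)))
  flag <- bodyPolII > median(bodyPolII) &
    k4me3 < median(k4me3) & k36me3 < median(k36me3)
  g[flag]
}

#' Write a CoverageTrack as bedGraph
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrackBedGraph <- function(track, path) {
  gr <- as(track@density, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a CoverageTrack
#'
#' @param path bedGraph path.
#' @param seqinfo \code{Seqinfo} giving chromosome lengths.
#' @param mark,hours,totalFragments,spikeFragments track metadata.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
readTrackBedGraph <- function(path, seqinfo, mark = "chip", hours = 0,
                              totalFragments = 0, spikeFragments = 0) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  seqlevels(gr) <- seqlevels(seqinfo)
  seqinfo(gr) <- seqinfo
  new("CoverageTrack", mark = mark, hours = as.numeric(hours),
      density = coverage(gr, weight = gr$score),
      totalFragments = as.numeric(totalFragments),
      spikeFragments = as.numeric(spikeFragments))
}
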