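#' Transcription units eligible for the first-internal-exon analysis
#'
#' Transcribed TUs (gene classified set2 or set3) with at least three exons
#' and a first internal exon no longer than 2 kb. The counts of each
#' exclusion are reported alongside the surviving TU ids.
#'
#' @param txs a \code{TxUnitSet}.
#' @param labels named set labels per gene (\code{set1}/\code{set2}/
#'   \code{set3}).
#' @param maxExonLength internal-exon length cap in bp (default 2000).
#' @return list with \code{tu_id} (eligible ids) and \code{excluded}
#'   (named counts: not_transcribed, few_exons, long_exon).
#' @export
eligibleTUs <- function(txs, labels, maxExonLength = 2000L) {
  gid <- geneIds(txs)
  transcribed <- labels[gid] %in% c("set2", "set3")
  nex <- lengths(txs@exons)
  fie <- firstInternalExon(txs)
  len <- width(fie)[match(txIds(txs), fie$tu_id)]
  enough <- nex >= 3L
  short <- !is.na(len) & len <= maxExonLength
  keep <- transcribed & enough & short
  list(tu_id = txIds(txs)[keep],
       excluded = c(not_transcribed = sum(!transcribed),
                    few_exons = sum(transcribed & !enough),
                    long_exon = sum(transcribed & enough & !short)))
}

#' H3K36me3 score over 2 kb downstream of the first-internal-exon 5' end
#'
#' Mean density over the 2 kb extending downstream (in transcription
#' orientation) from the 5' end of the first internal exon. Windows running
#' past the TU 3' end are still used at their fixed 2 kb extent and flagged.
#'
#' @param txs a \code{TxUnitSet}.
#' @param track an H3K36me3 \code{\linkS4class{CoverageTrack}} at the
#'   reference time.
#' @param tuIds TUs to score (must have an internal exon).
#' @param windowSize window extent in bp (default 2000).
#' @return named numeric scores with a logical \code{past_end} attribute.
#' @export
firstExonMe3Score <- function(txs, track, tuIds, windowSize = 2000L) {
  fie <- firstInternalExon(txs)
  m <- match(tuIds, fie$tu_id)
  if (anyNA(m)) stop("TU(s) without internal exon: ",
                     paste(head(tuIds[is.na(m)], 5), collapse = ", "))
  fie <- fie[m]
  u <- txs@units[tuIds]
  neg <- as.character(strand(u)) == "-"
  a5 <- ifelse(neg, end(fie), start(fie))
  s <- ifelse(neg, a5 - windowSize + 1L, a5)
  e <- ifelse(neg, a5, a5 + windowSize - 1L)
  pastEnd <- ifelse(neg, s < start(u), e > end(u))
  w <- GRanges(seqnames(u), IRanges(s, e), seqinfo = seqinfo(u))
  names(w) <- tuIds
  score <- quantifyWindow(track, w)
  attr(score, "past_end") <- setNames(pastEnd, tuIds)
  score
}

#' Median split of TUs by score
#'
#' Items strictly above the median form the upper group; items at or below
#' it the lower group, so n distinct odd scores split (n-1)/2 upper and
#' (n+1)/2 lower. Groups are returned sorted by id for determinism. A fully
#' tied score vector leaves the upper group empty with a warning.
#'
#' @param scores named numeric vector (finite).
#' @return list with \code{upper} and \code{lower} id vectors and
#'   \code{median}.
#' @export
medianSplit <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  md <- median(scores)
  upper <- sort(names(scores)[scores > md])
  lower <- sort(names(scores)[scores <= md])
  if (length(upper) == 0L)
    warning("degenerate split: all scores at or below the median")
  list(upper = upper, lower = lower, median = md)
}

#' Build a base-pair-resolution matrix anchored at the first internal exon
#'
#' For each TU, per-base densities from \code{upstream} bp before to
#' \code{downstream} bp after the 3' end of the first internal exon, in
#' transcription orientation (minus-strand rows are reversed). Rows are
#' sorted by increasing internal-exon length (ties by TU id), so the 5' exon
#' edge drifts across the matrix. Bases falling outside the chromosome are
#' NA and excluded from column statistics. Z-scoring is available per row
#' (each TU against its own mean/sd) or globally.
#'
#' @param txs a \code{TxUnitSet}.
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param tuIds TUs to include (need an internal exon).
#' @param upstream,downstream window extent around the anchor (defaults
#'   4000 and 1000, i.e. positions -4000..999).
#' @param zscore \code{"none"}, \code{"row"} or \code{"global"}.
#' @return an \code{\linkS4class{AnchoredMatrix}}.
#' @export
buildAnchoredMatrix <- function(txs, track, tuIds, upstream = 4000L,
                                downstream = 1000L,
                                zscore = c("none", "row", "global")) {
  zscore <- match.arg(zscore)
  fie <- firstInternalExon(txs)
  m <- match(tuIds, fie$tu_id)
  if (anyNA(m)) stop("TU(s) without internal exon")
  fie <- fie[m]
  u <- txs@units[tuIds]
  exonLen <- width(fie)
  o <- order(exonLen, tuIds)
  tuIds <- tuIds[o]; fie <- fie[o]; u <- u[o]; exonLen <- exonLen[o]
  neg <- as.character(strand(u)) == "-"
  anchor <- ifelse(neg, start(fie), end(fie))  # 3' end of internal exon
  chrom <- as.character(seqnames(u))
  width <- upstream + downstream
  mat <- matrix(NA_real_, length(tuIds), width)
  for (i in seq_along(tuIds)) {
    r <- track@density[[chrom[i]]]
    if (neg[i]) { gs <- anchor[i] - downstream + 1L; ge <- anchor[i] + upstream }
    else        { gs <- anchor[i] - upstream;        ge <- anchor[i] + downstream - 1L }
    cs <- max(gs, 1L); ce <- min(ge, length(r))
    vals <- as.numeric(r[cs:ce])
    row <- rep(NA_real_, width)
    row[(cs - gs + 1L):(ce - gs + 1L)] <- vals
    if (neg[i]) row <- rev(row)
    mat[i, ] <- row
  }
  positions <- seq.int(-upstream, downstream - 1L)
  if (zscore == "row") {
    mu <- rowMeans(mat, na.rm = TRUE)
    sdev <- apply(mat, 1, sd, na.rm = TRUE)
    mat <- (mat - mu) / ifelse(sdev > 0, sdev, 1)
  } else if (zscore == "global") {
    mu <- mean(mat, na.rm = TRUE); sdev <- sd(as.numeric(mat), na.rm = TRUE)
    mat <- (mat - mu) / if (sdev > 0) sdev else 1
  }
  new("AnchoredMatrix", mat = mat, positions = as.integer(positions),
      tuIds = tuIds, exonLength = as.integer(exonLen),
      anchorLabel = "3' end of first internal exon", zscored = zscore)
}

#' Two-segment change-point of an anchored profile
#'
#' Finds the split of the profile into a left and a right segment that
#' maximises the between-segment separation (equivalently minimises the
#' within-segment sum of squares) and returns the relative position of the
#' first base of the right segment. Adding a constant to the profile does
#' not move the estimate. Flat profiles have no change-point and return NA.
#'
#' @param profile numeric vector (e.g. one H3K36me3 row, or an
#'   me3 - me2 difference profile); NAs are ignored.
#' @param positions relative positions parallel to \code{profile}.
#' @return relative position of the step, or NA.
#' @export
transitionPoint <- function(profile, positions) {
  ok <- !is.na(profile)
  y <- profile[ok]; pos <- positions[ok]
  n <- length(y)
  if (n < 2L || diff(range(y)) < 1e-12) return(NA_real_)
  cs <- cumsum(y)
  j <- seq_len(n - 1L)
  m1 <- cs[j] / j
  m2 <- (cs[n] - cs[j]) / (n - j)
  between <- j * (n - j) * (m1 - m2)^2
  pos[which.max(between) + 1L]
}

#' Change-points for all rows of an anchored matrix
#'
#' @param am an \code{\linkS4class{AnchoredMatrix}} (optionally the
#'   difference of two, see \code{\link{anchoredDifference}}).
#' @return named numeric vector of per-TU transition positions (NA where
#'   undefined).
#' @export
transitionPoints <- function(am) {
  setNames(apply(am@mat, 1, transitionPoint, positions = am@positions),
           am@tuIds)
}

#' Difference of two anchored matrices (e.g. me3 - me2)
#'
#' @param a,b \code{\linkS4class{AnchoredMatrix}}s over the same TUs and
#'   positions.
#' @return an \code{\linkS4class{AnchoredMatrix}} of \code{a - b}.
#' @export
anchoredDifference <- function(a, b) {
  stopifnot(identical(a@tuIds, b@tuIds),
            identical(a@positions, b@positions))
  a@mat <- a@mat - b@mat
  a@anchorLabel <- paste(a@anchorLabel, "(difference)")
  a
}

#' H3K36me2 depletion contrast between the split groups
#'
#' Per group, the ratio of mean me2 density downstream of the anchor
#' (positions 0 to +1 kb) to upstream of it (-3 kb to -2 kb). On
#' me3-dominant TUs me2 drops where me3 appears (ratio < 1); on mixed TUs
#' the platform persists (ratio near 1). The difference (lower - upper)
#' summarises the contrast; a positive sign recovers the planted two-class
#' structure.
#'
#' @param upperMat,lowerMat me2 \code{\linkS4class{AnchoredMatrix}}s for the
#'   upper and lower median-split groups.
#' @param downstreamRange,upstreamRange relative position ranges.
#' @return list with \code{upper_ratio}, \code{lower_ratio},
#'   \code{difference}.
#' @export
me2DepletionContrast <- function(upperMat, lowerMat,
                                 downstreamRange = c(0, 999),
                                 upstreamRange = c(-3000, -2001)) {
  ratio <- function(am) {
    dn <- am@positions >= downstreamRange[1] &
      am@positions <= downstreamRange[2]
    up <- am@positions >= upstreamRange[1] &
      am@positions <= upstreamRange[2]
    den <- mean(am@mat[, up], na.rm = TRUE)
    if (!is.finite(den) || den <= 0) return(NA_real_)
    mean(am@mat[, dn], na.rm = TRUE) / den
  }
  ru <- ratio(upperMat); rl <- ratio(lowerMat)
  list(upper_ratio = ru, lower_ratio = rl, difference = rl - ru)
}
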