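#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle runValue
#' @importFrom IRanges IRanges IRangesList Views viewMeans RleList
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand strand<-
#'   start end width coverage granges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqinfo seqinfo<-
#'   seqlevels seqlevels<- Seqinfo
#' @importFrom stats approx as.dist cor cutree dist hclust median p.adjust pf
#'   phyper prcomp quantile rnorm rpois runif sd setNames var
#' @importFrom utils head read.delim write.table
NULL

#' Set of transcription units with exon structure
#'
#' A \code{TxUnitSet} holds one stranded gene model per transcription unit
#' (TU): the TU span as a \code{GRanges} (with \code{tu_id} and \code{gene_id}
#' metadata columns) and the exons as a parallel \code{GRangesList} in genomic
#' order. The transcription start site (TSS) is the 5'-most transcribed base,
#' the poly(A) end the 3'-most; on the minus strand the TSS is the genomically
#' rightmost base. Coordinates are 1-based closed throughout (the native
#' Bioconductor convention); BED input/output converts on the fly.
#'
#' @slot units \code{GRanges} of TU spans, named by \code{tu_id}.
#' @slot exons \code{GRangesList} of exons per TU, same names, genomic order.
#' @exportClass TxUnitSet
setClass("TxUnitSet", representation(units = "GRanges", exons = "GRangesList"))

setValidity("TxUnitSet", function(object) {
  u <- object@units; e <- object@exons
  if (length(u) != length(e)) return("units and exons lengths differ")
  if (!identical(names(u), names(e))) return("units and exons names differ")
  if (length(u) == 0L) return(TRUE)
  if (is.null(u$tu_id) || is.null(u$gene_id))
    return("units must carry tu_id and gene_id metadata columns")
  rng <- unlist(range(e))
  if (any(start(rng) < start(u)) || any(end(rng) > end(u)))
    return("exons extend outside their TU span")
  ok <- vapply(e, function(x) {
    s <- start(x)
    length(s) == 0L || (!is.unsorted(s, strictly = TRUE) &&
      all(start(x)[-1] > head(end(x), -1)))
  }, logical(1))
  if (!all(ok)) return("exons must be non-overlapping and sorted")
  TRUE
})

#' Per-base fragment-center density track
#'
#' One ChIP (or input) coverage track for one chromatin mark at one time
#' point. The density is the per-base count of central-50-bp fragment windows,
#' scaled per million fragments, stored run-length encoded. The spike fragment
#' count records how many sequenced fragments mapped to the exogenous spike
#' genome and never contributes to the density itself.
#'
#' @slot mark mark name, e.g. \code{"polII"}, \code{"h3k36me3"}, \code{"input"}.
#' @slot hours time point in hours post-surgery.
#' @slot density named \code{RleList}, one \code{Rle} per chromosome.
#' @slot totalFragments number of fragments on the experimental genome.
#' @slot spikeFragments number of fragments on the spike genome.
#' @exportClass CoverageTrack
setClass("CoverageTrack", representation(
  mark = "character", hours = "numeric", density = "RleList",
  totalFragments = "numeric", spikeFragments = "numeric"))

setValidity("CoverageTrack", function(object) {
  if (length(object@mark) != 1L) return("mark must be a single string")
  if (length(object@hours) != 1L) return("hours must be a single number")
  if (any(vapply(object@density, function(r) any(runValue(r) < 0), logical(1))))
    return("densities must be non-negative")
  if (object@totalFragments < 0 || object@spikeFragments < 0)
    return("fragment counts must be non-negative")
  TRUE
})

#' Partitioning-around-medoids clustering result
#'
#' @slot k number of clusters.
#' @slot ids item identifiers (dissimilarity matrix order).
#' @slot medoids integer indices of the k medoids into \code{ids}.
#' @slot assignment integer cluster label per item (1..k), named by id.
#' @slot cost total dissimilarity of items to their assigned medoid.
#' @slot metric label of the dissimilarity backend used.
#' @exportClass ClusterResult
setClass("ClusterResult", representation(
  k = "integer", ids = "character", medoids = "integer",
  assignment = "integer", cost = "numeric", metric = "character"))

setValidity("ClusterResult", function(object) {
  n <- length(object@ids)
  if (length(object@medoids) != object@k) return("need k medoids")
  if (length(object@assignment) != n) return("assignment length != n items")
  if (!all(object@assignment %in% seq_len(object@k)))
    return("assignments must lie in 1..k")
  if (!identical(object@assignment[object@medoids], seq_len(object@k)))
    return("medoid i must be assigned to cluster i")
  TRUE
})

#' TU-by-position density matrix anchored at the first internal exon
#'
#' Rows are transcription units sorted by increasing first-internal-exon
#' length (ties by TU id); columns are base positions relative to the 3' end
#' of the first internal exon, in transcription orientation (minus-strand TUs
#' are reversed so "upstream" is always 5').
#'
#' @slot mat numeric matrix, TUs x positions; off-chromosome bases are NA.
#' @slot positions integer vector of relative positions (default -4000..999).
#' @slot tuIds row TU ids.
#' @slot exonLength first-internal-exon length per row, in bp.
#' @slot anchorLabel free-text description of the anchor.
#' @slot zscored \code{"none"}, \code{"row"} or \code{"global"}.
#' @exportClass AnchoredMatrix
setClass("AnchoredMatrix", representation(
  mat = "matrix", positions = "integer", tuIds = "character",
  exonLength = "integer", anchorLabel = "character", zscored = "character"))

setValidity("AnchoredMatrix", function(object) {
  if (ncol(object@mat) != length(object@positions))
    return("column count must match positions")
  if (nrow(object@mat) != length(object@tuIds))
    return("row count must match tuIds")
  if (nrow(object@mat) != length(object@exonLength))
    return("row count must match exonLength")
  o <- order(object@exonLength, object@tuIds)
  if (!identical(o, seq_along(o)))
    return("rows must be sorted by increasing exon length (ties by TU id)")
  TRUE
})

#' Sample-level principal component analysis result
#'
#' @slot scores samples x components score matrix.
#' @slot loadings genes x components orthonormal loading matrix.
#' @slot varProp proportion of variance per component.
#' @slot center per-gene means removed before the SVD.
#' @exportClass PcaResult
setClass("PcaResult", representation(
  scores = "matrix", loadings = "matrix", varProp = "numeric",
  center = "numeric"))

setMethod("show", "TxUnitSet", function(object) {
  cat("TxUnitSet with", length(object@units), "transcription units,",
      length(unique(object@units$gene_id)), "genes\n")
  if (length(object@units)) {
    ne <- lengths(object@exons)
    cat("  exons per TU:", min(ne), "-", max(ne),
        "| >=3 exons:", sum(ne >= 3L), "\n")
  }
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:", object@mark, "at", object@hours, "h;",
      object@totalFragments, "fragments (+", object@spikeFragments,
      "spike)\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "on", length(object@ids),
      "items; cost =", format(object@cost, digits = 6),
      "; metric =", object@metric, "\n")
  print(table(cluster = object@assignment))
})

setMethod("show", "AnchoredMatrix", function(object) {
  cat("AnchoredMatrix:", nrow(object@mat), "TUs x", ncol(object@mat),
      "positions [", min(object@positions), "..", max(object@positions),
      "]; z-score:", object@zscored, "\n")
})

setMethod("show", "PcaResult", function(object) {
  cat("PcaResult:", nrow(object@scores), "samples,",
      ncol(object@scores), "components; variance proportions:",
      paste(format(head(object@varProp, 5), digits = 3), collapse = ", "),
      "...\n")
})

## ---- accessors ----

#' Accessors for TxUnitSet and related objects
#'
#' @param x a \code{TxUnitSet}, \code{CoverageTrack}, \code{ClusterResult},
#'   \code{AnchoredMatrix} or \code{PcaResult}.
#' @return the corresponding slot content; see individual functions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
txUnits <- function(x) x@units

#' @rdname accessors
#' @export
txExons <- function(x) x@exons

#' @rdname accessors
#' @export
txIds <- function(x) as.character(x@units$tu_id)

#' @rdname accessors
#' @export
geneIds <- function(x) as.character(x@units$gene_id)

#' Transcription start site positions (1-based, strand-aware)
#' @rdname accessors
#' @export
tssPos <- function(x) {
  u <- x@units
  ifelse(as.character(strand(u)) == "-", end(u), start(u))
}

#' Poly(A)-end positions (3'-most transcribed base)
#' @rdname accessors
#' @export
polyAPos <- function(x) {
  u <- x@units
  ifelse(as.character(strand(u)) == "-", start(u), end(u))
}

#' @rdname accessors
#' @export
trackDensity <- function(x) x@density

#' @rdname accessors
#' @export
trackMark <- function(x) x@mark

#' @rdname accessors
#' @export
trackHours <- function(x) x@hours

#' @rdname accessors
#' @export
totalFragments <- function(x) x@totalFragments

#' @rdname accessors
#' @export
spikeFragments <- function(x) x@spikeFragments

#' @rdname accessors
#' @export
clusterAssignment <- function(x) setNames(x@assignment, x@ids)

#' @rdname accessors
#' @export
clusterMedoids <- function(x) setNames(x@medoids, x@ids[x@medoids])

#' @rdname accessors
#' @export
clusterCost <- function(x) x@cost

#' @rdname accessors
#' @export
anchoredValues <- function(x) {
  m <- x@mat
  dimnames(m) <- list(x@tuIds, x@positions)
  m
}

#' @rdname accessors
#' @export
anchorPositions <- function(x) x@positions

#' @rdname accessors
#' @export
anchorExonLength <- function(x) setNames(x@exonLength, x@tuIds)

#' @rdname accessors
#' @export
pcaScores <- function(x) x@scores

#' @rdname accessors
#' @export
pcaLoadings <- function(x) x@loadings

#' @rdname accessors
#' @export
pcaVarProp <- function(x) x@varProp
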