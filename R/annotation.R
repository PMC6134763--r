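#' Construct a TxUnitSet
#'
#' @param units \code{GRanges} of TU spans with \code{tu_id} and
#'   \code{gene_id} metadata columns.
#' @param exons \code{GRangesList} of exons parallel to \code{units}
#'   (genomic order within each element).
#' @return a validated \code{\linkS4class{TxUnitSet}}.
#' @export
TxUnitSet <- function(units, exons) {
  names(units) <- as.character(units$tu_id)
  names(exons) <- names(units)
  new("TxUnitSet", units = units, exons = exons)
}

#' Exons in transcription (5' to 3') order
#'
#' For plus-strand TUs this is genomic order; for minus-strand TUs the
#' genomically rightmost exon comes first.
#'
#' @param txs a \code{TxUnitSet}.
#' @return a \code{GRangesList} with exons ordered 5' to 3' per TU.
#' @export
exonsByTranscription <- function(txs) {
  e <- txs@exons
  neg <- as.character(strand(txs@units)) == "-"
  if (any(neg)) e[neg] <- S4Vectors::endoapply(e[neg], rev)
  e
}

#' First internal exon of each eligible TU
#'
#' The first internal exon is the second exon in transcription order; it is
#' defined only for TUs with at least three exons (so that the exon is
#' flanked by exons on both sides).
#'
#' @param txs a \code{TxUnitSet}.
#' @return a \code{GRanges} with one range per TU having >= 3 exons, carrying
#'   \code{tu_id}; TUs without an internal exon are absent.
#' @export
firstInternalExon <- function(txs) {
  keep <- lengths(txs@exons) >= 3L
  if (!any(keep)) {
    g <- GRanges()
    g$tu_id <- character(0)
    return(g)
  }
  e5 <- exonsByTranscription(txs)[keep]
  second <- unlist(S4Vectors::endoapply(e5, `[`, 2L), use.names = FALSE)
  second$tu_id <- names(e5)
  names(second) <- names(e5)
  second
}

#' Read a gene-model annotation from GTF or BED12
#'
#' GTF files are recognised by their \code{.gtf}/\code{.gff} extension and
#' must carry \code{transcript_id}/\code{gene_id} attributes on exon records;
#' anything else is read as BED12, where the block structure defines the
#' exons and the BED name field the TU id (gene id defaults to the TU id
#' stripped of a trailing \code{.tN} suffix). Exons are returned in genomic
#' order regardless of file order; strand is preserved. Exon records falling
#' outside their TU span are rejected with a warning.
#'
#' @param path file path.
#' @return a \code{\linkS4class{TxUnitSet}}.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0L) {
    g <- GRanges(); g$tu_id <- character(0); g$gene_id <- character(0)
    return(TxUnitSet(g, GRangesList()))
  }
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    tu <- gr[gr$type == "transcript"]
    if (length(tu) == 0L && length(ex) == 0L)
      return(TxUnitSet(GRanges(tu_id = character(0), gene_id = character(0)),
                       GRangesList()))
    exl <- S4Vectors::split(granges(ex), as.character(ex$transcript_id))
    exl <- S4Vectors::endoapply(exl, BiocGenerics::sort)
    if (length(tu) == 0L) { # derive spans from exons
      sp <- unlist(range(exl))
      tuids <- names(exl)
      g2 <- ex$gene_id[match(tuids, as.character(ex$transcript_id))]
      str <- as.character(strand(ex))[match(tuids, as.character(ex$transcript_id))]
      strand(sp) <- str
      sp$tu_id <- tuids; sp$gene_id <- as.character(g2)
      return(TxUnitSet(sp, exl[tuids]))
    }
    tuids <- as.character(tu$transcript_id)
    units <- granges(tu)
    units$tu_id <- tuids
    units$gene_id <- as.character(tu$gene_id)
    # reject exons outside their TU span
    m <- match(names(exl), tuids)
    bad <- is.na(m)
    for (i in which(!bad)) {
      e <- exl[[i]]; u <- units[m[i]]
      out <- start(e) < start(u) | end(e) > end(u)
      if (any(out)) {
        warning("rejected ", sum(out), " exon(s) outside span of TU ",
                names(exl)[i])
        exl[[i]] <- e[!out]
      }
    }
    exl <- exl[!bad]
    m <- m[!bad]
    o <- order(m)
    TxUnitSet(units[sort(m)], exl[o])
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) {
      g <- GRanges(); g$tu_id <- character(0); g$gene_id <- character(0)
      return(TxUnitSet(g, GRangesList()))
    }
    tuids <- as.character(gr$name)
    blocks <- gr$blocks # IRangesList of starts relative to TU start
    exl <- GRangesList(lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      GRanges(seqnames(gr)[i],
              IRanges(start(gr)[i] + start(b) - 1L,
                      start(gr)[i] + end(b) - 1L),
              strand = strand(gr)[i])
    }))
    units <- granges(gr)
    units$tu_id <- tuids
    units$gene_id <- sub("\\.t[0-9]+$", "", tuids)
    TxUnitSet(units, exl)
  }
}

#' Write a TxUnitSet as GTF
#'
#' Emits gene, transcript and exon records with \code{gene_id},
#' \code{transcript_id} and (for exons) \code{exon_number} attributes.
#'
#' @param txs a \code{TxUnitSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGTF <- function(txs, path) {
  u <- txs@units
  e5 <- exonsByTranscription(txs)
  tu <- granges(u)
  tu$type <- "transcript"
  tu$gene_id <- as.character(u$gene_id)
  tu$transcript_id <- as.character(u$tu_id)
  ex <- unlist(e5, use.names = FALSE)
  idx <- rep(seq_along(u), lengths(e5))
  ex <- granges(ex)
  ex$type <- "exon"
  ex$gene_id <- as.character(u$gene_id)[idx]
  ex$transcript_id <- as.character(u$tu_id)[idx]
  ex$exon_number <- as.character(unlist(lapply(lengths(e5), seq_len)))
  all <- c(tu, ex)
  all <- all[order(match(all$transcript_id, u$tu_id),
                   all$type == "exon", as.integer(all$exon_number))]
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Write a TxUnitSet as BED12 (one record per TU)
#'
#' @param txs a \code{TxUnitSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationBED12 <- function(txs, path) {
  u <- granges(txs@units)
  u$name <- as.character(txs@units$tu_id)
  u$score <- 0L
  u$blocks <- IRangesList(mapply(function(e, s) {
    IRanges(start(e) - s + 1L, end(e) - s + 1L)
  }, as.list(txs@exons), start(u), SIMPLIFY = FALSE))
  names(u) <- NULL
  rtracklayer::export(u, path, format = "bed")
  invisible(path)
}

#' Symmetric promoter window around the TSS
#'
#' The promoter is defined as \code{half_width} bp upstream and downstream of
#' the annotated TSS (so 250 bp for Pol II quantification, 500 bp for
#' H3K4me3). Because the window is symmetric it is strand-independent in
#' genomic coordinates. Windows are clipped at chromosome bounds when
#' sequence lengths are available; a \code{clipped} metadata column flags
#' affected windows.
#'
#' @param txs a \code{TxUnitSet}.
#' @param half_width half window width in bp (> 0).
#' @return \code{GRanges} of promoter windows named by TU id, with
#'   \code{anchor_label} and \code{clipped} metadata columns.
#' @export
promoterWindow <- function(txs, half_width = 250L) {
  stopifnot(half_width > 0)
  u <- txs@units
  tss <- tssPos(txs)
  sl <- seqlengths(u)[as.character(seqnames(u))]
  s <- tss - half_width
  e <- tss + half_width - 1L
  clipped <- s < 1L | (!is.na(sl) & e > sl)
  s2 <- pmax(s, 1L)
  e2 <- ifelse(is.na(sl), e, pmin(e, sl))
  if (any(!is.na(sl) & (tss < 1L | tss > sl)))
    stop("TSS outside chromosome bounds")
  w <- GRanges(seqnames(u), IRanges(s2, e2), strand = strand(u),
               seqinfo = seqinfo(u))
  names(w) <- names(u)
  w$anchor_label <- if (half_width >= 500) "promoter_k4" else "promoter_polII"
  w$clipped <- clipped
  w
}

#' Gene-body window
#'
#' The gene body is defined strand-aware as 500 bp downstream of the TSS to
#' 2 kb downstream of the poly(A)-addition site, clipped at chromosome
#' bounds. TUs shorter than 500 bp have no body and raise an error.
#'
#' @param txs a \code{TxUnitSet}.
#' @return \code{GRanges} of body windows named by TU id.
#' @export
bodyWindow <- function(txs) {
  u <- txs@units
  if (any(width(u) <= 500L))
    stop("body undefined: TU(s) shorter than 500 bp: ",
         paste(head(names(u)[width(u) <= 500L], 5), collapse = ", "))
  neg <- as.character(strand(u)) == "-"
  s <- ifelse(neg, start(u) - 2000L, start(u) + 500L)
  e <- ifelse(neg, end(u) - 500L, end(u) + 2000L)
  sl <- seqlengths(u)[as.character(seqnames(u))]
  s <- pmax(s, 1L)
  e <- ifelse(is.na(sl), e, pmin(e, sl))
  w <- GRanges(seqnames(u), IRanges(s, e), strand = strand(u),
               seqinfo = seqinfo(u))
  names(w) <- names(u)
  w$anchor_label <- "body"
  w
}

#' Select the representative TU per gene by promoter Pol II occupancy
#'
#' Among the TUs annotated for one gene, the one with the maximal mean Pol II
#' density over its promoter window (TSS +/- 250 bp) at the reference time is
#' retained. Ties break deterministically to the 5'-most TSS, then to the
#' lexicographically smallest TU id.
#'
#' @param txs a \code{TxUnitSet} (possibly several TUs per gene).
#' @param polIITrack a \code{\linkS4class{CoverageTrack}} of Pol II at the
#'   reference time.
#' @param half_width promoter half width (bp).
#' @return a \code{TxUnitSet} with one TU per gene.
#' @export
selectRepresentativeTU <- function(txs, polIITrack, half_width = 250L) {
  if (length(txs@units) == 0L) return(txs)
  w <- promoterWindow(txs, half_width)
  dens <- quantifyWindow(polIITrack, w)
  u <- txs@units
  str <- as.character(strand(u))
  tss <- tssPos(txs)
  # 5'-most = smallest coordinate on +, largest on -
  tieTss <- ifelse(str == "-", -tss, tss)
  o <- order(as.character(u$gene_id), -dens, tieTss, as.character(u$tu_id))
  keep <- o[!duplicated(as.character(u$gene_id)[o])]
  keep <- sort(keep)
  TxUnitSet(u[keep], txs@exons[keep])
}

#' Export quantification windows as BED6
#'
#' Writes windows with the anchor label joined to the TU id in the BED name
#' field.
#'
#' @param windows \code{GRanges} as produced by \code{promoterWindow} or
#'   \code{bodyWindow}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWindowsBED <- function(windows, path) {
  g <- granges(windows)
  g$name <- paste(names(windows), windows$anchor_label, sep = "|")
  g$score <- 0L
  names(g) <- NULL
  rtracklayer::export(g, path, format = "bed")
  invisible(path)
}
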