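#' Default fragment rates for the chip simulator
#'
#' Rates are expected fragments per base pair before activation scaling.
#' \code{me2_depletion} is the multiplicative loss of H3K36me2 downstream of
#' the planted transition on me3-dominant TUs; \code{k4_premark} is the
#' activation-independent floor of promoter H3K4me3 (the pre-marking level);
#' \code{me3_leak} is the residual H3K36me3 rate upstream of the first
#' internal exon.
#'
#' @return named list of rates.
#' @export
chipRates <- function() {
  list(polII_prom = 0.30, polII_body = 0.08, h3k4me3 = 0.30,
       h3k36me2 = 0.12, h3k36me3 = 0.15, background = 0.002,
       input = 0.05, me3_leak = 0.005, me2_depletion = 0.3,
       k4_premark = 0.7)
}

# piecewise-linear activation curves planted for Post-PH genes: promoter
# Pol II recruitment precedes gene-body elongation. The planted onsets (half
# dynamic range crossing) are 4 h for the promoter and 36 h for the body.
.postPhPromCurve <- function(hours) {
  m <- matrix(c(0, 0.15, 1, 0.1, 4, 0.55, 10, 0.7, 20, 0.6, 28, 0.8,
                36, 0.95, 44, 1, 48, 0.9, 60, 0.5, 72, 0.3, 168, 0.15,
                672, 0.15), ncol = 2, byrow = TRUE)
  approx(m[, 1], m[, 2], xout = hours, rule = 2)$y
}

.postPhBodyCurve <- function(hours) {
  m <- matrix(c(0, 0.05, 20, 0.05, 28, 0.3, 36, 0.7, 44, 1, 48, 0.95,
                60, 0.7, 72, 0.4, 168, 0.1, 672, 0.1), ncol = 2,
              byrow = TRUE)
  approx(m[, 1], m[, 2], xout = hours, rule = 2)$y
}

#' Planted chromatin onset times for Post-PH genes
#'
#' First hour at which the planted activation curve crosses half of its
#' dynamic range: 4 h for promoter Pol II, 36 h for body Pol II and
#' H3K36me3.
#'
#' @return named numeric vector with \code{promoter} and \code{body}.
#' @export
plantedChipOnsets <- function() c(promoter = 4, body = 36)

# per-gene activation matrices (genes x times) for promoter and body
.chipActivation <- function(truth, hours, amplitude) {
  n <- nrow(truth)
  prom <- matrix(0, n, length(hours))
  body <- matrix(0, n, length(hours))
  stable <- truth$gene_class == "stable"
  prom[stable, ] <- 1; body[stable, ] <- 1
  chg <- which(!is.na(truth$archetype_id))
  if (length(chg)) {
    tmpl <- archetypeTemplates(hours)
    for (i in chg) {
      v <- tmpl[truth$archetype_id[i], ]
      lin <- 2^(amplitude * v)
      act <- 0.2 + 0.8 * (lin - min(lin)) /
        max(max(lin) - min(lin), 1e-12)
      prom[i, ] <- act; body[i, ] <- act
    }
  }
  pp <- which(truth$is_post_ph)
  if (length(pp)) {
    prom[pp, ] <- matrix(.postPhPromCurve(hours), length(pp),
                         length(hours), byrow = TRUE)
    body[pp, ] <- matrix(.postPhBodyCurve(hours), length(pp),
                         length(hours), byrow = TRUE)
  }
  list(prom = prom, body = body)
}

#' Simulate ChIP fragment-density tracks with planted chromatin structure
#'
#' For each requested (mark, time) pair, fragment midpoints are drawn from
#' planted per-TU rate profiles plus a uniform background, fragments of
#' 150-250 bp are formed around them, and the track is built with
#' \code{\link{fragmentCenterDensity}}. The planted structure follows the
#' regeneration chromatin programme: promoter Pol II rises before gene-body
#' Pol II on Post-PH TUs; H3K4me3 pre-marks active promoters at all times;
#' H3K36me2 forms a platform over the transcribed body; H3K36me3 is near
#' zero upstream of the first internal exon and rises downstream of it, with
#' me2 depleted downstream on me3-dominant TUs and retained on mixed TUs;
#' "Saa-like" TUs carry Pol II and me2 but neither H3K4me3 nor H3K36me3;
#' input is uniform. Spike-genome fragment counts are drawn per track with
#' the configured expected fraction.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param txs annotation from \code{simulateAnnotation}.
#' @param truth gene-level truth (the \code{rowData} of
#'   \code{simulateExpression}, as a data.frame-like with rownames = gene
#'   ids).
#' @param marks subset of \code{c("polII","h3k4me3","h3k36me2","h3k36me3",
#'   "input")}.
#' @param times hours at which to emit tracks.
#' @param rates rate list, see \code{\link{chipRates}}.
#' @return list with \code{tracks} (nested: \code{tracks[[mark]][[time]]}),
#'   and \code{truth} (per-TU data.frame: \code{tu_id}, \code{me3_class},
#'   \code{is_post_ph}, \code{prom_onset}, \code{body_onset},
#'   \code{transition_bp}).
#' @export
simulateChip <- function(cfg, txs, truth,
                         marks = c("polII", "h3k4me3", "h3k36me2",
                                   "h3k36me3", "input"),
                         times = cfg$time_grid_ph,
                         rates = chipRates()) {
  validateSimulationConfig(cfg)
  known <- c("polII", "h3k4me3", "h3k36me2", "h3k36me3", "input")
  if (!all(marks %in% known))
    stop("unknown mark(s): ", paste(setdiff(marks, known), collapse = ", "))
  u <- txs@units
  gidx <- match(geneIds(txs), rownames(truth))
  if (any(is.na(gidx))) stop("truth table does not cover all genes")
  tu_truth <- truth[gidx, , drop = FALSE]
  si <- seqinfo(u)
  L <- seqlengths(si)[[cfg$chrom]]
  act <- .chipActivation(tu_truth, times, cfg$amplitude)
  detected <- tu_truth$gene_class != "undetected"
  saa <- tu_truth$is_saa_like

  set.seed(.subSeed(cfg$seed, "chip-class"))
  hasInternal <- !is.na(u$transition_bp)
  me3class <- rep(NA_character_, length(u))
  cand <- which(detected & hasInternal)
  me3class[cand] <- ifelse(runif(length(cand)) < cfg$me3_dominant_fraction,
                           "dominant", "mixed")

  neg <- as.character(strand(u)) == "-"
  tss <- tssPos(txs)
  tr <- u$transition_bp
  upS <- ifelse(neg, tr + 1L, start(u)); upE <- ifelse(neg, end(u), tr - 1L)
  dnS <- ifelse(neg, start(u), tr);      dnE <- ifelse(neg, tr, end(u))
  prom250 <- promoterWindow(txs, 250L)
  prom500 <- promoterWindow(txs, 500L)
  # tolerant body coordinates (TSS+500 .. polyA+2000, strand-aware); unlike
  # bodyWindow() this does not reject sub-500 bp TUs, it just drops them
  bwS <- pmax(1L, ifelse(neg, start(u) - 2000L, start(u) + 500L))
  bwE <- pmin(L, ifelse(neg, end(u) - 500L, end(u) + 2000L))
  bodyOk <- width(u) > 500L

  regionsFor <- function(mark, ti) {
    a_p <- act$prom[, ti]; a_b <- act$body[, ti]
    s <- integer(0); e <- integer(0); r <- numeric(0)
    add <- function(ss, ee, rr) {
      keep <- rr > 0 & ee >= ss
      s <<- c(s, ss[keep]); e <<- c(e, ee[keep]); r <<- c(r, rr[keep])
    }
    if (mark == "polII") {
      add(start(prom250), end(prom250),
          rates$polII_prom * a_p * detected)
      # Saa-like TUs carry elevated body Pol II despite absent K4/K36me3
      add(bwS, bwE, rates$polII_body * a_b * detected * bodyOk *
            (1 + saa))
    } else if (mark == "h3k4me3") {
      rr <- rates$h3k4me3 *
        (rates$k4_premark + (1 - rates$k4_premark) * a_p) *
        detected * !saa
      add(start(prom500), end(prom500), rr)
    } else if (mark == "h3k36me2") {
      dep <- ifelse(!is.na(me3class) & me3class == "dominant",
                    rates$me2_depletion, 1)
      wI <- hasInternal & detected
      add(upS[wI], upE[wI], rep(rates$h3k36me2, sum(wI)))
      add(dnS[wI], dnE[wI], rates$h3k36me2 * dep[wI])
      wN <- !hasInternal & detected
      add(start(u)[wN], end(u)[wN], rep(rates$h3k36me2, sum(wN)))
    } else if (mark == "h3k36me3") {
      ok <- detected & !saa
      wI <- hasInternal & ok
      add(upS[wI], upE[wI], rep(rates$me3_leak, sum(wI)))
      add(dnS[wI], dnE[wI], rates$h3k36me3 * a_b[wI])
      wN <- !hasInternal & ok
      # no internal exon: me3 accumulates over the body past the TSS
      bs <- ifelse(neg, start(u), tss + 500L)
      be <- ifelse(neg, tss - 500L, end(u))
      add(bs[wN], be[wN], rates$h3k36me3 * a_b[wN])
    }
    if (mark == "input") {
      add(1L, L, rates$input)
    } else {
      add(1L, L, rates$background)
    }
    list(s = s, e = e, r = r)
  }

  tracks <- list()
  for (mark in marks) {
    tracks[[mark]] <- list()
    for (ti in seq_along(times)) {
      t <- times[ti]
      set.seed(.subSeed(cfg$seed, paste0("chip-", mark, "-", t)))
      rg <- regionsFor(mark, ti)
      len <- rg$e - rg$s + 1
      nfrag <- rpois(length(rg$s), rg$r * len)
      tot <- sum(nfrag)
      idx <- rep.int(seq_along(nfrag), nfrag)
      mid <- floor(runif(tot, rg$s[idx], rg$e[idx] + 1))
      flen <- sample(150:250, tot, replace = TRUE)
      fs <- pmax(1L, as.integer(mid - flen %/% 2L))
      fe <- pmin(L, as.integer(fs + flen - 1L))
      frags <- GRanges(cfg$chrom, IRanges(fs, fe), seqinfo = si)
      f <- cfg$spike_in_fraction
      spike <- rpois(1, tot * f / (1 - f))
      tracks[[mark]][[as.character(t)]] <-
        fragmentCenterDensity(frags, mark = mark, hours = t,
                              spikeFragments = spike)
    }
  }
  onsets <- plantedChipOnsets()
  list(tracks = tracks,
       truth = data.frame(
         tu_id = txIds(txs), me3_class = me3class,
         is_post_ph = tu_truth$is_post_ph,
         prom_onset = ifelse(tu_truth$is_post_ph, onsets["promoter"], NA),
         body_onset = ifelse(tu_truth$is_post_ph, onsets["body"], NA),
         transition_bp = u$transition_bp))
}
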