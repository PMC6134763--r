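# small chip+annotation simulation shared by the anchored-analysis tests
anchorSim <- function(n = 60, seed = 71) {
  cfg <- simulationConfig(
    n_genes = n, seed = seed,
    class_fractions = c(undetected = 0.1, stable = 0.9,
                        setNames(rep(0, 7), paste0("changing_", 1:7))))
  txs <- simulateAnnotation(cfg)
  se <- simulateExpression(cfg, txs)
  ch <- simulateChip(cfg, txs, SummarizedExperiment::rowData(se),
                     marks = c("h3k36me2", "h3k36me3"), times = 60)
  labels <- setNames(ifelse(
    SummarizedExperiment::rowData(se)$gene_class == "undetected",
    "set1", "set2"), rownames(se))
  list(cfg = cfg, txs = txs, se = se, ch = ch, labels = labels)
}

test_that("eligibility applies the exon-count and exon-length filters", {
  s <- anchorSim()
  el <- eligibleTUs(s$txs, s$labels)
  nex <- lengths(txExons(s$txs))
  fie <- firstInternalExon(s$txs)
  lens <- setNames(GenomicRanges::width(fie), fie$tu_id)
  manual <- txIds(s$txs)[s$labels[geneIds(s$txs)] != "set1" &
                           nex >= 3L &
                           !is.na(lens[txIds(s$txs)]) &
                           lens[txIds(s$txs)] <= 2000L]
  expect_setequal(el$tu_id, manual)
  expect_equal(sum(el$excluded) + length(el$tu_id), length(txUnits(s$txs)))
  # 2-exon TU and >2 kb internal exon are excluded
  two <- TxUnitSet(txUnits(toyTxUnits())[1],
                   S4Vectors::endoapply(txExons(toyTxUnits())[1], `[`, 1:2))
  lab <- c(gA = "set2")
  expect_length(eligibleTUs(two, lab)$tu_id, 0L)
  big <- toyTxUnits()
  e <- txExons(big)
  e[[1]] <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(1001, 2001, 9001), c(1200, 4500, 9500)),
    strand = "+", seqinfo = GenomeInfoDb::Seqinfo("chrT", 100000L))
  u <- txUnits(big); GenomicRanges::ranges(u)[1] <- IRanges::IRanges(1001, 9500)
  big <- TxUnitSet(u[1], e[1])
  expect_equal(unname(eligibleTUs(big, lab)$excluded["long_exon"]), 1L)
})

test_that("me3 scores over the 2 kb window match a per-base oracle", {
  s <- anchorSim()
  me3 <- s$ch$tracks$h3k36me3[["60"]]
  el <- eligibleTUs(s$txs, s$labels)
  score <- firstExonMe3Score(s$txs, me3, el$tu_id)
  r <- as.numeric(trackDensity(me3)[["chrS"]])
  fie <- firstInternalExon(s$txs)
  for (id in el$tu_id[1:5]) {
    f <- fie[fie$tu_id == id]
    u <- txUnits(s$txs)[id]
    if (as.character(GenomicRanges::strand(u)) == "+") {
      a <- GenomicRanges::start(f); win <- r[a:(a + 1999)]
    } else {
      a <- GenomicRanges::end(f); win <- r[(a - 1999):a]
    }
    expect_equal(unname(score[id]), mean(win), tolerance = 1e-12)
  }
  # zero track scores zero
  zero <- uniformTrack(0, GenomeInfoDb::seqinfo(txUnits(s$txs)),
                       mark = "h3k36me3")
  expect_true(all(firstExonMe3Score(s$txs, zero, el$tu_id) == 0))
})

test_that("median split puts strictly-above-median items in the upper half", {
  set.seed(31)
  sc <- setNames(sample(seq_len(9801)) / 7, paste0("tu", 1:9801))
  sp <- medianSplit(sc)
  expect_length(sp$upper, 4900L)
  expect_length(sp$lower, 4901L)
  expect_true(all(sc[sp$upper] > sp$median))
  expect_true(all(sc[sp$lower] <= sp$median))
  # n = 4 distinct scores -> 2/2
  sp4 <- medianSplit(setNames(c(1, 2, 3, 4), letters[1:4]))
  expect_equal(lengths(sp4[c("upper", "lower")]),
               c(upper = 2L, lower = 2L))
  # all-tied scores: empty upper with warning
  expect_warning(spT <- medianSplit(setNames(rep(1, 5), letters[1:5])),
                 "degenerate")
  expect_length(spT$upper, 0L)
  expect_error(medianSplit(c(a = 1, b = NA)), "finite")
})

test_that("anchored matrices align rows on the internal-exon 3' end", {
  s <- anchorSim()
  el <- eligibleTUs(s$txs, s$labels)
  # uniform track -> constant matrix, row z-scores ~ 0
  u <- uniformTrack(3, GenomeInfoDb::seqinfo(txUnits(s$txs)))
  amU <- buildAnchoredMatrix(s$txs, u, el$tu_id)
  expect_true(all(amU@mat == 3, na.rm = TRUE))
  amZ <- buildAnchoredMatrix(s$txs, u, el$tu_id, zscore = "row")
  expect_lt(max(abs(amZ@mat), na.rm = TRUE), 1e-9)
  expect_equal(ncol(amU@mat), 5000L)
  expect_equal(range(anchorPositions(amU)), c(-4000L, 999L))
  # rows sorted by increasing internal-exon length; row set = input TUs
  expect_setequal(amU@tuIds, el$tu_id)
  expect_true(!is.unsorted(anchorExonLength(amU)))
  # me3 rows step up within the row's exon span
  me3 <- s$ch$tracks$h3k36me3[["60"]]
  am <- buildAnchoredMatrix(s$txs, me3, el$tu_id)
  pos <- anchorPositions(am)
  vals <- anchoredValues(am)
  exl <- anchorExonLength(am)
  within <- vapply(seq_len(nrow(vals)), function(i)
    mean(vals[i, pos >= -exl[i] + 100 & pos < 0], na.rm = TRUE),
    numeric(1))
  expect_gt(median(within), 0)
})

test_that("strand mirroring leaves the anchored matrix unchanged", {
  s <- anchorSim(n = 12, seed = 42)
  el <- eligibleTUs(s$txs, s$labels)
  me3 <- s$ch$tracks$h3k36me3[["60"]]
  am <- buildAnchoredMatrix(s$txs, me3, el$tu_id)
  # mirror genome and annotation through position L+1-x
  L <- GenomeInfoDb::seqlengths(txUnits(s$txs))[["chrS"]]
  mirror <- function(gr) {
    s2 <- L + 1L - GenomicRanges::end(gr)
    e2 <- L + 1L - GenomicRanges::start(gr)
    GenomicRanges::ranges(gr) <- IRanges::IRanges(s2, e2)
    GenomicRanges::strand(gr) <- ifelse(
      as.character(GenomicRanges::strand(gr)) == "+", "-", "+")
    gr
  }
  u2 <- mirror(txUnits(s$txs))
  e2 <- S4Vectors::endoapply(txExons(s$txs),
                             function(e) BiocGenerics::sort(mirror(e)))
  txsM <- TxUnitSet(u2, e2)
  r <- trackDensity(me3)[["chrS"]]
  me3M <- new("CoverageTrack", mark = "h3k36me3", hours = 60,
              density = IRanges::RleList(chrS = rev(r)),
              totalFragments = totalFragments(me3), spikeFragments = 0)
  amM <- buildAnchoredMatrix(txsM, me3M, el$tu_id)
  expect_equal(amM@mat, am@mat, tolerance = 1e-12)
})

test_that("transition points recover planted me2-to-me3 switches", {
  # ideal noiseless step at -1200 is found exactly
  pos <- seq.int(-4000, 999)
  prof <- ifelse(pos >= -1200, 5, 0)
  expect_equal(transitionPoint(prof, pos), -1200)
  # adding a constant does not move the estimate
  expect_equal(transitionPoint(prof + 7, pos), -1200)
  # flat profile is undefined
  expect_true(is.na(transitionPoint(rep(2, 5000), pos)))
  # planted recovery on simulated tracks
  s <- anchorSim(n = 60, seed = 7)
  el <- eligibleTUs(s$txs, s$labels)
  me3 <- s$ch$tracks$h3k36me3[["60"]]
  am <- buildAnchoredMatrix(s$txs, me3, el$tu_id)
  tp <- transitionPoints(am)
  exl <- anchorExonLength(am)
  err <- tp + exl[names(tp)] - 1     # planted switch at -(len - 1)
  expect_lte(median(abs(err), na.rm = TRUE), 50)
})

test_that("me2 depletion separates me3-dominant from mixed TUs", {
  s <- anchorSim(n = 80, seed = 3)
  el <- eligibleTUs(s$txs, s$labels)
  me2 <- s$ch$tracks$h3k36me2[["60"]]
  cls <- setNames(s$ch$truth$me3_class, s$ch$truth$tu_id)
  dom <- intersect(el$tu_id, names(cls)[!is.na(cls) & cls == "dominant"])
  mix <- intersect(el$tu_id, names(cls)[!is.na(cls) & cls == "mixed"])
  amD <- buildAnchoredMatrix(s$txs, me2, dom)
  amM <- buildAnchoredMatrix(s$txs, me2, mix)
  ct <- me2DepletionContrast(amD, amM)
  expect_lt(ct$upper_ratio, 1)       # planted depletion past the switch
  expect_gt(ct$difference, 0)        # mixed TUs keep their platform
})
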