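fragTrack <- function(starts, ends, len = 10000L, normalize = FALSE) {
  si <- GenomeInfoDb::Seqinfo("chrT", seqlengths = len)
  fr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(starts, ends),
                               seqinfo = si)
  fragmentCenterDensity(fr, normalize = normalize)
}

test_that("fragment-center density covers the central 50 bp", {
  # fragment spanning bases 1..100 -> unit coverage on bases 26..75
  tr <- fragTrack(1, 100)
  r <- trackDensity(tr)[["chrT"]]
  expect_equal(as.numeric(r[25:76]), c(0, rep(1, 50), 0))
  # duplicate fragments double the density on the same support
  tr2 <- fragTrack(c(1, 1), c(100, 100))
  expect_equal(as.numeric(trackDensity(tr2)[["chrT"]][26:75]), rep(2, 50))
  # odd-length fragment: floored midpoint
  tr3 <- fragTrack(1, 101)   # 0-based [0,101), mid 50 -> bases 26..75
  expect_equal(sum(as.numeric(trackDensity(tr3)[["chrT"]][26:75])), 50)
  # short fragments contribute over their full extent, with warning
  expect_warning(tr4 <- fragTrack(11, 20), "shorter than 50")
  expect_equal(sum(as.numeric(trackDensity(tr4)[["chrT"]])), 10)
  expect_error(fragTrack(10, 9), "exceed")
})

test_that("track mass scales per million fragments", {
  set.seed(2)
  s <- sample(1000:8000, 200, replace = TRUE)
  tr <- fragTrack(s, s + 199, normalize = TRUE)
  # each of n fragments contributes 50 bases; per-million scaling means
  # total mass = 50 * 1e6 regardless of n
  expect_equal(sum(as.numeric(trackDensity(tr)[["chrT"]])), 50 * 1e6)
  expect_equal(totalFragments(tr), 200)
})

test_that("window quantification equals the per-base oracle", {
  set.seed(4)
  s <- sample(500:9000, 120, replace = TRUE)
  tr <- fragTrack(s, s + 180)
  r <- as.numeric(trackDensity(tr)[["chrT"]])
  w <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(400, 2000, 9900), c(900, 2000, 9990)))
  got <- quantifyWindow(tr, w)
  oracle <- vapply(seq_along(w), function(i)
    mean(r[GenomicRanges::start(w)[i]:GenomicRanges::end(w)[i]]),
    numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  # uniform track returns the constant for any window
  u <- toyUniformTrack(2.5)
  expect_equal(unname(quantifyWindow(u,
    GenomicRanges::GRanges("chrT", IRanges::IRanges(5, 500)))), 2.5)
  # region with no fragments is zero
  expect_equal(unname(got[3]), 0)
  # additivity: density integrates over disjoint windows
  w2 <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(1000, 3001), c(3000, 5000)))
  whole <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1000, 5000))
  lhs <- sum(quantifyWindow(tr, w2) * GenomicRanges::width(w2))
  rhs <- quantifyWindow(tr, whole) * GenomicRanges::width(whole)
  expect_equal(lhs, unname(rhs), tolerance = 1e-9)
})

test_that("spike-in factors follow the 19:1 reference mix", {
  tr <- fragTrack(1:50 * 100, 1:50 * 100 + 99)
  tr@spikeFragments <- 50 / 19          # observed fraction = 1/20
  expect_equal(spikeInFactor(tr), 1, tolerance = 1e-12)
  tr@spikeFragments <- 50 / 9           # observed fraction = 1/10
  expect_equal(spikeInFactor(tr), 0.5, tolerance = 1e-12)
  tr@spikeFragments <- 0
  expect_error(spikeInFactor(tr), "spike normalization impossible")
  # scaling leaves within-track ratios unchanged
  tr@spikeFragments <- 10
  sc <- scaleTrack(tr, spikeInFactor(tr))
  w <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(100, 300),
                                                       c(199, 399)))
  q0 <- quantifyWindow(tr, w); q1 <- quantifyWindow(sc, w)
  expect_equal(q1[1] / q1[2], q0[1] / q0[2], tolerance = 1e-12)
})

test_that("log2 chip/input ratios behave algebraically", {
  expect_equal(log2ChipInput(3, 3), 0)
  expect_equal(log2ChipInput(4, 1, eps = 1e-12), 2, tolerance = 1e-9)
  # antisymmetry
  expect_equal(log2ChipInput(5, 2), -log2ChipInput(2, 5))
})

test_that("Post-PH gene identification follows the low-then-elevated rule", {
  sim <- fixtureSim()
  se <- sim$se
  tr <- SummarizedExperiment::rowData(se)
  pp <- postPhGenes(se)
  truth <- rownames(se)[tr$is_post_ph]
  expect_gt(length(intersect(pp, truth)) / length(truth), 0.9)
  # all-zero gene can never qualify
  expect_false(any(pp %in% rownames(se)[tr$gene_class == "undetected"]))
})

test_that("distribution summaries report medians and onset ordering", {
  sig <- data.frame(id = rep(letters[1:5], 2),
                    mark = "polII", hours = rep(c(0, 4), each = 5),
                    chip = 1, input = 1,
                    log2_ratio = c(1, 2, 3, 4, 5, 2, 3, 9, 5, 6))
  sm <- markDistributionSummary(sig)
  expect_equal(sm$median, c(3, 5))
  # median invariant to adding a symmetric pair around it
  sig2 <- rbind(sig[sig$hours == 0, ],
                transform(sig[1:2, ], log2_ratio = c(-10, 16)))
  expect_equal(markDistributionSummary(sig2)$median, 3)
  expect_equal(medianOnset(sm, "polII"), 4)
  expect_error(medianOnset(sm, "missing"), "not in summary")
  # singleton gene set: median equals that gene's value
  one <- markDistributionSummary(sig[sig$id == "a", ])
  expect_equal(one$median, c(1, 2))
})

test_that("Pol II-only (Saa-like) genes are detected by the classifier", {
  cfg <- simulationConfig(n_genes = 80, seed = 55, saa_fraction = 0.2,
                          class_fractions = c(
                            undetected = 0, stable = 1,
                            setNames(rep(0, 7), paste0("changing_", 1:7))))
  txs <- simulateAnnotation(cfg)
  se <- simulateExpression(cfg, txs)
  tr <- SummarizedExperiment::rowData(se)
  ch <- simulateChip(cfg, txs, tr,
                     marks = c("polII", "h3k4me3", "h3k36me3", "input"),
                     times = 0)
  inp <- ch$tracks$input[["0"]]
  bw <- bodyWindow(txs); pw <- promoterWindow(txs, 500)
  body <- setNames(markSignal(ch$tracks$polII[["0"]], inp, bw)$log2_ratio,
                   geneIds(txs))
  k4 <- setNames(markSignal(ch$tracks$h3k4me3[["0"]], inp, pw)$log2_ratio,
                 geneIds(txs))
  me3 <- setNames(markSignal(ch$tracks$h3k36me3[["0"]], inp,
                             bw)$log2_ratio, geneIds(txs))
  flagged <- polIIOnlyGenes(body, k4, me3)
  truthSaa <- rownames(se)[tr$is_saa_like]
  expect_gt(length(intersect(flagged, truthSaa)) /
              max(length(truthSaa), 1), 0.8)
})

test_that("bedGraph round-trips preserve track densities", {
  set.seed(12)
  s <- sample(1000:9000, 60)
  tr <- fragTrack(s, s + 200)
  path <- tempfile(fileext = ".bedGraph")
  writeTrackBedGraph(tr, path)
  back <- readTrackBedGraph(path, GenomeInfoDb::Seqinfo("chrT", 10000L))
  expect_equal(as.numeric(trackDensity(back)[["chrT"]]),
               as.numeric(trackDensity(tr)[["chrT"]]), tolerance = 1e-9)
})
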