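test_that("configuration invariants are enforced", {
  expect_s3_class(simulationConfig(), "SimulationConfig")
  bad <- simulationConfig()
  bad$class_fractions["stable"] <- bad$class_fractions["stable"] + 0.1
  expect_error(validateSimulationConfig(bad), "sum to 1")
  expect_error(simulationConfig(time_grid_sham = c(0, 4)), "PH/control")
  expect_error(simulationConfig(time_grid_ph = c(0, 4, 4)),
               "strictly increasing")
  expect_error(simulationConfig(noise_sd = -0.1), "noise_sd")
})

test_that("annotation respects exon-count ranges and is seed-reproducible", {
  cfg3 <- simulationConfig(n_genes = 10, exon_count_range = c(3, 3),
                           seed = 4)
  txs3 <- simulateAnnotation(cfg3)
  expect_length(txUnits(txs3), 10L)
  expect_equal(unname(lengths(txExons(txs3))), rep(3L, 10))
  expect_equal(length(firstInternalExon(txs3)), 10L)

  cfg1 <- simulationConfig(n_genes = 8, exon_count_range = c(1, 1),
                           seed = 4)
  txs1 <- simulateAnnotation(cfg1)
  expect_equal(length(firstInternalExon(txs1)), 0L)

  g1 <- tempfile(fileext = ".gtf"); g2 <- tempfile(fileext = ".gtf")
  writeAnnotationGTF(simulateAnnotation(cfg3), g1)
  writeAnnotationGTF(simulateAnnotation(cfg3), g2)
  expect_identical(readLines(g1), readLines(g2))

  expect_error(
    simulateAnnotation(simulationConfig(n_genes = 50,
                                        chrom_length = 10000L)),
    "need at least")
})

test_that("expression generator plants the documented structure", {
  cfg0 <- simulationConfig(n_genes = 60, noise_sd = 0, seed = 9,
                           circadian_fraction = 0)
  txs <- simulateAnnotation(cfg0)
  se <- simulateExpression(cfg0, txs)
  tr <- SummarizedExperiment::rowData(se)
  m <- SummarizedExperiment::assay(se, "rpkm")
  cd <- SummarizedExperiment::colData(se)

  # undetected genes are exactly zero everywhere
  und <- tr$gene_class == "undetected"
  expect_true(all(m[und, ] == 0))

  # zero-noise stable genes are identical across all samples
  stab <- which(tr$gene_class == "stable")
  expect_true(all(apply(m[stab, , drop = FALSE], 1,
                        function(x) diff(range(x)) == 0)))

  # the proliferation archetype is PH-only: flat in the sham arm
  prolif <- which(!is.na(tr$archetype_id) & tr$archetype_id == 7L)
  if (length(prolif)) {
    sham <- cd$arm == "sham"
    expect_true(all(apply(m[prolif, sham, drop = FALSE], 1,
                          function(x) diff(range(x)) < 1e-9)))
  }
})

test_that("replicate means recover archetype curves (law of large numbers)", {
  fr <- c(undetected = 0, stable = 0,
          setNames(c(1, rep(0, 5), 1) / 2, paste0("changing_", 1:7)))
  cfg <- simulationConfig(n_genes = 40, class_fractions = fr,
                          n_replicates = 30L, seed = 21,
                          circadian_fraction = 0)
  txs <- simulateAnnotation(cfg)
  se <- simulateExpression(cfg, txs)
  tr <- SummarizedExperiment::rowData(se)
  cd <- SummarizedExperiment::colData(se)
  m <- log2(SummarizedExperiment::assay(se, "rpkm"))
  tmpl <- archetypeTemplates(cfg$time_grid_ph) * cfg$amplitude
  tol <- 3 * cfg$noise_sd / sqrt(cfg$n_replicates)
  phCols <- cd$arm %in% c("control", "PH")
  devs <- unlist(lapply(which(!is.na(tr$archetype_id)), function(g) {
    prof <- vapply(cfg$time_grid_ph, function(h)
      mean(m[g, phCols & cd$hours == h]), numeric(1))
    expected <- log2(tr$baseline_rpkm[g]) + tmpl[tr$archetype_id[g], ]
    abs(prof - expected)
  }))
  # replicate means concentrate on the planted curve at the 3-sigma scale
  expect_gte(mean(devs < tol), 0.99)
  expect_lt(max(devs), 2 * tol)
})

test_that("generated class fractions match the configuration (chi-square)", {
  cfg <- simulationConfig(n_genes = 10000, seed = 31)
  txs <- simulateAnnotation(cfg)
  se <- simulateExpression(cfg, txs)
  counts <- table(factor(SummarizedExperiment::rowData(se)$gene_class,
                         levels = names(cfg$class_fractions)))
  p <- suppressWarnings(
    stats::chisq.test(as.integer(counts), p = cfg$class_fractions))$p.value
  expect_gt(p, 0.01)
})

test_that("circadian genes oscillate identically in sham and PH arms", {
  fr <- c(undetected = 0, stable = 1,
          setNames(rep(0, 7), paste0("changing_", 1:7)))
  cfg <- simulationConfig(n_genes = 60, class_fractions = fr,
                          circadian_fraction = 1, seed = 13)
  txs <- simulateAnnotation(cfg)
  se <- simulateExpression(cfg, txs)
  tr <- SummarizedExperiment::rowData(se)
  cd <- SummarizedExperiment::colData(se)
  m <- log2(SummarizedExperiment::assay(se, "rpkm"))
  fitSin <- function(g, arm, grid) {
    y <- vapply(grid, function(h)
      mean(m[g, cd$arm %in% arm & cd$hours == h]), numeric(1))
    zt <- 2 * pi * (2 + grid) / 24
    co <- stats::lm(y ~ cos(zt) + sin(zt))$coefficients
    c(amp = sqrt(sum(co[2:3]^2)), phase = atan2(-co[3], co[2]))
  }
  sharedGrid <- intersect(cfg$time_grid_ph, cfg$time_grid_sham)
  noiseTol <- 3 * cfg$noise_sd / sqrt(cfg$n_replicates * 2)
  for (g in which(tr$is_circadian)[1:10]) {
    ph <- fitSin(g, c("control", "PH"), sharedGrid)
    sh <- fitSin(g, "sham", sharedGrid)
    expect_lt(abs(ph["amp"] - sh["amp"]), noiseTol * 2)
  }
})

test_that("chip simulator plants me3 onset at the first internal exon", {
  cfg <- simulationConfig(n_genes = 40, seed = 17,
                          class_fractions = c(
                            undetected = 0, stable = 1,
                            setNames(rep(0, 7), paste0("changing_", 1:7))))
  txs <- simulateAnnotation(cfg)
  se <- simulateExpression(cfg, txs)
  ch <- simulateChip(cfg, txs, SummarizedExperiment::rowData(se),
                     marks = c("h3k36me3", "input"), times = 60)
  me3 <- ch$tracks$h3k36me3[["60"]]
  expect_error(
    simulateChip(cfg, txs, SummarizedExperiment::rowData(se),
                 marks = "h3k9me3", times = 60), "unknown mark")
  u <- txUnits(txs)
  fie <- firstInternalExon(txs)
  i <- match(fie$tu_id, txIds(txs))
  neg <- as.character(GenomicRanges::strand(u[i])) == "-"
  a5 <- ifelse(neg, GenomicRanges::end(fie), GenomicRanges::start(fie))
  # mean density over [anchor5'-2kb, -1kb) is ~0, over [anchor5', +1kb) > 0
  upW <- GenomicRanges::GRanges("chrS", IRanges::IRanges(
    ifelse(neg, a5 + 1000L, a5 - 2000L),
    ifelse(neg, a5 + 2000L, a5 - 1001L)))
  dnW <- GenomicRanges::GRanges("chrS", IRanges::IRanges(
    ifelse(neg, a5 - 999L, a5), ifelse(neg, a5, a5 + 999L)))
  up <- quantifyWindow(me3, upW)
  dn <- quantifyWindow(me3, dnW)
  expect_gt(mean(dn), 10 * mean(up))
  # input with zero noise is constant everywhere
  flat <- toyUniformTrack(0.5)
  expect_equal(length(unique(S4Vectors::runValue(
    trackDensity(flat)[["chrT"]]))), 1L)
})
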