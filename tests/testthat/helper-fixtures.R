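# shared fixtures, built once per test run

.fixtureEnv <- new.env(parent = emptyenv())

# moderate simulated dataset reused across test files
fixtureSim <- function() {
  if (is.null(.fixtureEnv$sim)) {
    cfg <- simulationConfig(n_genes = 400, seed = 101)
    txs <- simulateAnnotation(cfg)
    se <- simulateExpression(cfg, txs)
    .fixtureEnv$sim <- list(cfg = cfg, txs = txs, se = se)
  }
  .fixtureEnv$sim
}

# hand-built two-TU gene model on a 100 kb chromosome:
#   gA.t1 (+): exons [1001,1200], [2001,2400], [3001,3500]; span 1001-3500
#   gA.t2 (+): exons [1001,1200], [2601,2800], [3001,3500]
#   gB.t1 (-): exons [10001,10500], [11001,11300], [12001,12200]; TSS 12200
toyTxUnits <- function() {
  si <- GenomeInfoDb::Seqinfo("chrT", seqlengths = 100000L)
  mk <- function(starts, ends, strand)
    GenomicRanges::GRanges("chrT", IRanges::IRanges(starts, ends),
                           strand = strand, seqinfo = si)
  exons <- GenomicRanges::GRangesList(
    mk(c(1001, 2001, 3001), c(1200, 2400, 3500), "+"),
    mk(c(1001, 2601, 3001), c(1200, 2800, 3500), "+"),
    mk(c(10001, 11001, 12001), c(10500, 11300, 12200), "-"))
  units <- unlist(range(exons))
  GenomicRanges::strand(units) <- c("+", "+", "-")
  units$tu_id <- c("gA.t1", "gA.t2", "gB.t1")
  units$gene_id <- c("gA", "gA", "gB")
  TxUnitSet(units, exons)
}

# deterministic track with a given constant value
toyUniformTrack <- function(value = 1, len = 100000L, chrom = "chrT",
                            mark = "input") {
  uniformTrack(value, GenomeInfoDb::Seqinfo(chrom, seqlengths = len),
               mark = mark)
}
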