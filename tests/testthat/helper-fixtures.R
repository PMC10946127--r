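# Shared small fixtures, built once per test run.

tinyConfig <- function(seed = 11L, ...) {
  args <- list(nGradients = 2L, popsPerCell = 1L, samplesPerPop = 10L,
               nChromosomes = 1L, chromLength = 2e6, nSnps = 400L,
               founderHaplotypes = 12L, recombRate = 1e-6,
               fstLevel = 0.05, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}

tinyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tinyConfig()
      frame <- simulateMetadata(cfg)
      panel <- simulateHaplotypes(cfg, frame)
      cache <<- list(cfg = cfg, frame = frame, panel = panel)
    }
    cache
  }
})

# A small panel built directly from an explicit haplotype matrix.
manualPanel <- function(hap, pos = NULL, chrom = "chr1", missing = NULL,
                        popLabels = NULL) {
  m <- ncol(hap)
  n <- nrow(hap) / 2
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  meta <- list(chromLength = max(pos) + 1000)
  if (!is.null(popLabels)) meta$populations <- popLabels
  HaplotypePanel(rep(chrom, m), pos, rep("A", m), rep("G", m),
                 hap, sprintf("s%02d", seq_len(n)), missing,
                 metadata = meta)
}
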