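## Window-to-gene interval mapping and generic hypergeometric gene-set
## enrichment over user-supplied sets.

#' Map scan windows to overlapping genes
#'
#' A gene maps to a window when their 1-based inclusive intervals share at
#' least one base pair. Genes on chromosomes absent from the window tiling
#' are skipped (their count is reported).
#'
#' @param windows a `WindowStats` data.frame (or any data.frame with
#'   `chrom`, `start`, `end`, and optionally `significant`).
#' @param genes a `GRanges` with a `gene` metadata column, e.g. from
#'   [readGeneIntervals()].
#' @return list: `perWindow` (character vector of gene names per window
#'   row), `significantGenes` (deduplicated union over windows flagged
#'   significant; empty when no flags are present), `nSkippedChrom`.
#' @export
mapWindowsToGenes <- function(windows, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  known <- as.character(GenomicRanges::seqnames(genes)) %in% windows$chrom
  nSkipped <- sum(!known)
  genes <- genes[known]
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  hits <- GenomicRanges::findOverlaps(wgr, genes, minoverlap = 1L)
  perWindow <- rep(list(character()), nrow(windows))
  if (length(hits)) {
    sp <- split(genes$gene[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits),
                       levels = seq_len(nrow(windows))))
    perWindow <- lapply(sp, function(g) unique(as.character(g)))
  }
  sig <- if ("significant" %in% names(windows))
    which(windows$significant %in% TRUE) else integer()
  list(perWindow = perWindow,
       significantGenes = unique(unlist(perWindow[sig], use.names = FALSE)),
       nSkippedChrom = nSkipped)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each gene set's overlap with the
#' query, against a fixed gene universe, with Benjamini-Hochberg control
#' across sets. Significance is reported at q < 0.1.
#'
#' @param query character vector of candidate genes (must lie within
#'   `universe`).
#' @param geneSets named list of character vectors (subsets of
#'   `universe`).
#' @param universe background gene identifiers (non-empty).
#' @return data.frame `(set, overlap, setSize, universeSize, p, q,
#'   significant)` in the input set order.
#' @export
hypergeomEnrichment <- function(query, geneSets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  bad <- !vapply(geneSets, function(s) all(s %in% universe), logical(1))
  if (any(bad))
    stop("gene set(s) outside the universe: ",
         paste(names(geneSets)[bad], collapse = ", "))
  N <- length(universe)
  k <- length(query)
  rows <- lapply(names(geneSets), function(nm) {
    s <- unique(geneSets[[nm]])
    ov <- length(intersect(query, s))
    p <- phyper(ov - 1L, length(s), N - length(s), k, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, setSize = length(s),
               universeSize = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.1
  out
}
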