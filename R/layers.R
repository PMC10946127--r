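## The three-layer comparison framework: gradient-level contrasts (layer I),
## agroecology contrasts pooled over all gradients but one with a distinct
## evolutionary history (layer II), and agroecology contrasts within that
## one gradient (layer III).

#' Expand an analytical layer into pairwise sample contrasts
#'
#' Layer "I" groups samples by gradient; layer "II" groups by agroecology
#' pooled over every gradient except `separateGradient`; layer "III" groups
#' by agroecology within `separateGradient` only.
#'
#' @param frame sample metadata with `gradient` and `agroecology` columns.
#' @param layer one of "I", "II", "III".
#' @param pairs optional list of length-2 character vectors naming the
#'   group pairs to contrast; default: all pairs of observed groups.
#' @param separateGradient the gradient analysed on its own in layer III
#'   and excluded from the pooled layer II (default "II").
#' @return list of contrasts, each `list(name, groupA, groupB, samplesA,
#'   samplesB)`. Contrasts with an empty side are dropped with a warning.
#' @export
layerContrasts <- function(frame, layer = c("I", "II", "III"), pairs = NULL,
                           separateGradient = "II") {
  layer <- match.arg(layer)
  sub <- switch(layer,
    I = frame,
    II = frame[frame$gradient != separateGradient, , drop = FALSE],
    III = frame[frame$gradient == separateGradient, , drop = FALSE])
  groupCol <- if (layer == "I") "gradient" else "agroecology"
  groups <- unique(sub[[groupCol]])
  if (is.null(pairs)) {
    if (length(groups) < 2L) stop("layer ", layer, " has fewer than 2 groups")
    cmb <- utils::combn(groups, 2L, simplify = FALSE)
  } else cmb <- pairs
  out <- list()
  for (pp in cmb) {
    sA <- sub$sample_id[sub[[groupCol]] == pp[1L]]
    sB <- sub$sample_id[sub[[groupCol]] == pp[2L]]
    if (!length(sA) || !length(sB)) {
      warning("contrast ", pp[1L], " vs ", pp[2L], " has an empty side; skipped")
      next
    }
    out[[paste(pp[1L], "vs", pp[2L])]] <-
      list(name = paste(pp[1L], "vs", pp[2L]), groupA = pp[1L],
           groupB = pp[2L], samplesA = sA, samplesB = sB)
  }
  out
}

.panelWindows <- function(panel, span, step) {
  chroms <- unique(panel@chrom)
  L <- panel@metadata$chromLength
  if (is.null(L)) {
    lens <- tapply(panel@pos, panel@chrom, max)[chroms]
  } else lens <- setNames(rep(L, length(chroms)), chroms)
  makeWindows(lens, span = span, step = step)
}

#' Run the windowed FST + XP-EHH scan over one analytical layer
#'
#' For every pairwise contrast of the layer, computes windowed
#' Weir-Cockerham FST (one-sided empirical p) and windowed XP-EHH
#' (two-sided empirical p) over the same 50-kb / 25-kb-step tiling, flags
#' the top `topFrac` of windows per method, and reports their overlap and
#' the contrast's mean FST.
#'
#' @param panel a phased [HaplotypePanel-class].
#' @param frame sample metadata.
#' @param layer "I", "II" or "III" (see [layerContrasts()]).
#' @param span,step window geometry in bp.
#' @param topFrac retained significance fraction (default 0.01).
#' @param cutoff,minMaf XP-EHH parameters (see [xpehh()]).
#' @param pairs,separateGradient forwarded to [layerContrasts()].
#' @return a list of class `LayeredScan`: one element per contrast with
#'   `fst` and `xpehh` `WindowStats`, the `overlap` report, `meanFst`
#'   (mean of defined window FST), and the contrast definition.
#' @export
layeredScan <- function(panel, frame, layer = "I", span = 50000,
                        step = 25000, topFrac = 0.01, cutoff = 0.05,
                        minMaf = 0.05, pairs = NULL,
                        separateGradient = "II") {
  contrasts <- layerContrasts(frame, layer, pairs, separateGradient)
  windows <- .panelWindows(panel, span, step)
  out <- lapply(contrasts, function(ct) {
    fst <- empiricalP(windowedFst(panel, ct$samplesA, ct$samplesB, windows),
                      twoSided = FALSE, topFrac = topFrac)
    xp <- xpehh(panel, ct$samplesA, ct$samplesB, windows,
                cutoff = cutoff, minMaf = minMaf)
    xpw <- empiricalP(xp$windows, twoSided = TRUE, topFrac = topFrac)
    list(contrast = ct, fst = fst, xpehh = xpw, xpehhSites = xp$sites,
         overlap = overlapWindows(fst, xpw),
         meanFst = mean(fst$stat, na.rm = TRUE))
  })
  structure(out, class = "LayeredScan", layer = layer)
}

#' Summarize per-contrast scan results
#'
#' Tabulates, per contrast: mean windowed FST, counts of significant
#' windows per method, and the cross-method overlap percentages under all
#' three denominators.
#'
#' @param scan a `LayeredScan` from [layeredScan()].
#' @return a `data.frame`, one row per contrast, in the input order.
#' @export
summarizeContrasts <- function(scan) {
  stopifnot(inherits(scan, "LayeredScan"))
  do.call(rbind, lapply(unname(scan), function(res) {
    ov <- res$overlap
    data.frame(contrast = res$contrast$name,
               meanFst = res$meanFst,
               nSigFst = ov$nA, nSigXpehh = ov$nB,
               nOverlap = ov$nIntersect,
               pctUnion = ov$pctUnion, pctOfFst = ov$pctOfA,
               pctOfXpehh = ov$pctOfB)
  }))
}
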