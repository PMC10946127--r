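## Fixture I/O: phased VCFv4.2 plus metadata/environment/trait TSV tables
## and a ground-truth JSON. Reading goes through vcfR; writing emits the
## fixed-layout VCF text directly so runtime outputs stay plain text.

#' Write a simulated panel and its metadata to disk
#'
#' Emits `genotypes.vcf` (VCFv4.2, phased `GT` with `|`, contigs declared,
#' sample order matching the metadata, masked genotypes as `./.`),
#' `metadata.tsv`, `env.tsv`, `traits.tsv`, and `ground_truth.json`
#' recording injected sweeps and clines so recovery analyses never
#' re-derive them. Files round-trip through [readFixture()] with an
#' identical haplotype matrix (missingness permitting: the phase under a
#' masked genotype is not representable in VCF).
#'
#' @param panel a [HaplotypePanel-class].
#' @param frame matching metadata from [simulateMetadata()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeFixture <- function(panel, frame, outDir) {
  stopifnot(is(panel, "HaplotypePanel"),
            identical(panel@samples, frame$sample_id))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)

  chroms <- unique(panel@chrom)
  L <- panel@metadata$chromLength
  lens <- if (is.null(L)) tapply(panel@pos, panel@chrom, max)[chroms]
          else setNames(rep(L, length(chroms)), chroms)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", chroms,
                      as.integer(lens[chroms])),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel@samples), collapse = "\t"))
  H <- panel@haplotypes
  a1 <- H[seq(1, nrow(H), 2), , drop = FALSE]
  a2 <- H[seq(2, nrow(H), 2), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow(a1), ncol(a1))
  gt[panel@missing] <- "./."
  body <- do.call(paste, c(
    list(panel@chrom, panel@pos,
         paste0(panel@chrom, ":", panel@pos),
         panel@ref, panel@alt, ".", "PASS", ".", "GT"),
    as.data.frame(t(gt), optional = TRUE), list(sep = "\t")))
  vcfPath <- file.path(outDir, "genotypes.vcf")
  writeLines(c(header, body), vcfPath)

  metaCols <- c("sample_id", "population_id", "gradient", "agroecology",
                "longitude", "latitude", "elevation")
  envCols <- attr(frame, "envPredictors")
  traitCols <- attr(frame, "traits")
  wtsv <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  metaPath <- wtsv(frame[metaCols], "metadata.tsv")
  envPath <- wtsv(frame[c("sample_id", envCols)], "env.tsv")
  traitPath <- wtsv(frame[c("sample_id", traitCols)], "traits.tsv")

  truth <- list(sweeps = panel@metadata$sweeps,
                clines = panel@metadata$clines,
                traitTruth = attr(frame, "traitTruth"),
                envPredictors = envCols, traits = traitCols)
  truthPath <- file.path(outDir, "ground_truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(vcf = vcfPath, metadata = metaPath, env = envPath,
              traits = traitPath, truth = truthPath))
}

#' Read a fixture directory back into panel and metadata
#'
#' @param dir directory written by [writeFixture()], or any directory with
#'   a phased `genotypes.vcf` plus the three TSV tables.
#' @return `list(panel, frame, truth)`; `truth` is NULL when no
#'   ground-truth JSON is present.
#' @export
readFixture <- function(dir) {
  vcfPath <- file.path(dir, "genotypes.vcf")
  panel <- readVcfPanel(vcfPath)
  frame <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                             sep = "\t", colClasses = c(gradient = "character"))
  env <- utils::read.table(file.path(dir, "env.tsv"), header = TRUE,
                           sep = "\t")
  traits <- utils::read.table(file.path(dir, "traits.tsv"), header = TRUE,
                              sep = "\t")
  frame <- merge(merge(frame, env, by = "sample_id", sort = FALSE),
                 traits, by = "sample_id", sort = FALSE)
  frame <- frame[match(panel@samples, frame$sample_id), , drop = FALSE]
  rownames(frame) <- NULL
  attr(frame, "envPredictors") <- setdiff(names(env), "sample_id")
  attr(frame, "traits") <- setdiff(names(traits), "sample_id")
  truthPath <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else NULL
  panel@metadata$populations <- frame$population_id
  list(panel = panel, frame = frame, truth = truth)
}

#' Read a phased VCF into a HaplotypePanel
#'
#' Parses a VCFv4.2 file (via vcfR), requiring phased `GT` (`|` separator)
#' for called genotypes; `./.` genotypes are masked as missing (their
#' haplotype entries are set to 0). Only biallelic SNPs are kept.
#'
#' @param path VCF file path.
#' @return a [HaplotypePanel-class]; contig lengths from the header, when
#'   declared, populate `metadata$chromLength`.
#' @export
readVcfPanel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L
  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  if (is.null(dim(gt))) {
    gt <- t(as.matrix(gt))
    rownames(gt) <- rownames(fix)
  }
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  miss <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  phased <- grepl("^[01]\\|[01]$", gt)
  if (!all(phased | miss))
    stop("unphased or malformed GT entries; phased haplotypes ('|') required")
  a1 <- ifelse(miss, 0L, as.integer(substr(gt, 1L, 1L)))
  a2 <- ifelse(miss, 0L, as.integer(substr(gt, 3L, 3L)))
  n <- ncol(gt)
  m <- nrow(gt)
  hap <- matrix(0L, 2L * n, m)
  hap[seq(1, 2L * n, 2L), ] <- t(matrix(a1, m, n))
  hap[seq(2, 2L * n, 2L), ] <- t(matrix(a2, m, n))
  missing <- t(matrix(miss, m, n))

  meta <- list()
  contig <- grep("^##contig", vcf@meta, value = TRUE)
  if (length(contig)) {
    lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", contig))
    if (length(unique(lens)) == 1L) meta$chromLength <- lens[1L]
  }
  HaplotypePanel(fix[, "CHROM"], as.integer(fix[, "POS"]),
                 fix[, "REF"], fix[, "ALT"], hap, colnames(gt),
                 missing, metadata = meta)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' both converted to the package's internal 1-based inclusive convention
#' (the conversion is rtracklayer's). For GFF3, only `gene` features are
#' kept when present; the gene name is taken from `Name`, falling back to
#' `ID` (GFF3) or the BED name column.
#'
#' @param path a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return a `GRanges` with a `gene` metadata column.
#' @export
readGeneIntervals <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  gene <- if ("Name" %in% names(mc) && !all(is.na(mc$Name))) mc$Name
          else if ("name" %in% names(mc)) mc$name
          else if ("ID" %in% names(mc)) mc$ID
          else paste0("gene", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene = as.character(gene))
  gr
}
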