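## Gene annotation handling and region definition.

#' Load a gene annotation from GTF or BED12
#'
#' Reads a gene annotation and reduces it to one record per gene, keeping the
#' longest transcript when several are annotated (ties broken by coordinate).
#' The result is a `GRanges` ordered by gene id; the transcription start and
#' end sites follow the strand (TSS = 5' end in transcription direction).
#'
#' @param path Path to a GTF (1-based, closed intervals) or BED12 (0-based,
#'   half-open) file.
#' @param format `"auto"` (from the file extension), `"gtf"` or `"bed"`.
#' @return A `GRanges` with one range per gene and a `gene_id` metadata
#'   column.
#' @seealso [defineRegions()], [tssCoord()]
#' @export
loadAnnotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("malformed ", format, " annotation '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (format == "gtf") {
    keep <- if ("type" %in% names(S4Vectors::mcols(gr)))
      gr[gr$type %in% c("transcript", "mRNA")] else gr
    if (length(keep) == 0L) keep <- gr   # GTFs carrying only gene/exon rows
    ids <- as.character(keep$gene_id)
    if (all(is.na(ids)) || is.null(ids))
      stop("GTF records carry no gene_id attribute")
  } else {
    keep <- gr
    ids <- if (!is.null(keep$name)) as.character(keep$name)
           else paste0("gene", seq_along(keep))
  }
  if (length(keep) == 0L) stop("annotation contains zero genes")
  if (any(!as.character(GenomicRanges::strand(keep)) %in% c("+", "-")))
    stop("all records must be stranded (+/-)")
  ## longest transcript per gene; tie -> first by coordinate
  ord <- order(ids, -GenomicRanges::width(keep),
               GenomicRanges::start(keep))
  keep <- keep[ord]; ids <- ids[ord]
  first <- !duplicated(ids)
  out <- GenomicRanges::granges(keep[first])
  out$gene_id <- ids[first]
  names(out) <- out$gene_id
  out[order(out$gene_id)]
}

#' Strand-oriented TSS / TES coordinates
#'
#' Coordinates in 0-based half-open convention: on the plus strand the TSS is
#' the interval start and the TES the interval end; reversed on the minus
#' strand, so that the TSS is always the start of transcription.
#'
#' @param ann A `GRanges` from [loadAnnotation()].
#' @return Integer vector of coordinates, named by gene.
#' @export
tssCoord <- function(ann) {
  plus <- as.logical(GenomicRanges::strand(ann) == "+")
  setNames(ifelse(plus, GenomicRanges::start(ann) - 1L,
                  GenomicRanges::end(ann)), names(ann))
}

#' @rdname tssCoord
#' @export
tesCoord <- function(ann) {
  plus <- as.logical(GenomicRanges::strand(ann) == "+")
  setNames(ifelse(plus, GenomicRanges::end(ann),
                  GenomicRanges::start(ann) - 1L), names(ann))
}

.grFromHalfOpen <- function(chrom, s, e, strand, ids) {
  zero <- e <= s
  e2 <- ifelse(zero, s, e)   # zero-width placeholder for flagged genes
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = s + 1L, end = e2),
                               strand = strand)
  names(gr) <- ids
  gr
}

#' Derive promoter / gene-body / TES windows
#'
#' Windows are strand-oriented and pairwise non-overlapping: the promoter is
#' `[TSS - promoterUp, TSS + promoterDown)`, the gene body
#' `[TSS + promoterDown, TES)` and the TES window `[TES, TES + tesDown)` in
#' transcription-direction coordinates. Genes whose body would have
#' non-positive length are flagged in `excluded` (and carry zero-width
#' placeholders) rather than causing failure.
#'
#' @param ann A `GRanges` from [loadAnnotation()].
#' @param promoterUp,promoterDown,tesDown Window extents in bp (defaults
#'   500/500/1000, common RNAPII-pausing practice).
#' @return A [RegionSet-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000), "+")
#' names(gr) <- gr$gene_id <- "g1"
#' defineRegions(gr)
#' @export
defineRegions <- function(ann, promoterUp = 500, promoterDown = 500,
                          tesDown = 1000) {
  stopifnot(promoterUp > 0, promoterDown > 0, tesDown > 0)
  ids <- if (!is.null(names(ann))) names(ann) else as.character(ann$gene_id)
  tss <- tssCoord(ann); tes <- tesCoord(ann)
  chrom <- as.character(GenomicRanges::seqnames(ann))
  strand <- as.character(GenomicRanges::strand(ann))
  plus <- strand == "+"
  ## half-open interval arithmetic in transcription direction
  proS <- ifelse(plus, tss - promoterUp, tss - promoterDown)
  proE <- ifelse(plus, tss + promoterDown, tss + promoterUp)
  bodS <- ifelse(plus, tss + promoterDown, tes)
  bodE <- ifelse(plus, tes, tss - promoterDown)
  tesS <- ifelse(plus, tes, tes - tesDown)
  tesE <- ifelse(plus, tes + tesDown, tes)
  flagged <- (bodE - bodS) <= 0
  new("RegionSet",
      promoter = .grFromHalfOpen(chrom, proS, proE, strand, ids),
      geneBody = .grFromHalfOpen(chrom, bodS, bodE, strand, ids),
      tes = .grFromHalfOpen(chrom, tesS, tesE, strand, ids),
      excluded = ids[flagged])
}

#' Accessors for RegionSet windows
#' @param x A [RegionSet-class].
#' @return A `GRanges` (or character vector for `excludedGenes`).
#' @export
promoterRegions <- function(x) x@promoter

#' @rdname promoterRegions
#' @export
geneBodyRegions <- function(x) x@geneBody

#' @rdname promoterRegions
#' @export
tesRegions <- function(x) x@tes

#' @rdname promoterRegions
#' @export
excludedGenes <- function(x) x@excluded
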