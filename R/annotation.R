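#' Gene annotations as GRanges
#'
#' Gene models are carried as a [GenomicRanges::GRanges] with a unique
#' `gene_id` metadata column and explicit strand; coordinates are the usual
#' 1-based closed GRanges convention internally (BED is converted on I/O).
#' `makeGeneAnnotation()` builds and validates one from vectors;
#' `geneTss()` returns the strand-aware transcription start site of each
#' gene (the 5' end: `start` on `+`, `end` on `-`); `promoterWindows()`
#' returns TSS-centred windows of the given half-width, clipped at
#' position 1 and at the chromosome length when known.
#'
#' @param chrom,start,end,strand,gene_id per-gene vectors; `start`/`end`
#'   1-based closed.
#' @param seqlengths optional named vector of chromosome lengths.
#' @param annotation a gene annotation `GRanges`.
#' @param halfWidth promoter half-width in bp (default 2000, i.e. TSS +/- 2 kb).
#' @return `makeGeneAnnotation()` a `GRanges`; `geneTss()` an integer vector
#'   named by `gene_id`; `promoterWindows()` a `GRanges` of promoter windows.
#' @examples
#' ann <- makeGeneAnnotation(chrom = "chr1", start = c(1000, 8000),
#'                           end = c(3000, 9000), strand = c("+", "-"),
#'                           gene_id = c("g1", "g2"))
#' geneTss(ann)
#' promoterWindows(ann, halfWidth = 500)
#' @export
makeGeneAnnotation <- function(chrom, start, end, strand, gene_id,
                               seqlengths = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (any(start > end)) stop("gene start must be <= end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, gene_id = as.character(gene_id))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  checkAnnotation(gr)
  gr
}

checkAnnotation <- function(annotation) {
  if (!is(annotation, "GRanges")) stop("annotation must be a GRanges")
  if (length(annotation) == 0L) stop("annotation is empty")
  if (is.null(annotation$gene_id)) stop("annotation must carry a gene_id column")
  if (anyDuplicated(annotation$gene_id)) stop("gene_id values must be unique")
  if (any(BiocGenerics::strand(annotation) == "*"))
    stop("every gene needs an explicit strand (+ or -)")
  invisible(annotation)
}

#' @rdname makeGeneAnnotation
#' @export
geneTss <- function(annotation) {
  checkAnnotation(annotation)
  minus <- as.logical(BiocGenerics::strand(annotation) == "-")
  tss <- ifelse(minus, BiocGenerics::end(annotation),
                BiocGenerics::start(annotation))
  stats::setNames(as.integer(tss), annotation$gene_id)
}

#' @rdname makeGeneAnnotation
#' @export
promoterWindows <- function(annotation, halfWidth = 2000L) {
  stopifnot(isCount(halfWidth))
  tss <- geneTss(annotation)
  sl <- GenomeInfoDb::seqlengths(annotation)
  chromLen <- unname(sl[as.character(GenomeInfoDb::seqnames(annotation))])
  end <- tss + as.integer(halfWidth) - 1L
  end <- ifelse(is.na(chromLen), end, pmin(end, chromLen))
  win <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(annotation),
                                IRanges::IRanges(pmax(1L, tss - as.integer(halfWidth)),
                                                 end),
                                strand = BiocGenerics::strand(annotation),
                                gene_id = annotation$gene_id,
                                seqinfo = GenomeInfoDb::seqinfo(annotation))
  win
}
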