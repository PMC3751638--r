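## BED6 reading with per-line validation. BED is 0-based half-open; the
## in-memory GRanges convention is 1-based closed, so start is shifted by +1
## on input and -1 on output. A dedicated reader (rather than a generic
## importer) is used so malformed input is rejected with the line number.
readBed6 <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop(sprintf("malformed BED at line %d of %s: expected >= 6 tab-separated fields",
                 lineNo[bad[1]], path))
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad))
    stop(sprintf(paste0("malformed BED at line %d of %s: start/end must be ",
                        "non-negative integers with start < end"),
                 lineNo[bad[1]], path))
  strand <- m[, 6]
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf("malformed BED at line %d of %s: strand must be +, - or .",
                 lineNo[bad[1]], path))
  data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
             score = suppressWarnings(as.numeric(m[, 5])), strand = strand)
}

writeBed6 <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                   df$name, format(df$score, trim = TRUE, scientific = FALSE),
                   df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write tag libraries as BED6
#'
#' Tags are stored as single-base BED6 intervals (0-based half-open, so each
#' record spans one base: `end = start + 1`). `readTags()` rejects malformed
#' input with the offending line number; `writeTags()` writes the name column
#' as the sample id and the score as 0. `writeTags(readTags(x))` reproduces
#' the file byte for byte.
#'
#' @param path BED file path.
#' @param sampleId,condition,role library identity (see [TagLibrary]).
#' @param library a [TagLibrary].
#' @return `readTags()` a [TagLibrary]; `writeTags()` the path, invisibly.
#' @export
readTags <- function(path, sampleId = NULL, condition = "SS", role = "IP") {
  df <- readBed6(path)
  if (nrow(df) && any(df$end - df$start != 1L))
    stop("tag BED records must be single-base (end = start + 1)")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, width = 1L),
                               strand = ifelse(df$strand == ".", "*", df$strand))
  TagLibrary(tags = gr,
             sampleId = sampleId %||% (if (nrow(df)) df$name[1] else basename(path)),
             condition = condition, role = role)
}

#' @rdname readTags
#' @export
writeTags <- function(library, path) {
  stopifnot(is(library, "TagLibrary"))
  gr <- tagPositions(library)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::start(gr),
                   name = rep(sampleId(library), length(gr)),
                   score = rep(0L, length(gr)),
                   strand = as.character(BiocGenerics::strand(gr)))
  df$strand[df$strand == "*"] <- "."
  writeBed6(df, path)
}

#' Read and write gene annotations (BED6 and GFF3)
#'
#' BED6 is 0-based half-open with the gene id in the name column; GFF3 is
#' 1-based closed (`type = "gene"`, id in the `ID` attribute, written and
#' read through `rtracklayer`). Both dialects round-trip the same in-memory
#' annotation. Chromosome lengths are not representable in either format and
#' must be re-attached for simulation use.
#'
#' @param path file path.
#' @param annotation a gene annotation `GRanges` (see [makeGeneAnnotation]).
#' @return readers return the annotation `GRanges`; writers the path,
#'   invisibly.
#' @export
readAnnotationBed <- function(path) {
  df <- readBed6(path)
  if (nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges(gene_id = character(0))
    return(gr)
  }
  makeGeneAnnotation(df$chrom, df$start + 1L, df$end, df$strand, df$name)
}

#' @rdname readAnnotationBed
#' @export
writeAnnotationBed <- function(annotation, path) {
  checkAnnotation(annotation)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(annotation)),
                   start = BiocGenerics::start(annotation) - 1L,
                   end = BiocGenerics::end(annotation),
                   name = annotation$gene_id,
                   score = rep(0L, length(annotation)),
                   strand = as.character(BiocGenerics::strand(annotation)))
  writeBed6(df, path)
}

#' @rdname readAnnotationBed
#' @export
writeAnnotationGff3 <- function(annotation, path) {
  checkAnnotation(annotation)
  gr <- annotation
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "acetylscan", type = "gene", ID = annotation$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname readAnnotationBed
#' @export
readAnnotationGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  makeGeneAnnotation(as.character(GenomeInfoDb::seqnames(gr)),
                     BiocGenerics::start(gr), BiocGenerics::end(gr),
                     as.character(BiocGenerics::strand(gr)), gr$ID)
}

#' Read and write an expression matrix with its group design
#'
#' The matrix is a TSV with gene ids in the first column and one column per
#' sample; the design is a sidecar TSV mapping `sample_id` to `group`
#' (SS/SM/MS/MM). Values must be strictly positive intensities.
#'
#' @param path expression TSV path.
#' @param groupPath sidecar group-map TSV path.
#' @param se a `SummarizedExperiment` with assay `"intensity"` and
#'   `colData$group`.
#' @return `readExpression()` a `SummarizedExperiment`; `writeExpression()`
#'   the paths, invisibly.
#' @export
readExpression <- function(path, groupPath) {
  tab <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("expression values must be finite and strictly positive")
  gmap <- utils::read.delim(groupPath)
  if (!all(c("sample_id", "group") %in% names(gmap)))
    stop("group map must have columns sample_id and group")
  miss <- setdiff(colnames(mat), gmap$sample_id)
  if (length(miss))
    stop("samples missing from the group map: ", paste(miss, collapse = ", "))
  grp <- gmap$group[match(colnames(mat), gmap$sample_id)]
  if (!all(grp %in% CONDITIONS))
    stop("groups must be one of ", paste(CONDITIONS, collapse = ", "))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(group = factor(grp, levels = CONDITIONS),
                                   row.names = colnames(mat)))
}

#' @rdname readExpression
#' @export
writeExpression <- function(se, path, groupPath) {
  mat <- SummarizedExperiment::assay(se, "intensity")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gmap <- data.frame(sample_id = colnames(mat),
                     group = as.character(SummarizedExperiment::colData(se)$group))
  utils::write.table(gmap, groupPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, groupPath))
}

#' Write called binding sites as BED6
#'
#' The score column carries `-log10(enrichment_p)` clipped at 1000.
#'
#' @param sites a `GRanges` of sites from [callBindingSites].
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeSites <- function(sites, path) {
  score <- pmin(round(-log10(pmax(sites$enrichment_p, .Machine$double.xmin)), 3), 1000)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(sites)),
                   start = BiocGenerics::start(sites) - 1L,
                   end = BiocGenerics::end(sites),
                   name = sprintf("site_%d", seq_along(sites)),
                   score = score,
                   strand = rep(".", length(sites)))
  writeBed6(df, path)
}
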