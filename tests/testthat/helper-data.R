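# helpers shared across test files; all fixtures are built in code

tagLib <- function(pos, chrom = "chr1", strand = "+", condition = "SS",
                   role = "IP", sampleId = "t") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = strand)
  TagLibrary(tags = gr, sampleId = sampleId, condition = condition, role = role)
}

# annotation with three plus-strand genes whose TSSs sit at 1000/5000/9000
threeGeneAnn <- function() {
  makeGeneAnnotation(rep("chr1", 3), c(1000, 5000, 9000),
                     c(1999, 5999, 9999), rep("+", 3), c("g1", "g2", "g3"))
}

# SummarizedExperiment from a plain intensity matrix and group labels
exprSe <- function(mat, groups) {
  colnames(mat) <- colnames(mat) %||%
    paste0(groups, "_", stats::ave(seq_along(groups), groups, FUN = seq_along))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(group = factor(groups,
                                                  levels = c("SS", "SM", "MS", "MM")),
                                   row.names = colnames(mat)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force nearest-TSS oracle: O(genes x tags) argmin with the documented
# tie-break (smaller TSS coordinate, then lexicographic gene_id)
bruteNearest <- function(chrom, pos, ann) {
  tss <- geneTss(ann)
  annChrom <- as.character(GenomeInfoDb::seqnames(ann))
  ids <- ann$gene_id
  vapply(seq_along(pos), function(i) {
    j <- which(annChrom == chrom[i])
    if (!length(j)) return(NA_character_)
    d <- abs(pos[i] - tss[j])
    cand <- j[d == min(d)]
    cand <- cand[order(tss[cand], ids[cand])]
    ids[cand[1]]
  }, character(1))
}
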