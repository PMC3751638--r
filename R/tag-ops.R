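## Nearest-TSS lookup. For each (chrom, pos) returns the index into
## `annotation` of the gene whose TSS is closest (distance |pos - tss|),
## with deterministic tie-breaking: the smaller TSS coordinate wins, then
## the lexicographically smaller gene_id. Tags on chromosomes absent from
## the annotation get NA. O((n+m) log n) via sorted TSSs and findInterval.
nearestTssIndex <- function(chrom, pos, annotation) {
  checkAnnotation(annotation)
  tss <- geneTss(annotation)
  annChrom <- as.character(GenomeInfoDb::seqnames(annotation))
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    inAnn <- which(annChrom == ch)
    sel <- which(chrom == ch)
    if (length(inAnn) == 0L) next
    ## order by (tss, gene_id); for duplicated TSS coordinates keep the
    ## first gene in that order as the representative
    ord <- inAnn[order(tss[inAnn], annotation$gene_id[inAnn])]
    t <- tss[ord]
    keep <- !duplicated(t)
    t <- t[keep]; ord <- ord[keep]
    i <- findInterval(pos[sel], t)
    dLeft <- ifelse(i >= 1L, pos[sel] - t[pmax(i, 1L)], Inf)
    dRight <- ifelse(i < length(t), t[pmin(i + 1L, length(t))] - pos[sel], Inf)
    pick <- ifelse(dLeft <= dRight, pmax(i, 1L), pmin(i + 1L, length(t)))
    out[sel] <- ord[pick]
  }
  out
}

#' Tags-per-million normalization factor
#'
#' Returns `1e6 / total_count` for a library, so that a gene with `n` raw
#' tags has a normalized count of `n * factor` tags per million.
#'
#' @param library a [TagLibrary] with at least one tag.
#' @return scalar normalization factor.
#' @examples
#' \dontrun{normalizeFactor(lib)  # 1.0 for a library of exactly 1e6 tags}
#' @export
normalizeFactor <- function(library) {
  stopifnot(is(library, "TagLibrary"))
  n <- totalCount(library)
  if (n == 0L) stop("cannot normalize an empty library (total_count = 0)")
  1e6 / n
}

#' Assign tags to the nearest promoter
#'
#' Each tag is assigned to the gene whose TSS is nearest on the same
#' chromosome (`distance = |position - tss|`). Because promoter windows are
#' TSS-centred, the nearest promoter coincides with the nearest TSS.
#' Equidistant ties go to the smaller TSS coordinate, then to the
#' lexicographically smaller `gene_id`. Tags on chromosomes unknown to the
#' annotation are counted as unassigned; assigned plus unassigned always
#' equals the library total.
#'
#' @param library a [TagLibrary].
#' @param annotation gene annotation `GRanges` (non-empty).
#' @return a list with `counts` (named integer vector over all genes, zeros
#'   included), `assigned` and `unassigned` totals.
#' @examples
#' ann <- makeGeneAnnotation("chr1", c(1000, 5000), c(2000, 6000),
#'                           c("+", "+"), c("g1", "g2"))
#' lib <- TagLibrary(tags = GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1100, 4900), width = 1), strand = "+"))
#' assignTagsToNearestPromoter(lib, ann)$counts
#' @export
assignTagsToNearestPromoter <- function(library, annotation) {
  stopifnot(is(library, "TagLibrary"))
  checkAnnotation(annotation)
  gr <- tagPositions(library)
  idx <- nearestTssIndex(as.character(GenomeInfoDb::seqnames(gr)),
                         BiocGenerics::start(gr), annotation)
  counts <- tabulate(idx, nbins = length(annotation))
  names(counts) <- annotation$gene_id
  list(counts = counts,
       assigned = sum(!is.na(idx)),
       unassigned = sum(is.na(idx)))
}

#' Metagene tag-density profile around TSSs
#'
#' Histograms the strand-signed distance from each tag to its nearest TSS
#' over `[-flank, flank)` (upstream of the TSS is negative on both strands)
#' and scales counts to tags per million of the library total. Tags farther
#' than `flank` from any TSS are excluded; the sum of raw bin counts equals
#' the number of tags within the flank.
#'
#' @param library a [TagLibrary].
#' @param annotation gene annotation `GRanges`.
#' @param flank half-width of the window (bp); must be a multiple of
#'   `binwidth`.
#' @param binwidth bin width (bp, > 0).
#' @return a [TssProfile].
#' @export
tssProfile <- function(library, annotation, flank = 5000L, binwidth = 100L) {
  stopifnot(is(library, "TagLibrary"))
  checkAnnotation(annotation)
  if (!isCount(binwidth)) stop("binwidth must be a positive integer")
  if (!isCount(flank) || flank %% binwidth != 0L)
    stop("flank must be a positive multiple of binwidth")
  flank <- as.integer(flank); binwidth <- as.integer(binwidth)
  gr <- tagPositions(library)
  idx <- nearestTssIndex(as.character(GenomeInfoDb::seqnames(gr)),
                         BiocGenerics::start(gr), annotation)
  ok <- !is.na(idx)
  tss <- geneTss(annotation)[idx[ok]]
  sgn <- ifelse(as.logical(BiocGenerics::strand(annotation)[idx[ok]] == "-"), -1L, 1L)
  d <- (BiocGenerics::start(gr)[ok] - tss) * sgn
  inWin <- d >= -flank & d < flank
  nb <- 2L * flank %/% binwidth
  bin <- (d[inWin] + flank) %/% binwidth + 1L
  counts <- tabulate(bin, nbins = nb)
  total <- totalCount(library)
  dens <- if (total > 0L) counts * 1e6 / total else as.numeric(counts)
  new("TssProfile", flank = flank, binwidth = binwidth,
      binStart = as.integer(seq(-flank, flank - binwidth, by = binwidth)),
      counts = as.numeric(counts), density = dens)
}

#' Call enrichment sites against an input control
#'
#' Slides windows of width `window` every `step` bp over each chromosome and
#' tests the IP tag count against the library-size-scaled input expectation:
#' `expected = input_count * (ip_total / input_total)`, floored at
#' `pseudocount`. A window is significant when the upper-tail Poisson
#' probability `P(X >= ip_count | expected)` is below `alpha` and
#' `ip_count / expected >= minFold`. Overlapping or adjacent significant
#' windows are merged into one site that keeps the minimum window p-value;
#' its `ip_tags` and `expected_input_tags` are recounted over the merged
#' interval. This Poisson window caller is a generic enrichment caller with
#' all knobs exposed; `alpha` is per-window (no multiple-testing correction)
#' unless `correct = "BH"` applies Benjamini-Hochberg across windows first.
#'
#' @param ip,input [TagLibrary] objects (both non-empty).
#' @param window,step window width and slide step in bp, `window >= step`.
#' @param alpha per-window significance level.
#' @param minFold minimum IP/expected fold enrichment.
#' @param pseudocount floor on the expected count (guards empty input
#'   windows).
#' @param correct `"none"` (default) or `"BH"`.
#' @return a `GRanges` of sites with metadata `ip_tags`,
#'   `expected_input_tags`, `enrichment_p`.
#' @export
callBindingSites <- function(ip, input, window = 1000L, step = 500L,
                             alpha = 1e-5, minFold = 2,
                             pseudocount = 0.5, correct = c("none", "BH")) {
  stopifnot(is(ip, "TagLibrary"), is(input, "TagLibrary"))
  correct <- match.arg(correct)
  if (totalCount(input) == 0L) stop("input library is empty (total_count = 0)")
  if (totalCount(ip) == 0L) stop("IP library is empty (total_count = 0)")
  if (window < step) stop("window must be >= step")
  ratio <- totalCount(ip) / totalCount(input)
  ipGr <- tagPositions(ip); inGr <- tagPositions(input)
  ipChrom <- as.character(GenomeInfoDb::seqnames(ipGr))
  inChrom <- as.character(GenomeInfoDb::seqnames(inGr))
  ipPos <- BiocGenerics::start(ipGr); inPos <- BiocGenerics::start(inGr)

  chroms <- union(unique(ipChrom), unique(inChrom))
  winChrom <- character(0); winStart <- integer(0)
  ipCnt <- integer(0); inCnt <- integer(0)
  countIn <- function(sorted, s, e) {  # tags with s <= pos <= e
    findInterval(e + 0.5, sorted) - findInterval(s - 0.5, sorted)
  }
  for (ch in chroms) {
    ipP <- sort(ipPos[ipChrom == ch]); inP <- sort(inPos[inChrom == ch])
    L <- max(c(ipP, inP, 1L))
    starts <- seq.int(1L, max(1L, L - window + 1L), by = step)
    winChrom <- c(winChrom, rep(ch, length(starts)))
    winStart <- c(winStart, starts)
    ipCnt <- c(ipCnt, countIn(ipP, starts, starts + window - 1L))
    inCnt <- c(inCnt, countIn(inP, starts, starts + window - 1L))
  }
  expected <- pmax(inCnt * ratio, pseudocount)
  p <- stats::ppois(ipCnt - 1L, lambda = expected, lower.tail = FALSE)
  pTest <- if (correct == "BH") stats::p.adjust(p, method = "BH") else p
  sig <- pTest < alpha & (ipCnt / expected) >= minFold
  if (!any(sig))
    return(GenomicRanges::GRanges(ip_tags = numeric(0),
                                  expected_input_tags = numeric(0),
                                  enrichment_p = numeric(0)))
  sigWin <- GenomicRanges::GRanges(winChrom[sig],
                                   IRanges::IRanges(winStart[sig],
                                                    winStart[sig] + window - 1L),
                                   p = p[sig])
  merged <- GenomicRanges::reduce(sigWin, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(sigWin, merged)
  minP <- tapply(sigWin$p[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), min)
  mChrom <- as.character(GenomeInfoDb::seqnames(merged))
  mIp <- mIn <- numeric(length(merged))
  for (ch in unique(mChrom)) {
    ipP <- sort(ipPos[ipChrom == ch]); inP <- sort(inPos[inChrom == ch])
    j <- which(mChrom == ch)
    mIp[j] <- countIn(ipP, BiocGenerics::start(merged)[j],
                      BiocGenerics::end(merged)[j])
    mIn[j] <- countIn(inP, BiocGenerics::start(merged)[j],
                      BiocGenerics::end(merged)[j])
  }
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    ip_tags = mIp,
    expected_input_tags = pmax(mIn * ratio, pseudocount),
    enrichment_p = as.numeric(minP[as.character(seq_along(merged))]))
  merged
}

#' Map binding sites to their nearest genes
#'
#' Annotates each site to the gene with the TSS nearest to the site midpoint
#' when that distance is at most `maxDistance`; farther sites stay
#' unannotated. Returns the distinct annotated gene set and per-gene site
#' counts.
#'
#' @param sites a `GRanges` of sites (e.g. from [callBindingSites]).
#' @param annotation gene annotation `GRanges`.
#' @param maxDistance maximum midpoint-to-TSS distance in bp.
#' @return list with `genes` (character vector of distinct gene ids),
#'   `siteCounts` (named integer, sites per annotated gene) and
#'   `unannotated` (number of sites beyond `maxDistance`).
#' @export
sitesToGenes <- function(sites, annotation, maxDistance = 10000L) {
  checkAnnotation(annotation)
  if (length(sites) == 0L)
    return(list(genes = character(0),
                siteCounts = integer(0), unannotated = 0L))
  mid <- (BiocGenerics::start(sites) + BiocGenerics::end(sites)) %/% 2L
  idx <- nearestTssIndex(as.character(GenomeInfoDb::seqnames(sites)), mid,
                         annotation)
  dist <- abs(mid - geneTss(annotation)[idx])
  ok <- !is.na(idx) & dist <= maxDistance
  counts <- table(annotation$gene_id[idx[ok]])
  list(genes = sort(names(counts)),
       siteCounts = stats::setNames(as.integer(counts), names(counts)),
       unannotated = sum(!ok))
}

#' Overlap partition of named sets
#'
#' Computes the count of elements in every non-empty membership signature of
#' two or more named sets (the regions of a Venn diagram); signature counts
#' sum to the size of the union. Also reports, for each set, the percentage
#' of a reference set it shares.
#'
#' @param sets named list (length >= 2) of character vectors.
#' @param reference name of the reference set for pairwise percentages
#'   (default the first set).
#' @return list with `signatures` (named integer; names like `"SM&MM"` in
#'   input set order), `pairwisePct` (named numeric, `100 * |ref ∩ s| /
#'   |ref|`), and `unionSize`.
#' @examples
#' overlapPartition(list(A = c("x", "y"), B = c("y", "z"), C = "y"))
#' @export
overlapPartition <- function(sets, reference = names(sets)[1]) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("sets must be a named list of length >= 2")
  stopifnot(reference %in% names(sets))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  signatures <- table(sig)
  ref <- sets[[reference]]
  pct <- vapply(sets, function(s)
    if (length(ref)) 100 * length(intersect(ref, s)) / length(ref) else NA_real_,
    numeric(1))
  list(signatures = stats::setNames(as.integer(signatures), names(signatures)),
       pairwisePct = pct,
       unionSize = length(universe))
}
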