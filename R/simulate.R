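#' Simulate a gene annotation on a synthetic genome
#'
#' Places `nGenes` gene models on equally sized chromosomes so that
#' transcription start sites on the same chromosome are at least
#' `minGeneSpacing` bp apart. Genes are distributed as evenly as possible
#' across chromosomes; TSS positions are drawn uniformly under the spacing
#' constraint (a sorted uniform draw plus a fixed spacing offset), strands
#' are assigned at random, and gene lengths are uniform on 1-10 kb (gene
#' bodies are minimal: all downstream computation uses only TSS, strand and
#' extent). Deterministic for a fixed `seed`.
#'
#' @param spec a [GenomeSpec].
#' @return a gene annotation `GRanges` (see [makeGeneAnnotation]) with
#'   `seqlengths` set; empty when `nGenes = 0`.
#' @examples
#' ann <- simulateAnnotation(GenomeSpec(nChroms = 1, chromLength = 1e5,
#'                                      nGenes = 10, minGeneSpacing = 5000,
#'                                      seed = 7))
#' length(ann)
#' @export
simulateAnnotation <- function(spec) {
  stopifnot(is(spec, "GenomeSpec"))
  validObject(spec)
  chroms <- sprintf("chr%d", seq_len(spec@nChroms))
  sl <- stats::setNames(rep(spec@chromLength, spec@nChroms), chroms)
  if (spec@nGenes == 0L) {
    gr <- GenomicRanges::GRanges(gene_id = character(0))
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    return(gr)
  }
  ## even split across chromosomes; spacing feasibility per chromosome
  base <- spec@nGenes %/% spec@nChroms
  extra <- spec@nGenes %% spec@nChroms
  perChrom <- rep(base, spec@nChroms) + c(rep(1L, extra), rep(0L, spec@nChroms - extra))
  s <- spec@minGeneSpacing
  L <- spec@chromLength
  bad <- perChrom > 0L & (L - (perChrom - 1L) * as.double(s)) < perChrom
  if (any(bad))
    stop(sprintf(paste0("infeasible packing: %d genes with min spacing %d bp ",
                        "do not fit on a %d bp chromosome"),
                 max(perChrom), s, L))
  withSeed(spec@seed, {
    pieces <- lapply(seq_len(spec@nChroms), function(i) {
      k <- perChrom[i]
      if (k == 0L) return(NULL)
      tss <- sort(sample.int(L - (k - 1L) * s, k)) + (seq_len(k) - 1L) * s
      strand <- sample(c("+", "-"), k, replace = TRUE)
      len <- sample(1000:10000, k, replace = TRUE)
      start <- ifelse(strand == "+", tss, pmax(1L, tss - len + 1L))
      end <- ifelse(strand == "+", pmin(L, tss + len - 1L), tss)
      data.frame(chrom = chroms[i], start = start, end = end,
                 strand = strand, tss = tss)
    })
    df <- do.call(rbind, pieces)
    df$gene_id <- sprintf("g%0*d", nchar(spec@nGenes), seq_len(nrow(df)))
    makeGeneAnnotation(df$chrom, df$start, df$end, df$strand, df$gene_id,
                       seqlengths = sl)
  })
}

#' Simulate a four-group expression matrix with planted effects
#'
#' Generates positive expression intensities for the SS/SM/MS/MM design with
#' known ground truth. Per-gene baselines are drawn on the log2 scale
#' (Normal(7, 1.5), a typical bead-array intensity scale); planted SM genes
#' have a population fold change of exactly `effectFold` versus SS, planted
#' MM genes have their log2 effect multiplied by `bluntingFactor` (the
#' blunted acute response after chronic pre-exposure); MS stays at baseline.
#' Noise is log-normal: Normal(0, `noiseSdLog2`) added per sample on the
#' log2 scale. Deterministic for a fixed `seed`.
#'
#' @param annotation gene annotation `GRanges` (non-empty).
#' @param cfg an [EffectConfig].
#' @param seed integer seed for the expression RNG stream.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"intensity"` (linear scale, strictly positive), `colData$group`, and
#'   truth labels `rowData()$truth_SM`, `rowData()$truth_MM` in
#'   `c("up", "down", "null")` for parameter-recovery tests.
#' @examples
#' ann <- simulateAnnotation(GenomeSpec(nGenes = 50, seed = 1))
#' se <- simulateExpression(ann, EffectConfig(nReplicates = 3), seed = 2)
#' table(SummarizedExperiment::rowData(se)$truth_SM)
#' @export
simulateExpression <- function(annotation, cfg, seed) {
  checkAnnotation(annotation)
  stopifnot(is(cfg, "EffectConfig"))
  validObject(cfg)
  ids <- annotation$gene_id
  n <- length(ids)
  withSeed(seed, {
    baseline <- rnorm(n, mean = 7, sd = 1.5)
    plant <- function(fracUp, fracDown) {
      nUp <- round(fracUp * n); nDown <- round(fracDown * n)
      lab <- rep("null", n)
      pick <- sample.int(n, nUp + nDown)
      lab[pick[seq_len(nUp)]] <- "up"
      if (nDown > 0) lab[pick[nUp + seq_len(nDown)]] <- "down"
      lab
    }
    truthSM <- plant(cfg@fracUpSM, cfg@fracDownSM)
    truthMM <- plant(cfg@fracUpMM, cfg@fracDownMM)
    lfc <- log2(cfg@effectFold)
    eff <- function(lab, scale) (lab == "up") * scale - (lab == "down") * scale
    groupMean <- cbind(SS = baseline,
                       SM = baseline + eff(truthSM, lfc),
                       MS = baseline,
                       MM = baseline + eff(truthMM, lfc * cfg@bluntingFactor))
    k <- cfg@nReplicates
    groups <- rep(CONDITIONS, each = k)
    log2mat <- groupMean[, groups, drop = FALSE] +
      matrix(rnorm(n * length(groups), sd = cfg@noiseSdLog2), nrow = n)
    mat <- 2^log2mat
    dimnames(mat) <- list(ids, paste(groups, rep(seq_len(k), times = 4), sep = "_"))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = mat),
      rowData = S4Vectors::DataFrame(truth_SM = truthSM, truth_MM = truthMM,
                                     row.names = ids),
      colData = S4Vectors::DataFrame(group = factor(groups, levels = CONDITIONS),
                                     row.names = colnames(mat)))
  })
}

#' Simulate a single-position ChIP tag library
#'
#' Emits exactly `librarySize` width-1 tags. An `input` library draws every
#' tag from the uniform genomic background. An `IP` library mixes
#' `backgroundFraction` uniform tags with TSS-centred tags: the gene is
#' chosen with probability proportional to
#' `exp(couplingSlope * log2(expression))` and the tag is placed at
#' TSS + Normal(0, `enrichmentSd`), the offset signed along the gene strand
#' (so the enrichment is symmetric on the strand-signed metagene axis).
#' Positions are clipped to chromosome bounds. By default a tag models the
#' fragment midpoint; `tagMode = "fiveprime"` instead emits the 5' end of
#' the fragment on the tag's strand (midpoint minus `fragmentLength/2`
#' along the strand), for use with a matching midpoint shift in the
#' quantifier. Deterministic for the seed in `params`.
#'
#' @param annotation gene annotation `GRanges` with `seqlengths` set.
#' @param conditionMeanExpression named numeric vector of linear-scale mean
#'   expression per gene (names = `gene_id`); required for `role = "IP"`
#'   unless `backgroundFraction = 1`.
#' @param params a [TagSimParams].
#' @param role `"IP"` or `"input"`.
#' @param condition treatment group label for the library.
#' @param sampleId sample identifier (default `<condition>_<role>`).
#' @param tagMode `"midpoint"` (default) or `"fiveprime"`.
#' @return a [TagLibrary].
#' @examples
#' ann <- simulateAnnotation(GenomeSpec(nGenes = 20, seed = 1))
#' expr <- stats::setNames(rep(100, 20), ann$gene_id)
#' lib <- simulateTagLibrary(ann, expr, TagSimParams(librarySize = 1000, seed = 3))
#' totalCount(lib)
#' @export
simulateTagLibrary <- function(annotation, conditionMeanExpression = NULL,
                               params = TagSimParams(), role = c("IP", "input"),
                               condition = "SS", sampleId = NULL,
                               tagMode = c("midpoint", "fiveprime")) {
  checkAnnotation(annotation)
  role <- match.arg(role)
  tagMode <- match.arg(tagMode)
  stopifnot(is(params, "TagSimParams"))
  validObject(params)
  sl <- GenomeInfoDb::seqlengths(annotation)
  if (any(is.na(sl))) stop("annotation must carry seqlengths for simulation")
  nTotal <- params@librarySize
  nBg <- if (role == "input") nTotal else as.integer(round(params@backgroundFraction * nTotal))
  nFg <- nTotal - nBg
  if (nFg > 0L && is.null(conditionMeanExpression))
    stop("conditionMeanExpression is required for an IP library with enrichment")
  if (nFg > 0L) {
    expr <- conditionMeanExpression[annotation$gene_id]
    if (any(is.na(expr)))
      stop("conditionMeanExpression must cover every annotated gene")
    if (any(expr <= 0)) stop("expression values must be strictly positive")
  }
  withSeed(params@seed, {
    ## uniform background over the genome
    chromIdx <- sample.int(length(sl), nBg, replace = TRUE, prob = sl / sum(sl))
    bgChrom <- names(sl)[chromIdx]
    bgPos <- floor(runif(nBg) * sl[chromIdx]) + 1
    fgChrom <- character(0); fgPos <- integer(0)
    if (nFg > 0L) {
      w <- params@couplingSlope * log2(expr)
      w <- exp(w - max(w))
      gi <- sample.int(length(annotation), nFg, replace = TRUE, prob = w)
      tss <- geneTss(annotation)[gi]
      sgn <- ifelse(as.logical(BiocGenerics::strand(annotation)[gi] == "-"), -1, 1)
      off <- round(rnorm(nFg, mean = 0, sd = params@enrichmentSd))
      fgChrom <- as.character(GenomeInfoDb::seqnames(annotation)[gi])
      fgPos <- tss + sgn * off
    }
    chrom <- c(bgChrom, fgChrom)
    pos <- c(bgPos, fgPos)
    strand <- sample(c("+", "-"), nTotal, replace = TRUE)
    if (tagMode == "fiveprime") {
      shift <- as.integer(params@fragmentLength %/% 2L)
      pos <- pos - ifelse(strand == "+", shift, -shift)
    }
    pos <- pmin(pmax(pos, 1), sl[chrom])
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(pos), width = 1L),
                                 strand = strand)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    TagLibrary(tags = gr, sampleId = sampleId %||% paste(condition, role, sep = "_"),
               condition = condition, role = role)
  })
}
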