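#' Bin genes by expression Z score
#'
#' Sorts genes in ascending order of Z (ties broken by `gene_id` for
#' determinism) and groups consecutive runs of `binSize` genes; a trailing
#' remainder forms a final bin flagged `partial`. Per-bin means of Z and of
#' normalized tag counts are the observations of the downstream regression;
#' averaging within 100-gene bins damps per-gene measurement noise before
#' binding is regressed on expression.
#'
#' @param zByGene named numeric vector of per-gene Z scores.
#' @param normTagsByGene named numeric vector of per-gene normalized tag
#'   counts (tags per million); must cover exactly the same genes.
#' @param binSize genes per bin (default 100).
#' @return a `data.frame` ordered by ascending `mean_z`: `bin_index`,
#'   `n_genes`, `mean_z`, `mean_norm_tags`, `partial`.
#' @examples
#' z <- stats::setNames(rnorm(250), sprintf("g%03d", 1:250))
#' tags <- stats::setNames(rpois(250, 20), names(z))
#' binGenes(z, tags)  # bins of 100, 100, and a partial 50
#' @export
binGenes <- function(zByGene, normTagsByGene, binSize = 100L) {
  if (length(zByGene) == 0L) stop("empty input: no genes to bin")
  if (!isCount(binSize)) stop("binSize must be a positive integer")
  extraZ <- setdiff(names(zByGene), names(normTagsByGene))
  extraT <- setdiff(names(normTagsByGene), names(zByGene))
  if (length(extraZ) || length(extraT))
    stop("gene sets differ; only in Z: {",
         paste(head(extraZ, 5), collapse = ", "), "}; only in tags: {",
         paste(head(extraT, 5), collapse = ", "), "}")
  ord <- order(zByGene, names(zByGene))
  z <- zByGene[ord]
  tg <- normTagsByGene[names(z)]
  n <- length(z)
  bin <- (seq_len(n) - 1L) %/% binSize + 1L
  nb <- max(bin)
  data.frame(bin_index = seq_len(nb),
             n_genes = as.integer(tabulate(bin, nb)),
             mean_z = as.numeric(tapply(z, bin, mean)),
             mean_norm_tags = as.numeric(tapply(tg, bin, mean)),
             partial = tabulate(bin, nb) < binSize,
             row.names = NULL)
}

#' Ordinary least squares over expression bins
#'
#' Regresses mean normalized tag count on mean Z score across bins (one
#' observation per bin). `r_squared = 1 - SS_res / SS_tot`; a constant
#' response has slope 0 and, by convention, `r_squared = 0`. Partial bins
#' are excluded by default since their means average fewer genes.
#'
#' Because binding intensity couples log-linearly with expression, the bin
#' means are exponential in Z on the natural scale; `response = "log2"`
#' regresses `log2(mean_norm_tags + logOffset)` instead, which linearizes
#' that relationship and is the scale used by [runPipeline] for the
#' expression/binding correlation. The default `"linear"` regresses the tag
#' counts as-is.
#'
#' @param bins a `data.frame` from [binGenes].
#' @param includePartial include partial bins as observations (default
#'   `FALSE`).
#' @param response `"linear"` (default) or `"log2"`.
#' @param logOffset offset (tags per million) added before the log2
#'   transform to guard empty bins.
#' @return list with `slope`, `intercept`, `r_squared`, `n_bins`,
#'   `response`.
#' @export
binRegression <- function(bins, includePartial = FALSE,
                          response = c("linear", "log2"), logOffset = 1) {
  response <- match.arg(response)
  use <- if (includePartial) bins else bins[!bins$partial, , drop = FALSE]
  if (nrow(use) < 3L) stop("need >= 3 usable bins for regression")
  x <- use$mean_z
  y <- if (response == "log2") log2(use$mean_norm_tags + logOffset)
       else use$mean_norm_tags
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                n_bins = nrow(use), response = response))
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot,
       n_bins = nrow(use), response = response)
}

#' Input-corrected binding fold change between two conditions
#'
#' Per gene, the IP count is first corrected for the DNA input:
#' `enrichment = (ip + pseudocount) / (input + pseudocount)`; the binding
#' change is the ratio of enrichments `B / A`, reported in the signed
#' convention ([signedFold]). The pseudocount guards genes with zero counts.
#'
#' @param ipA,inputA,ipB,inputB named numeric vectors of per-gene normalized
#'   tag counts for the two conditions; all four must cover the same genes.
#' @param pseudocount positive count offset (default 0.5).
#' @return named numeric vector of signed binding folds (B vs A).
#' @examples
#' bindingFoldChange(c(g = 10), c(g = 5), c(g = 40), c(g = 10))
#' @export
bindingFoldChange <- function(ipA, inputA, ipB, inputB, pseudocount = 0.5) {
  stopifnot(isScalarNum(pseudocount), pseudocount > 0)
  genes <- names(ipA)
  for (v in list(inputA, ipB, inputB))
    if (!setequal(names(v), genes)) stop("all four count vectors must cover the same genes")
  enrA <- (ipA[genes] + pseudocount) / (inputA[genes] + pseudocount)
  enrB <- (ipB[genes] + pseudocount) / (inputB[genes] + pseudocount)
  stats::setNames(signedFold(as.numeric(enrB / enrA)), genes)
}

#' Classify expression/binding concordance
#'
#' For each differentially expressed gene, the binding status is `absent`
#' when the gene was not detected on the ChIP platform, `NC` (no change)
#' when its binding fold is below `ncThreshold` in magnitude (or when the
#' gene is detected but no fold is available), and `increased`/`decreased`
#' by the sign of the binding fold otherwise. Rows of the result correspond
#' to rows of the DE table, so probe-level duplicates of a symbol stay
#' distinct records.
#'
#' @param deTable a `data.frame` with columns `gene_id`, `signed_fc` and
#'   optionally `call` (rows with `call == "null"` are dropped); one row per
#'   DE record.
#' @param bindingFold signed binding folds: either a named vector (looked up
#'   by `gene_id`) or an unnamed vector aligned with the rows of `deTable`;
#'   `NA` means no fold available.
#' @param bindingDetected character vector of genes detected on the ChIP
#'   platform, or a logical vector aligned with the rows.
#' @param ncThreshold no-change threshold in signed-fold units (>= 1,
#'   default 1.4 — below the smallest changed binding magnitude in the
#'   packaged tables; the choice is configurable).
#' @return a `data.frame`: `gene_id`, `expr_signed_fc`, `expr_direction`
#'   (`up`/`down`), `binding_fold`, `binding_status`
#'   (`increased`/`decreased`/`NC`/`absent`).
#' @export
classifyConcordance <- function(deTable, bindingFold, bindingDetected,
                                ncThreshold = 1.4) {
  stopifnot(isScalarNum(ncThreshold), ncThreshold >= 1)
  stopifnot(all(c("gene_id", "signed_fc") %in% names(deTable)))
  if (!is.null(deTable$call))
    deTable <- deTable[deTable$call != "null", , drop = FALSE]
  n <- nrow(deTable)
  if (n == 0L)
    return(data.frame(gene_id = character(0), expr_signed_fc = numeric(0),
                      expr_direction = character(0), binding_fold = numeric(0),
                      binding_status = character(0)))
  fold <- if (is.null(names(bindingFold)) && length(bindingFold) == n)
    as.numeric(bindingFold)
  else
    as.numeric(bindingFold[deTable$gene_id])
  detected <- if (is.logical(bindingDetected) && length(bindingDetected) == n)
    bindingDetected
  else
    deTable$gene_id %in% bindingDetected
  status <- ifelse(!detected, "absent",
                   ifelse(is.na(fold) | abs(fold) < ncThreshold, "NC",
                          ifelse(fold > 0, "increased", "decreased")))
  data.frame(gene_id = deTable$gene_id,
             expr_signed_fc = deTable$signed_fc,
             expr_direction = ifelse(deTable$signed_fc >= 0, "up", "down"),
             binding_fold = ifelse(status %in% c("increased", "decreased"),
                                   fold, NA_real_),
             binding_status = status,
             row.names = NULL)
}

#' Contingency counts of expression direction by binding status
#'
#' Tabulates concordance records into a 2 x 4 table (expression `up`/`down`
#' by binding `increased`/`decreased`/`NC`/`absent`) and reports
#' "both-platform" totals: the number of up- and down-regulated records
#' detected on the ChIP platform (status not `absent`).
#'
#' @param records a `data.frame` from [classifyConcordance].
#' @return list with `table` (2 x 4 integer matrix), `bothPlatform` (named
#'   vector, `up` and `down` totals excluding `absent`), and `n` (total
#'   records).
#' @export
concordanceCounts <- function(records) {
  dirs <- c("up", "down")
  stats <- c("increased", "decreased", "NC", "absent")
  tab <- table(factor(records$expr_direction, levels = dirs),
               factor(records$binding_status, levels = stats))
  tab <- matrix(as.integer(tab), nrow = 2, dimnames = list(dirs, stats))
  both <- rowSums(tab[, c("increased", "decreased", "NC"), drop = FALSE])
  list(table = tab,
       bothPlatform = stats::setNames(as.integer(both), dirs),
       n = nrow(records))
}

#' Overlap partition of differentially expressed gene sets
#'
#' Reduces each DE table to its called gene set (`up` or `down`) and
#' delegates to [overlapPartition].
#'
#' @param deTables named list (>= 2) of DE tables from
#'   [differentialExpression], one per contrast.
#' @param reference passed to [overlapPartition].
#' @return see [overlapPartition].
#' @export
deSetOverlap <- function(deTables, reference = names(deTables)[1]) {
  if (!is.list(deTables) || length(deTables) < 2L)
    stop("need >= 2 DE tables")
  sets <- lapply(deTables, function(d) d$gene_id[d$call != "null"])
  overlapPartition(sets, reference = reference)
}
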