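getIntensity <- function(se) {
  stopifnot(is(se, "SummarizedExperiment"))
  mat <- SummarizedExperiment::assay(se, "intensity")
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("expression values must be finite and strictly positive")
  mat
}

sampleGroups <- function(se) {
  grp <- SummarizedExperiment::colData(se)$group
  if (is.null(grp)) stop("colData must carry a 'group' column")
  as.character(grp)
}

#' Global (median-scaling) normalization of an expression matrix
#'
#' Scales each sample by a single factor so that its median equals the grand
#' median of the input matrix; values stay strictly positive and per-gene
#' ratios within a sample are untouched.
#'
#' @param se a `SummarizedExperiment` with assay `"intensity"`.
#' @return the `SummarizedExperiment` with the intensity assay rescaled.
#' @export
globalNormalize <- function(se) {
  mat <- getIntensity(se)
  grand <- stats::median(mat)
  med <- apply(mat, 2L, stats::median)
  SummarizedExperiment::assay(se, "intensity") <-
    sweep(mat, 2L, grand / med, "*")
  se
}

#' Per-gene mean expression of one treatment group
#'
#' @param se a `SummarizedExperiment` with assay `"intensity"` and
#'   `colData$group`.
#' @param group one of `"SS"`, `"SM"`, `"MS"`, `"MM"`.
#' @return named numeric vector of linear-scale means over the group's
#'   samples.
#' @export
conditionMeans <- function(se, group) {
  mat <- getIntensity(se)
  sel <- sampleGroups(se) == group
  if (!any(sel)) stop("no samples in group ", group)
  rowMeans(mat[, sel, drop = FALSE])
}

## Welch's two-sample t-test, vectorized over genes, on log2 values.
## Degenerate case (both group variances zero): p = 1 when the means agree,
## 0 otherwise (the limit of the t statistic).
welchRows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  list(t = t, p = p)
}

#' Differential expression by fold-change and Welch's t-test
#'
#' For each gene, the fold change is `mean(B) / mean(A)` on the linear scale,
#' reported in the signed convention ([signedFold]); the p-value comes from
#' Welch's two-sample t-test on log2 intensities (a documented stand-in for
#' the unspecified array-suite statistic, swappable in principle). A gene is
#' called `up` when `signed_fc >= fcCut` and `p < pCut` (strict), `down`
#' symmetrically, else `null`. Benjamini-Hochberg adjusted p-values are
#' reported alongside but do not enter the calls.
#'
#' @param se a `SummarizedExperiment` with assay `"intensity"` and
#'   `colData$group`.
#' @param groupA,groupB group labels to compare (fold is B over A); each
#'   needs >= 2 samples.
#' @param fcCut fold-change cutoff in signed-fold units (default 1.7).
#' @param pCut p-value cutoff (default 0.01).
#' @return a `data.frame` (one row per gene): `gene_id`, `signed_fc`,
#'   `p_value`, `p_adj`, `call`.
#' @examples
#' ann <- simulateAnnotation(GenomeSpec(nGenes = 100, seed = 1))
#' se <- simulateExpression(ann, EffectConfig(), seed = 2)
#' de <- differentialExpression(se, "SS", "SM")
#' table(de$call)
#' @export
differentialExpression <- function(se, groupA, groupB, fcCut = 1.7, pCut = 0.01) {
  stopifnot(isScalarNum(fcCut), fcCut >= 1, isProportion(pCut))
  mat <- getIntensity(se)
  grp <- sampleGroups(se)
  selA <- grp == groupA; selB <- grp == groupB
  if (sum(selA) < 2L || sum(selB) < 2L)
    stop("each compared group needs >= 2 samples")
  fold <- rowMeans(mat[, selB, drop = FALSE]) / rowMeans(mat[, selA, drop = FALSE])
  sfc <- signedFold(fold)
  w <- welchRows(log2(mat[, selA, drop = FALSE]), log2(mat[, selB, drop = FALSE]))
  call <- rep("null", nrow(mat))
  call[sfc >= fcCut & w$p < pCut] <- "up"
  call[sfc <= -fcCut & w$p < pCut] <- "down"
  data.frame(gene_id = rownames(mat), signed_fc = sfc, p_value = w$p,
             p_adj = stats::p.adjust(w$p, method = "BH"), call = call,
             row.names = NULL)
}

#' Z scores of per-gene expression within a condition
#'
#' Standardizes log2 mean expression across genes: `Z = (log2(x) - mean) /
#' sd` with the sample standard deviation (denominator n - 1). The mean of
#' the result is 0 and its SD 1 whenever the input is not constant; an
#' all-equal input returns all zeros by convention.
#'
#' @param conditionMeanExpression named numeric vector of positive
#'   linear-scale mean expression per gene (>= 2 genes).
#' @return named numeric vector of Z scores.
#' @examples
#' zscoreExpression(stats::setNames(2^c(1, 2, 3), c("a", "b", "c")))
#' @export
zscoreExpression <- function(conditionMeanExpression) {
  x <- conditionMeanExpression
  if (length(x) < 2L) stop("need >= 2 genes to standardize")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("expression values must be finite and strictly positive")
  lx <- log2(x)
  s <- stats::sd(lx)
  z <- if (s > 0) (lx - mean(lx)) / s else rep(0, length(lx))
  stats::setNames(z, names(x))
}
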