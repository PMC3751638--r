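#' @import methods
#' @importClassesFrom GenomicRanges GRanges
NULL

CONDITIONS <- c("SS", "SM", "MS", "MM")
ROLES <- c("IP", "input")

#' GenomeSpec: layout of a synthetic genome
#'
#' Describes the synthetic genome on which gene annotations are simulated:
#' a set of equally sized chromosomes and the number of genes to place on
#' them with a minimum spacing between transcription start sites.
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength length of every chromosome (bp).
#' @slot nGenes number of genes to place.
#' @slot minGeneSpacing minimum distance between TSSs on a chromosome (bp).
#' @slot seed integer seed for the placement RNG stream.
#'
#' @param nChroms,chromLength,nGenes,minGeneSpacing,seed see slots.
#' @return a validated `GenomeSpec` object.
#' @examples
#' GenomeSpec(nChroms = 2, chromLength = 1e6, nGenes = 100,
#'            minGeneSpacing = 5000, seed = 1)
#' @aliases GenomeSpec-class
#' @export GenomeSpec
#' @exportClass GenomeSpec
GenomeSpec <- setClass("GenomeSpec",
  slots = c(nChroms = "integer", chromLength = "integer", nGenes = "integer",
            minGeneSpacing = "integer", seed = "integer"))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  for (s in c("nChroms", "chromLength", "minGeneSpacing"))
    if (!isCount(slot(object, s))) msg <- c(msg, paste(s, "must be a positive integer"))
  if (!(isScalarNum(object@nGenes) && object@nGenes >= 0))
    msg <- c(msg, "nGenes must be a non-negative integer")
  if (length(msg) == 0 &&
      as.double(object@nGenes) * object@minGeneSpacing >
      as.double(object@nChroms) * object@chromLength)
    msg <- c(msg, "infeasible: nGenes * minGeneSpacing exceeds total genome length")
  if (length(msg)) msg else TRUE
})

.GenomeSpecInit <- function(.Object, nChroms = 1L, chromLength = 1e6L,
                            nGenes = 100L, minGeneSpacing = 5000L, seed = 1L, ...) {
  .Object@nChroms <- as.integer(nChroms)
  .Object@chromLength <- as.integer(chromLength)
  .Object@nGenes <- as.integer(nGenes)
  .Object@minGeneSpacing <- as.integer(minGeneSpacing)
  .Object@seed <- as.integer(seed)
  validObject(.Object)
  .Object
}
setMethod("initialize", "GenomeSpec", .GenomeSpecInit)

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@nGenes, "genes on", object@nChroms,
      "chromosome(s) of", object@chromLength, "bp; min TSS spacing",
      object@minGeneSpacing, "bp; seed", object@seed, "\n")
})

#' EffectConfig: planted differential-expression design
#'
#' Parameters of the simulated four-group expression experiment. The four
#' groups follow the chronic/acute pretreatment design: SS (saline/saline),
#' SM (saline/drug), MS (drug/saline), MM (drug/drug). Effects are planted
#' for the SM-vs-SS and MM-vs-SS contrasts; effects in MM are attenuated
#' ("blunted") by `bluntingFactor` on the log2 scale, emulating the reduced
#' acute transcriptional response after chronic pre-exposure.
#'
#' @slot nReplicates samples per group (>= 2).
#' @slot fracUpSM,fracDownSM fraction of genes planted up/down in SM vs SS.
#' @slot fracUpMM,fracDownMM fraction of genes planted up/down in MM vs SS.
#' @slot effectFold population fold change of planted genes (> 1).
#' @slot bluntingFactor multiplier on the log2 effect in MM, in \[0, 1\].
#' @slot noiseSdLog2 per-sample log2-scale noise SD (>= 0).
#'
#' @param nReplicates,fracUpSM,fracDownSM,fracUpMM,fracDownMM see slots.
#' @param effectFold,bluntingFactor,noiseSdLog2 see slots.
#' @return a validated `EffectConfig`.
#' @examples
#' EffectConfig(nReplicates = 5, fracUpSM = 0.05, fracDownSM = 0.02,
#'              effectFold = 4, noiseSdLog2 = 0.25)
#' @aliases EffectConfig-class
#' @export EffectConfig
#' @exportClass EffectConfig
EffectConfig <- setClass("EffectConfig",
  slots = c(nReplicates = "integer",
            fracUpSM = "numeric", fracDownSM = "numeric",
            fracUpMM = "numeric", fracDownMM = "numeric",
            effectFold = "numeric", bluntingFactor = "numeric",
            noiseSdLog2 = "numeric"))

setValidity("EffectConfig", function(object) {
  msg <- character()
  if (!(isScalarNum(object@nReplicates) && object@nReplicates >= 2))
    msg <- c(msg, "nReplicates must be >= 2 (variance undefined otherwise)")
  for (s in c("fracUpSM", "fracDownSM", "fracUpMM", "fracDownMM", "bluntingFactor"))
    if (!isProportion(slot(object, s))) msg <- c(msg, paste(s, "must be in [0, 1]"))
  if (length(msg) == 0) {
    if (object@fracUpSM + object@fracDownSM > 1)
      msg <- c(msg, "fracUpSM + fracDownSM must be <= 1")
    if (object@fracUpMM + object@fracDownMM > 1)
      msg <- c(msg, "fracUpMM + fracDownMM must be <= 1")
  }
  if (!(isScalarNum(object@effectFold) && object@effectFold > 1))
    msg <- c(msg, "effectFold must be > 1")
  if (!(isScalarNum(object@noiseSdLog2) && object@noiseSdLog2 >= 0))
    msg <- c(msg, "noiseSdLog2 must be >= 0")
  if (length(msg)) msg else TRUE
})

.EffectConfigInit <- function(.Object, nReplicates = 5L,
                              fracUpSM = 0.05, fracDownSM = 0.02,
                              fracUpMM = 0.015, fracDownMM = 0.045,
                              effectFold = 4, bluntingFactor = 0.5,
                              noiseSdLog2 = 0.25, ...) {
  .Object@nReplicates <- as.integer(nReplicates)
  .Object@fracUpSM <- fracUpSM; .Object@fracDownSM <- fracDownSM
  .Object@fracUpMM <- fracUpMM; .Object@fracDownMM <- fracDownMM
  .Object@effectFold <- effectFold
  .Object@bluntingFactor <- bluntingFactor
  .Object@noiseSdLog2 <- noiseSdLog2
  validObject(.Object)
  .Object
}
setMethod("initialize", "EffectConfig", .EffectConfigInit)

setMethod("show", "EffectConfig", function(object) {
  cat(sprintf(paste0("EffectConfig: n=%d/group; SM up/down %.3f/%.3f; ",
                     "MM up/down %.3f/%.3f; fold %.2f, blunting %.2f, ",
                     "noise sd(log2) %.2f\n"),
              object@nReplicates, object@fracUpSM, object@fracDownSM,
              object@fracUpMM, object@fracDownMM, object@effectFold,
              object@bluntingFactor, object@noiseSdLog2))
})

#' TagSimParams: ChIP tag-library simulation parameters
#'
#' Parameters of the simulated single-position tag library. An IP library
#' mixes a uniform background with TSS-centred tags whose gene is chosen with
#' probability proportional to `exp(couplingSlope * log2(expression))`; an
#' input library is entirely background. Tags model the midpoints of sheared
#' chromatin fragments (default fragment length within the 300-600 bp
#' sonication range); each tag is a single genomic position, as produced by
#' aligning short sequenced ends.
#'
#' @slot librarySize number of tags to emit.
#' @slot backgroundFraction fraction of IP tags drawn from the uniform
#'   background, in \[0, 1\].
#' @slot enrichmentSd SD (bp) of the Gaussian spread of enriched tags
#'   around the TSS.
#' @slot couplingSlope planted log-linear slope of promoter tag intensity
#'   on log2 expression.
#' @slot fragmentLength sheared fragment length (bp).
#' @slot seed integer seed for the tag RNG stream.
#'
#' @param librarySize,backgroundFraction,enrichmentSd see slots.
#' @param couplingSlope,fragmentLength,seed see slots.
#' @return a validated `TagSimParams`.
#' @examples
#' TagSimParams(librarySize = 1e5, backgroundFraction = 0.2,
#'              couplingSlope = 1, seed = 1)
#' @aliases TagSimParams-class
#' @export TagSimParams
#' @exportClass TagSimParams
TagSimParams <- setClass("TagSimParams",
  slots = c(librarySize = "integer", backgroundFraction = "numeric",
            enrichmentSd = "numeric", couplingSlope = "numeric",
            fragmentLength = "integer", seed = "integer"))

setValidity("TagSimParams", function(object) {
  msg <- character()
  if (!isCount(object@librarySize)) msg <- c(msg, "librarySize must be a positive integer")
  if (!isProportion(object@backgroundFraction))
    msg <- c(msg, "backgroundFraction must be in [0, 1]")
  if (!(isScalarNum(object@enrichmentSd) && object@enrichmentSd > 0))
    msg <- c(msg, "enrichmentSd must be > 0")
  if (!isScalarNum(object@couplingSlope)) msg <- c(msg, "couplingSlope must be numeric")
  if (!isCount(object@fragmentLength)) msg <- c(msg, "fragmentLength must be a positive integer")
  if (length(msg)) msg else TRUE
})

.TagSimParamsInit <- function(.Object, librarySize = 1e5L, backgroundFraction = 0.2,
                              enrichmentSd = 200, couplingSlope = 1,
                              fragmentLength = 450L, seed = 1L, ...) {
  .Object@librarySize <- as.integer(librarySize)
  .Object@backgroundFraction <- backgroundFraction
  .Object@enrichmentSd <- enrichmentSd
  .Object@couplingSlope <- couplingSlope
  .Object@fragmentLength <- as.integer(fragmentLength)
  .Object@seed <- as.integer(seed)
  validObject(.Object)
  .Object
}
setMethod("initialize", "TagSimParams", .TagSimParamsInit)

setMethod("show", "TagSimParams", function(object) {
  cat(sprintf(paste0("TagSimParams: %d tags; background %.2f; enrichment sd ",
                     "%.0f bp; coupling slope %.2f; fragment %d bp; seed %d\n"),
              object@librarySize, object@backgroundFraction, object@enrichmentSd,
              object@couplingSlope, object@fragmentLength, object@seed))
})

#' TagLibrary: one sample's single-position ChIP tags
#'
#' Container for one sequencing library: single-base tag positions as a
#' [GenomicRanges::GRanges] plus the sample's identity (condition and
#' IP/input role). The total tag count is the unit of library-size
#' normalization (tags per million).
#'
#' @slot tags `GRanges` of width-1 tag positions (strand recorded).
#' @slot sampleId sample identifier.
#' @slot condition one of `"SS"`, `"SM"`, `"MS"`, `"MM"`.
#' @slot role `"IP"` or `"input"`.
#'
#' @param tags,sampleId,condition,role see slots.
#' @return a validated `TagLibrary`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'                              strand = c("+", "-"))
#' TagLibrary(tags = gr, sampleId = "SS_IP", condition = "SS", role = "IP")
#' @aliases TagLibrary-class
#' @export TagLibrary
#' @exportClass TagLibrary
TagLibrary <- setClass("TagLibrary",
  slots = c(tags = "GRanges", sampleId = "character",
            condition = "character", role = "character"))

setValidity("TagLibrary", function(object) {
  msg <- character()
  if (length(object@tags) && any(GenomicRanges::width(object@tags) != 1L))
    msg <- c(msg, "tags must be single-base positions (width 1)")
  if (length(object@tags) && any(GenomicRanges::start(object@tags) < 1L))
    msg <- c(msg, "tag positions must be non-negative (1-based start >= 1)")
  if (!(length(object@condition) == 1L && object@condition %in% CONDITIONS))
    msg <- c(msg, "condition must be one of SS, SM, MS, MM")
  if (!(length(object@role) == 1L && object@role %in% ROLES))
    msg <- c(msg, "role must be IP or input")
  if (length(msg)) msg else TRUE
})

.TagLibraryInit <- function(.Object, tags = GenomicRanges::GRanges(),
                            sampleId = "sample", condition = "SS", role = "IP", ...) {
  .Object@tags <- tags
  .Object@sampleId <- sampleId
  .Object@condition <- condition
  .Object@role <- role
  validObject(.Object)
  .Object
}
setMethod("initialize", "TagLibrary", .TagLibraryInit)

setMethod("show", "TagLibrary", function(object) {
  cat(sprintf("TagLibrary '%s' (%s, %s): %d tags on %d seqname(s)\n",
              object@sampleId, object@condition, object@role,
              length(object@tags),
              length(GenomeInfoDb::seqlevelsInUse(object@tags))))
})

#' TssProfile: metagene tag density around TSSs
#'
#' Aggregate distribution of tag distances to the nearest TSS, binned at
#' fixed width over `[-flank, flank)`. Distances are strand-signed (upstream
#' of the TSS is negative for both strands) so minus-strand genes fold
#' correctly onto the metagene axis. Densities are raw bin counts scaled to
#' tags per million of the library total.
#'
#' @slot flank half-width of the profiled window (bp).
#' @slot binwidth bin width (bp); `flank` must be a multiple.
#' @slot binStart left edge (signed distance, bp) of each bin.
#' @slot counts raw tag count per bin.
#' @slot density counts per million total tags.
#'
#' @param flank,binwidth,binStart,counts,density see slots.
#' @return a validated `TssProfile`.
#' @aliases TssProfile-class
#' @export TssProfile
#' @exportClass TssProfile
TssProfile <- setClass("TssProfile",
  slots = c(flank = "integer", binwidth = "integer", binStart = "integer",
            counts = "numeric", density = "numeric"))

setValidity("TssProfile", function(object) {
  msg <- character()
  if (!isCount(object@flank)) msg <- c(msg, "flank must be a positive integer")
  if (!isCount(object@binwidth)) msg <- c(msg, "binwidth must be a positive integer")
  if (length(msg) == 0) {
    nb <- 2L * object@flank / object@binwidth
    if (object@flank %% object@binwidth != 0L)
      msg <- c(msg, "flank must be a multiple of binwidth")
    else if (length(object@binStart) != nb || length(object@counts) != nb ||
             length(object@density) != nb)
      msg <- c(msg, "bin vectors must have length 2*flank/binwidth")
  }
  if (any(object@counts < 0) || any(object@density < 0))
    msg <- c(msg, "counts and density must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TssProfile", function(object) {
  peak <- if (length(object@counts)) object@binStart[which.max(object@counts)] else NA
  cat(sprintf(paste0("TssProfile: flank %d bp, binwidth %d bp (%d bins); ",
                     "%g tags in window; peak bin starts at %s bp\n"),
              object@flank, object@binwidth, length(object@counts),
              sum(object@counts), peak))
})
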