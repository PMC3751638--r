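## Default pipeline configuration: one flat key/value list. Simulation keys
## mirror GenomeSpec/EffectConfig/TagSimParams; threshold keys mirror the
## analysis operations. Paths, when given, replace the corresponding
## simulation stage (annotation_bed; expression_tsv + group_map_tsv;
## tag_dir containing <condition>_IP.bed / <condition>_input.bed).
defaultConfig <- function() list(
  n_chroms = 4L, chrom_length = 1000000L, n_genes = 500L,
  min_gene_spacing = 5000L,
  n_replicates = 5L, frac_up_sm = 0.05, frac_down_sm = 0.02,
  frac_up_mm = 0.015, frac_down_mm = 0.045, effect_fold = 4,
  blunting_factor = 0.5, noise_sd_log2 = 0.25,
  library_size = 100000L, background_fraction = 0.2, enrichment_sd = 200,
  coupling_slope = 1, fragment_length = 450L,
  fc_cut = 1.7, p_cut = 0.01, promoter_halfwidth = 2000L,
  flank = 5000L, binwidth = 100L,
  window = 1000L, step = 500L, alpha = 1e-5, min_fold = 2,
  site_max_distance = 10000L, bin_size = 100L, nc_threshold = 1.4,
  seed = 1L, out_dir = "acetylscan_out",
  annotation_bed = NULL, expression_tsv = NULL, group_map_tsv = NULL,
  tag_dir = NULL, write_tag_libraries = FALSE, verbose = TRUE)

## polynomial rolling hash over a string; used only as a provenance checksum
configHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list of overrides; unknown keys are
#' rejected with a suggestion for the nearest known key, defaults are filled
#' in, and every threshold is checked against its documented domain.
#'
#' @param config a YAML path or a named list of settings (may be empty).
#' @return the full normalized configuration list.
#' @examples
#' cfg <- validateConfig(list(n_genes = 200, seed = 42))
#' cfg$fc_cut
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config) %||% list()
  stopifnot(is.list(config))
  defaults <- defaultConfig()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    d <- utils::adist(unknown[1], names(defaults))
    stop(sprintf("unknown config key '%s'; did you mean '%s'?",
                 unknown[1], names(defaults)[which.min(d)]))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  chk <- function(ok, what) if (!ok) stop("config: ", what)
  chk(cfg$fc_cut >= 1, "fc_cut must be >= 1 (signed-fold units)")
  chk(cfg$p_cut > 0 && cfg$p_cut <= 1, "p_cut must be in (0, 1]")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  chk(cfg$min_fold >= 1, "min_fold must be >= 1")
  chk(cfg$nc_threshold >= 1, "nc_threshold must be >= 1")
  chk(cfg$window >= cfg$step, "window must be >= step")
  chk(cfg$flank %% cfg$binwidth == 0, "flank must be a multiple of binwidth")
  chk(cfg$bin_size >= 1, "bin_size must be >= 1")
  chk(cfg$promoter_halfwidth >= 1, "promoter_halfwidth must be >= 1")
  chk(cfg$site_max_distance >= 1, "site_max_distance must be >= 1")
  ## simulation parameter objects run their own validity checks
  GenomeSpec(nChroms = cfg$n_chroms, chromLength = cfg$chrom_length,
             nGenes = cfg$n_genes, minGeneSpacing = cfg$min_gene_spacing,
             seed = cfg$seed)
  EffectConfig(nReplicates = cfg$n_replicates,
               fracUpSM = cfg$frac_up_sm, fracDownSM = cfg$frac_down_sm,
               fracUpMM = cfg$frac_up_mm, fracDownMM = cfg$frac_down_mm,
               effectFold = cfg$effect_fold,
               bluntingFactor = cfg$blunting_factor,
               noiseSdLog2 = cfg$noise_sd_log2)
  TagSimParams(librarySize = cfg$library_size,
               backgroundFraction = cfg$background_fraction,
               enrichmentSd = cfg$enrichment_sd,
               couplingSlope = cfg$coupling_slope,
               fragmentLength = cfg$fragment_length, seed = cfg$seed)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

logInfo <- function(verbose, ...) if (verbose) message("INFO ", sprintf(...))

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full integration pipeline
#'
#' Orchestrates simulate (or load) -> quantify -> differential expression ->
#' integrate: gene annotation; four-group expression matrix; per-condition
#' IP and input tag libraries; global normalization; DE for SM-vs-SS and
#' MM-vs-SS at the configured fold/p cutoffs; per-condition Z scores,
#' nearest-promoter tag counts, 100-gene bins and the expression-vs-binding
#' regression; Poisson enrichment sites against input, site-to-gene
#' annotation and the cross-condition overlap partition; input-corrected
#' binding fold changes and the expression/binding concordance tables.
#' All intermediate tables are written as TSV/BED under `out_dir` with a
#' machine-readable JSON report; the run is deterministic for a fixed
#' config and seed (one global seed is fanned out to per-stage streams by
#' fixed offsets).
#'
#' @param config a config list or YAML path (see [validateConfig]).
#' @return the run report (a nested list), invisibly; also written as
#'   `report.json` under `out_dir`.
#' @examples
#' \donttest{
#' rep <- runPipeline(list(n_genes = 100, library_size = 5000,
#'                         out_dir = tempfile(), verbose = FALSE))
#' rep$de$SM_vs_SS
#' }
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  v <- cfg$verbose
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in c("fc_cut", "p_cut", "promoter_halfwidth", "window", "step",
              "alpha", "min_fold", "bin_size", "nc_threshold", "flank",
              "binwidth", "site_max_distance", "seed"))
    logInfo(v, "threshold %s=%s", k, format(cfg[[k]]))

  ann <- stage("annotation", {
    if (!is.null(cfg$annotation_bed)) readAnnotationBed(cfg$annotation_bed)
    else simulateAnnotation(GenomeSpec(nChroms = cfg$n_chroms,
                                       chromLength = cfg$chrom_length,
                                       nGenes = cfg$n_genes,
                                       minGeneSpacing = cfg$min_gene_spacing,
                                       seed = cfg$seed + 101L))
  })
  writeAnnotationBed(ann, file.path(cfg$out_dir, "annotation.bed"))
  logInfo(v, "annotation: %d genes", length(ann))

  se <- stage("expression", {
    if (!is.null(cfg$expression_tsv))
      readExpression(cfg$expression_tsv, cfg$group_map_tsv)
    else simulateExpression(ann, EffectConfig(
      nReplicates = cfg$n_replicates,
      fracUpSM = cfg$frac_up_sm, fracDownSM = cfg$frac_down_sm,
      fracUpMM = cfg$frac_up_mm, fracDownMM = cfg$frac_down_mm,
      effectFold = cfg$effect_fold, bluntingFactor = cfg$blunting_factor,
      noiseSdLog2 = cfg$noise_sd_log2), seed = cfg$seed + 202L)
  })
  se <- stage("normalization", globalNormalize(se))
  writeExpression(se, file.path(cfg$out_dir, "expression.tsv"),
                  file.path(cfg$out_dir, "groups.tsv"))

  libs <- stage("tag libraries", {
    if (!is.null(cfg$tag_dir)) {
      out <- list()
      for (cond in CONDITIONS) for (role in ROLES)
        out[[paste(cond, role, sep = "_")]] <- readTags(
          file.path(cfg$tag_dir, sprintf("%s_%s.bed", cond, role)),
          condition = cond, role = role)
      out
    } else {
      out <- list()
      for (i in seq_along(CONDITIONS)) {
        cond <- CONDITIONS[i]
        meanExpr <- conditionMeans(se, cond)
        for (role in ROLES) {
          p <- TagSimParams(librarySize = cfg$library_size,
                            backgroundFraction = cfg$background_fraction,
                            enrichmentSd = cfg$enrichment_sd,
                            couplingSlope = cfg$coupling_slope,
                            fragmentLength = cfg$fragment_length,
                            seed = cfg$seed + 300L + 10L * i +
                              (role == "IP"))
          out[[paste(cond, role, sep = "_")]] <-
            simulateTagLibrary(ann, meanExpr, p, role = role,
                               condition = cond)
        }
      }
      out
    }
  })
  if (isTRUE(cfg$write_tag_libraries))
    for (nm in names(libs))
      writeTags(libs[[nm]], file.path(cfg$out_dir, paste0(nm, ".bed")))

  ## differential expression
  de <- stage("differential expression", list(
    SM_vs_SS = differentialExpression(se, "SS", "SM", cfg$fc_cut, cfg$p_cut),
    MM_vs_SS = differentialExpression(se, "SS", "MM", cfg$fc_cut, cfg$p_cut)))
  for (nm in names(de))
    writeTsv(de[[nm]], file.path(cfg$out_dir, sprintf("de_%s.tsv", nm)))
  deCounts <- lapply(de, function(d) table(factor(d$call, c("up", "down", "null"))))

  ## per-condition quantification and regression
  perCond <- stage("quantification", lapply(stats::setNames(CONDITIONS, CONDITIONS),
    function(cond) {
    ipLib <- libs[[paste0(cond, "_IP")]]
    inLib <- libs[[paste0(cond, "_input")]]
    ipRaw <- assignTagsToNearestPromoter(ipLib, ann)$counts
    inRaw <- assignTagsToNearestPromoter(inLib, ann)$counts
    ipNorm <- ipRaw * normalizeFactor(ipLib)
    inNorm <- inRaw * normalizeFactor(inLib)
    z <- zscoreExpression(conditionMeans(se, cond))
    bins <- binGenes(z, ipNorm, binSize = cfg$bin_size)
    reg <- binRegression(bins, response = "log2")
    writeTsv(data.frame(gene_id = names(ipRaw), raw_count = ipRaw,
                        normalized_count = ipNorm),
             file.path(cfg$out_dir, sprintf("gene_counts_%s.tsv", cond)))
    writeTsv(bins, file.path(cfg$out_dir, sprintf("bins_%s.tsv", cond)))
    list(ipNorm = ipNorm, inNorm = inNorm, z = z, bins = bins, reg = reg)
  }))
  for (cond in CONDITIONS)
    logInfo(v, "regression %s: slope %.3f, R^2 %.3f", cond,
            perCond[[cond]]$reg$slope, perCond[[cond]]$reg$r_squared)

  ## enrichment sites, per-condition gene sets, overlap partition
  sitesByCond <- stage("site calling", lapply(
    stats::setNames(CONDITIONS, CONDITIONS), function(cond) {
      s <- callBindingSites(libs[[paste0(cond, "_IP")]],
                            libs[[paste0(cond, "_input")]],
                            window = cfg$window, step = cfg$step,
                            alpha = cfg$alpha, minFold = cfg$min_fold)
      writeSites(s, file.path(cfg$out_dir, sprintf("sites_%s.bed", cond)))
      s
    }))
  geneSets <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond)
    sitesToGenes(sitesByCond[[cond]], ann, cfg$site_max_distance)$genes)
  bindingVenn <- stage("binding overlap", overlapPartition(geneSets, "SS"))
  writeTsv(data.frame(signature = names(bindingVenn$signatures),
                      count = bindingVenn$signatures),
           file.path(cfg$out_dir, "venn_binding_genes.tsv"))

  ## metagene profile for the control condition
  prof <- stage("TSS profile",
                tssProfile(libs[["SS_IP"]], ann, cfg$flank, cfg$binwidth))
  writeTsv(profileTable(prof), file.path(cfg$out_dir, "profile_SS.tsv"))

  ## concordance of expression and binding changes
  concord <- stage("concordance", {
    out <- list()
    for (contrast in list(c("SS", "SM", "SM_vs_SS"), c("SS", "MM", "MM_vs_SS"))) {
      a <- contrast[1]; b <- contrast[2]; nm <- contrast[3]
      bf <- bindingFoldChange(perCond[[a]]$ipNorm, perCond[[a]]$inNorm,
                              perCond[[b]]$ipNorm, perCond[[b]]$inNorm)
      detected <- union(geneSets[[a]], geneSets[[b]])
      recs <- classifyConcordance(de[[nm]], bf, detected,
                                  ncThreshold = cfg$nc_threshold)
      writeTsv(recs, file.path(cfg$out_dir, sprintf("concordance_%s.tsv", nm)))
      out[[nm]] <- concordanceCounts(recs)
    }
    out
  })

  deVenn <- stage("DE overlap", deSetOverlap(de))
  writeTsv(data.frame(signature = names(deVenn$signatures),
                      count = deVenn$signatures),
           file.path(cfg$out_dir, "venn_de_genes.tsv"))

  report <- list(
    provenance = list(seed = cfg$seed,
                      config_hash = configHash(paste(deparse(cfg), collapse = "")),
                      package_version = as.character(utils::packageVersion("acetylscan"))),
    n_genes = length(ann),
    sites = lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond)
      list(n_sites = length(sitesByCond[[cond]]),
           n_annotated_genes = length(geneSets[[cond]]))),
    binding_venn = list(signatures = as.list(bindingVenn$signatures),
                        pairwise_pct = as.list(bindingVenn$pairwisePct),
                        union_size = bindingVenn$unionSize),
    de = lapply(deCounts, function(x) as.list(x)[c("up", "down")]),
    de_venn = list(signatures = as.list(deVenn$signatures),
                   union_size = deVenn$unionSize),
    regression = lapply(perCond, function(p) p$reg),
    concordance = lapply(concord, function(cc)
      list(table = as.list(as.data.frame(cc$table)),
           both_platform = as.list(cc$bothPlatform), n = cc$n)))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logInfo(v, "report written to %s", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
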