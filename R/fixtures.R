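#' Packaged expression/binding concordance tables
#'
#' The package ships two transcribed published summary tables of acute
#' drug-induced differential expression with the per-gene promoter
#' histone-acetylation binding response: `"table1"` for drug-naive animals
#' (acute challenge vs control) and `"table2"` for chronically pretreated
#' animals. Columns: `symbol`, `fc` (signed expression fold change) and
#' `binding_code` — a signed binding fold, `"NC"` for detected-but-unchanged
#' binding, or `"*"` for genes not detected on the ChIP platform. Probe-level
#' duplicate symbols are distinct rows. `concordanceFixture()` parses a table
#' into the inputs of [classifyConcordance] and returns the classified
#' records.
#'
#' @param name `"table1"` or `"table2"`.
#' @return `concordanceFixturePath()` the installed TSV path;
#'   `readConcordanceFixture()` the raw `data.frame` (`symbol`, `fc`,
#'   `binding_code`); `concordanceFixture()` the record `data.frame` from
#'   [classifyConcordance].
#' @examples
#' recs <- concordanceFixture("table1")
#' concordanceCounts(recs)$bothPlatform
#' @export
concordanceFixturePath <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, "_fixture.tsv"), package = "acetylscan",
              mustWork = TRUE)
}

#' @rdname concordanceFixturePath
#' @export
readConcordanceFixture <- function(name = c("table1", "table2")) {
  df <- utils::read.delim(concordanceFixturePath(name),
                          colClasses = c("character", "numeric", "character"))
  stopifnot(identical(names(df), c("symbol", "fc", "binding_code")))
  df
}

#' @rdname concordanceFixturePath
#' @param ncThreshold passed to [classifyConcordance].
#' @export
concordanceFixture <- function(name = c("table1", "table2"), ncThreshold = 1.4) {
  df <- readConcordanceFixture(name)
  fold <- suppressWarnings(as.numeric(df$binding_code))  # NA for "NC" and "*"
  detected <- df$binding_code != "*"
  de <- data.frame(gene_id = df$symbol, signed_fc = df$fc)
  classifyConcordance(de, bindingFold = fold, bindingDetected = detected,
                      ncThreshold = ncThreshold)
}
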