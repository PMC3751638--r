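test_that("gene binning follows the sort-and-chunk rule with a partial tail", {
  # one full bin: its mean is the overall mean
  z <- stats::setNames(rnorm(100), sprintf("g%03d", 1:100))
  tg <- stats::setNames(runif(100, 0, 50), names(z))
  b1 <- binGenes(z, tg, binSize = 100)
  expect_identical(nrow(b1), 1L)
  expect_equal(b1$mean_z, mean(z))
  expect_false(b1$partial)

  # 250 genes -> 100/100/50 with the last flagged partial
  z2 <- stats::setNames(rnorm(250), sprintf("g%03d", 1:250))
  tg2 <- stats::setNames(runif(250), names(z2))
  b2 <- binGenes(z2, tg2, binSize = 100)
  expect_identical(b2$n_genes, c(100L, 100L, 50L))
  expect_identical(b2$partial, c(FALSE, FALSE, TRUE))
  expect_true(all(diff(b2$mean_z) > 0))

  # brute-force group-and-average oracle on 7 genes, bin size 3
  z3 <- c(a = 0.5, b = -1, c = 2, d = 0, e = -2, f = 1, g = 0.1)
  t3 <- c(a = 10, b = 2, c = 40, d = 8, e = 1, f = 20, g = 9)
  b3 <- binGenes(z3, t3, binSize = 3)
  ordered <- names(sort(z3))
  groups <- split(ordered, ceiling(seq_along(ordered) / 3))
  expect_equal(b3$mean_z, vapply(groups, function(g) mean(z3[g]), numeric(1)),
               ignore_attr = TRUE)
  expect_equal(b3$mean_norm_tags,
               vapply(groups, function(g) mean(t3[g]), numeric(1)),
               ignore_attr = TRUE)

  # conservation: sum over bins of n_genes * mean equals the plain sums
  expect_lt(abs(sum(b2$n_genes * b2$mean_z) - sum(z2)), 1e-9)
  expect_lt(abs(sum(b2$n_genes * b2$mean_norm_tags) - sum(tg2)), 1e-9)

  # mismatched gene universes are rejected, listing the difference
  expect_error(binGenes(z3, t3[-1]), "only in Z")
  expect_error(binGenes(stats::setNames(numeric(0), character(0)),
                        stats::setNames(numeric(0), character(0))), "empty")
})

test_that("bin regression matches the closed-form least-squares solution", {
  mkBins <- function(x, y) data.frame(bin_index = seq_along(x),
                                      n_genes = 100L, mean_z = x,
                                      mean_norm_tags = y, partial = FALSE)
  # exact line
  r <- binRegression(mkBins(c(-1, 0, 1, 2), 2 * c(-1, 0, 1, 2) + 1))
  expect_equal(r$slope, 2); expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  # constant response: slope 0 and R^2 = 0 by convention
  rc <- binRegression(mkBins(c(-1, 0, 1), c(5, 5, 5)))
  expect_equal(rc$slope, 0); expect_equal(rc$r_squared, 0)

  # normal-equations oracle on (-1,1), (0,2), (1,4)
  x <- c(-1, 0, 1); y <- c(1, 2, 4)
  r2 <- binRegression(mkBins(x, y))
  n <- 3
  slopeO <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  interO <- mean(y) - slopeO * mean(x)
  ssRes <- sum((y - interO - slopeO * x)^2)
  r2O <- 1 - ssRes / sum((y - mean(y))^2)
  expect_equal(r2$slope, 1.5, tolerance = 1e-12)
  expect_equal(r2$intercept, 7 / 3, tolerance = 1e-12)
  expect_equal(r2$slope, slopeO, tolerance = 1e-12)
  expect_equal(r2$r_squared, r2O, tolerance = 1e-12)

  # R^2 is invariant under affine rescaling of the Z axis
  r3 <- binRegression(mkBins(10 * x + 3, y))
  expect_equal(r3$r_squared, r2$r_squared, tolerance = 1e-12)

  # partial bins are excluded by default; too few bins is an error
  b <- mkBins(c(-1, 0, 1, 2), c(1, 2, 4, 100)); b$partial[4] <- TRUE
  expect_equal(binRegression(b)$n_bins, 3L)
  expect_equal(binRegression(b, includePartial = TRUE)$n_bins, 4L)
  expect_error(binRegression(mkBins(1:2, 1:2)), ">= 3")
})

test_that("binding fold change corrects for input and uses the signed scale", {
  # identical conditions: +1 everywhere
  x <- c(g1 = 3, g2 = 0, g3 = 12)
  expect_equal(bindingFoldChange(x, x, x, x),
               stats::setNames(rep(1, 3), names(x)))

  # worked arithmetic: ((40.5/10.5)/(10.5/5.5)) with pseudocount 0.5
  bf <- bindingFoldChange(c(g = 10), c(g = 5), c(g = 40), c(g = 10),
                          pseudocount = 0.5)
  expect_equal(unname(bf), (40.5 / 10.5) / (10.5 / 5.5), tolerance = 1e-12)
  expect_equal(unname(bf), 2.020408, tolerance = 1e-6)

  # doubling IP at unchanged input approaches +2 as the pseudocount vanishes
  bf2 <- bindingFoldChange(c(g = 1e4), c(g = 1e4), c(g = 2e4), c(g = 1e4),
                           pseudocount = 1e-6)
  expect_equal(unname(bf2), 2, tolerance = 1e-3)

  # decreases are the negative reciprocal
  bf3 <- bindingFoldChange(c(g = 2e4), c(g = 1e4), c(g = 1e4), c(g = 1e4),
                           pseudocount = 1e-6)
  expect_equal(unname(bf3), -2, tolerance = 1e-3)
})

test_that("concordance classification follows the four-way rule", {
  expect_identical(nrow(classifyConcordance(
    data.frame(gene_id = character(0), signed_fc = numeric(0)),
    numeric(0), character(0))), 0L)

  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   signed_fc = c(2.0, 3.5, -1.8, 2.2))
  recs <- classifyConcordance(de,
                              bindingFold = c(a = 3.1, b = 1.2, c = -2.0),
                              bindingDetected = c("a", "b", "c"),
                              ncThreshold = 1.5)
  expect_identical(recs$binding_status, c("increased", "NC", "decreased", "absent"))
  expect_identical(recs$expr_direction, c("up", "up", "down", "up"))
  # rows with call == "null" are dropped when a call column is present
  de$call <- c("up", "null", "down", "up")
  expect_identical(nrow(classifyConcordance(de, c(a = 3.1, c = -2, d = 2),
                                            c("a", "c", "d"))), 3L)
})

test_that("packaged summary tables classify exactly as printed, row by row", {
  for (name in c("table1", "table2")) {
    raw <- readConcordanceFixture(name)
    recs <- concordanceFixture(name)
    expect_identical(nrow(recs), nrow(raw))
    code <- suppressWarnings(as.numeric(raw$binding_code))
    want <- ifelse(raw$binding_code == "*", "absent",
                   ifelse(raw$binding_code == "NC", "NC",
                          ifelse(code > 0, "increased", "decreased")))
    expect_identical(recs$binding_status, unname(want))
    expect_identical(recs$expr_direction, ifelse(raw$fc >= 0, "up", "down"))
  }
  # probe-level duplicate symbols survive as distinct records
  t1 <- readConcordanceFixture("table1")
  expect_identical(sum(t1$symbol == "Nr4a3"), 2L)
})

test_that("concordance counts cross-tabulate direction by binding status", {
  expect_equal(concordanceCounts(
    data.frame(expr_direction = character(0),
               binding_status = character(0)))$table,
    matrix(0L, 2, 4, dimnames = list(c("up", "down"),
                                     c("increased", "decreased", "NC", "absent"))))

  recs <- data.frame(expr_direction = c("up", "up", "down", "down", "up"),
                     binding_status = c("increased", "NC", "decreased",
                                        "absent", "increased"))
  cc <- concordanceCounts(recs)
  expect_identical(cc$table["up", "increased"], 2L)
  expect_identical(cc$bothPlatform, c(up = 3L, down = 1L))
  expect_identical(sum(cc$table), cc$n)
})

test_that("DE set overlaps delegate to the partition with called genes only", {
  deA <- data.frame(gene_id = c("a", "b", "c", "d"),
                    call = c("up", "down", "null", "up"))
  deB <- data.frame(gene_id = c("a", "b", "c", "d"),
                    call = c("up", "null", "null", "down"))
  res <- deSetOverlap(list(SM = deA, MM = deB))
  expect_identical(res$signatures[["SM&MM"]], 2L)  # a and d
  expect_identical(res$signatures[["SM"]], 1L)     # b
  expect_identical(res$unionSize, 3L)

  # identical tables: full overlap only; disjoint tables: no shared signature
  expect_identical(deSetOverlap(list(x = deA, y = deA))$signatures,
                   c(`x&y` = 3L))
  deC <- data.frame(gene_id = c("z1", "z2"), call = c("up", "up"))
  expect_false("x&y" %in% names(deSetOverlap(list(x = deA, y = deC))$signatures))
})

test_that("bin means of coupled data rise monotonically with expression", {
  ann <- simulateAnnotation(GenomeSpec(nChroms = 5, chromLength = 1000000L,
                                       nGenes = 1000, minGeneSpacing = 4000L,
                                       seed = 1))
  se <- simulateExpression(ann, EffectConfig(), seed = 2)
  me <- conditionMeans(se, "SS")
  lib <- simulateTagLibrary(ann, me, TagSimParams(librarySize = 100000L,
                                                  couplingSlope = 1, seed = 3))
  cnt <- assignTagsToNearestPromoter(lib, ann)$counts * normalizeFactor(lib)
  bins <- binGenes(zscoreExpression(me), cnt, binSize = 100)
  inc <- diff(bins$mean_norm_tags) > 0
  expect_gte(mean(inc), 0.9)
  reg <- binRegression(bins, response = "log2")
  expect_gt(reg$slope, 0)
  expect_gt(reg$r_squared, 0.8)
})
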