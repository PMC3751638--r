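test_that("normalization factor is tags-per-million and conserves totals", {
  expect_equal(normalizeFactor(tagLib(seq_len(10))), 1e5)
  expect_error(normalizeFactor(TagLibrary()), "empty")

  # 40 raw tags in a 2e5-tag library -> 200 tags per million
  expect_equal(40 * (1e6 / 2e5), 200)

  # normalized assigned + unassigned counts sum to exactly one million
  ann <- threeGeneAnn()
  pos <- c(sample(1:10000, 400, replace = TRUE), rep(1, 100))
  chrom <- c(rep("chr1", 400), rep("chrUn", 100))
  lib <- tagLib(pos, chrom = chrom)
  res <- assignTagsToNearestPromoter(lib, ann)
  f <- normalizeFactor(lib)
  expect_equal((sum(res$counts) + res$unassigned) * f, 1e6)
})

test_that("nearest-promoter assignment matches documented examples and ties", {
  ann <- threeGeneAnn()
  res <- assignTagsToNearestPromoter(tagLib(c(1100, 4900, 8000)), ann)
  expect_identical(res$counts, c(g1 = 1L, g2 = 1L, g3 = 1L))

  # tag equidistant from two TSSs goes to the smaller coordinate
  two <- makeGeneAnnotation(rep("chr1", 2), c(1000, 5000), c(1999, 5999),
                            c("+", "+"), c("g1", "g2"))
  res2 <- assignTagsToNearestPromoter(tagLib(3000), two)
  expect_identical(res2$counts, c(g1 = 1L, g2 = 0L))

  # equal TSS coordinates: lexicographically smaller gene_id wins
  dup <- makeGeneAnnotation(rep("chr1", 2), c(1000, 1000), c(1999, 2999),
                            c("+", "+"), c("gB", "gA"))
  res3 <- assignTagsToNearestPromoter(tagLib(1500), dup)
  expect_identical(res3$counts[res3$counts > 0], c(gA = 1L))

  # no tags -> all zeros; empty annotation -> error
  expect_true(all(assignTagsToNearestPromoter(TagLibrary(), ann)$counts == 0))
  expect_error(assignTagsToNearestPromoter(tagLib(1),
                                           GenomicRanges::GRanges()), "empty")
})

test_that("assignment agrees with the brute-force argmin oracle", {
  set.seed(42)
  for (rep in 1:20) {
    nGenes <- sample(2:50, 1)
    nTags <- sample(1:500, 1)
    chroms <- c("chr1", "chr2")
    annDf <- data.frame(chrom = sample(chroms, nGenes, TRUE),
                        tss = sample(1:100000, nGenes))
    ann <- makeGeneAnnotation(annDf$chrom, annDf$tss, annDf$tss + 500,
                              rep("+", nGenes), sprintf("g%02d", seq_len(nGenes)))
    tChrom <- sample(c(chroms, "chrUn"), nTags, TRUE)
    tPos <- sample(1:100000, nTags, TRUE)
    lib <- tagLib(tPos, chrom = tChrom)
    got <- assignTagsToNearestPromoter(lib, ann)$counts
    oracle <- bruteNearest(tChrom, tPos, ann)
    want <- table(factor(oracle, levels = ann$gene_id))
    expect_identical(unname(got), as.integer(want))
    expect_identical(sum(got) + sum(is.na(oracle)), length(tPos))
  }
})

test_that("TSS profiles bin strand-signed distances and conserve mass", {
  ann <- threeGeneAnn()
  # all tags exactly at TSSs -> all mass in the bin containing distance 0
  lib0 <- tagLib(c(1000, 5000, 9000))
  prof0 <- tssProfile(lib0, ann, flank = 200, binwidth = 100)
  tab <- profileTable(prof0)
  expect_equal(tab$count[tab$bin_start == 0], 3)
  expect_equal(sum(tab$count), 3)

  # hand histogram at signed offsets -150, -50, +50
  lib1 <- tagLib(1000 + c(-150, -50, 50))
  tab1 <- profileTable(tssProfile(lib1, ann, flank = 200, binwidth = 100))
  expect_equal(tab1$count, c(1, 1, 1, 0))

  # minus-strand gene: downstream of TSS is the smaller coordinate
  mAnn <- makeGeneAnnotation("chr1", 4000, 5000, "-", "m1")
  tabM <- profileTable(tssProfile(tagLib(5000 - 150), mAnn,
                                  flank = 200, binwidth = 100))
  expect_equal(tabM$count, c(0, 0, 0, 1))  # +150 signed (downstream)

  # mass conservation: raw profile counts = tags within flank
  set.seed(7)
  posR <- sample(1:10000, 500, TRUE)
  libR <- tagLib(posR)
  profR <- tssProfile(libR, ann, flank = 500, binwidth = 50)
  g <- bruteNearest(rep("chr1", 500), posR, ann)
  d <- posR - geneTss(ann)[g]            # all genes are plus-strand
  expect_equal(sum(profileTable(profR)$count), sum(d >= -500 & d < 500))

  expect_error(tssProfile(lib0, ann, flank = 250, binwidth = 100), "multiple")
})

test_that("symmetric enrichment yields a centred, balanced profile", {
  ann <- simulateAnnotation(GenomeSpec(nChroms = 1, chromLength = 1000000L,
                                       nGenes = 50, minGeneSpacing = 15000L,
                                       seed = 5))
  expr <- stats::setNames(rep(100, 50), ann$gene_id)
  lib <- simulateTagLibrary(ann, expr,
                            TagSimParams(librarySize = 20000L,
                                         backgroundFraction = 0,
                                         enrichmentSd = 150, seed = 6))
  tab <- profileTable(tssProfile(lib, ann, flank = 1000, binwidth = 100))
  peak <- which.max(tab$count)
  expect_true(tab$bin_start[peak] %in% c(-100, 0))
  up <- sum(tab$count[tab$bin_start < 0]); down <- sum(tab$count[tab$bin_start >= 0])
  n <- up + down
  # binomial 99% bound on the up/down split around p = 1/2
  expect_lt(abs(up - n / 2), 2.58 * sqrt(n / 4) + 0.5 * sqrt(n))
})

test_that("the Poisson window caller reports exact tail probabilities", {
  # 50 IP tags against an input-derived expectation of 5 in one window
  ipPos <- rep(500, 50)
  inPos <- seq(100, 900, length.out = 5)
  ip <- tagLib(c(ipPos, 2e6), sampleId = "ip")          # far tag fixes totals
  input <- tagLib(c(rep(round(inPos), 10), rep(2e6, 460)), sampleId = "in",
                  role = "input")
  # totals: ip 51, input 510 -> ratio 0.1; window 1-1000 input count 50
  sites <- callBindingSites(ip, input, window = 1000, step = 1000,
                            alpha = 1e-5, minFold = 2)
  hit <- sites[BiocGenerics::start(sites) == 1]
  expect_length(hit, 1)
  lambda <- 50 * (51 / 510)
  expect_equal(hit$enrichment_p, stats::ppois(49, lambda, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hit$expected_input_tags, lambda, tolerance = 1e-12)

  # no IP tags in a region -> no sites there
  expect_false(any(BiocGenerics::start(sites) > 1000 &
                   BiocGenerics::end(sites) < 2e6 - 1000))

  # empty input is an error
  expect_error(callBindingSites(ip, TagLibrary(role = "input")), "input")
})

test_that("stricter alpha never increases called sites on fixed input", {
  ann <- simulateAnnotation(GenomeSpec(nChroms = 1, chromLength = 500000L,
                                       nGenes = 20, minGeneSpacing = 20000L,
                                       seed = 9))
  expr <- stats::setNames(2^rnorm(20, 7, 1), ann$gene_id)
  ip <- simulateTagLibrary(ann, expr, TagSimParams(librarySize = 20000L,
                                                   backgroundFraction = 0.3,
                                                   seed = 10))
  input <- simulateTagLibrary(ann, NULL, TagSimParams(librarySize = 20000L,
                                                      backgroundFraction = 1,
                                                      seed = 11),
                              role = "input")
  alphas <- c(1e-2, 1e-4, 1e-6, 1e-10)
  nSites <- vapply(alphas, function(a)
    length(callBindingSites(ip, input, alpha = a)), integer(1))
  expect_true(all(diff(nSites) <= 0))
})

test_that("sites map to nearest genes within the distance cap", {
  ann <- threeGeneAnn()
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(900, 1200, 5100, 40000, 8500),
                     width = 200))
  res <- sitesToGenes(sites, ann, maxDistance = 10000)
  # brute-force midpoint scan
  mids <- (BiocGenerics::start(sites) + BiocGenerics::end(sites)) %/% 2
  oracle <- bruteNearest(rep("chr1", 5), mids, ann)
  oracle[abs(mids - geneTss(ann)[oracle]) > 10000] <- NA
  expect_setequal(res$genes, unique(oracle[!is.na(oracle)]))
  expect_equal(res$unannotated, sum(is.na(oracle)))
  expect_equal(res$siteCounts[["g1"]], sum(oracle == "g1", na.rm = TRUE))

  # two sites nearest the same TSS -> one gene, two sites
  two <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(950, 1100), width = 10))
  res2 <- sitesToGenes(two, ann, maxDistance = 10000)
  expect_identical(res2$genes, "g1")
  expect_identical(res2$siteCounts[["g1"]], 2L)

  # no sites -> empty set
  expect_length(sitesToGenes(GenomicRanges::GRanges(), ann)$genes, 0)
})

test_that("overlap partitions enumerate signatures and conserve the union", {
  # worked example
  res <- overlapPartition(list(A = c("x", "y"), B = c("y", "z"), C = "y"))
  expect_identical(res$signatures[["A"]], 1L)
  expect_identical(res$signatures[["B"]], 1L)
  expect_identical(res$signatures[["A&B&C"]], 1L)
  expect_identical(sum(res$signatures), res$unionSize)

  # identical sets collapse to one full signature
  res2 <- overlapPartition(list(A = c("a", "b"), B = c("a", "b")))
  expect_identical(res2$signatures, c(`A&B` = 2L))

  # disjoint sets: each exclusive signature equals its set size
  res3 <- overlapPartition(list(A = c("a", "b"), B = c("c"), C = c("d", "e")))
  expect_identical(res3$signatures[["A"]], 2L)
  expect_identical(res3$signatures[["C"]], 2L)
  expect_identical(sum(res3$signatures), 5L)

  # pairwise percentages are relative to the reference set
  expect_equal(res$pairwisePct[["B"]], 50)   # |A intersect B| / |A|
  expect_error(overlapPartition(list(A = "x")), ">= 2")
})
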