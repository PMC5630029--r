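test_that("BED12 annotation loads with strand-oriented TSS/TES", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(bed12Line("chr1", 100L, 1100L, "geneA", "+"),
               bed12Line("chr1", 100L, 1100L, "geneB", "-")), f)
  ann <- loadAnnotation(f)
  expect_identical(names(ann), c("geneA", "geneB"))
  expect_equal(unname(tssCoord(ann)), c(100, 1100))
  expect_equal(unname(tesCoord(ann)), c(1100, 100))
})

test_that("GTF loading keeps the longest transcript per gene", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", "101", "1100", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.short";', sep = "\t"),
    paste("chr1", "src", "transcript", "101", "5000", ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.long";', sep = "\t")), f)
  ann <- loadAnnotation(f)
  expect_length(ann, 1L)
  expect_equal(GenomicRanges::width(ann), 4900L)
})

test_that("malformed or empty annotations raise errors", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\tnot_a_number\toops", f)
  expect_error(loadAnnotation(f), "malformed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  file.create(f2)
  expect_error(suppressWarnings(loadAnnotation(f2)), "zero genes")
})

test_that("region windows follow the stated arithmetic", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000), "+")
  names(gr) <- "g1"
  rs <- defineRegions(gr, promoterUp = 500, promoterDown = 500,
                      tesDown = 1000)
  ## half-open [500,1500) [1500,5000) [5000,6000) -> 1-based closed
  expect_equal(GenomicRanges::start(promoterRegions(rs)), 501L)
  expect_equal(GenomicRanges::end(promoterRegions(rs)), 1500L)
  expect_equal(GenomicRanges::start(geneBodyRegions(rs)), 1501L)
  expect_equal(GenomicRanges::end(geneBodyRegions(rs)), 5000L)
  expect_equal(GenomicRanges::start(tesRegions(rs)), 5001L)
  expect_equal(GenomicRanges::end(tesRegions(rs)), 6000L)
  expect_length(excludedGenes(rs), 0L)
})

test_that("genes too short for all three windows are flagged, not dropped", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1001, 1001), c(1600, 1400)),
                               "+")
  names(gr) <- c("keep", "short")   # lengths 600 and 400, promoterDown 500
  rs <- defineRegions(gr)
  expect_identical(excludedGenes(rs), "short")
  expect_length(promoterRegions(rs), 2L)
})

test_that("region arithmetic is strand-symmetric", {
  span <- 1e6L
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 50000), "+")
  names(plus) <- "g"
  minus <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(span - 50000 + 1,
                                                   span - 10001 + 1), "-")
  names(minus) <- "g"
  rsP <- defineRegions(plus); rsM <- defineRegions(minus)
  mirror <- function(gr) sort(c(span - GenomicRanges::end(gr) + 1,
                                span - GenomicRanges::start(gr) + 1))
  for (acc in list(promoterRegions, geneBodyRegions, tesRegions))
    expect_equal(mirror(acc(rsP)),
                 sort(c(GenomicRanges::start(acc(rsM)),
                        GenomicRanges::end(acc(rsM)))))
})

test_that("normalization yields CPM and response matrices follow the log2 rule", {
  grid <- TimeGrid(c(0, 1), labelingDuration = 1)
  v <- array(c(10, 20, 40, 40), dim = c(2, 2, 1),
             dimnames = list(c("g1", "g2"), NULL, NULL))
  st <- SignalTable("MYC", v, librarySizes = 1e6, timeGrid = grid)
  stn <- normalizeSignal(st)
  expect_equal(signalValues(stn)[, , 1], v[, , 1])   # 1e6 library -> CPM = raw
  expect_error(normalizeSignal(stn), "already normalized")
  rm <- responseMatrix(stn, pseudocount = 0.001)
  expect_equal(unname(rm[, 1]), c(0, 0))             # t0 column identically 0
  expect_equal(unname(rm[, 2]), c(2, 1), tolerance = 1e-3)
  ## pseudocount rule: x0 = 0, pc = 1, xt = 7 -> log2(8)
  v2 <- array(c(0, 7), dim = c(1, 2, 1), dimnames = list("g", NULL, NULL))
  st2 <- SignalTable("MYC", v2, 1e6, grid, normalized = TRUE)
  expect_equal(unname(responseMatrix(st2, pseudocount = 1)[, 2]), 3)
})

test_that("replicate averaging and library-rescaling invariance hold", {
  grid <- TimeGrid(c(0, 1), labelingDuration = 1)
  v <- array(c(4, 4, 6, 6), dim = c(1, 2, 2), dimnames = list("g", NULL, NULL))
  st <- SignalTable("MYC", v, librarySizes = 1e6, timeGrid = grid,
                    normalized = TRUE)
  expect_equal(unname(averageReplicates(st)[1, ]), c(5, 5))
  ## multiplying one library and its raw counts by a constant changes nothing
  raw <- array(runif(6, 10, 100), dim = c(3, 2, 1),
               dimnames = list(paste0("g", 1:3), NULL, NULL))
  ls <- matrix(c(2e6, 3e6), 2, 1)
  a <- responseMatrix(SignalTable("MYC", raw, ls, grid))
  raw2 <- raw; raw2[, 2, 1] <- raw2[, 2, 1] * 7
  ls2 <- ls; ls2[2, 1] <- ls2[2, 1] * 7
  b <- responseMatrix(SignalTable("MYC", raw2, ls2, grid))
  expect_equal(a, b)
})

test_that("SignalTable TSV round-trip preserves values to 12 digits", {
  gt <- cohortFixture()$gt
  st <- cohortFixture()$noisy$tables$total_exon
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSignalTable(st, f)
  st2 <- readSignalTable(f)
  expect_equal(assayName(st2), assayName(st))
  expect_equal(signalValues(st2), signalValues(st), tolerance = 1e-12)
  expect_equal(librarySizes(st2), librarySizes(st), tolerance = 1e-12)
  expect_equal(gridTimes(timeGrid(st2)), gridTimes(timeGrid(st)))
})

test_that("rate functions evaluate their stated forms", {
  expect_equal(evalRate(constantRate(2), c(0, 1, 4)), rep(2, 3))
  sg <- sigmoidRate(1, 5, t1 = 1, beta = 50)
  expect_equal(evalRate(sg, c(-5, 5)), c(1, 5), tolerance = 1e-6)
  im <- impulseRate(1, 6, 2, t1 = 0.5, t2 = 2, beta = 50)
  expect_equal(evalRate(im, -10), 1, tolerance = 1e-6)   # baseline
  expect_equal(evalRate(im, 10), 2, tolerance = 1e-6)    # late plateau
  expect_equal(evalRate(im, 1.25), 6, tolerance = 1e-2)  # peak
  gr <- gridRate(c(0, 1, 2), c(2, 4, 4))
  expect_equal(evalRate(gr, c(0.5, 3)), c(3, 4))
})
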