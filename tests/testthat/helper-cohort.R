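# Shared synthetic fixtures, built once per test session.

cohortFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- generateGroundTruth(nGenes = 120, seed = 401)
      cache <<- list(
        gt = gt,
        clean = simulateCohort(gt, NoiseModel(cv = 0), replicates = 1),
        noisy = simulateCohort(gt, NoiseModel(cv = 0.2), replicates = 3))
    }
    cache
  }
})

# derived abundances + synthesis for a simulated cohort
kineticInputs <- function(co) {
  ab <- deriveAbundances(co$tables$total_exon, co$tables$total_intron)
  k1 <- estimateSynthesis(co$tables$nascent_exon, co$tables$nascent_intron)
  list(ab = ab, k1 = k1, grid = timeGrid(co$tables$total_exon))
}

# plain BED12 line helper
bed12Line <- function(chrom, start, end, name, strand,
                      blocks = list(c(0L, end - start))) {
  sizes <- paste0(paste(vapply(blocks, `[`, integer(1L), 2L),
                        collapse = ","), ",")
  starts <- paste0(paste(vapply(blocks, `[`, integer(1L), 1L),
                         collapse = ","), ",")
  paste(chrom, start, end, name, 0, strand, start, end, "0",
        length(blocks), sizes, starts, sep = "\t")
}
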