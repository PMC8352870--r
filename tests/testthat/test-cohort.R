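makeSites <- function() {
  data.frame(chrom = as.character(1:5), pos = c(1000L, 2000L, 3000L,
                                                4000L, 5000L),
             id = sprintf("rs%d", 101:105),
             ref = c("A", "C", "G", "T", "A"),
             alt = c("G", "T", "A", "C", "T"),
             af = c(0.4, 0.3, 0.5, 0.2, 0.35),
             stringsAsFactors = FALSE)
}

test_that("quality filtering excludes only strictly-below values", {
  spec <- qualityFilter()
  expect_false(passesQuality(4, 60, spec))
  expect_true(passesQuality(5, 30, spec))   # boundary inclusive
  expect_false(passesQuality(40, 29, spec))
  expect_false(passesQuality(NA, 50, spec))               # fail closed
  expect_true(passesQuality(NA, 50, spec, onMissing = "pass"))
})

test_that("allele frequency counts alternate alleles over called alleles", {
  expect_equal(alleleFrequency(c("0/0", "0/1", "1/1")), 0.5)
  expect_equal(alleleFrequency(c("0/0", "0/0")), 0)
  expect_equal(alleleFrequency(c("./.", "0/1")), 0.5)
  expect_true(is.na(alleleFrequency(c("./.", "./."))))
  expect_equal(alleleFrequency(c("0|1", "1|1"), alleleIndex = 1L), 0.75)
  expect_error(alleleFrequency(c(S1 = "0/x")), "S1")
})

test_that("dataset matching recovers exactly the quality-passing, alt-carrying sites", {
  sites <- makeSites()
  sim <- simulateVcf(sites, nSamples = 30, failFraction = 0, seed = 21,
                     path = withr::local_tempfile(fileext = ".vcf"))
  dataset <- data.frame(rsid = sites$id, chrom = sites$chrom,
                        pos = sites$pos, stringsAsFactors = FALSE)
  m <- matchDataset(c(pop = sim$path), dataset)
  expect_setequal(matchedRsids(m),
                  sim$truth$id[sim$truth$shouldMatch])
  # a dataset variant with no VCF record at all
  extra <- rbind(dataset, data.frame(rsid = "rs999", chrom = "9",
                                     pos = 99L))
  m2 <- matchDataset(c(pop = sim$path), extra)
  expect_equal(m2$reason[m2$rsid == "rs999"], "no_record")
})

test_that("sites with the alternate unobserved or low depth do not match", {
  sites <- makeSites()
  sites$af[1] <- 0  # homozygous reference everywhere
  sim <- simulateVcf(sites, nSamples = 25, failFraction = 0, seed = 9,
                     path = withr::local_tempfile(fileext = ".vcf"))
  dataset <- data.frame(rsid = sites$id, chrom = sites$chrom,
                        pos = sites$pos)
  m <- matchDataset(c(pop = sim$path), dataset)
  expect_equal(m$reason[m$rsid == "rs101"], "alt_unobserved")
  expect_false("rs101" %in% matchedRsids(m))

  # rewrite site 2 with depth 2: fails the depth filter
  lines <- readLines(sim$path)
  lines <- sub("^(2\t2000\trs102\t[^\t]*\t[^\t]*\t[^\t]*\tPASS\t)DP=[0-9]+",
               "\\1DP=2", lines)
  writeLines(lines, sim$path)
  m2 <- matchDataset(c(pop = sim$path), dataset)
  expect_equal(m2$reason[m2$rsid == "rs102"], "fails_quality")
})

test_that("matching is monotone in the filter and unions across populations", {
  sites <- makeSites()
  simA <- simulateVcf(sites, nSamples = 20, failFraction = 0.5, seed = 33,
                      path = withr::local_tempfile(fileext = ".vcf"))
  simB <- simulateVcf(sites, nSamples = 20, failFraction = 0.5, seed = 34,
                      path = withr::local_tempfile(fileext = ".vcf"))
  dataset <- data.frame(rsid = sites$id, chrom = sites$chrom,
                        pos = sites$pos)
  strictSet <- matchedRsids(matchDataset(c(a = simA$path), dataset))
  relaxedDepth <- matchedRsids(matchDataset(c(a = simA$path), dataset,
                                            qualityFilter(minDepth = 1)))
  relaxedQual <- matchedRsids(matchDataset(c(a = simA$path), dataset,
                                           qualityFilter(minQual = 0)))
  expect_true(all(strictSet %in% relaxedDepth))
  expect_true(all(strictSet %in% relaxedQual))

  both <- matchedRsids(matchDataset(c(a = simA$path, b = simB$path),
                                    dataset))
  expect_setequal(both,
                  union(strictSet,
                        matchedRsids(matchDataset(c(b = simB$path),
                                                  dataset))))
})

test_that("contig aliasing bridges chr-prefixed VCFs", {
  sites <- makeSites()[1:2, ]
  sites$chrom <- paste0("chr", sites$chrom)
  sim <- simulateVcf(sites, nSamples = 10, failFraction = 0, seed = 2,
                     path = withr::local_tempfile(fileext = ".vcf"))
  dataset <- data.frame(rsid = sites$id, chrom = c("1", "2"),
                        pos = sites$pos)
  m <- matchDataset(c(p = sim$path), dataset)
  expect_setequal(matchedRsids(m), sim$truth$id[sim$truth$shouldMatch])
})
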