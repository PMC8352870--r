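test_that("benchmark generation is deterministic given the seed", {
  spec <- syntheticSpec(nPathogenic = 10, nBenign = 10, missingness = 0.2,
                        seed = 77)
  a <- simulateBenchmark(spec)
  b <- simulateBenchmark(spec)
  expect_identical(as.data.frame(a$profiles), as.data.frame(b$profiles))
  expect_identical(a$truth, b$truth)
  c <- simulateBenchmark(syntheticSpec(nPathogenic = 10, nBenign = 10,
                                       missingness = 0.2, seed = 78))
  expect_false(identical(as.data.frame(a$profiles),
                         as.data.frame(c$profiles)))
})

test_that("per-tool substreams are independent of other components' settings", {
  base <- simulateBenchmark(syntheticSpec(nPathogenic = 10, nBenign = 10,
                                          seed = 5))
  shifted <- simulateBenchmark(syntheticSpec(nPathogenic = 10, nBenign = 10,
                                             missingness = c(sift = 0.9,
                                                             pp2 = 0, condel = 0,
                                                             provean = 0,
                                                             panther = 0),
                                             seed = 5))
  # changing SIFT's missingness leaves every other tool's scores untouched
  for (col in c("pp2_score", "condel_score", "provean_score",
                "panther_score"))
    expect_identical(base$profiles[[col]], shifted$profiles[[col]])
})

test_that("class separation drives the scores to the right side of each threshold", {
  sep <- simulateBenchmark(syntheticSpec(nPathogenic = 20, nBenign = 20,
                                         toolAccuracy = 1, seed = 13))
  calls <- toolCalls(sep$profiles)
  expect_true(all(calls[sep$truth == "pathogenic", ] == "significant"))
  expect_true(all(calls[sep$truth == "benign", ] == "not_significant"))
  expect_error(syntheticSpec(nPathogenic = 5, nBenign = 5,
                             toolAccuracy = 0.3, seed = 1), "0.5")
})

test_that("generated VCF genotypes track the target allele frequency", {
  sites <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      id = c("s1", "s2", "s3"), ref = "A", alt = "G",
                      af = c(0.1, 0.4, 0.8), stringsAsFactors = FALSE)
  sim <- simulateVcf(sites, nSamples = 500, failFraction = 0, seed = 55,
                     path = withr::local_tempfile(fileext = ".vcf"))
  # binomial sampling: empirical AF within 3 standard errors at n = 500
  se <- sqrt(sites$af * (1 - sites$af) / (2 * 500))
  expect_true(all(abs(sim$truth$empiricalAF - sites$af) <= 3 * se))

  zero <- simulateVcf(transform(sites, af = 0), nSamples = 50,
                      failFraction = 0, seed = 56,
                      path = withr::local_tempfile(fileext = ".vcf"))
  expect_false(any(zero$truth$shouldMatch))

  all_fail <- simulateVcf(sites, nSamples = 20, failFraction = 1, seed = 57,
                          path = withr::local_tempfile(fileext = ".vcf"))
  expect_false(any(all_fail$truth$passesFilter))
})

test_that("generated VCFs parse back with the written depth and quality", {
  sites <- data.frame(chrom = "2", pos = 10L * (1:4),
                      id = sprintf("s%d", 1:4), ref = "C", alt = "T",
                      af = 0.5, stringsAsFactors = FALSE)
  sim <- simulateVcf(sites, nSamples = 12, failFraction = 0.5, seed = 8,
                     path = withr::local_tempfile(fileext = ".vcf"))
  tab <- readCohortVcf(sim$path)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$depth, sim$truth$depth)
  expect_equal(tab$qual, round(sim$truth$qual, 1), tolerance = 0.051)
  expect_equal(tab$af, sim$truth$empiricalAF)
})
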