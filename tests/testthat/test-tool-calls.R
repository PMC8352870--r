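test_that("score thresholds follow the published damaging directions", {
  cfg <- defaultThresholds()
  sig <- function(tool, score) classifyCall(tool, score = score,
                                            cfg = cfg)$call
  expect_equal(sig("sift", c(0.01, 0.05, 0.06)),
               c("significant", "significant", "not_significant"))
  expect_equal(sig("pp2", c(0.95, 0.9, 0.3)),
               c("significant", "not_significant", "not_significant"))
  expect_equal(sig("condel", c(0.51, 0.5, 1.0)),
               c("significant", "not_significant", "significant"))
  expect_equal(sig("provean", c(-2.5, -2.4, -7)),
               c("significant", "not_significant", "significant"))
  expect_equal(sig("panther", c(500, 450, 120)),
               c("significant", "not_significant", "not_significant"))
  # monotonicity in the damaging direction
  s <- sort(runif(50))
  calls <- classifyCall("sift", score = s, cfg = cfg)$call
  expect_true(all(diff(calls == "significant") <= 0))
})

test_that("threshold variants are configurable", {
  strict_sift <- thresholdConfig(sift_inclusive = FALSE)
  expect_equal(classifyCall("sift", score = 0.05, cfg = strict_sift)$call,
               "not_significant")
  exact1 <- thresholdConfig(condel_exact_one = TRUE)
  expect_equal(classifyCall("condel", score = 0.8, cfg = exact1)$call,
               "not_significant")
  expect_equal(classifyCall("condel", score = 1.0, cfg = exact1)$call,
               "significant")
})

test_that("categorical labels resolve through the printed vocabulary", {
  expect_equal(classifyCall("provean", label = "Neu")$call,
               "not_significant")
  # 'possibly damaging' is below the PolyPhen-2 score cut, hence benign-side
  expect_equal(classifyCall("pp2", label = "pos_dam")$call,
               "not_significant")
  expect_equal(classifyCall("pp2", label = "Prob_dam")$call, "significant")
  lc <- classifyCall("sift", label = "Del_low_con")
  expect_equal(lc$call, "significant")
  expect_true(lc$lowConfidence)
  expect_equal(classifyCall("sift")$call, "missing")
  expect_error(classifyCall("panther", label = "whatever"),
               "known: prob_dam")
  # score takes precedence over a disagreeing label
  expect_equal(classifyCall("sift", score = 0.5, label = "Del")$call,
               "not_significant")
})

test_that("the packaged cohort table loads with calls resolved", {
  ps <- referenceProfiles()
  expect_equal(nrow(ps), 48L)
  calls <- toolCalls(ps)
  expect_true(all(calls %in% c("significant", "not_significant", "missing")))
  expect_equal(unname(calls["rs1801591", "panther"]), "missing")
  expect_equal(unname(calls["rs1126809", ]),
               c("significant", "significant", "significant",
                 "not_significant", "significant"))
})

test_that("profile loading reports malformed rows instead of dropping them silently", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("rsid\tgene\taa_change\tsift_score",
                     "rs1\tG1\tR402Q\t0.01",
                     "rs2\tG2\tnot-a-change\t0.5"), collapse = "\n"), path)
  ps <- readProfiles(path)
  expect_equal(nrow(ps), 1L)
  rej <- S4Vectors::metadata(ps)$rejected
  expect_equal(rej$rsid, "rs2")
  expect_match(rej$message, "aa_change")

  writeLines("rsid\tgene\taa_change", path)
  expect_equal(nrow(readProfiles(path)), 0L)
  writeLines("rsid\tgene", path)
  expect_error(readProfiles(path), "mandatory")
})
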