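test_that("vote counts reflect the per-tool call states and the policy", {
  ps <- referenceProfiles()
  v <- countVotes(ps)
  expect_equal(v$nSignificant[v$rsid == "rs1126809"], 4L)
  rs671 <- which(v$rsid == "rs671")
  expect_equal(v$nSignificant[rs671], 3L)
  expect_equal(v$nMissing[rs671], 1L)
  expect_true(all(v$nSignificant + v$nNotSignificant + v$nMissing == 5L))

  gone <- profileFromStates(rep("missing", 5))
  expect_equal(countVotes(gone, "strict")$nEffective, 0L)
  expect_equal(countVotes(gone, "permissive")$nEffective, 5L)
})

test_that("model decisions on the cohort table match the vote arithmetic", {
  ps <- referenceProfiles()
  decide <- function(model, rs) {
    d <- applyModel(ps, consensusModel(model))
    unique(d$decision[d$rsid == rs])
  }
  expect_equal(decide("D", "rs1126809"), "deleterious")  # 4 of 5
  expect_equal(decide("D", "rs671"), "benign")           # 3 of 5
  expect_equal(decide("C", "rs671"), "deleterious")
  expect_equal(decide("D", "rs9379084"), "deleterious")  # 5 of 5
})

test_that("X3 models require conserved and destabilizing evidence", {
  five_sig <- rep("significant", 5)
  ps <- profileFromStates(five_sig, consurf_score = 8L,
                          imutant_direction = "decrease",
                          imutant_ddg = -0.48, imutant_ri = 5L)
  expect_equal(applyModel(ps, consensusModel("D3"))$decision, "deleterious")
  # direction gate (default) keeps a neutral-band DDG decrease
  ddg_gate <- consensusModel("D3", stabilityGate = "ddg")
  expect_equal(applyModel(ps, ddg_gate)$decision, "benign")

  low <- profileFromStates(five_sig, consurf_score = 5L,
                           imutant_direction = "decrease")
  expect_equal(applyModel(low, consensusModel("D3"))$decision, "benign")
  none <- profileFromStates(five_sig)
  d <- applyModel(none, consensusModel("D3"))
  expect_equal(d$decision, "not_evaluated")
  expect_equal(d$conservationGate, "absent")
})

test_that("decisions agree with a brute-force counter over all 243 call states", {
  states <- allCallStates()
  ps <- profileFromStates(states, consurf_score = 8L,
                          imutant_direction = "decrease", imutant_ri = 7L)
  for (policy in c("strict", "permissive", "fraction")) {
    for (id in c("A", "B", "C", "D", "A3", "B3", "C3", "D3")) {
      model <- consensusModel(id, missingPolicy = policy)
      got <- applyModel(ps, model)$decision
      want <- vapply(seq_len(nrow(states)), function(i)
        bruteForceDecision(states[i, ], model@minVotes, policy), "")
      expect_identical(got, want,
                       label = sprintf("model %s, %s policy", id, policy))
    }
  }
})

test_that("deleterious sets are nested: A >= B >= C >= D and X3 within X", {
  set.seed(42)
  states <- matrix(sample(c("significant", "not_significant", "missing"),
                          200 * 5, TRUE), ncol = 5)
  ps <- profileFromStates(states, consurf_score = sample(1:9, 200, TRUE),
                          imutant_direction = sample(c("increase", "decrease"),
                                                     200, TRUE))
  for (policy in c("strict", "permissive", "fraction")) {
    dele <- function(id) {
      d <- applyModel(ps, consensusModel(id, missingPolicy = policy))
      d$rsid[d$decision == "deleterious"]
    }
    for (pair in list(c("B", "A"), c("C", "B"), c("D", "C"),
                      c("A3", "A"), c("B3", "B"), c("C3", "C"),
                      c("D3", "D")))
      expect_true(all(dele(pair[1]) %in% dele(pair[2])),
                  label = sprintf("%s within %s under %s", pair[1], pair[2],
                                  policy))
  }
})

test_that("permissive counting never yields fewer effective votes than strict", {
  set.seed(7)
  states <- matrix(sample(c("significant", "not_significant", "missing"),
                          100 * 5, TRUE), ncol = 5)
  ps <- profileFromStates(states)
  expect_true(all(countVotes(ps, "permissive")$nEffective >=
                    countVotes(ps, "strict")$nEffective))
})

test_that("confusion tallies fix the class sizes for every model", {
  sep <- simulateBenchmark(syntheticSpec(nPathogenic = 25, nBenign = 25,
                                         toolAccuracy = 1,
                                         evidenceAccuracy = 1, seed = 3))
  counts <- rankModels(sep$profiles, sep$truth)
  expect_true(all(counts$fp == 0 & counts$fn == 0))
  expect_true(all(counts$tp + counts$fn == 25))
  expect_true(all(counts$tn + counts$fp == 25))

  benign_only <- rankModels(sep$profiles, rep("benign", 50))
  expect_true(all(benign_only$tp == 0 & benign_only$fn == 0))
  expect_error(rankModels(sep$profiles, rep("maybe", 50)), "truth label")
  expect_error(rankModels(sep$profiles, c("benign")), "cover")
})
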