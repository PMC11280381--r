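test_that("candidate ranking is ordered, complete and reference-flagged", {
  m <- load_fixture("eq1_model")
  cand <- load_fixture("table4_candidates")
  scr <- screen_candidates(m, cand)
  expect_equal(nrow(scr), 11)
  expect_setequal(scr$id, cand$ids)
  expect_equal(scr$id[1], "M1")                    # highest predicted activity
  expect_equal(scr$predicted_pic50, sort(scr$predicted_pic50, decreasing = TRUE))
  expect_equal(scr$rank, 1:11)
  expect_equal(scr$predicted_pic50[1], max(scr$predicted_pic50))

  # a candidate with the reference's own prediction is not an improvement
  ref_like <- qsar_dataset(matrix(c(0, 0, (7.259 - 2.587) / 0.010), 1,
                                  dimnames = list("R", c("PSA", "DM", "MW"))),
                           role = "candidate")
  expect_false(screen_candidates(m, ref_like)$improved)

  empty <- qsar_dataset(matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("PSA", "DM", "MW"))),
                        role = "candidate")
  expect_equal(nrow(screen_candidates(m, empty)), 0)
})

test_that("ties in predicted activity break by id", {
  m <- load_fixture("eq1_model")
  same <- qsar_dataset(matrix(rep(c(30, 3, 470), 2), 2, byrow = TRUE,
                              dimnames = list(c("Z9", "A1"), c("PSA", "DM", "MW"))),
                       role = "candidate")
  expect_equal(screen_candidates(m, same)$id, c("A1", "Z9"))
})

test_that("Lipinski violations count with inclusive bounds", {
  cfg <- screening_config()
  # published M1 drug-likeness row: only logP exceeds its bound
  m1 <- admet_profile(logp = 6.86, mw = 476.50, hba = 7, hbd = 0)
  lp <- lipinski_profile(m1, cfg)
  expect_equal(lp$violations, 1L)
  expect_true(lp$pass)
  expect_true(lp$detail[["logp"]])

  # sitting exactly on every bound violates nothing
  edge <- admet_profile(logp = 5, mw = 500, hba = 10, hbd = 5)
  expect_equal(lipinski_profile(edge, cfg)$violations, 0L)

  worst <- admet_profile(logp = 6, mw = 501, hba = 11, hbd = 6)
  lw <- lipinski_profile(worst, cfg)
  expect_equal(lw$violations, 4L)
  expect_false(lw$pass)
})

test_that("violation counts equal a brute-force check on random profiles", {
  cfg <- screening_config()
  set.seed(2)
  for (i in 1:1000) {
    p <- admet_profile(logp = runif(1, 0, 8), mw = runif(1, 200, 700),
                       hba = sample(0:14, 1), hbd = sample(0:8, 1))
    brute <- (p$mw > 500) + (p$logp > 5) + (p$hbd > 5) + (p$hba > 10)
    expect_equal(lipinski_profile(p, cfg)$violations, as.integer(brute))
  }
})

test_that("brain-penetration classes use strict cutoffs", {
  cfg <- screening_config()
  m1 <- admet_profile(logp = 6.86, mw = 476.5, hba = 7, hbd = 0,
                      logbb = 0.39, logps = -1.292)
  expect_equal(bbb_cns_classify(m1, cfg), list(bbb = "permeant", cns = "penetrant"))
  m10 <- admet_profile(logp = 4.4, mw = 476.49, hba = 8, hbd = 3,
                       logbb = -1.299, logps = -2.193)
  expect_equal(bbb_cns_classify(m10, cfg)$bbb, "poor")
  mid <- admet_profile(logp = 1, mw = 300, hba = 2, hbd = 1,
                       logbb = 0.0, logps = -2.5)
  expect_equal(bbb_cns_classify(mid, cfg),
               list(bbb = "intermediate", cns = "intermediate"))
  # values exactly at a cutoff are intermediate (strict inequalities)
  at <- admet_profile(logp = 1, mw = 300, hba = 2, hbd = 1,
                      logbb = 0.3, logps = -2)
  expect_equal(bbb_cns_classify(at, cfg),
               list(bbb = "intermediate", cns = "intermediate"))
})

test_that("ADMET gates pass and fail per the published profiles", {
  profs <- fixture_admet_profiles()
  g1 <- admet_gate(profs$M1)
  expect_true(all(g1))
  g10 <- admet_gate(profs$M10)
  expect_false(g10[["hepatotoxicity"]])
  expect_false(g10[["overall"]])
  expect_true(all(g10[c("hia", "caco2", "cyp2d6", "ames", "skin_sensitization")]))
  # M9's permeability misses the Caco-2 cutoff
  g9 <- admet_gate(profs$M9)
  expect_false(g9[["caco2"]])
  expect_true(g9[["hia"]])
})

test_that("tightening a cutoff never converts a failure into a pass", {
  profs <- fixture_admet_profiles()
  set.seed(3)
  for (i in 1:50) {
    loose <- screening_config(hia_min = runif(1, 50, 95),
                              caco2_min = runif(1, 0, 1.5))
    tight <- screening_config(hia_min = loose$hia_min + runif(1, 0, 10),
                              caco2_min = loose$caco2_min + runif(1, 0, 0.5))
    for (p in profs) {
      gl <- admet_gate(p, loose)
      gt_ <- admet_gate(p, tight)
      expect_false(any(!gl[c("hia", "caco2")] & gt_[c("hia", "caco2")]))
    }
  }
})
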