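test_that("every configured risk cell matches the published classification", {
  # independent listing of the Miettinen-Lasota (AFIP) table:
  # site group, size band (1: <=2, 2: >2-5, 3: >5-10, 4: >10 cm),
  # mitotic band (<=5 / >5 per 5 mm2) -> class
  expected <- rbind(
    c("stomach", 1, "le5", "none"), c("stomach", 2, "le5", "very_low"),
    c("stomach", 3, "le5", "low"), c("stomach", 4, "le5", "moderate"),
    c("stomach", 1, "gt5", "none"), c("stomach", 2, "gt5", "moderate"),
    c("stomach", 3, "gt5", "high"), c("stomach", 4, "gt5", "high"),
    c("duodenum", 1, "le5", "none"), c("duodenum", 2, "le5", "low"),
    c("duodenum", 3, "le5", "insufficient_data"), c("duodenum", 4, "le5", "high"),
    c("duodenum", 1, "gt5", "insufficient_data"), c("duodenum", 2, "gt5", "high"),
    c("duodenum", 3, "gt5", "insufficient_data"), c("duodenum", 4, "gt5", "high"),
    c("small-intestine", 1, "le5", "none"), c("small-intestine", 2, "le5", "low"),
    c("small-intestine", 3, "le5", "moderate"), c("small-intestine", 4, "le5", "high"),
    c("small-intestine", 1, "gt5", "high"), c("small-intestine", 2, "gt5", "high"),
    c("small-intestine", 3, "gt5", "high"), c("small-intestine", 4, "gt5", "high"),
    c("colon-rectum", 1, "le5", "none"), c("colon-rectum", 2, "le5", "very_low"),
    c("colon-rectum", 3, "le5", "insufficient_data"), c("colon-rectum", 4, "le5", "high"),
    c("colon-rectum", 1, "gt5", "high"), c("colon-rectum", 2, "gt5", "high"),
    c("colon-rectum", 3, "gt5", "high"), c("colon-rectum", 4, "gt5", "high")
  )
  sizes_mm <- c(15, 40, 80, 150)      # representatives of the four bands
  mits <- c(le5 = 3, gt5 = 8)
  for (i in seq_len(nrow(expected))) {
    got <- miettinen_lasota(expected[i, 1],
                            sizes_mm[as.integer(expected[i, 2])],
                            mits[[expected[i, 3]]])
    expect_equal(as.character(got), expected[i, 4],
                 label = paste(expected[i, 1:3], collapse = "/"))
  }
})

test_that("band edges are inclusive on the upper bound", {
  # 50 mm sits in the >2-5 cm band, 20 mm in <=2, 100 mm in >5-10
  expect_equal(as.character(miettinen_lasota("stomach", 50, 0)), "very_low")
  expect_equal(as.character(miettinen_lasota("stomach", 20, 0)), "none")
  expect_equal(as.character(miettinen_lasota("stomach", 100, 0)), "low")
  expect_equal(as.character(miettinen_lasota("stomach", 100.0001, 0)), "moderate")
  # mitotic threshold: exactly 5 is the low band
  expect_equal(as.character(miettinen_lasota("stomach", 80, 5)), "low")
  expect_equal(as.character(miettinen_lasota("stomach", 80, 5.0001)), "high")
})

test_that("a 72 mm gastric tumor with low biopsy count classifies as low", {
  expect_equal(as.character(miettinen_lasota("stomach", 72, 3)), "low")
  expect_equal(as.character(miettinen_lasota("stomach", 15, 0)), "none")
})

test_that("risk is nondecreasing in size and mitotic bands where classifiable", {
  ord <- c(none = 1, very_low = 2, low = 3, moderate = 4, high = 5)
  sizes <- c(15, 40, 80, 150)
  for (site in gist_sites()) {
    for (mit in c(3, 8)) {
      cls <- as.character(miettinen_lasota(rep(site, 4), sizes, rep(mit, 4)))
      r <- ord[cls[cls != "insufficient_data"]]
      if (length(r) > 1) expect_true(all(diff(r) >= 0), label = site)
    }
    lo <- as.character(miettinen_lasota(rep(site, 4), sizes, rep(3, 4)))
    hi <- as.character(miettinen_lasota(rep(site, 4), sizes, rep(8, 4)))
    ok <- lo != "insufficient_data" & hi != "insufficient_data"
    expect_true(all(ord[hi[ok]] >= ord[lo[ok]]), label = site)
  }
})

test_that("predictive risk pushes the pmf through the lookup exactly", {
  # point mass at 3 mitoses
  pm <- prometheus:::new_gist_pred(1e-12, support_max = 50)
  pm$pmf <- rep(0, 51); pm$pmf[4] <- 1
  pr <- predictive_risk(pm, "stomach", 72)
  expect_equal(unname(pr["low"]), 1)
  # 0.5/0.5 split over counts 4 and 7 on a 72 mm gastric tumor
  ps <- pm; ps$pmf <- rep(0, 51); ps$pmf[c(5, 8)] <- 0.5
  pr2 <- predictive_risk(ps, "stomach", 72)
  expect_equal(unname(pr2["low"]), 0.5)
  expect_equal(unname(pr2["high"]), 0.5)
  expect_equal(sum(pr2), 1, tolerance = 1e-9)
  # probabilities always normalized and in [0, 1]
  fitpred <- prometheus:::new_gist_pred(c(2, 5, 9), support_max = 100)
  pr3 <- predictive_risk(fitpred, "duodenum", 30)
  expect_equal(sum(pr3), 1, tolerance = 1e-9)
  expect_true(all(pr3 >= 0 & pr3 <= 1))
})

test_that("shifting mass above the mitotic threshold never lowers P(high)", {
  base <- prometheus:::new_gist_pred(c(3, 6), support_max = 60)
  for (site in c("stomach", "colon-rectum")) {
    for (size in c(15, 40, 80, 150)) {
      p0 <- predictive_risk(base, site, size)
      shifted <- base
      # move mass from counts <=5 onto count 10
      low_ids <- 1:6
      moved <- sum(shifted$pmf[low_ids]) * 0.5
      shifted$pmf[low_ids] <- shifted$pmf[low_ids] * 0.5
      shifted$pmf[11] <- shifted$pmf[11] + moved
      p1 <- predictive_risk(shifted, site, size)
      expect_gte(p1[["high"]] + 1e-12, p0[["high"]])
    }
  }
})

test_that("preoperative classification follows severity-first precedence", {
  expect_equal(preoperative_class("stomach", 40, "low", resectable = FALSE), "4")
  expect_equal(preoperative_class("stomach", 40, "low", metastatic = TRUE), "3")
  # any non-gastric site is at least locally advanced
  expect_equal(preoperative_class("duodenum", 60, "low"), "2")
  expect_equal(preoperative_class("small-intestine", 30, "none"), "2")
  # gastric triggers: size, rupture, mutilating surgery, model high risk
  expect_equal(preoperative_class("stomach", 120, "low"), "2")
  expect_equal(preoperative_class("stomach", 40, "high"), "2")
  expect_equal(preoperative_class("stomach", 40, "low", rupture_risk = TRUE), "2")
  expect_equal(preoperative_class("stomach", 40, "low",
                                  mutilating_resection = TRUE), "2")
  # gastric low-risk strata
  expect_equal(preoperative_class("stomach", 15, "low"), "0")
  expect_equal(preoperative_class("stomach", 72, "low"), "1")
  # rows the table does not cover are reported, not defaulted
  expect_equal(preoperative_class("stomach", 40, "moderate"), "unclassified")
  # precedence: unresectable dominates everything else
  expect_equal(preoperative_class("duodenum", 200, "high", resectable = FALSE,
                                  metastatic = FALSE), "4")
})
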