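test_that("HDPI is the shortest interval containing the requested mass", {
  # uniform grid: every window ties, the lowest is returned
  expect_equal(hdpi(1:100, 0.89), c(1, 89))
  expect_equal(hdpi(rep(3.5, 10)), c(3.5, 3.5))
  # standard normal: shortest 89% interval is the symmetric one
  set.seed(2)
  x <- rnorm(1e5)
  h <- hdpi(x, 0.89)
  q <- qnorm(1 - (1 - 0.89) / 2)
  expect_lt(abs(h[1] + q), 0.05)
  expect_lt(abs(h[2] - q), 0.05)
  # skewed sample: HDPI is shorter than the equal-tailed interval
  y <- rlnorm(1e5)
  h2 <- hdpi(y, 0.89)
  et <- quantile(y, c(0.055, 0.945))
  expect_lt(diff(h2), diff(et))
  expect_error(hdpi(numeric(0)), "empty")
})

test_that("posterior predictive pmf is the Poisson mixture over rate draws", {
  # single rate draw: exactly Poisson
  p1 <- prometheus:::new_gist_pred(1, support_max = 200)
  ref <- dpois(0:200, 1); ref <- ref / sum(ref)
  expect_equal(p1$pmf, ref, tolerance = 1e-12)
  # two draws: equal-weight mixture, closed form
  p2 <- prometheus:::new_gist_pred(c(2, 8), support_max = 200)
  mix <- 0.5 * dpois(0:200, 2) + 0.5 * dpois(0:200, 8)
  mix <- mix / sum(mix)
  expect_lt(max(abs(p2$pmf - mix)), 1e-12)
  expect_equal(sum(p2$pmf), 1, tolerance = 1e-9)
  # law of total expectation: predictive mean = mean of rate draws
  expect_equal(p2$mean, 5, tolerance = 1e-6)
  # modal band holds at least its mass and is minimal at its width
  cs <- cumsum(p2$pmf)
  band <- p2$modal_band
  mass_in <- sum(p2$pmf[(band[1]:band[2]) + 1])
  expect_gte(mass_in, 0.5)
  w <- band[2] - band[1] + 1
  if (w > 1) {
    nw <- length(p2$pmf) - (w - 1) + 1
    shorter <- sapply(seq_len(nw), function(i) sum(p2$pmf[i:(i + w - 2)]))
    expect_lt(max(shorter), 0.5)
  }
  # truncation is warned about
  expect_warning(prometheus:::new_gist_pred(300, support_max = 100),
                 "truncated")
})

test_that("prediction from a fit uses the no-response arm and is monotone", {
  fit <- fixture_fit()
  base <- list(site = "stomach", size_mm = 60, surface_mm2 = 2.5)
  preds <- lapply(c(0, 2, 6, 12), function(mb) {
    predict(fit, gist_data(site = base$site, size_mm = base$size_mm,
                           surface_mm2 = base$surface_mm2,
                           biopsy_mitoses = mb))
  })
  means <- vapply(preds, `[[`, numeric(1), "mean")
  # delta > 0 in essentially all posterior draws, so more biopsy mitoses
  # must predict more specimen mitoses
  expect_true(all(diff(means) > 0))

  # response flag on the input record must not change the forecast
  # (the response coefficient is never used for prediction)
  r0 <- gist_data(site = "stomach", size_mm = 60, surface_mm2 = 2.5,
                  biopsy_mitoses = 4, response = FALSE)
  r1 <- gist_data(site = "stomach", size_mm = 60, surface_mm2 = 2.5,
                  biopsy_mitoses = 4, response = TRUE)
  expect_equal(predict(fit, r0)$pmf, predict(fit, r1)$pmf, tolerance = 1e-12)

  # predictive mean equals mean of the rate draws (truncation negligible)
  pr <- preds[[2]]
  expect_equal(pr$mean, mean(pr$lambda_samples), tolerance = 1e-6)
})

test_that("retrodiction reports per-record intervals and coverage", {
  fit <- fixture_fit()
  rd <- retrodiction(fit)
  expect_equal(nrow(rd), nrow(fit$data))
  expect_true(all(rd$pred_lo <= rd$pred_hi))
  expect_true(all(rd$lambda_lo <= rd$lambda_mean & rd$lambda_mean <= rd$lambda_hi))
  # on well-specified data most records are covered
  expect_gt(mean(rd$covered), 0.75)
  # inferred rates correlate with the generating truth
  truth <- attr(fixture_cohort(), "truth")
  expect_gt(cor(rd$lambda_mean, truth$lambda), 0.5)

  # single-record cohort gives a single-row report
  one <- fixture_cohort()[1, ]
  class(one) <- class(fixture_cohort())
  f1 <- fit; f1$data <- one
  expect_equal(nrow(retrodiction(f1)), 1)
})
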