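test_that("fits are reproducible under the same seed and configuration", {
  d <- fixture_cohort(n = 40)
  # deliberately tiny fits: convergence warnings are expected and irrelevant
  f1 <- suppressWarnings(gist_fit(d, chains = 2, warmup = 150, draws = 100,
                                  seed = 3))
  f2 <- suppressWarnings(gist_fit(d, chains = 2, warmup = 150, draws = 100,
                                  seed = 3))
  expect_identical(f1$draws_array, f2$draws_array)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- suppressWarnings(gist_fit(d, chains = 2, warmup = 150, draws = 100,
                                  seed = 4))
  expect_false(identical(f1$draws_array, f3$draws_array))
})

test_that("an intercept-only posterior recovers the Poisson mean", {
  # constant covariates reduce size_no_surface to an intercept model with
  # inert hierarchical terms; the posterior mean of exp(alpha) must match
  # the sample mean
  set.seed(8)
  n <- 200
  y <- rpois(n, 5)
  d <- gist_data(site = rep("stomach", n), size_mm = rep(40, n),
                 surface_mm2 = rep(2, n), biopsy_mitoses = rep(0, n),
                 specimen_mitoses = y)
  fit <- gist_fit(d, variant = "size_no_surface", chains = 2,
                  warmup = 400, draws = 600, seed = 5)
  lam_draws <- exp(as.matrix(fit)[, "alpha"])
  mc_se <- sd(lam_draws) / sqrt(fit$diagnostics$parameters$ess_bulk[
    fit$diagnostics$parameters$parameter == "alpha"])
  # posterior mean ~ MLE within posterior sd (weak prior, n = 200)
  expect_lt(abs(mean(lam_draws) - mean(y)),
            3 * (sd(lam_draws) / sqrt(10) + mc_se))
})

test_that("mock-data fits converge and retrodict the generating rates", {
  fit <- fixture_fit()
  dg <- fit$diagnostics
  expect_true(all(dg$parameters$rhat <= 1.02, na.rm = TRUE))
  expect_true(all(dg$parameters$ess_bulk > 50))
  # inferred rates track the simulation truth
  truth <- attr(fixture_cohort(), "truth")
  expect_gt(cor(fitted(fit), truth$lambda), 0.5)
})

test_that("rank-normalized split R-hat separates mixed from unmixed chains", {
  set.seed(42)
  # independent draws: R-hat ~ 1
  x <- matrix(rnorm(4000), ncol = 4)
  expect_gte(rhat(x), 0.999)
  expect_lte(rhat(x), 1.01)
  # disjoint chains: R-hat far above threshold
  y <- cbind(matrix(rnorm(2000, 0), ncol = 2),
             matrix(rnorm(2000, 10), ncol = 2))
  expect_gt(rhat(y), 1.2)
  # chains mixed in mean but not in scale are caught by the folded part
  z <- cbind(matrix(rnorm(2000, 0, 1), ncol = 2),
             matrix(rnorm(2000, 0, 8), ncol = 2))
  expect_gt(rhat(z), 1.1)
  # single chain unavailable
  expect_true(is.na(rhat(matrix(rnorm(100), ncol = 1))))
})

test_that("bulk ESS reflects autocorrelation and flags degeneracy", {
  set.seed(9)
  x <- matrix(rnorm(4000), ncol = 4)
  expect_gt(ess_bulk(x), 2500)
  # strongly autocorrelated chains have far fewer effective draws
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.95), 1000)))
  expect_lt(ess_bulk(ar), 400)
  # constant chains are degenerate
  expect_true(is.na(ess_bulk(matrix(1, 100, 2))))
})

test_that("diagnostics report flags pathologies instead of hiding them", {
  fit <- fixture_fit()
  # healthy fit: no flags
  expect_true(fit$diagnostics$ok)
  # degenerate constant chains produce a flagged report
  broken <- fit
  broken$draws_array[, , "alpha"] <- 1
  dg <- mcmc_diagnostics(broken)
  expect_false(dg$ok)
  expect_true(any(grepl("degenerate|ESS", dg$flags)))
})

test_that("rank plot data is near-uniform for well-mixed chains", {
  fit <- fixture_fit()
  rc <- rank_counts(fit, "alpha", bins = 10)
  expect_equal(dim(rc), c(10, fit$sampler$chains))
  expect_equal(sum(rc), fit$sampler$chains * fit$sampler$draws)
  # chi-square-style departure from uniformity should be modest
  expected <- fit$sampler$draws / 10
  stat <- sum((rc - expected)^2 / expected)
  expect_lt(stat, 2 * qchisq(0.999, df = 9))
})
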