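make_record <- function(site = "stomach", size = 50, surface = 2.5, mb = 2,
                        response = FALSE) {
  gist_data(site = site, size_mm = size, surface_mm2 = surface,
            biopsy_mitoses = mb, response = response, specimen_mitoses = 0)
}

identity_tf <- function(data) {
  # fit on the data itself; with one record, z-scored size is 0
  fit_transform(covariate_transform(), data)
}

test_that("linear predictor matches its closed form", {
  rec <- make_record()
  tf <- identity_tf(rec)
  expect_equal(linear_predictor(gist_params(), rec, tf), 1)
  expect_equal(linear_predictor(gist_params(alpha = log(5)), rec, tf), 5)

  # response flips the biopsy-count coefficient from delta to epsilon
  p <- gist_params(alpha = 0.3, delta = 1, epsilon = -0.4)
  r0 <- make_record(mb = 4, response = FALSE)
  r1 <- make_record(mb = 4, response = TRUE)
  r1$response <- TRUE
  tf0 <- identity_tf(r0)
  m <- log1p(4)
  expect_equal(linear_predictor(p, r1, tf0) / linear_predictor(p, r0, tf0),
               exp((-0.4 - 1) * m), tolerance = 1e-12)

  # all rates positive for wild but finite parameters
  set.seed(1)
  d <- fixture_cohort(n = 30)
  tfd <- identity_tf(d)
  for (i in 1:20) {
    p <- gist_params(alpha = rnorm(1, 0, 5), beta = rnorm(4, 0, 5),
                     gamma = rnorm(4, 0, 5), delta = rnorm(1, 0, 5),
                     epsilon = rnorm(1, 0, 5))
    expect_true(all(linear_predictor(p, d, tfd) > 0))
  }
})

test_that("pointwise log-likelihood equals the exact Poisson pmf", {
  rec <- make_record()
  tf <- identity_tf(rec)
  # lambda = 1, y = 0: log p = -1
  expect_equal(log_likelihood_pointwise(gist_params(), rec, tf), -1)
  # lambda = 5, y = 5: closed form
  r5 <- rec; r5$specimen_mitoses <- 5
  expect_equal(log_likelihood_pointwise(gist_params(alpha = log(5)), r5, tf),
               5 * log(5) - 5 - log(factorial(5)), tolerance = 1e-12)
  # exact-factorial oracle for y <= 20
  p <- fixture_params()
  d <- fixture_cohort(n = 40)
  keep <- d$specimen_mitoses <= 20
  tfd <- fit_transform(covariate_transform(), d)
  lam <- linear_predictor(p, d, tfd)
  oracle <- d$specimen_mitoses * log(lam) - lam -
    log(factorial(d$specimen_mitoses))
  ll <- log_likelihood_pointwise(p, d, tfd)
  expect_equal(ll[keep], oracle[keep], tolerance = 1e-10)
  # missing specimen counts are reported by row
  dna <- d; dna$specimen_mitoses[c(2, 5)] <- NA
  expect_error(log_likelihood_pointwise(p, dna, tfd), "rows 2, 5")
})

test_that("total log-likelihood is maximized at the Poisson MLE intercept", {
  d <- fixture_cohort(n = 60)
  tf <- fit_transform(covariate_transform(), d)
  mle <- log(mean(d$specimen_mitoses))
  ll_at <- function(a) sum(log_likelihood_pointwise(gist_params(alpha = a),
                                                    d, tf))
  alphas <- mle + seq(-0.5, 0.5, by = 0.05)
  expect_equal(alphas[which.max(vapply(alphas, ll_at, numeric(1)))], mle,
               tolerance = 1e-9)
})

test_that("log-prior matches closed-form densities and support rules", {
  pr <- gist_priors()
  # parameters at the prior means with unit hierarchy scales
  p <- gist_params(alpha = pr$alpha[1], beta = rep(0, 4), gamma = rep(0, 4),
                   delta = pr$delta[1], epsilon = pr$epsilon[1],
                   mu_beta = 0, sigma_beta = 1, mu_gamma = 0, sigma_gamma = 1)
  manual <- dnorm(pr$alpha[1], pr$alpha[1], pr$alpha[2], log = TRUE) +
    sum(dnorm(rep(0, 4), 0, 1, log = TRUE)) +            # beta | hyper
    sum(dnorm(rep(0, 4), 0, 1, log = TRUE)) +            # gamma | hyper
    dnorm(0, pr$mu_beta[1], pr$mu_beta[2], log = TRUE) +
    dnorm(0, pr$mu_gamma[1], pr$mu_gamma[2], log = TRUE) +
    dexp(1, pr$sigma_beta, log = TRUE) +
    dexp(1, pr$sigma_gamma, log = TRUE) +
    dnorm(pr$delta[1], pr$delta[1], pr$delta[2], log = TRUE) +
    dnorm(pr$epsilon[1], pr$epsilon[1], pr$epsilon[2], log = TRUE)
  expect_equal(log_prior(p, pr), manual, tolerance = 1e-12)

  # nonpositive scale is out of support, not an exception
  bad <- p; bad$sigma_beta <- -1
  expect_identical(log_prior(bad, pr), -Inf)

  # doubling an exponential rate shifts that contribution by log 2 - sigma*rate
  pr2 <- gist_priors(sigma_beta = 2 * pr$sigma_beta)
  expect_equal(log_prior(p, pr2) - log_prior(p, pr),
               log(2) - p$sigma_beta * pr$sigma_beta, tolerance = 1e-12)
})

test_that("noncentered map is exactly invertible and z = 0 recovers the mean", {
  p <- gist_params(alpha = 0.5, beta = c(0.1, 0.4, -0.2, 0.3),
                   gamma = c(-0.3, 0.2, 0, -0.1), delta = 1, epsilon = -0.5,
                   mu_beta = 0.2, sigma_beta = 0.7, mu_gamma = -0.05,
                   sigma_gamma = 0.4)
  raw <- noncenter_params(p)
  back <- center_params(raw)
  for (nm in names(p)) expect_equal(back[[nm]], p[[nm]], tolerance = 1e-12)
  raw$z_beta <- rep(0, 4)
  expect_equal(center_params(raw)$beta, rep(p$mu_beta, 4), tolerance = 1e-12)
})

test_that("both parameterizations define the same posterior density", {
  # at matched points the two log-densities differ exactly by the Jacobian
  # of beta = mu + sigma z (4 log sigma per hierarchical block)
  d <- fixture_cohort(n = 40)
  pr <- gist_priors()
  tf <- fit_transform(covariate_transform(), d)
  pc <- prometheus:::make_posterior("full", d, pr, tf, "centered")
  pn <- prometheus:::make_posterior("full", d, pr, tf, "noncentered")
  lay <- pc$layout
  set.seed(77)
  for (i in 1:100) {
    th_c <- rnorm(pc$n_par, 0, 0.5)
    sb <- exp(th_c[lay$lsigma_beta]); sg <- exp(th_c[lay$lsigma_gamma])
    th_n <- th_c
    th_n[lay$beta] <- (th_c[lay$beta] - th_c[lay$mu_beta]) / sb
    th_n[lay$gamma] <- (th_c[lay$gamma] - th_c[lay$mu_gamma]) / sg
    lp_c <- pc$lp_grad(th_c)$lp
    lp_n <- pn$lp_grad(th_n)$lp
    if (is.finite(lp_c) && is.finite(lp_n)) {
      expect_equal(lp_c, lp_n - 4 * log(sb) - 4 * log(sg), tolerance = 1e-8)
    }
  }
})

test_that("the full model nests the size-only variant", {
  d <- fixture_cohort(n = 30)
  tf <- fit_transform(covariate_transform(), d)
  p <- gist_params(alpha = 0.8, beta = c(0.1, 0.2, 0.3, 0.4),
                   gamma = rep(0, 4), delta = 0, epsilon = 0)
  expect_equal(linear_predictor(p, d, tf, variant = "full"),
               linear_predictor(p, d, tf, variant = "size_no_surface"),
               tolerance = 1e-12)
})

test_that("prior predictive rates obey the field-knowledge constraints", {
  pp <- prior_predictive(n = 1000, seed = 4)
  expect_gt(pp$share_below_5, 0.5)
  expect_lt(pp$share_above_50, 0.10)
  expect_gt(pp$share_above_50, 0)   # high counts rare but not impossible
  # degenerate priors pin every rate at exp(alpha)
  degen <- gist_priors(alpha = c(log(3), 1e-9), delta = c(0, 1e-9),
                       epsilon = c(0, 1e-9), mu_beta = c(0, 1e-9),
                       mu_gamma = c(0, 1e-9), sigma_beta = 1e9,
                       sigma_gamma = 1e9)
  pp3 <- prior_predictive(degen, n = 50, seed = 5)
  expect_equal(pp3$lambda, rep(3, 50), tolerance = 1e-5)
})
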