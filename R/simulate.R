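#' Cohort generator configuration
#'
#' Parameterizes the synthetic GIST cohort generator. Defaults describe a
#' plausible referral-center case mix: gastric predominance (60% stomach,
#' 20% small intestine, 10% duodenum, 10% colon-rectum), log-normal tumor
#' sizes with median 50 mm for gastric and 35 mm for non-gastric tumors
#' (log-sd 0.5), biopsy surfaces on (0.05, 5] mm2 following a scaled
#' Beta(2, 2) (biopsies rarely reach the full 5 mm2 reference area), 15% of
#' cases with response to neoadjuvant therapy, and biopsy counts drawn
#' negative-binomially with mean proportional to the sampled surface
#' (dispersion 1, i.e. substantial overdispersion, as real biopsy counts
#' cluster at zero with a long tail).
#'
#' @param site_probs Length-4 probabilities over [gist_sites()], summing to 1.
#' @param size_median_mm Length-4 median tumor size per site, mm.
#' @param size_log_sd Log-scale standard deviation of tumor size.
#' @param surface_range Length-2: support of the biopsy surface, mm2.
#' @param surface_shape Length-2 Beta shape parameters for the surface.
#' @param response_prob Probability of a response-to-therapy case.
#' @param mb_rate_per_5mm2 Mean biopsy mitotic count per 5 mm2 used by the
#'   marginal biopsy-count sampler (model-faithful mode).
#' @param mb_dispersion Negative-binomial size parameter of that sampler.
#' @param dag_lambda_meanlog,dag_lambda_sdlog Log-normal parameters of the
#'   latent specimen rate in dag-faithful mode.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(site_probs = c(0.10, 0.10, 0.20, 0.60),
                          size_median_mm = c(35, 35, 35, 50),
                          size_log_sd = 0.5,
                          surface_range = c(0.05, 5),
                          surface_shape = c(2, 2),
                          response_prob = 0.15,
                          mb_rate_per_5mm2 = 2,
                          mb_dispersion = 1,
                          dag_lambda_meanlog = log(2),
                          dag_lambda_sdlog = 1.2) {
  stopifnot(length(site_probs) == 4, abs(sum(site_probs) - 1) < 1e-8,
            all(site_probs >= 0), length(size_median_mm) == 4,
            size_log_sd > 0, length(surface_range) == 2,
            surface_range[1] > 0, surface_range[2] > surface_range[1],
            response_prob >= 0, response_prob <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

## Draw covariates only (site, size, surface, response, biopsy count);
## specimen count left NA. Used by the prior predictive and model mode.
draw_covariates <- function(n, config = cohort_config()) {
  L <- sample.int(4, n, replace = TRUE, prob = config$site_probs)
  size <- stats::rlnorm(n, log(config$size_median_mm[L]), config$size_log_sd)
  surf <- config$surface_range[1] +
    diff(config$surface_range) * stats::rbeta(n, config$surface_shape[1],
                                              config$surface_shape[2])
  resp <- stats::runif(n) < config$response_prob
  mb <- stats::rnbinom(n, size = config$mb_dispersion,
                       mu = config$mb_rate_per_5mm2 * surf / 5)
  gist_data(site = gist_sites()[L], size_mm = size, surface_mm2 = surf,
            biopsy_mitoses = mb, response = resp,
            provenance = "synthetic covariates")
}

#' Simulate a synthetic GIST cohort
#'
#' Generates cohorts with the statistical structure the analysis assumes, in
#' one of two modes:
#'
#' * `"model"` (model-faithful): covariates are drawn from the generator
#'   marginals, the Poisson rate is computed from the model's linear
#'   predictor at known ("true") parameters, and the specimen count drawn
#'   from it. This is the mode used for parameter-recovery studies.
#' * `"dag"` (dag-faithful): a latent specimen rate \eqn{\lambda_i} is drawn
#'   per tumor and both counts are drawn from it, the biopsy count at the
#'   surface-scaled rate \eqn{\lambda_i S_i / 5}. This reproduces the causal
#'   sampling-bias story: small biopsy surfaces under-sample mitoses.
#'
#' @param n Number of tumors.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @param params True parameters ([gist_params()]), or `"prior"` to draw
#'   them from `priors` (model mode only).
#' @param mode `"model"` or `"dag"`.
#' @param config A [cohort_config()].
#' @param priors Priors used when `params = "prior"`.
#' @param transform Covariate transform fitted on the simulated covariates
#'   before computing rates (model mode).
#' @return A `gist_data` cohort with attribute `truth`: a list holding the
#'   generating `params` (model mode), per-record `lambda`, and the fitted
#'   `transform`.
#' @export
simulate_gist_cohort <- function(n, seed = NULL, params = "prior",
                                 mode = c("model", "dag"),
                                 config = cohort_config(),
                                 priors = gist_priors(),
                                 transform = covariate_transform()) {
  stopifnot(n >= 1)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "model") {
    cov <- draw_covariates(n, config)
    if (identical(params, "prior")) params <- sample_prior_params(priors)
    tf <- fit_transform(transform, cov)
    lambda <- linear_predictor(params, cov, tf, variant = "full")
    y <- stats::rpois(n, lambda)
    out <- gist_data(site = as.character(cov$site), size_mm = cov$size_mm,
                     surface_mm2 = cov$surface_mm2,
                     biopsy_mitoses = cov$biopsy_mitoses,
                     response = cov$response, specimen_mitoses = y,
                     provenance = "synthetic cohort (model-faithful)")
    attr(out, "truth") <- list(params = params, lambda = lambda,
                               transform = tf, mode = mode)
  } else {
    cov <- draw_covariates(n, config)
    lambda <- stats::rlnorm(n, config$dag_lambda_meanlog,
                            config$dag_lambda_sdlog)
    y <- stats::rpois(n, lambda)
    mb <- stats::rpois(n, lambda * cov$surface_mm2 / 5)
    out <- gist_data(site = as.character(cov$site), size_mm = cov$size_mm,
                     surface_mm2 = cov$surface_mm2, biopsy_mitoses = mb,
                     response = FALSE, specimen_mitoses = y,
                     provenance = "synthetic cohort (dag-faithful)")
    attr(out, "truth") <- list(params = NULL, lambda = lambda,
                               transform = NULL, mode = mode)
  }
  out
}
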