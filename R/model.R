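#' Model variants
#'
#' Five alternative structures for the log-linear Poisson rate of the
#' specimen mitotic count, compared by WAIC/PSIS-LOO:
#'
#' * `"full"` — site-hierarchical size and surface coefficients plus the
#'   biopsy-count term with its response/no-response arms (the reference
#'   model used for forecasting);
#' * `"hier_delta"` — as `"full"`, but the no-response biopsy-count
#'   coefficient is itself hierarchical across sites;
#' * `"size_hier"` — hierarchical size and surface coefficients only, no
#'   biopsy-count term;
#' * `"size_no_surface"` — hierarchical size coefficient only;
#' * `"flat_no_size"` — no size term and no hierarchy: independent
#'   fixed-prior surface coefficients per site plus the biopsy-count term.
#'
#' @return Character vector of variant names.
#' @export
gist_variants <- function() {
  c("full", "hier_delta", "size_hier", "size_no_surface", "flat_no_size")
}

variant_info <- function(variant) {
  variant <- match.arg(variant, gist_variants())
  switch(variant,
    full = list(name = variant, use_size = TRUE, use_surface = TRUE,
                use_mb = TRUE, hier = TRUE, delta_hier = FALSE),
    hier_delta = list(name = variant, use_size = TRUE, use_surface = TRUE,
                      use_mb = TRUE, hier = TRUE, delta_hier = TRUE),
    size_hier = list(name = variant, use_size = TRUE, use_surface = TRUE,
                     use_mb = FALSE, hier = TRUE, delta_hier = FALSE),
    size_no_surface = list(name = variant, use_size = TRUE, use_surface = FALSE,
                           use_mb = FALSE, hier = TRUE, delta_hier = FALSE),
    flat_no_size = list(name = variant, use_size = FALSE, use_surface = TRUE,
                        use_mb = TRUE, hier = FALSE, delta_hier = FALSE)
  )
}

## Linear predictor on transformed covariates tc (list from apply_transform).
## params$delta may be a scalar or, for the hierarchical-delta variant, a
## length-4 vector indexed by site.
eta_from <- function(params, tc, info) {
  eta <- rep(params$alpha, length(tc$L))
  if (info$use_size) eta <- eta + params$beta[tc$L] * tc$d
  if (info$use_surface) eta <- eta + params$gamma[tc$L] * tc$s
  if (info$use_mb) {
    dl <- if (info$delta_hier) params$delta[tc$L] else params$delta
    eta <- eta + ((1 - tc$R) * dl + tc$R * params$epsilon) * tc$m
  }
  eta
}

#' Poisson rate of the specimen mitotic count
#'
#' Evaluates the model's rate \eqn{\lambda_i = \exp(\alpha + \beta_{L_i} d_i
#' + \gamma_{L_i} s_i + ((1-R_i)\delta + R_i\epsilon) m_i)} for each record,
#' where \eqn{d, s, m} are the transformed size, surface and biopsy-count
#' covariates and \eqn{R} the response indicator.
#'
#' @param params A [gist_params()] object (or compatible named list).
#' @param data A `gist_data` cohort.
#' @param transform A fitted [covariate_transform()].
#' @param variant One of [gist_variants()].
#' @return Positive numeric vector of rates, one per record.
#' @export
linear_predictor <- function(params, data, transform, variant = "full") {
  info <- variant_info(variant)
  tc <- apply_transform(transform, data)
  exp(eta_from(params, tc, info))
}

#' Pointwise Poisson log-likelihood
#'
#' @inheritParams linear_predictor
#' @return Numeric vector: log Poisson pmf of each record's specimen count at
#'   its model rate. Sum it for the total log-likelihood.
#' @export
log_likelihood_pointwise <- function(params, data, transform,
                                     variant = "full") {
  y <- data$specimen_mitoses
  if (anyNA(y)) {
    stop("records without specimen_mitoses: rows ",
         paste(which(is.na(y)), collapse = ", "), call. = FALSE)
  }
  lambda <- linear_predictor(params, data, transform, variant)
  stats::dpois(y, lambda, log = TRUE)
}

#' Joint log-prior density
#'
#' Site-level coefficients are normal around their hyper-means in
#' hierarchical variants (independent fixed-prior normals in the flat
#' variant); location-invariant coefficients and hyper-means are normal and
#' hierarchical scales exponential, all per the [gist_priors()]
#' configuration. Non-positive scales are out of support and return `-Inf`.
#'
#' @inheritParams linear_predictor
#' @param priors A [gist_priors()] object.
#' @return Scalar log-density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors = gist_priors(), variant = "full") {
  info <- variant_info(variant)
  dn <- function(x, hp) sum(stats::dnorm(x, hp[1], hp[2], log = TRUE))
  lp <- dn(params$alpha, priors$alpha)
  if (info$use_size) {
    if (params$sigma_beta <= 0) return(-Inf)
    lp <- lp + dn(params$beta, c(params$mu_beta, params$sigma_beta)) +
      dn(params$mu_beta, priors$mu_beta) +
      stats::dexp(params$sigma_beta, priors$sigma_beta, log = TRUE)
  }
  if (info$use_surface) {
    if (info$hier) {
      if (params$sigma_gamma <= 0) return(-Inf)
      lp <- lp + dn(params$gamma, c(params$mu_gamma, params$sigma_gamma)) +
        dn(params$mu_gamma, priors$mu_gamma) +
        stats::dexp(params$sigma_gamma, priors$sigma_gamma, log = TRUE)
    } else {
      lp <- lp + dn(params$gamma, priors$flat_coef)
    }
  }
  if (info$use_mb) {
    if (info$delta_hier) {
      sd_delta <- params$sigma_delta
      if (is.null(sd_delta) || sd_delta <= 0) return(-Inf)
      lp <- lp + dn(params$delta, c(params$mu_delta, sd_delta)) +
        dn(params$mu_delta, priors$mu_delta) +
        stats::dexp(sd_delta, priors$sigma_delta, log = TRUE)
    } else {
      lp <- lp + dn(params$delta, priors$delta)
    }
    lp <- lp + dn(params$epsilon, priors$epsilon)
  }
  lp
}

#' Noncentered reparameterization
#'
#' Hierarchical coefficients can be rewritten as
#' \eqn{\beta_l = \mu_\beta + \sigma_\beta z_l} with standard-normal
#' \eqn{z_l}; sampling in \eqn{z} removes the funnel-shaped coupling between
#' coefficients and their hyper-scale that produces divergent transitions.
#' `noncenter_params()` maps parameters to the raw coordinates and
#' `center_params()` inverts it; the two parameterizations define the same
#' posterior (the map is affine in the coefficients at fixed hyper-
#' parameters, with the standard-normal density on `z` replacing the normal
#' density on the coefficients).
#'
#' @param params A [gist_params()] object.
#' @return For `noncenter_params()`, a list with `z_beta`, `z_gamma` and the
#'   unchanged remaining parameters; `center_params()` restores `beta` and
#'   `gamma`.
#' @export
noncenter_params <- function(params) {
  list(alpha = params$alpha,
       z_beta = (params$beta - params$mu_beta) / params$sigma_beta,
       z_gamma = (params$gamma - params$mu_gamma) / params$sigma_gamma,
       delta = params$delta, epsilon = params$epsilon,
       mu_beta = params$mu_beta, sigma_beta = params$sigma_beta,
       mu_gamma = params$mu_gamma, sigma_gamma = params$sigma_gamma)
}

#' @rdname noncenter_params
#' @param raw A list as returned by `noncenter_params()`.
#' @export
center_params <- function(raw) {
  gist_params(alpha = raw$alpha,
              beta = raw$mu_beta + raw$sigma_beta * raw$z_beta,
              gamma = raw$mu_gamma + raw$sigma_gamma * raw$z_gamma,
              delta = raw$delta, epsilon = raw$epsilon,
              mu_beta = raw$mu_beta, sigma_beta = raw$sigma_beta,
              mu_gamma = raw$mu_gamma, sigma_gamma = raw$sigma_gamma)
}

#' Prior predictive simulation of the mitotic rate
#'
#' Draws `n` replicates, each pairing one parameter set sampled from the
#' priors with one covariate record sampled from the cohort generator, and
#' returns the implied Poisson rates \eqn{\lambda} (expected specimen counts
#' per 5 mm2). The summary reports the shares of rates below 5 and above 50,
#' the two field-knowledge checkpoints the priors are calibrated against:
#' most GISTs are mitotically quiet, and counts above 50 are biologically
#' exceptional.
#'
#' @param priors A [gist_priors()] object.
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param config Cohort generator configuration ([cohort_config()]) used as
#'   the covariate sampler.
#' @param transform Covariate transform; fitted on the sampled covariates.
#' @param draw_counts If `TRUE`, also draw a Poisson specimen count per
#'   replicate.
#' @return Object of class `"prior_predictive"`: list with `lambda`,
#'   optional `counts`, `share_below_5`, `share_above_50`.
#' @export
prior_predictive <- function(priors = gist_priors(), n = 1000, seed = NULL,
                             config = cohort_config(),
                             transform = covariate_transform(),
                             draw_counts = TRUE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cov <- draw_covariates(n, config)
  tf <- fit_transform(transform, cov)
  tc <- apply_transform(tf, cov)
  info <- variant_info("full")
  lambda <- vapply(seq_len(n), function(i) {
    p <- sample_prior_params(priors)
    tci <- lapply(tc, `[`, i)
    exp(eta_from(p, tci, info))
  }, numeric(1))
  out <- list(
    lambda = lambda,
    counts = if (draw_counts) stats::rpois(n, pmin(lambda, 1e8)) else NULL,
    share_below_5 = mean(lambda < 5),
    share_above_50 = mean(lambda > 50),
    n = n
  )
  class(out) <- "prior_predictive"
  out
}

#' @export
print.prior_predictive <- function(x, ...) {
  cat(sprintf("Prior predictive simulation (%d replicates)\n", x$n))
  cat(sprintf("  median rate: %.2f / 5 mm2\n", stats::median(x$lambda)))
  cat(sprintf("  share with rate < 5:  %.1f%%\n", 100 * x$share_below_5))
  cat(sprintf("  share with rate > 50: %.1f%%\n", 100 * x$share_above_50))
  invisible(x)
}
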