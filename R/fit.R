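#' Fit the mitotic-count model by Hamiltonian Monte Carlo
#'
#' Draws from the posterior of a model variant given a training cohort.
#' The specimen mitotic count is Poisson with log-rate
#' \deqn{\log\lambda_i = \alpha + \beta_{L_i} d_i + \gamma_{L_i} s_i +
#'   ((1-R_i)\,\delta + R_i\,\epsilon)\, m_i,}
#' where \eqn{L_i} indexes the anatomical site, \eqn{d_i} the transformed
#' tumor size, \eqn{s_i} the biopsy surface, \eqn{m_i} the transformed
#' biopsy count and \eqn{R_i} the response-to-therapy flag; site-level
#' coefficients are partially pooled through normal hyper-priors (see
#' [gist_variants()] for the alternative structures). Sampling uses the
#' package's adaptive HMC with dual-averaging step size, diagonal mass
#' adaptation and jittered trajectory lengths; hierarchical variants default
#' to the noncentered parameterization, which removes the coefficient/scale
#' funnel that causes divergent transitions in the centered form.
#'
#' Pointwise log-likelihoods are evaluated at every retained draw, so WAIC
#' and PSIS-LOO ([waic()], [psis_loo()]) come at no extra cost. Convergence
#' is checked on return ([mcmc_diagnostics()]); a failing fit is returned
#' with a warning and `fit$diagnostics$ok == FALSE`, never silently.
#'
#' @param data A `gist_data` cohort; every record needs `specimen_mitoses`.
#' @param variant One of [gist_variants()].
#' @param priors A [gist_priors()] object.
#' @param transform A [covariate_transform()]; fitted on `data`.
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param warmup,draws Warmup and retained iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param parameterization `"auto"` (noncentered for hierarchical variants),
#'   `"noncentered"` or `"centered"`.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_leapfrog Upper bound of the jittered leapfrog step count.
#' @return An object of class `"gist_fit"`.
#' @export
gist_fit <- function(data, variant = "full", priors = gist_priors(),
                     transform = covariate_transform(),
                     chains = 4, warmup = 1000, draws = 1000, seed = 1,
                     parameterization = c("auto", "noncentered", "centered"),
                     target_accept = 0.9, max_leapfrog = 32) {
  stopifnot(inherits(data, "gist_data"), chains >= 1, warmup >= 10,
            draws >= 10)
  variant <- match.arg(variant, gist_variants())
  parameterization <- match.arg(parameterization)
  if (parameterization == "auto") {
    parameterization <- if (variant_info(variant)$hier) "noncentered"
                        else "centered"
  }
  tf <- fit_transform(transform, data)
  post <- make_posterior(variant, data, priors, tf,
                         parameterization = parameterization)
  res <- hmc_sample(post, chains = chains, warmup = warmup, draws = draws,
                    seed = seed, target_accept = target_accept,
                    max_leapfrog = max_leapfrog)

  first <- post$unpack(res[[1]]$theta[1, ])
  cpar <- names(first)
  arr <- array(NA_real_, dim = c(draws, chains, length(cpar)),
               dimnames = list(NULL, NULL, cpar))
  loglik <- matrix(NA_real_, nrow = draws * chains, ncol = post$n_records)
  energy <- matrix(NA_real_, nrow = draws, ncol = chains)
  lp <- matrix(NA_real_, nrow = draws, ncol = chains)
  for (c in seq_len(chains)) {
    for (j in seq_len(draws)) {
      arr[j, c, ] <- post$unpack(res[[c]]$theta[j, ])
      loglik[(c - 1) * draws + j, ] <- post$loglik(res[[c]]$theta[j, ])
    }
    energy[, c] <- res[[c]]$energy
    lp[, c] <- res[[c]]$lp
  }

  fit <- structure(list(
    draws_array = arr,
    loglik = loglik,
    lp = lp,
    energy = energy,
    divergences = vapply(res, `[[`, integer(1), "divergences"),
    accept = vapply(res, function(r) mean(r$accept), numeric(1)),
    step_size = vapply(res, `[[`, numeric(1), "step_size"),
    variant = variant,
    parameterization = post$parameterization,
    priors = priors,
    transform = tf,
    data = data,
    sampler = list(chains = chains, warmup = warmup, draws = draws,
                   seed = seed, target_accept = target_accept,
                   max_leapfrog = max_leapfrog)
  ), class = "gist_fit")
  fit$diagnostics <- mcmc_diagnostics(fit)
  if (!fit$diagnostics$ok) {
    warning("fit did not pass convergence diagnostics: ",
            paste(fit$diagnostics$flags, collapse = "; "), call. = FALSE)
  }
  fit
}

#' @export
print.gist_fit <- function(x, ...) {
  d <- x$sampler
  cat(sprintf("Mitotic-count model fit ('%s', %s parameterization)\n",
              x$variant, x$parameterization))
  cat(sprintf("  %d records; %d chains x %d draws (+%d warmup); seed %d\n",
              nrow(x$data), d$chains, d$draws, d$warmup, d$seed))
  cat(sprintf("  divergent transitions: %d; mean acceptance %.2f\n",
              sum(x$divergences), mean(x$accept)))
  if (!x$diagnostics$ok) {
    cat("  CONVERGENCE FLAGS:",
        paste(x$diagnostics$flags, collapse = "; "), "\n")
  }
  cat("use summary() for posterior estimates\n")
  invisible(x)
}

#' Posterior summary
#'
#' Posterior mean, sd, highest-posterior-density interval (89% by default,
#' bounds labelled 5.5% / 94.5%), rank-normalized split R-hat and bulk ESS
#' per parameter.
#'
#' @param object A `gist_fit`.
#' @param prob Mass of the HDPI.
#' @param ... Unused.
#' @export
summary.gist_fit <- function(object, prob = 0.89, ...) {
  m <- as.matrix(object)
  dg <- object$diagnostics$parameters
  lo_lab <- sprintf("%.1f%%", 100 * (1 - prob) / 2)
  hi_lab <- sprintf("%.1f%%", 100 * (1 - (1 - prob) / 2))
  hd <- t(apply(m, 2, hdpi, mass = prob))
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m),
                    sd = apply(m, 2, stats::sd),
                    lo = hd[, 1], hi = hd[, 2],
                    rhat = dg$rhat[match(colnames(m), dg$parameter)],
                    ess_bulk = dg$ess_bulk[match(colnames(m), dg$parameter)],
                    row.names = NULL)
  names(out)[4:5] <- c(lo_lab, hi_lab)
  class(out) <- c("summary.gist_fit", "data.frame")
  out
}

#' @export
print.summary.gist_fit <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
as.matrix.gist_fit <- function(x, ...) {
  a <- x$draws_array
  matrix(aperm(a, c(1, 2, 3)), nrow = dim(a)[1] * dim(a)[2],
         dimnames = list(NULL, dimnames(a)[[3]]))
}

#' @export
coef.gist_fit <- function(object, ...) {
  colMeans(as.matrix(object))
}

#' Posterior-mean fitted rates
#'
#' @param object A `gist_fit`.
#' @param ... Unused.
#' @return Posterior mean of each training record's rate \eqn{\lambda_i}.
#' @export
fitted.gist_fit <- function(object, ...) {
  colMeans(lambda_draws(object, object$data))
}

#' Pearson residuals
#'
#' Observed specimen count minus the posterior-mean rate, scaled by its
#' square root (Poisson variance equals the mean).
#'
#' @param object A `gist_fit`.
#' @param type `"pearson"` or `"response"`.
#' @param ... Unused.
#' @export
residuals.gist_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$specimen_mitoses - mu
  if (type == "pearson") r / sqrt(mu) else r
}

#' Simulate specimen counts from the posterior predictive
#'
#' For each requested replicate, one posterior draw is selected and a
#' Poisson count simulated at each training record's rate under that draw.
#'
#' @param object A `gist_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix, `nsim` x records.
#' @export
simulate.gist_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lam <- lambda_draws(object, object$data)
  pick <- sample.int(nrow(lam), nsim, replace = TRUE)
  t(vapply(pick, function(s) stats::rpois(ncol(lam), lam[s, ]),
           numeric(ncol(lam))))
}

## Rate draws for arbitrary records: matrix draws x records. Response arms
## follow the records' flags unless force_no_response = TRUE (prediction).
lambda_draws <- function(fit, data, force_no_response = FALSE) {
  m <- as.matrix(fit)
  info <- variant_info(fit$variant)
  if (force_no_response && any(data$response)) {
    data$response <- FALSE
    data <- validate_gist_data(data)
  }
  tc <- apply_transform(fit$transform, data)
  S <- nrow(m)
  eta <- matrix(rep(m[, "alpha"], length(tc$L)), nrow = S)
  if (info$use_size) {
    B <- m[, paste0("beta[", 1:4, "]")]
    eta <- eta + B[, tc$L] * matrix(tc$d, nrow = S, ncol = length(tc$d),
                                    byrow = TRUE)
  }
  if (info$use_surface) {
    G <- m[, paste0("gamma[", 1:4, "]")]
    eta <- eta + G[, tc$L] * matrix(tc$s, nrow = S, ncol = length(tc$s),
                                    byrow = TRUE)
  }
  if (info$use_mb) {
    dl <- if (info$delta_hier) m[, paste0("delta[", 1:4, "]")][, tc$L]
          else matrix(m[, "delta"], nrow = S, ncol = length(tc$L))
    ep <- matrix(m[, "epsilon"], nrow = S, ncol = length(tc$L))
    w0 <- matrix((1 - tc$R) * tc$m, nrow = S, ncol = length(tc$L), byrow = TRUE)
    w1 <- matrix(tc$R * tc$m, nrow = S, ncol = length(tc$L), byrow = TRUE)
    eta <- eta + dl * w0 + ep * w1
  }
  exp(eta)
}

#' Trace, rank and energy plots
#'
#' @param x A `gist_fit`.
#' @param type `"trace"`, `"rank"` or `"energy"`.
#' @param parameters Parameter names (defaults to the first six).
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.gist_fit <- function(x, type = c("trace", "rank", "energy"),
                          parameters = NULL, ...) {
  type <- match.arg(type)
  a <- x$draws_array
  pars <- parameters %||% utils::head(dimnames(a)[[3]], 6)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (type == "energy") {
    graphics::par(mfrow = c(1, 1))
    graphics::matplot(x$energy, type = "l", lty = 1,
                      xlab = "iteration", ylab = "Hamiltonian energy", ...)
    return(invisible(x))
  }
  graphics::par(mfrow = c(ceiling(length(pars) / 2), 2), mar = c(3, 3, 2, 1))
  for (p in pars) {
    m <- matrix(a[, , p], nrow = dim(a)[1])
    if (type == "trace") {
      graphics::matplot(m, type = "l", lty = 1, main = p,
                        xlab = "", ylab = "", ...)
    } else {
      rc <- rank_counts(x, p)
      graphics::barplot(t(rc), beside = TRUE, main = p, border = NA,
                        xlab = "rank bin", ylab = "count", ...)
    }
  }
  invisible(x)
}
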