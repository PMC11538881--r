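## Internal: build the unconstrained log-posterior, its gradient, and the
## bookkeeping needed by the sampler for one model variant.
##
## The unconstrained vector theta concatenates, in layout order: the
## intercept; site-level coefficient blocks (either the coefficients
## themselves, centered, or their standard-normal deviates z, noncentered);
## hyper-means; and log hierarchical scales (sampled on the log scale, with
## the Jacobian term included so the exponential prior applies to the scale
## itself).
make_posterior <- function(variant, data, priors, transform,
                           parameterization = c("noncentered", "centered")) {
  info <- variant_info(variant)
  parameterization <- match.arg(parameterization)
  nc <- parameterization == "noncentered" && info$hier
  y <- data$specimen_mitoses
  if (anyNA(y)) {
    stop("records without specimen_mitoses: rows ",
         paste(which(is.na(y)), collapse = ", "), call. = FALSE)
  }
  if (!is_fitted_transform(transform)) {
    stop("transform has not been fitted", call. = FALSE)
  }
  tc <- apply_transform(transform, data)
  n <- length(y)
  idx <- lapply(1:4, function(l) which(tc$L == l))
  lgam_y <- lgamma(y + 1)
  w_noresp <- (1 - tc$R) * tc$m   # multiplies the delta arm
  w_resp <- tc$R * tc$m           # multiplies the epsilon arm

  lay <- list(); pos <- 0L
  add <- function(name, k) {
    lay[[name]] <<- pos + seq_len(k)
    pos <<- pos + as.integer(k)
  }
  add("alpha", 1)
  if (info$use_size) { add("beta", 4); add("mu_beta", 1); add("lsigma_beta", 1) }
  if (info$use_surface) {
    add("gamma", 4)
    if (info$hier) { add("mu_gamma", 1); add("lsigma_gamma", 1) }
  }
  if (info$use_mb) {
    if (info$delta_hier) {
      add("delta", 4); add("mu_delta", 1); add("lsigma_delta", 1)
    } else {
      add("delta", 1)
    }
    add("epsilon", 1)
  }
  n_par <- pos

  par_names <- local({
    nm <- character(0)
    for (b in names(lay)) {
      k <- length(lay[[b]])
      nm <- c(nm, if (k == 1) b else paste0(b, "[", seq_len(k), "]"))
    }
    nm
  })

  ## Map theta to the constrained coefficient values used by the likelihood.
  constrain <- function(theta) {
    p <- list(alpha = theta[lay$alpha])
    if (info$use_size) {
      p$mu_beta <- theta[lay$mu_beta]
      p$sigma_beta <- exp(theta[lay$lsigma_beta])
      p$beta <- if (nc) p$mu_beta + p$sigma_beta * theta[lay$beta]
                else theta[lay$beta]
    }
    if (info$use_surface) {
      if (info$hier) {
        p$mu_gamma <- theta[lay$mu_gamma]
        p$sigma_gamma <- exp(theta[lay$lsigma_gamma])
        p$gamma <- if (nc) p$mu_gamma + p$sigma_gamma * theta[lay$gamma]
                   else theta[lay$gamma]
      } else {
        p$gamma <- theta[lay$gamma]
      }
    }
    if (info$use_mb) {
      if (info$delta_hier) {
        p$mu_delta <- theta[lay$mu_delta]
        p$sigma_delta <- exp(theta[lay$lsigma_delta])
        p$delta <- if (nc) p$mu_delta + p$sigma_delta * theta[lay$delta]
                   else theta[lay$delta]
      } else {
        p$delta <- theta[lay$delta]
      }
      p$epsilon <- theta[lay$epsilon]
    }
    p
  }

  eta_of <- function(p) {
    eta <- rep(p$alpha, n)
    if (info$use_size) eta <- eta + p$beta[tc$L] * tc$d
    if (info$use_surface) eta <- eta + p$gamma[tc$L] * tc$s
    if (info$use_mb) {
      dl <- if (info$delta_hier) p$delta[tc$L] else p$delta
      eta <- eta + w_noresp * dl + w_resp * p$epsilon
    }
    eta
  }

  bad <- list(lp = -Inf, grad = NULL)

  ## Gradient contributions of one hierarchical block. gb = likelihood
  ## gradient w.r.t. the constrained coefficients b (length 4).
  hier_block <- function(theta, slot_b, slot_mu, slot_ls, hp_mu, rate,
                         gb, g, lp) {
    mu <- theta[slot_mu]; u <- theta[slot_ls]; sig <- exp(u)
    if (nc) {
      z <- theta[slot_b]
      lp <- lp + sum(stats::dnorm(z, log = TRUE))
      g[slot_b] <- gb * sig - z
      g[slot_mu] <- sum(gb) - (mu - hp_mu[1]) / hp_mu[2]^2
      g[slot_ls] <- sum(gb * z) * sig - rate * sig + 1
    } else {
      b <- theta[slot_b]
      lp <- lp + sum(stats::dnorm(b, mu, sig, log = TRUE))
      g[slot_b] <- gb - (b - mu) / sig^2
      g[slot_mu] <- sum(b - mu) / sig^2 - (mu - hp_mu[1]) / hp_mu[2]^2
      g[slot_ls] <- sum((b - mu)^2 / sig^2 - 1) - rate * sig + 1
    }
    lp <- lp + stats::dnorm(mu, hp_mu[1], hp_mu[2], log = TRUE) +
      stats::dexp(sig, rate, log = TRUE) + u
    list(lp = lp, g = g)
  }

  lp_grad <- function(theta) {
    p <- constrain(theta)
    eta <- eta_of(p)
    if (any(eta > 500)) return(bad)
    lambda <- exp(eta)
    r <- y - lambda
    lp <- sum(y * eta - lambda - lgam_y)
    if (!is.finite(lp)) return(bad)
    g <- numeric(n_par)
    g[lay$alpha] <- sum(r) - (p$alpha - priors$alpha[1]) / priors$alpha[2]^2
    lp <- lp + stats::dnorm(p$alpha, priors$alpha[1], priors$alpha[2],
                            log = TRUE)
    if (info$use_size) {
      gb <- vapply(1:4, function(l) sum(r[idx[[l]]] * tc$d[idx[[l]]]),
                   numeric(1))
      res <- hier_block(theta, lay$beta, lay$mu_beta, lay$lsigma_beta,
                        priors$mu_beta, priors$sigma_beta, gb, g, lp)
      g <- res$g; lp <- res$lp
    }
    if (info$use_surface) {
      gg <- vapply(1:4, function(l) sum(r[idx[[l]]] * tc$s[idx[[l]]]),
                   numeric(1))
      if (info$hier) {
        res <- hier_block(theta, lay$gamma, lay$mu_gamma, lay$lsigma_gamma,
                          priors$mu_gamma, priors$sigma_gamma, gg, g, lp)
        g <- res$g; lp <- res$lp
      } else {
        gm <- theta[lay$gamma]
        lp <- lp + sum(stats::dnorm(gm, priors$flat_coef[1],
                                    priors$flat_coef[2], log = TRUE))
        g[lay$gamma] <- gg - (gm - priors$flat_coef[1]) / priors$flat_coef[2]^2
      }
    }
    if (info$use_mb) {
      if (info$delta_hier) {
        gd <- vapply(1:4, function(l) sum(r[idx[[l]]] * w_noresp[idx[[l]]]),
                     numeric(1))
        res <- hier_block(theta, lay$delta, lay$mu_delta, lay$lsigma_delta,
                          priors$mu_delta, priors$sigma_delta, gd, g, lp)
        g <- res$g; lp <- res$lp
      } else {
        dl <- theta[lay$delta]
        lp <- lp + stats::dnorm(dl, priors$delta[1], priors$delta[2],
                                log = TRUE)
        g[lay$delta] <- sum(r * w_noresp) -
          (dl - priors$delta[1]) / priors$delta[2]^2
      }
      ep <- theta[lay$epsilon]
      lp <- lp + stats::dnorm(ep, priors$epsilon[1], priors$epsilon[2],
                              log = TRUE)
      g[lay$epsilon] <- sum(r * w_resp) -
        (ep - priors$epsilon[1]) / priors$epsilon[2]^2
    }
    if (!is.finite(lp) || !all(is.finite(g))) return(bad)
    list(lp = lp, grad = g)
  }

  ## Constrained draw as a named vector (canonical parameter names).
  unpack <- function(theta) {
    p <- constrain(theta)
    out <- c(alpha = unname(p$alpha))
    if (info$use_size) {
      out <- c(out, stats::setNames(p$beta, paste0("beta[", 1:4, "]")),
               mu_beta = unname(p$mu_beta), sigma_beta = unname(p$sigma_beta))
    }
    if (info$use_surface) {
      out <- c(out, stats::setNames(p$gamma, paste0("gamma[", 1:4, "]")))
      if (info$hier) {
        out <- c(out, mu_gamma = unname(p$mu_gamma),
                 sigma_gamma = unname(p$sigma_gamma))
      }
    }
    if (info$use_mb) {
      if (info$delta_hier) {
        out <- c(out, stats::setNames(p$delta, paste0("delta[", 1:4, "]")),
                 mu_delta = unname(p$mu_delta),
                 sigma_delta = unname(p$sigma_delta))
      } else {
        out <- c(out, delta = unname(p$delta))
      }
      out <- c(out, epsilon = unname(p$epsilon))
    }
    out
  }

  loglik_point <- function(theta) {
    p <- constrain(theta)
    eta <- pmin(eta_of(p), 500)
    stats::dpois(y, exp(eta), log = TRUE)
  }

  init <- function() {
    theta <- stats::rnorm(n_par, 0, 0.1)
    theta[lay$alpha] <- log(mean(y) + 0.1) + stats::rnorm(1, 0, 0.1)
    for (s in c("lsigma_beta", "lsigma_gamma", "lsigma_delta")) {
      if (!is.null(lay[[s]])) theta[lay[[s]]] <- log(0.3) + stats::rnorm(1, 0, 0.1)
    }
    if (!nc && info$hier) {
      ## centered: start coefficients at their (jittered) hyper-means
      if (!is.null(lay$beta)) theta[lay$beta] <- theta[lay$mu_beta] + stats::rnorm(4, 0, 0.05)
      if (!is.null(lay$gamma) && !is.null(lay$mu_gamma)) {
        theta[lay$gamma] <- theta[lay$mu_gamma] + stats::rnorm(4, 0, 0.05)
      }
      if (!is.null(lay$mu_delta)) theta[lay$delta] <- theta[lay$mu_delta] + stats::rnorm(4, 0, 0.05)
    }
    theta
  }

  list(lp_grad = lp_grad, unpack = unpack, loglik = loglik_point,
       init = init, n_par = n_par, par_names = par_names, layout = lay,
       info = info, parameterization = if (nc) "noncentered" else "centered",
       n_records = n)
}
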