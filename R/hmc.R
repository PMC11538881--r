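## Internal: adaptive Hamiltonian Monte Carlo.
##
## One chain: leapfrog integration with a jittered number of steps (uniform
## on 1..max_leapfrog, which breaks trajectory-length resonance), dual-
## averaging step-size adaptation toward a target acceptance statistic, and
## diagonal mass-matrix estimation from a middle warmup window. Transitions
## whose Hamiltonian error exceeds `div_threshold` (or turns non-finite) are
## flagged divergent, as in Stan.
hmc_chain <- function(lp_grad, init, warmup, draws, target_accept = 0.9,
                      max_leapfrog = 32, div_threshold = 1000) {
  theta <- init
  cur <- lp_grad(theta)
  tries <- 0
  while (!is.finite(cur$lp) && tries < 100) {
    theta <- init * 0.5 + stats::rnorm(length(init), 0, 0.05)
    cur <- lp_grad(theta)
    tries <- tries + 1
  }
  if (!is.finite(cur$lp)) stop("could not find a finite starting point")
  n_par <- length(theta)
  inv_mass <- rep(1, n_par)   # estimated posterior variances

  leapfrog <- function(theta, p, eps, L, cur) {
    ## returns end state + whether the trajectory diverged
    H0 <- -cur$lp + 0.5 * sum(p^2 * inv_mass)
    g <- cur$grad
    divergent <- FALSE
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      theta <- theta + eps * p * inv_mass
      nxt <- lp_grad(theta)
      if (!is.finite(nxt$lp)) { divergent <- TRUE; break }
      g <- nxt$grad
      p <- p + 0.5 * eps * g
      H <- -nxt$lp + 0.5 * sum(p^2 * inv_mass)
      if (!is.finite(H) || H - H0 > div_threshold) { divergent <- TRUE; break }
    }
    if (divergent) {
      list(theta = theta, lp = -Inf, grad = NULL, H = Inf, H0 = H0,
           divergent = TRUE)
    } else {
      list(theta = theta, lp = nxt$lp, grad = g, H = H, H0 = H0,
           divergent = FALSE)
    }
  }

  find_eps <- function(theta, cur) {
    eps <- 0.1
    p <- stats::rnorm(n_par, 0, sqrt(1 / inv_mass))
    step <- leapfrog(theta, p, eps, 1L, cur)
    a <- if (is.finite(step$H)) exp(step$H0 - step$H) else 0
    dir <- if (a > 0.5) 1 else -1
    for (i in 1:40) {
      eps <- eps * 2^dir
      step <- leapfrog(theta, p, eps, 1L, cur)
      a <- if (is.finite(step$H)) exp(step$H0 - step$H) else 0
      if ((dir == 1 && a < 0.5) || (dir == -1 && a > 0.5)) break
    }
    eps
  }

  ## dual averaging state
  eps <- find_eps(theta, cur)
  da_mu <- log(10 * eps); da_h <- 0; da_leps_bar <- log(eps); da_count <- 0
  da_reset <- function() {
    da_mu <<- log(10 * eps); da_h <<- 0; da_leps_bar <<- log(eps)
    da_count <<- 0
  }
  da_update <- function(accept) {
    da_count <<- da_count + 1
    da_h <<- (1 - 1 / (da_count + 10)) * da_h +
      (target_accept - accept) / (da_count + 10)
    leps <- da_mu - sqrt(da_count) / 0.05 * da_h
    w <- da_count^(-0.75)
    da_leps_bar <<- w * leps + (1 - w) * da_leps_bar
    eps <<- exp(leps)
  }

  mass_lo <- max(1L, floor(0.35 * warmup))
  mass_hi <- floor(0.85 * warmup)
  mass_buf <- matrix(NA_real_, nrow = max(0L, mass_hi - mass_lo + 1L),
                     ncol = n_par)

  total <- warmup + draws
  out_theta <- matrix(NA_real_, nrow = draws, ncol = n_par)
  out_lp <- numeric(draws)
  out_energy <- numeric(draws)
  out_accept <- numeric(draws)
  divergences <- 0L

  for (i in seq_len(total)) {
    p <- stats::rnorm(n_par, 0, sqrt(1 / inv_mass))
    L <- sample.int(max_leapfrog, 1L)
    step <- leapfrog(theta, p, eps, L, cur)
    accept <- if (is.finite(step$H)) min(1, exp(step$H0 - step$H)) else 0
    if (stats::runif(1) < accept && !step$divergent) {
      theta <- step$theta
      cur <- list(lp = step$lp, grad = step$grad)
    }
    if (i <= warmup) {
      da_update(accept)
      if (i >= mass_lo && i <= mass_hi) mass_buf[i - mass_lo + 1L, ] <- theta
      if (i == mass_hi && nrow(mass_buf) >= 10) {
        v <- apply(mass_buf, 2, stats::var)
        nw <- nrow(mass_buf)
        inv_mass <- (nw / (nw + 5)) * v + (5 / (nw + 5)) * 1e-3
        inv_mass[!is.finite(inv_mass) | inv_mass <= 0] <- 1e-3
        eps <- find_eps(theta, cur)
        da_reset()
      }
      if (i == warmup) eps <- exp(da_leps_bar)
    } else {
      j <- i - warmup
      out_theta[j, ] <- theta
      out_lp[j] <- cur$lp
      out_energy[j] <- step$H0
      out_accept[j] <- accept
      if (step$divergent) divergences <- divergences + 1L
    }
  }

  list(theta = out_theta, lp = out_lp, energy = out_energy,
       accept = out_accept, divergences = divergences, step_size = eps)
}

## Multi-chain driver; chain c uses seed + c - 1.
hmc_sample <- function(post, chains, warmup, draws, seed,
                       target_accept = 0.9, max_leapfrog = 32) {
  res <- vector("list", chains)
  for (c in seq_len(chains)) {
    set.seed(as.integer(seed) + c - 1L)
    res[[c]] <- hmc_chain(post$lp_grad, post$init(), warmup, draws,
                          target_accept = target_accept,
                          max_leapfrog = max_leapfrog)
  }
  res
}
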