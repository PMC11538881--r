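#' Convergence diagnostics
#'
#' Rank-normalized split R-hat and bulk effective sample size. Chains are
#' split in half, pooled draws are rank-normalized through the inverse
#' normal transform, and the classic between/within-chain variance ratio is
#' computed on the transformed draws; the reported R-hat is the maximum of
#' the bulk statistic and the same statistic on folded (median-absolute)
#' draws, so both location and scale mixing failures are caught. This is the
#' modern definition, not the original Gelman-Rubin ratio. ESS combines
#' chain autocorrelations with Geyer's initial monotone positive sequence.
#'
#' @param x Numeric matrix of posterior draws, iterations x chains.
#' @return `rhat()`: scalar; `ess_bulk()`: scalar effective sample size.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(NA_real_)
  xs <- split_chains(x)
  max(rhat_basic(z_scale(xs)),
      rhat_basic(z_scale(abs(xs - stats::median(xs)))))
}

#' @rdname rhat
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  ess_basic(z_scale(split_chains(x)))
}

split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

## Rank-normalization (inverse-normal transform of average ranks).
z_scale <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

rhat_basic <- function(x) {
  n <- nrow(x)
  if (n < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w == 0) {
    ## constant chains: identical constants give NA, differing give Inf
    return(if (is.finite(b) && b > 0) Inf else NA_real_)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 3) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  w <- mean(vars)
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- if (m > 1) n * stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * w + b / n
  ## mean autocovariance across chains at each lag
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- rowMeans(as.matrix(acov))
  rho <- 1 - (w - acov) / var_plus   # rho[1] is lag 0
  ## Geyer pairs (lag 0+1, 2+3, ...): truncate at the first non-positive
  ## pair and enforce a monotone non-increasing sequence.
  tau <- -1
  prev_pair <- Inf
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    k <- k + 2
  }
  s <- n * m
  if (tau <= 0) return(s * log10(max(s, 10)))
  min(s / tau, s * log10(max(s, 10)))
}

## Energy-Bayesian-fraction-of-missing-information per chain.
ebfmi <- function(energy) {
  apply(as.matrix(energy), 2, function(e) {
    if (length(e) < 3 || stats::var(e) == 0) return(NA_real_)
    mean(diff(e)^2) / stats::var(e)
  })
}

#' Sampler diagnostics report
#'
#' Per-parameter rank-normalized split R-hat and bulk effective sample
#' size, post-warmup divergence counts, and the Hamiltonian energy summary
#' (E-BFMI per chain; values below 0.2 indicate poor energy exploration).
#' The fit is flagged as suspect if any R-hat exceeds `rhat_max`, any ESS
#' falls below `ess_min`, or any chain's E-BFMI is below 0.2.
#'
#' @param fit A [gist_fit()] object.
#' @param rhat_max,ess_min Flagging thresholds.
#' @return A list of class `"gist_diagnostics"`: `parameters` (data frame),
#'   `divergences` (per chain), `ebfmi` (per chain), `ok` (logical),
#'   `flags` (character).
#' @export
mcmc_diagnostics <- function(fit, rhat_max = 1.01, ess_min = 100) {
  stopifnot(inherits(fit, "gist_fit"))
  a <- fit$draws_array
  pars <- dimnames(a)[[3]]
  tab <- data.frame(
    parameter = pars,
    mean = NA_real_, sd = NA_real_, rhat = NA_real_, ess_bulk = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(pars)) {
    m <- a[, , k, drop = TRUE]
    m <- matrix(m, nrow = dim(a)[1])
    tab$mean[k] <- mean(m)
    tab$sd[k] <- stats::sd(as.vector(m))
    tab$rhat[k] <- rhat(m)
    tab$ess_bulk[k] <- ess_bulk(m)
  }
  e <- ebfmi(fit$energy)
  flags <- character(0)
  if (dim(a)[2] < 2) {
    flags <- c(flags, "single chain: R-hat unavailable")
  } else {
    if (any(!is.finite(tab$rhat))) {
      flags <- c(flags, "degenerate chains: R-hat/ESS undefined for some parameters")
    }
    if (any(tab$rhat > rhat_max, na.rm = TRUE)) {
      flags <- c(flags, sprintf("R-hat > %g for: %s", rhat_max,
                                paste(tab$parameter[which(tab$rhat > rhat_max)],
                                      collapse = ", ")))
    }
  }
  if (any(tab$ess_bulk < ess_min, na.rm = TRUE) || any(!is.finite(tab$ess_bulk))) {
    flags <- c(flags, sprintf("low or undefined ESS (< %g)", ess_min))
  }
  if (sum(fit$divergences) > 0) {
    flags <- c(flags, sprintf("%d divergent transitions", sum(fit$divergences)))
  }
  if (any(e < 0.2, na.rm = TRUE)) flags <- c(flags, "E-BFMI < 0.2")
  out <- list(parameters = tab, divergences = fit$divergences, ebfmi = e,
              ok = length(flags) == 0, flags = flags)
  class(out) <- "gist_diagnostics"
  out
}

#' @export
print.gist_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics\n")
  print(transform(x$parameters,
                  mean = round(mean, 3), sd = round(sd, 3),
                  rhat = round(rhat, 4), ess_bulk = round(ess_bulk)),
        row.names = FALSE)
  cat(sprintf("divergences per chain: %s\n",
              paste(x$divergences, collapse = ", ")))
  cat(sprintf("E-BFMI per chain: %s\n",
              paste(sprintf("%.2f", x$ebfmi), collapse = ", ")))
  if (x$ok) cat("no convergence flags\n") else {
    cat("FLAGS:\n"); for (f in x$flags) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Rank-plot data
#'
#' Within-chain histogram counts of the pooled-draw ranks of one parameter
#' ("trankplot" data): for well-mixed chains the rank histograms are close
#' to uniform.
#'
#' @param fit A [gist_fit()] object.
#' @param parameter Parameter name.
#' @param bins Number of rank bins.
#' @return Matrix of counts, bins x chains.
#' @export
rank_counts <- function(fit, parameter, bins = 20) {
  a <- fit$draws_array
  stopifnot(parameter %in% dimnames(a)[[3]])
  m <- matrix(a[, , parameter], nrow = dim(a)[1])
  r <- matrix(rank(as.vector(m), ties.method = "average"), nrow = nrow(m))
  edges <- seq(0, length(r), length.out = bins + 1)
  apply(r, 2, function(col) {
    tabulate(findInterval(col, edges, rightmost.closed = TRUE), nbins = bins)
  })
}
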