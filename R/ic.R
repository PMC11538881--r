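log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

get_loglik <- function(x) {
  if (inherits(x, "gist_fit")) x$loglik
  else as.matrix(x)
}

new_ic <- function(method, pointwise, p_point, pareto_k = NULL,
                   lpd_point = NULL, flags = character(0)) {
  n <- length(pointwise)
  elpd <- sum(pointwise)
  out <- list(method = method,
              elpd = elpd,
              p_eff = sum(p_point),
              deviance = -2 * elpd,
              se = sqrt(n * stats::var(pointwise)),
              pointwise = pointwise,
              p_pointwise = p_point,
              lpd_pointwise = lpd_point,
              pareto_k = pareto_k,
              n = n,
              flags = flags)
  class(out) <- "gist_ic"
  out
}

#' Widely applicable information criterion
#'
#' Out-of-sample deviance estimate computed from the pointwise
#' log-likelihood matrix: per record, the log of the mean posterior
#' likelihood (lppd) penalized by the posterior variance of the
#' log-likelihood, \eqn{\widehat{elpd}_i = \mathrm{lppd}_i - p_i}. The
#' headline scale is the deviance \eqn{-2\,\widehat{elpd}}; smaller is
#' better.
#'
#' @param x A `gist_fit` or a draws x records log-likelihood matrix.
#' @return An object of class `"gist_ic"`.
#' @export
waic <- function(x) {
  ll <- get_loglik(x)
  if (anyNA(ll) || any(!is.finite(ll))) {
    stop("log-likelihood matrix contains NA or non-finite values",
         call. = FALSE)
  }
  s <- nrow(ll)
  lppd <- apply(ll, 2, log_sum_exp) - log(s)
  p <- apply(ll, 2, stats::var)
  new_ic("waic", pointwise = lppd - p, p_point = p, lpd_point = lppd)
}

#' PSIS-LOO cross-validation
#'
#' Leave-one-out cross-validation approximated by Pareto-smoothed
#' importance sampling: per record the raw importance ratios
#' \eqn{r_s = 1/p(y_i \mid \theta_s)} are tail-stabilized by replacing the
#' largest \eqn{\min(0.2 S, 3\sqrt{S})} with expected order statistics of a
#' generalized Pareto distribution fitted to them (Zhang-Stephens
#' estimator), truncated at the raw maximum. The fitted tail index \eqn{\hat k} is reported per record:
#' values above 0.7 mean the importance-sampling estimate for that record
#' is unreliable. With fewer than 5 tail draws, plain truncated importance
#' sampling is used and flagged.
#'
#' @inheritParams waic
#' @param tail_frac Fraction of draws treated as the weight tail.
#' @return An object of class `"gist_ic"` with per-record `pareto_k`.
#' @export
psis_loo <- function(x, tail_frac = 0.2) {
  ll <- get_loglik(x)
  if (anyNA(ll) || any(!is.finite(ll))) {
    stop("log-likelihood matrix contains NA or non-finite values",
         call. = FALSE)
  }
  s <- nrow(ll)
  n <- ncol(ll)
  lppd <- apply(ll, 2, log_sum_exp) - log(s)
  pointwise <- numeric(n)
  k_hat <- rep(NA_real_, n)
  flags <- character(0)
  ## published tail-size recommendation: at most 20% of draws, capped at
  ## 3*sqrt(S) for large S
  m_tail <- ceiling(min(tail_frac * s, 3 * sqrt(s)))
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    r <- exp(lw)
    if (m_tail >= 5 && stats::sd(r) > 0) {
      ord <- order(r)
      tail_ids <- ord[(s - m_tail + 1):s]
      cut <- r[ord[s - m_tail]]
      exceed <- r[tail_ids] - cut
      gp <- gpd_fit(exceed)
      if (is.finite(gp$k)) {
        k_hat[i] <- gp$k
        probs <- (seq_len(m_tail) - 0.5) / m_tail
        smoothed <- cut + qgpd(probs, gp$k, gp$sigma)
        r[tail_ids[order(r[tail_ids])]] <- pmin(smoothed, max(r))
      }
    }
    lw_s <- log(r)
    pointwise[i] <- log_sum_exp(lw_s + ll[, i]) - log_sum_exp(lw_s)
  }
  if (m_tail < 5) {
    flags <- c(flags, "fewer than 5 tail draws: truncated importance sampling only")
  }
  if (any(k_hat > 0.7, na.rm = TRUE)) {
    flags <- c(flags, sprintf("%d record(s) with Pareto k > 0.7",
                              sum(k_hat > 0.7, na.rm = TRUE)))
  }
  new_ic("psis_loo", pointwise = pointwise, p_point = lppd - pointwise,
         pareto_k = k_hat, lpd_point = lppd, flags = flags)
}

## Generalized Pareto fit to exceedances (Zhang & Stephens 2009 empirical
## Bayes estimator). Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior_bs * xstar)
  k_of <- function(th) mean(log1p(-th * x))
  prof <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(-th / k) - k - 1)
  }, numeric(1))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  list(k = k, sigma = -k / theta_hat)
}

## Generalized Pareto quantile function (shape k, scale sigma).
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' @export
print.gist_ic <- function(x, ...) {
  cat(sprintf("%s: elpd = %.2f (se %.2f), p_eff = %.2f, deviance = %.2f (n = %d)\n",
              toupper(x$method), x$elpd, x$se, x$p_eff, x$deviance, x$n))
  if (!is.null(x$pareto_k) && any(is.finite(x$pareto_k))) {
    cat(sprintf("Pareto k: max %.2f; %d record(s) > 0.7\n",
                max(x$pareto_k, na.rm = TRUE),
                sum(x$pareto_k > 0.7, na.rm = TRUE)))
  }
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}

#' Compare model variants by out-of-sample deviance
#'
#' Sorts fitted variants by estimated out-of-sample deviance (−2 elpd),
#' with the standard error of each difference from the best model computed
#' from paired pointwise contributions, an 89% interval on each deviance,
#' and the in-sample deviance (−2 sum of lppd) alongside.
#'
#' @param ... Named `gist_ic` objects (or a single named list of them),
#'   all computed on the same records.
#' @return A data frame of class `"gist_compare"`, best model first.
#' @export
compare_models <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) &&
      !inherits(dots[[1]], "gist_ic")) {
    dots <- dots[[1]]
  }
  stopifnot(length(dots) >= 1, all(vapply(dots, inherits, logical(1), "gist_ic")))
  if (is.null(names(dots)) || any(names(dots) == "")) {
    names(dots) <- paste0("model", seq_along(dots))
  }
  ns <- vapply(dots, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) {
    stop("criteria computed on different numbers of records", call. = FALSE)
  }
  n <- ns[1]
  z89 <- stats::qnorm(1 - (1 - 0.89) / 2)
  tab <- data.frame(
    model = names(dots),
    elpd = vapply(dots, `[[`, numeric(1), "elpd"),
    se = vapply(dots, `[[`, numeric(1), "se"),
    p_eff = vapply(dots, `[[`, numeric(1), "p_eff"),
    deviance = vapply(dots, `[[`, numeric(1), "deviance"),
    deviance_in = vapply(dots, function(ic) {
      if (is.null(ic$lpd_pointwise)) NA_real_ else -2 * sum(ic$lpd_pointwise)
    }, numeric(1)),
    row.names = NULL
  )
  tab$dev_lo89 <- tab$deviance - z89 * 2 * tab$se
  tab$dev_hi89 <- tab$deviance + z89 * 2 * tab$se
  tab <- tab[order(tab$deviance), ]
  best <- dots[[tab$model[1]]]
  tab$d_elpd <- tab$elpd - best$elpd
  tab$se_diff <- vapply(tab$model, function(nm) {
    d <- best$pointwise - dots[[nm]]$pointwise
    sqrt(n * stats::var(d))
  }, numeric(1))
  rownames(tab) <- NULL
  class(tab) <- c("gist_compare", "data.frame")
  tab
}

#' @export
print.gist_compare <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Deviance comparison plot
#'
#' Dot-whisker display of the model comparison: filled dots are in-sample
#' deviance, open dots the out-of-sample estimate with its 89% interval,
#' and the vertical line marks the best model's deviance.
#'
#' @param x A `gist_compare` table.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gist_compare <- function(x, ...) {
  k <- nrow(x)
  yy <- rev(seq_len(k))
  rng <- range(c(x$dev_lo89, x$dev_hi89, x$deviance_in), na.rm = TRUE)
  graphics::plot(x$deviance, yy, pch = 1, xlim = rng, ylim = c(0.5, k + 0.5),
                 yaxt = "n", xlab = "deviance", ylab = "", ...)
  graphics::axis(2, at = yy, labels = x$model, las = 1)
  graphics::segments(x$dev_lo89, yy, x$dev_hi89, yy)
  graphics::points(x$deviance_in, yy, pch = 16)
  graphics::abline(v = x$deviance[1], lty = 2)
  invisible(x)
}
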