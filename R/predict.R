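#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested mass: over the
#' sorted sample, every window of \eqn{\lceil mass \cdot n \rceil} draws is
#' considered and the narrowest returned (ties resolved in favor of the
#' first, lowest window).
#'
#' @param samples Numeric vector of draws.
#' @param mass Interval mass, in (0, 1); defaults to 0.89.
#' @return Numeric `c(lo, hi)`.
#' @export
hdpi <- function(samples, mass = 0.89) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("empty sample", call. = FALSE)
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  n <- length(x)
  k <- min(n, max(1L, ceiling(mass * n)))
  if (k == n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- starts[which.min(widths)]
  c(x[i], x[i + k - 1])
}

#' Posterior predictive distribution of the specimen count
#'
#' For a new tumor described by site, size, biopsy surface and biopsy
#' mitotic count, averages the Poisson pmf over the posterior rate draws:
#' \eqn{p(k) = \frac{1}{S}\sum_s \mathrm{Pois}(k \mid \lambda_s)}. The
#' response arm is always evaluated with the no-response coefficient
#' \eqn{\delta}: the response coefficient is identified from treated cases
#' during fitting but deliberately not used for forecasting. The pmf is
#' truncated at `support_max` and renormalized; if the truncated tail held
#' more than 1e-3 of mass, a warning is recorded on the object.
#'
#' @param object A [gist_fit()].
#' @param newdata A `gist_data` (or data frame with the cohort columns) of
#'   new tumors; specimen counts are ignored.
#' @param support_max Largest count in the returned support.
#' @param mass Mass of the reported HDPI on the rate.
#' @param band_mass Mass captured by the modal count band.
#' @param ... Unused.
#' @return A `"gist_pred"` object for one record, or a list of them.
#' @export
predict.gist_fit <- function(object, newdata, support_max = 200,
                             mass = 0.89, band_mass = 0.5, ...) {
  if (!inherits(newdata, "gist_data")) {
    newdata <- gist_data(site = newdata$site, size_mm = newdata$size_mm,
                         surface_mm2 = newdata$surface_mm2,
                         biopsy_mitoses = newdata$biopsy_mitoses,
                         response = newdata$response %||% FALSE)
  }
  lam <- lambda_draws(object, newdata, force_no_response = TRUE)
  preds <- lapply(seq_len(nrow(newdata)), function(i) {
    new_gist_pred(lam[, i], support_max = support_max, mass = mass,
                  band_mass = band_mass,
                  record = as.data.frame(newdata)[i, , drop = FALSE])
  })
  if (length(preds) == 1) preds[[1]] else preds
}

new_gist_pred <- function(lambda_samples, support_max = 200, mass = 0.89,
                          band_mass = 0.5, record = NULL) {
  support <- 0:support_max
  pmf <- rowMeans(outer(support, lambda_samples, stats::dpois))
  truncated <- max(0, 1 - sum(pmf))
  if (truncated > 1e-3) {
    warning(sprintf("truncated predictive mass %.2g above support_max = %d",
                    truncated, support_max), call. = FALSE)
  }
  pmf <- pmf / sum(pmf)
  out <- list(support = support, pmf = pmf,
              lambda_samples = lambda_samples,
              mean = sum(support * pmf),
              lambda_mean = mean(lambda_samples),
              lambda_hdpi = hdpi(lambda_samples, mass),
              modal_band = modal_band(pmf, band_mass),
              band_mass = band_mass,
              truncated_mass = truncated,
              record = record)
  class(out) <- "gist_pred"
  out
}

## Smallest set of consecutive counts reaching `mass` predictive mass.
modal_band <- function(pmf, mass = 0.5) {
  n <- length(pmf)
  cs <- c(0, cumsum(pmf))
  for (w in 1:n) {
    windows <- cs[(1 + w):(n + 1)] - cs[1:(n - w + 1)]
    if (max(windows) >= mass) {
      i <- which.max(windows)
      return(c(lo = i - 1, hi = i + w - 2))
    }
  }
  c(lo = 0, hi = n - 1)
}

#' @export
print.gist_pred <- function(x, ...) {
  cat("Posterior predictive specimen mitotic count (per 5 mm2)\n")
  if (!is.null(x$record)) {
    r <- x$record
    cat(sprintf("  input: %s, %.0f mm, %.2f mm2 biopsy, %d biopsy mitoses\n",
                r$site, r$size_mm, r$surface_mm2, r$biopsy_mitoses))
  }
  cat(sprintf("  predictive mean %.1f; rate HDPI 89%% [%.1f, %.1f]\n",
              x$mean, x$lambda_hdpi[1], x$lambda_hdpi[2]))
  cat(sprintf("  most probable counts: %d to %d (%.0f%% of mass)\n",
              x$modal_band[1], x$modal_band[2], 100 * x$band_mass))
  invisible(x)
}

#' @export
plot.gist_pred <- function(x, max_count = NULL, ...) {
  k <- max_count %||% max(20, x$modal_band[2] * 3)
  graphics::barplot(x$pmf[1:(k + 1)], names.arg = 0:k, border = NA,
                    xlab = "specimen mitoses / 5 mm2", ylab = "probability",
                    ...)
  invisible(x)
}

#' Retrodiction (posterior predictive check on the training data)
#'
#' Per training record: posterior mean and HDPI of the rate, an equal-tailed
#' predictive interval on the count (from the mixture-over-draws predictive
#' cdf, so the result is deterministic), the observed counts and a coverage
#' flag. For a well-specified model about `prob` of records should be
#' covered.
#'
#' @param fit A [gist_fit()].
#' @param prob Interval mass.
#' @return Data frame of class `"gist_retro"`, one row per record.
#' @export
retrodiction <- function(fit, prob = 0.89) {
  stopifnot(inherits(fit, "gist_fit"))
  data <- fit$data
  lam <- lambda_draws(fit, data)
  a <- (1 - prob) / 2
  n <- nrow(data)
  lo <- integer(n); hi <- integer(n)
  for (i in seq_len(n)) {
    kmax <- max(10, ceiling(stats::quantile(lam[, i], 0.999) * 3))
    cdf <- vapply(0:kmax, function(k) mean(stats::ppois(k, lam[, i])),
                  numeric(1))
    lo[i] <- match(TRUE, cdf >= a) - 1L
    hi[i] <- match(TRUE, cdf >= 1 - a) - 1L
  }
  hd <- t(apply(lam, 2, hdpi, mass = prob))
  out <- data.frame(
    site = data$site,
    size_mm = data$size_mm,
    surface_mm2 = data$surface_mm2,
    biopsy_mitoses = data$biopsy_mitoses,
    observed = data$specimen_mitoses,
    lambda_mean = colMeans(lam),
    lambda_lo = hd[, 1], lambda_hi = hd[, 2],
    pred_lo = lo, pred_hi = hi,
    covered = data$specimen_mitoses >= lo & data$specimen_mitoses <= hi
  )
  class(out) <- c("gist_retro", "data.frame")
  out
}

#' @export
plot.gist_retro <- function(x, log = "y", ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  eps <- 0.5
  for (s in levels(x$site)) {
    xi <- x[x$site == s, ]
    if (!nrow(xi)) next
    ord <- order(xi$lambda_mean)
    xi <- xi[ord, ]
    graphics::plot(seq_len(nrow(xi)), xi$lambda_mean + eps, log = log,
                   pch = 1, cex = 0.5 + xi$size_mm / max(x$size_mm),
                   xlab = "case (ordered)", ylab = "rate / count + 0.5",
                   main = s,
                   ylim = range(c(x$lambda_lo, x$lambda_hi, x$observed) + eps),
                   ...)
    graphics::segments(seq_len(nrow(xi)), xi$lambda_lo + eps,
                       seq_len(nrow(xi)), xi$lambda_hi + eps, col = "grey")
    graphics::points(seq_len(nrow(xi)), xi$observed + eps, pch = 4,
                     cex = 0.5 + xi$surface_mm2 / max(x$surface_mm2))
  }
  invisible(x)
}
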