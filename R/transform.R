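#' Covariate transforms
#'
#' The linear predictor works on transformed covariates; the transform is
#' fitted on the training cohort (so that e.g. z-scoring uses training
#' statistics) and stored with the fit, and predictions reuse it. Defaults:
#' tumor size is z-scored over the training cohort, biopsy surface enters
#' untransformed in mm2, and the biopsy count enters as `log1p(count)` so that
#' a coefficient of 1 means "specimen rate proportional to biopsy count".
#'
#' @param size One of `"zscore"` (default) or `"identity_cm"` (size/10, no
#'   centering).
#' @param surface One of `"identity"` (mm2, default) or `"zscore"`.
#' @param mb One of `"log1p"` (default, log1p of the raw biopsy count),
#'   `"log1p_rate"` (log1p of the count rescaled to a 5 mm2 rate), or
#'   `"raw"`.
#' @return An unfitted object of class `"covariate_transform"`; fit it with
#'   [fit_transform()].
#' @export
covariate_transform <- function(size = c("zscore", "identity_cm"),
                                surface = c("identity", "zscore"),
                                mb = c("log1p", "log1p_rate", "raw")) {
  structure(list(size = match.arg(size), surface = match.arg(surface),
                 mb = match.arg(mb), stats = NULL),
            class = "covariate_transform")
}

#' Fit a covariate transform on a training cohort
#'
#' @param transform A [covariate_transform()].
#' @param data A `gist_data` cohort.
#' @return The transform with training statistics attached.
#' @export
fit_transform <- function(transform, data) {
  stopifnot(inherits(transform, "covariate_transform"),
            inherits(data, "gist_data"))
  sd0 <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) 1 else s
  }
  transform$stats <- list(
    size_mean = mean(data$size_mm), size_sd = sd0(data$size_mm),
    surface_mean = mean(data$surface_mm2), surface_sd = sd0(data$surface_mm2)
  )
  transform
}

is_fitted_transform <- function(transform) {
  inherits(transform, "covariate_transform") && !is.null(transform$stats)
}

#' Apply a fitted transform
#'
#' @param transform A fitted [covariate_transform()].
#' @param data A `gist_data` cohort (training or new records).
#' @return A list with numeric vectors `d` (size), `s` (surface), `m`
#'   (biopsy count), and `R` (0/1 response indicator).
#' @export
apply_transform <- function(transform, data) {
  if (!is_fitted_transform(transform)) {
    stop("transform has not been fitted; call fit_transform() first",
         call. = FALSE)
  }
  st <- transform$stats
  d <- switch(transform$size,
              zscore = (data$size_mm - st$size_mean) / st$size_sd,
              identity_cm = data$size_mm / 10)
  s <- switch(transform$surface,
              identity = data$surface_mm2,
              zscore = (data$surface_mm2 - st$surface_mean) / st$surface_sd)
  m <- switch(transform$mb,
              log1p = log1p(data$biopsy_mitoses),
              log1p_rate = log1p(data$biopsy_mitoses * 5 / data$surface_mm2),
              raw = data$biopsy_mitoses)
  list(d = d, s = s, m = m, R = as.numeric(data$response),
       L = as.integer(data$site))
}
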