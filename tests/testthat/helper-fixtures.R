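# Shared fixtures. Fits are cached per test run so several test files can
# reuse the same small posterior without re-sampling.

.fixture_env <- new.env(parent = emptyenv())

# A "typical" parameter point used wherever a fixed, plausible truth is
# needed: moderate site-level size effects, mild negative surface effects,
# biopsy-count coefficient 1 on the log1p scale.
fixture_params <- function() {
  gist_params(alpha = 1,
              beta = c(0.2, 0.3, 0.4, 0.5),
              gamma = c(-0.1, -0.2, -0.1, -0.15),
              delta = 1, epsilon = -0.5,
              mu_beta = 0.35, sigma_beta = 0.15,
              mu_gamma = -0.15, sigma_gamma = 0.1)
}

fixture_cohort <- function(n = 100, seed = 11) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_gist_cohort(n, seed = seed,
                                                params = fixture_params())
  }
  .fixture_env[[key]]
}

# Convergent mock-data fit of the full model, shared across test files.
fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- gist_fit(fixture_cohort(), chains = 4,
                                 warmup = 500, draws = 500, seed = 2)
  }
  .fixture_env$fit
}

# Tiny well-formed CSV written to a temp file.
fixture_csv <- function(path = tempfile(fileext = ".csv"), surface_col = "surface_mm2") {
  header <- c("site", "size_mm", surface_col, "biopsy_mitoses", "response",
              "specimen_mitoses")
  rows <- c("stomach,72,3.0,3,FALSE,6",
            "2,40,2.5,1,FALSE,2",
            "small-intestine,35,1.2,0,TRUE,0")
  writeLines(c(paste(header, collapse = ","), rows), path)
  path
}
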