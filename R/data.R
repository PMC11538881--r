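#' Anatomical sites
#'
#' The model indexes the four anatomical sites of gastrointestinal stromal
#' tumors as 1 = colon-rectum, 2 = duodenum, 3 = small-intestine, 4 = stomach.
#' @return Character vector of the four site labels in index order.
#' @export
gist_sites <- function() {
  c("colon-rectum", "duodenum", "small-intestine", "stomach")
}

## Resolve a site given as label or index 1..4 to the canonical factor level.
## Returns NA_character_ for unresolvable input.
resolve_site <- function(x) {
  sites <- gist_sites()
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  idx <- suppressWarnings(as.integer(x))
  ok <- !is.na(idx) & idx >= 1 & idx <= 4
  out[ok] <- sites[idx[ok]]
  lab <- tolower(gsub("[ _]", "-", x))
  hit <- is.na(out) & lab %in% sites
  out[hit] <- lab[hit]
  out
}

#' Assemble and validate a GIST patient cohort
#'
#' Builds the canonical cohort data frame used throughout the package. Each
#' row is one tumor with the covariates available at biopsy time and,
#' for training data, the mitotic count on the surgical specimen.
#'
#' Units are canonical: tumor size in millimetres, biopsy surface in mm2
#' (use [hpf_to_mm2()] for surfaces reported in high-power fields), and
#' mitotic counts as raw non-negative integers. `specimen_mitoses` is the
#' count per 5 mm2 of specimen; it may be `NA` for records used only for
#' prediction. `response` flags tumors whose specimen count fell below the
#' biopsy count after neoadjuvant therapy; it routes the biopsy-count
#' coefficient onto a separate arm during fitting and must be `FALSE` for
#' untreated patients.
#'
#' @param site Site label (see [gist_sites()]) or index 1-4.
#' @param size_mm Tumor size in millimetres, positive.
#' @param surface_mm2 Biopsy surface examined, mm2, positive.
#' @param biopsy_mitoses Mitotic count observed on the biopsy surface,
#'   non-negative integer.
#' @param response Logical, response to neoadjuvant therapy.
#' @param specimen_mitoses Mitotic count per 5 mm2 on the surgical specimen,
#'   non-negative integer or `NA`.
#' @param provenance Free-text note on where the records came from.
#' @return A data frame of class `"gist_data"`.
#' @export
gist_data <- function(site, size_mm, surface_mm2, biopsy_mitoses,
                      response = FALSE, specimen_mitoses = NA_integer_,
                      provenance = "unspecified") {
  n <- length(site)
  df <- data.frame(
    site = factor(resolve_site(site), levels = gist_sites()),
    size_mm = as.numeric(size_mm),
    surface_mm2 = as.numeric(surface_mm2),
    biopsy_mitoses = as.numeric(biopsy_mitoses),
    response = rep_len(as.logical(response), n),
    specimen_mitoses = as.numeric(rep_len(specimen_mitoses, n)),
    stringsAsFactors = FALSE
  )
  validate_gist_data(df)
  structure(df, class = c("gist_data", "data.frame"), provenance = provenance)
}

## Per-row validation; stops with a message listing offending row numbers.
validate_gist_data <- function(df) {
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf("%s (rows %s)", what,
                                       paste(rows, collapse = ", ")))
    }
  }
  flag(is.na(df$site), "unknown or missing site")
  flag(!is.na(df$size_mm) & df$size_mm <= 0 | is.na(df$size_mm),
       "size_mm must be positive")
  flag(!is.na(df$surface_mm2) & df$surface_mm2 <= 0 | is.na(df$surface_mm2),
       "surface_mm2 must be positive")
  flag(is.na(df$biopsy_mitoses) | df$biopsy_mitoses < 0 |
         df$biopsy_mitoses != round(df$biopsy_mitoses),
       "biopsy_mitoses must be a non-negative integer")
  flag(!is.na(df$specimen_mitoses) &
         (df$specimen_mitoses < 0 | df$specimen_mitoses != round(df$specimen_mitoses)),
       "specimen_mitoses must be a non-negative integer")
  flag(is.na(df$response), "response must be TRUE/FALSE")
  if (length(problems)) {
    stop("invalid cohort: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  invisible(df)
}

#' Read a GIST cohort from CSV
#'
#' Expects a header with columns `site`, `size_mm`, `surface_mm2` (or
#' `surface_hpf`, converted through [hpf_to_mm2()]), `biopsy_mitoses`,
#' `response`, and optionally `specimen_mitoses`. Site accepts either the
#' labels from [gist_sites()] or indices 1-4.
#'
#' @param path Path to a CSV file.
#' @param hpf_per_5mm2 Microscope calibration used when the surface column is
#'   given in high-power fields.
#' @return A `gist_data` data frame.
#' @export
read_gist_csv <- function(path, hpf_per_5mm2 = 23.5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "size_mm", "biopsy_mitoses")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("surface_mm2" %in% names(raw)) {
    surface <- raw$surface_mm2
  } else if ("surface_hpf" %in% names(raw)) {
    surface <- hpf_to_mm2(raw$surface_hpf, hpf_per_5mm2)
  } else {
    stop("missing columns: surface_mm2 or surface_hpf", call. = FALSE)
  }
  site <- resolve_site(raw$site)
  if (any(is.na(site))) {
    stop("unknown site label (rows ",
         paste(which(is.na(site)), collapse = ", "), ")", call. = FALSE)
  }
  gist_data(
    site = site,
    size_mm = raw$size_mm,
    surface_mm2 = surface,
    biopsy_mitoses = raw$biopsy_mitoses,
    response = if ("response" %in% names(raw)) as.logical(raw$response) else FALSE,
    specimen_mitoses = if ("specimen_mitoses" %in% names(raw))
      raw$specimen_mitoses else NA_integer_,
    provenance = path
  )
}

#' Write a GIST cohort to CSV
#'
#' @param data A `gist_data` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gist_csv <- function(data, path) {
  stopifnot(inherits(data, "gist_data"))
  out <- as.data.frame(data)
  out$site <- as.character(out$site)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.gist_data <- function(x, ...) {
  cat(sprintf("GIST cohort: %d records (%d with specimen count, %d with therapy response)\n",
              nrow(x), sum(!is.na(x$specimen_mitoses)), sum(x$response)))
  cat("provenance:", attr(x, "provenance") %||% "unspecified", "\n\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
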