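#' Risk classes
#'
#' The Miettinen-Lasota classes in increasing order of risk, plus the
#' `insufficient_data` outcome used for table cells the source
#' classification could not populate.
#'
#' @return Character vector of class labels.
#' @export
risk_classes <- function() {
  c("none", "very_low", "low", "moderate", "high", "insufficient_data")
}

#' Load a risk-classification table
#'
#' The Miettinen-Lasota (AFIP) lookup ships as an editable JSON
#' configuration rather than hard-coded constants: cells map a site group,
#' a size band (cut at 2, 5 and 10 cm, upper bounds inclusive) and a
#' mitotic band (at most 5 vs more than 5 per 5 mm2) to a risk class.
#' Cells the source classification left unpopulated are encoded as
#' `insufficient_data` and surfaced as such. The default config maps the
#' model's colon-rectum site onto the rectum column (the original table has
#' no colon column) and small intestine onto jejunum/ileum; both mappings
#' are editable in the file.
#'
#' @param path Path to a JSON table; defaults to the packaged
#'   Miettinen-Lasota configuration.
#' @return A list of class `"risk_table"`.
#' @export
risk_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "miettinen_lasota.json",
                                package = "prometheus", mustWork = TRUE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(length(cfg$size_breaks_cm) == 3,
            is.numeric(cfg$mitotic_threshold_per_5mm2))
  for (g in names(cfg$classes)) {
    for (band in c("low_mitoses", "high_mitoses")) {
      cls <- cfg$classes[[g]][[band]]
      if (length(cls) != 4 || !all(cls %in% risk_classes())) {
        stop("malformed risk table: ", g, "/", band, call. = FALSE)
      }
    }
  }
  structure(cfg, class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat(x$name, "\n")
  bands <- c("<=2 cm", ">2-5 cm", ">5-10 cm", ">10 cm")
  for (g in names(x$classes)) {
    cat(sprintf("  %-14s <=5: %s\n", g,
                paste(sprintf("%s=%s", bands, x$classes[[g]]$low_mitoses),
                      collapse = ", ")))
    cat(sprintf("  %-14s  >5: %s\n", "",
                paste(sprintf("%s=%s", bands, x$classes[[g]]$high_mitoses),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Miettinen-Lasota risk class
#'
#' Deterministic site/size/mitoses lookup. Size bands are half-open with
#' inclusive upper bounds (\eqn{\le 2}, \eqn{(2,5]}, \eqn{(5,10]},
#' \eqn{>10} cm); the mitotic bands are at most 5 vs more than 5 per 5 mm2.
#'
#' @param site Site label or index (see [gist_sites()]).
#' @param size_mm Tumor size, mm (vectorized).
#' @param mitoses_per_5mm2 Mitotic count per 5 mm2 (vectorized; need not be
#'   an integer, e.g. a predictive mean).
#' @param table A [risk_table()].
#' @return Factor with levels [risk_classes()].
#' @export
miettinen_lasota <- function(site, size_mm, mitoses_per_5mm2,
                             table = risk_table()) {
  n <- max(length(site), length(size_mm), length(mitoses_per_5mm2))
  site <- rep_len(resolve_site(site), n)
  size_mm <- rep_len(size_mm, n)
  mit <- rep_len(mitoses_per_5mm2, n)
  if (any(is.na(site))) stop("unknown site", call. = FALSE)
  stopifnot(all(size_mm > 0), all(mit >= 0))
  group <- unlist(table$site_groups[site])
  band <- findInterval(size_mm / 10, table$size_breaks_cm,
                       left.open = TRUE) + 1L
  mit_band <- ifelse(mit <= table$mitotic_threshold_per_5mm2,
                     "low_mitoses", "high_mitoses")
  out <- vapply(seq_len(n), function(i) {
    table$classes[[group[i]]][[mit_band[i]]][band[i]]
  }, character(1))
  factor(out, levels = risk_classes())
}

#' Risk-class probabilities from a predictive distribution
#'
#' Pushes the posterior predictive pmf of the specimen count through the
#' deterministic risk lookup: \eqn{P(\mathrm{class}=c) = \sum_k p(k)\,
#' 1[\mathrm{class}(site, size, k) = c]}.
#'
#' @param pred A `gist_pred` from [predict.gist_fit()].
#' @param site,size_mm Tumor site and size.
#' @param table A [risk_table()].
#' @return Named numeric vector of probabilities over [risk_classes()],
#'   summing to 1.
#' @export
predictive_risk <- function(pred, site, size_mm, table = risk_table()) {
  stopifnot(inherits(pred, "gist_pred"))
  cls <- miettinen_lasota(rep(site, length(pred$support)),
                          rep(size_mm, length(pred$support)),
                          pred$support, table)
  p <- vapply(risk_classes(), function(cc) sum(pred$pmf[cls == cc]),
              numeric(1))
  p / sum(p)
}

#' Proposed preoperative clinical classification
#'
#' Assigns the clinical type 0-4 combining resectability (a clinical
#' judgment supplied by the caller, not computed), metastatic status, site,
#' size and the model-based risk class. Precedence is
#' highest-severity-first: unresectable disease is type 4; resectable
#' synchronous metastatic disease type 3; any locally-advanced trigger
#' (gastric tumor > 10 cm, non-gastric > 5 cm, any non-gastric site, risk
#' of intraoperative rupture, need for mutilating/multivisceral resection,
#' or model-predicted high risk) type 2; a gastric tumor under 2 cm with
#' low predicted risk type 0; gastric 2-10 cm with low predicted risk
#' type 1. Input combinations matching no row return `"unclassified"`
#' explicitly.
#'
#' @param site Site label or index.
#' @param size_mm Tumor size, mm.
#' @param risk Risk class for the tumor (a [risk_classes()] label, e.g. the
#'   modal predictive class).
#' @param resectable Is the tumor resectable?
#' @param metastatic Synchronous metastatic disease?
#' @param rupture_risk Elevated risk of intraoperative rupture?
#' @param mutilating_resection Would resection be mutilating or complex
#'   multivisceral?
#' @return Character scalar: `"0"`..`"4"` or `"unclassified"`.
#' @export
preoperative_class <- function(site, size_mm, risk, resectable = TRUE,
                               metastatic = FALSE, rupture_risk = FALSE,
                               mutilating_resection = FALSE) {
  site <- resolve_site(site)
  if (is.na(site)) stop("unknown site", call. = FALSE)
  risk <- as.character(risk)
  stopifnot(risk %in% risk_classes(), size_mm > 0)
  gastric <- site == "stomach"
  if (!resectable) return("4")
  if (metastatic) return("3")
  if ((gastric && size_mm > 100) || (!gastric && size_mm > 50) ||
      !gastric || rupture_risk || mutilating_resection || risk == "high") {
    return("2")
  }
  if (gastric && size_mm < 20 && risk == "low") return("0")
  if (gastric && size_mm >= 20 && size_mm <= 100 && risk == "low") return("1")
  "unclassified"
}
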