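#' Convert high-power fields to square millimetres
#'
#' Mitotic counts in gastrointestinal stromal tumors are standardized to an
#' area of 5 mm2. On a calibrated microscope that area corresponds to a fixed
#' number of high-power fields (HPFs); with the default calibration, 23.5 HPFs
#' cover 5 mm2. These helpers convert between the two units at the package
#' boundary; internally all surfaces are kept in mm2.
#'
#' @param n_hpf Number of high-power fields (non-negative).
#' @param hpf_per_5mm2 Calibration constant: HPFs needed to cover 5 mm2.
#'   Defaults to 23.5; override for a differently calibrated microscope.
#' @return Area in mm2.
#' @examples
#' hpf_to_mm2(23.5)  # 5 mm2
#' hpf_to_mm2(14.3)  # about 3 mm2
#' @export
hpf_to_mm2 <- function(n_hpf, hpf_per_5mm2 = 23.5) {
  stopifnot(is.numeric(n_hpf), is.numeric(hpf_per_5mm2), hpf_per_5mm2 > 0)
  if (any(n_hpf < 0, na.rm = TRUE)) {
    stop("'n_hpf' must be non-negative", call. = FALSE)
  }
  n_hpf / hpf_per_5mm2 * 5.0
}

#' @rdname hpf_to_mm2
#' @param area_mm2 Area in mm2 (non-negative).
#' @export
mm2_to_hpf <- function(area_mm2, hpf_per_5mm2 = 23.5) {
  stopifnot(is.numeric(area_mm2), is.numeric(hpf_per_5mm2), hpf_per_5mm2 > 0)
  if (any(area_mm2 < 0, na.rm = TRUE)) {
    stop("'area_mm2' must be non-negative", call. = FALSE)
  }
  area_mm2 / 5.0 * hpf_per_5mm2
}
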