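# NGSP master equation constants: NGSP% = 0.09148 * IFCC + 2.152
.NGSP_SLOPE <- 0.09148
.NGSP_INTERCEPT <- 2.152

#' Convert HbA1c between IFCC and NGSP scales
#'
#' HbA1c is reported either in IFCC units (mmol/mol) or as an NGSP
#' percentage; the two scales are linked by the linear master equation
#' `NGSP% = 0.09148 * IFCC + 2.152`. `ifcc_to_ngsp()` applies the map,
#' `ngsp_to_ifcc()` its exact inverse. Both are strictly increasing and
#' vectorised; round-tripping is an identity to floating-point precision.
#'
#' @param hba1c_ifcc HbA1c in mmol/mol; must be non-negative.
#' @param hba1c_pct HbA1c in percent (NGSP); must be at least 2.152, the
#'   image of 0 mmol/mol.
#' @return Converted values on the other scale.
#' @export
#' @examples
#' ifcc_to_ngsp(65)          # 8.0982 -> prints as 8.10%
#' round(ifcc_to_ngsp(c(42, 64, 86, 108)))  # 6, 8, 10, 12
#' ngsp_to_ifcc(ifcc_to_ngsp(100))          # 100
ifcc_to_ngsp <- function(hba1c_ifcc) {
  if (any(hba1c_ifcc < 0)) stop("HbA1c in mmol/mol must be >= 0")
  .NGSP_SLOPE * hba1c_ifcc + .NGSP_INTERCEPT
}

#' @rdname ifcc_to_ngsp
#' @export
ngsp_to_ifcc <- function(hba1c_pct) {
  if (any(hba1c_pct < .NGSP_INTERCEPT))
    stop("HbA1c in % must be >= ", .NGSP_INTERCEPT,
         " (the image of 0 mmol/mol)")
  (hba1c_pct - .NGSP_INTERCEPT) / .NGSP_SLOPE
}
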