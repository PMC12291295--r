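#' Molecular weight of an analyte
#'
#' Molecular weights used throughout the package to bridge the bioanalytical
#' reporting units (mg/L) and the enzymatic assay units (micromolar).
#'
#' @param analyte `"MPA"` (mycophenolic acid, 320.34 g/mol) or `"MPAG"`
#'   (7-O-MPA-glucuronide, 496.46 g/mol).
#' @return Molecular weight in g/mol.
#' @export
molecular_weight <- function(analyte) {
  analyte <- match.arg(analyte, c("MPA", "MPAG"))
  switch(analyte, MPA = 320.34, MPAG = 496.46)
}

#' Convert concentrations between mg/L and micromolar
#'
#' @param value Numeric vector of concentrations, all `>= 0`.
#' @param analyte `"MPA"` or `"MPAG"`.
#' @return Converted concentration vector.
#' @examples
#' mg_per_l_to_um(0.25, "MPA") # LLOQ of the bioanalytical assay, ~0.780 uM
#' um_to_mg_per_l(200, "MPAG") # assay starting substrate concentration
#' @export
mg_per_l_to_um <- function(value, analyte) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  value / molecular_weight(analyte) * 1000
}

#' @rdname mg_per_l_to_um
#' @export
um_to_mg_per_l <- function(value, analyte) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  value * molecular_weight(analyte) / 1000
}
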