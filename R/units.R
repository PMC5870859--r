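#' Convert an affinity measurement to the pChEMBL scale
#'
#' A pChEMBL value is the negative base-10 logarithm of a molar
#' Ki/Kd/IC50/EC50 measurement, so 10 uM corresponds to a pChEMBL of 5.
#' Only units with a fixed conversion to molar are accepted (`nM`, `uM`,
#' `mM`, `M`); anything else -- percentages, mg/kg, unlabelled numbers --
#' is rejected rather than guessed at.
#'
#' @param value numeric vector of measured affinities; must be positive.
#' @param units character vector (recycled) of unit labels.
#' @return numeric vector of pChEMBL values.
#' @examples
#' to_pchembl(10, "uM")   # 5
#' to_pchembl(1, "nM")    # 9
#' @seealso [from_pchembl()] for the inverse transform.
#' @export
to_pchembl <- function(value, units) {
  stopifnot(length(value) > 0)
  units <- rep_len(as.character(units), length(value))
  fac <- MOLAR_FACTORS[normalize_units(units)]
  if (anyNA(fac)) {
    bad <- unique(units[is.na(fac)])
    stop("cannot convert units to molar: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(value) & value <= 0))
    stop("affinity values must be positive to take -log10", call. = FALSE)
  -log10(value * unname(fac))
}

#' Invert a pChEMBL value back to a concentration
#'
#' @param pchembl numeric vector of pChEMBL values.
#' @param units unit to express the result in (default `"nM"`).
#' @return numeric vector of concentrations in `units`.
#' @export
from_pchembl <- function(pchembl, units = "nM") {
  fac <- MOLAR_FACTORS[normalize_units(units)]
  if (anyNA(fac)) stop("unknown unit: ", units, call. = FALSE)
  10^(-pchembl) / unname(fac)
}

MOLAR_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

normalize_units <- function(units) {
  u <- trimws(units)
  u[u %in% c("µM", "um", "UM", "μM")] <- "uM"
  u[u %in% c("nm", "NM")] <- "nM"
  u[u %in% c("mol/L", "mol/l")] <- "M"
  u
}

convertible_units <- function(units) {
  normalize_units(units) %in% names(MOLAR_FACTORS)
}
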