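#' Relative water content
#'
#' Drought-severity index `RWC = (FW - DW) / (RW - DW) * 100`, where FW, DW
#' and RW are the weights of control, drought-treated and re-watered plants.
#' Values outside `[0, 100]` are returned as-is with a warning (measurement
#' error should be visible, not clipped).
#'
#' @param FW,DW,RW Numeric weights (g); vectorised.
#' @return RWC in percent.
#' @export
relative_water_content <- function(FW, DW, RW) {
  if (any(RW <= DW)) stop("RW must exceed DW for a defined RWC")
  rwc <- (FW - DW) / (RW - DW) * 100
  if (any(rwc < 0 | rwc > 100)) {
    warning("RWC outside [0, 100]%; check the FW/DW/RW measurements")
  }
  rwc
}

#' Maximum quantum yield of photosystem II
#'
#' `Fv/Fm = (Fm - F0) / Fm` from dark-adapted minimum (F0) and maximum (Fm)
#' chlorophyll fluorescence. Values outside `[0, 1]` are returned with a
#' warning.
#'
#' @param F0,Fm Numeric fluorescence readings; vectorised.
#' @return Fv/Fm ratio.
#' @export
fv_over_fm <- function(F0, Fm) {
  if (any(Fm <= 0)) stop("Fm must be positive")
  r <- (Fm - F0) / Fm
  if (any(r < 0 | r > 1)) {
    warning("Fv/Fm outside [0, 1]; check that 0 <= F0 <= Fm")
  }
  r
}
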