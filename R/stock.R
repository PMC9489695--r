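#' Soil organic carbon stock of a depth interval
#'
#' Converts SOC content of the fine-earth fraction to an areal stock,
#' correcting for coarse fragments:
#' `SOC_s = SOC_c/1000 * D * BD * (1 - G/100)` in kg C m^-2.
#' SOC_c/1000 is the carbon mass fraction of fine earth (SOC_c is in
#' g C per kg), D the interval thickness in m, BD the fine-earth bulk
#' density in kg m^-3 and G the volumetric gravel percentage.
#'
#' @param soc_c SOC content, g C kg^-1 fine earth (>= 0).
#' @param depth interval thickness, m (> 0).
#' @param bd bulk density of fine earth, kg m^-3 (> 0); NA gives NA stock.
#' @param gravel volumetric gravel content, % in [0, 100]; NA gives NA stock.
#' @return SOC stock in kg C m^-2 (multiply by 10 for Mg C ha^-1).
#' @examples
#' compute_soc_stock(20, 0.3, 1300, 10)   # 7.02 kg C m^-2
#' @export
compute_soc_stock <- function(soc_c, depth, bd, gravel) {
  if (any(soc_c < 0, na.rm = TRUE)) stop("`soc_c` must be >= 0")
  if (any(depth <= 0, na.rm = TRUE)) stop("`depth` must be positive")
  if (any(bd <= 0, na.rm = TRUE)) stop("`bd` must be positive")
  if (any(gravel < 0 | gravel > 100, na.rm = TRUE))
    stop("`gravel` must be in [0, 100]")
  (soc_c / 1000) * depth * bd * (1 - gravel / 100)
}

#' Standard depth intervals used for harmonization
#'
#' The three standard layers (m): 0-0.3, 0.3-1 and 1-2.
#'
#' @return data.frame with columns `layer`, `top`, `bottom`, `thickness`.
#' @export
standard_layers <- function() {
  data.frame(layer = c("0-0.3", "0.3-1", "1-2"),
             top = c(0, 0.3, 1), bottom = c(0.3, 1, 2),
             thickness = c(0.3, 0.7, 1))
}
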