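#' Phantom calibration measurements of water and corn oil at 7 T
#'
#' The tabulated T1/R1 group means (n = 3, mean +/- SD) of water and
#' corn-oil tube phantoms equilibrated at ~30 degrees C with N2, air,
#' carbogen, or 100% O2, shipped as a CSV in `inst/extdata`. These are
#' the inputs of the O2 relaxivity calibration: regressing each sample's
#' R1 on the dry-gas pO2 gives the aqueous and lipidic relaxivities.
#'
#' @param sample optional filter, `"water"` or `"corn_oil"`.
#' @return A data.frame with columns `sample`, `gas`, `o2_fraction`,
#'   `t1_s`, `t1_sd`, `r1_mean`, `r1_sd`, `n`.
#' @examples
#' cal <- phantom_calibration("corn_oil")
#' fit <- fit_relaxivity(cal$r1_mean, gas_po2(cal$o2_fraction))
#' coef(fit)["slope"]
#' @export
phantom_calibration <- function(sample = NULL) {
  path <- system.file("extdata", "phantom_calibration.csv",
                      package = "toldmri", mustWork = TRUE)
  cal <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(sample)) {
    sample <- match.arg(sample, unique(cal$sample))
    cal <- cal[cal$sample == sample, , drop = FALSE]
  }
  cal
}
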