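#' Published linear crosswalks between mHHS, HOOS and HOOS-12
#'
#' The four reported linear conversion equations between the modified
#' Harris Hip Score and the HOOS / HOOS-12, tabulated on the full integer
#' source grids and clamped to the target ranges:
#'
#' * mHHS -> HOOS:    `CWD HOOS    = 0.7568 * PD mHHS    + 8.8474`
#' * HOOS -> mHHS:    `CWD mHHS    = 1.0713 * PD HOOS    + 2.6526`
#' * mHHS -> HOOS-12: `CWD HOOS-12 = 0.728  * PD mHHS    + 13.192`
#' * HOOS-12 -> mHHS: `CWD mHHS    = 1.1124 * PD HOOS-12 - 3.1421`
#'
#' These coefficients were estimated on 121 matched PD score pairs from a
#' primary total-hip-arthroplasty cohort; out-of-range line values (e.g.
#' the negative HOOS-12 -> mHHS intercept at source 0) are clamped to the
#' target instrument's limits.
#'
#' @return Named list of four `crosswalk_table` objects:
#'   `mHHS_to_HOOS`, `HOOS_to_mHHS`, `mHHS_to_HOOS-12`, `HOOS-12_to_mHHS`.
#' @examples
#' cw <- published_crosswalks()
#' apply_crosswalk(cw$mHHS_to_HOOS, 0)   # 8.8474 (the intercept)
#' @export
published_crosswalks <- function() {
  out <- list(
    "mHHS_to_HOOS"    = lr_table_from_coef(0.7568, 8.8474, "mHHS", "HOOS", 121L),
    "HOOS_to_mHHS"    = lr_table_from_coef(1.0713, 2.6526, "HOOS", "mHHS", 121L),
    "mHHS_to_HOOS-12" = lr_table_from_coef(0.728, 13.192, "mHHS", "HOOS-12", 121L),
    "HOOS-12_to_mHHS" = lr_table_from_coef(1.1124, -3.1421, "HOOS-12", "mHHS", 121L))
  out
}
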