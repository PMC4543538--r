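#' Labelled cDNA yield from absorbance
#'
#' Yield in nanograms of single-stranded labelled cDNA, computed from the
#' A260 absorbance reading as `A260 x 330 ng/ul x elution volume`.
#'
#' @param a260 Absorbance at 260 nm (vectorized, >= 0).
#' @param elution_volume_ul Elution volume in microliters (default 50).
#' @return Yield in ng.
#' @examples
#' cdna_yield(0.05)  # 825 ng, the hybridization suitability threshold
#' @export
cdna_yield <- function(a260, elution_volume_ul = 50) {
  if (!is.numeric(a260) || any(!is.finite(a260)) || any(a260 < 0)) {
    abort("`a260` must be non-negative and finite.")
  }
  check_scalar_number(elution_volume_ul, "elution_volume_ul", lower = 0,
                      strict_lower = TRUE)
  a260 * 330 * elution_volume_ul
}

#' Dye specific activity of labelled cDNA
#'
#' Picomoles of Cy3 or Cy5 dye per microgram of cDNA:
#' `(dye pmol/ul) / (cDNA ng/ul) x 1000`.
#'
#' @param dye_pmol_per_ul Dye concentration in pmol/ul (vectorized, >= 0).
#' @param cdna_ng_per_ul cDNA concentration in ng/ul (> 0).
#' @return Specific activity in pmol dye per ug cDNA.
#' @examples
#' specific_activity(0.008, 1)  # 8 pmol/ug, the suitability threshold
#' @export
specific_activity <- function(dye_pmol_per_ul, cdna_ng_per_ul) {
  if (!is.numeric(dye_pmol_per_ul) || any(!is.finite(dye_pmol_per_ul)) ||
      any(dye_pmol_per_ul < 0)) {
    abort("`dye_pmol_per_ul` must be non-negative and finite.")
  }
  if (!is.numeric(cdna_ng_per_ul) || any(!is.finite(cdna_ng_per_ul)) ||
      any(cdna_ng_per_ul <= 0)) {
    abort("`cdna_ng_per_ul` must be strictly positive.")
  }
  dye_pmol_per_ul / cdna_ng_per_ul * 1000
}

#' Hybridization suitability QC for labelled samples
#'
#' Applies the two labelling quality gates: a sample passes iff its cDNA
#' yield exceeds `yield_threshold_ng` (strict) and its dye specific activity
#' exceeds `activity_threshold` (strict).
#'
#' @param samples Data frame with columns `sample_id`, `a260`,
#'   `dye_pmol_per_ul`, `cdna_ng_per_ul`.
#' @param elution_volume_ul Elution volume used for the yield formula.
#' @param yield_threshold_ng Minimum acceptable yield (exclusive), ng.
#' @param activity_threshold Minimum acceptable specific activity
#'   (exclusive), pmol/ug.
#' @return The input tibble with added `cdna_yield_ng`, `specific_activity`
#'   and logical `pass` columns.
#' @export
qc_assess <- function(samples, elution_volume_ul = 50,
                      yield_threshold_ng = 825, activity_threshold = 8) {
  check_columns(samples, c("sample_id", "a260", "dye_pmol_per_ul",
                           "cdna_ng_per_ul"), "samples")
  out <- as_tibble(samples)
  out$cdna_yield_ng <- cdna_yield(out$a260, elution_volume_ul)
  out$specific_activity <- specific_activity(out$dye_pmol_per_ul,
                                             out$cdna_ng_per_ul)
  out$pass <- out$cdna_yield_ng > yield_threshold_ng &
    out$specific_activity > activity_threshold
  out
}
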