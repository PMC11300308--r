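#' Criterion thresholds for cachexia staging
#'
#' Returns the cut-offs applied to laboratory values and instrument scores
#' when deriving staging criteria and prognostic scores. Defaults are the
#' published clinical cut-offs; every comparator is strict (`>` or `<`)
#' except the neutrophil-to-lymphocyte ratio, which is flagged at `>= 5`.
#'
#' Canonical units: CRP mg/L, albumin g/dL, hemoglobin g/dL, WBC cells/uL,
#' CA19-9 U/mL, platelets 10^3/uL, bilirubin mg/dL.
#'
#' @param crp_high CRP elevation cut, mg/L (criterion met when CRP `>` cut).
#' @param alb_low hypoalbuminemia cut, g/dL (`<`).
#' @param alb_severe severe hypoalbuminemia cut, g/dL (`<`); feeds the
#'   refractory-stage routes.
#' @param wbc_high leukocytosis cut, cells/uL (`>`).
#' @param hgb_low_male,hgb_low_female sex-specific anemia cuts, g/dL (`<`).
#' @param ca19_9_high CA19-9 cut, U/mL (`>`).
#' @param nlr_high neutrophil-to-lymphocyte ratio cut (`>=`).
#' @param platelets_high platelet count cut, 10^3/uL (`>`).
#' @param bilirubin_high total bilirubin cut, mg/dL (`>`).
#' @param gps_crp,gps_alb Glasgow Prognostic Score component cuts: CRP mg/L
#'   (`>`) and albumin g/dL (`<`).
#' @param box2_cut aPG-SGA box-2 (food intake) cut; criterion met when `>` cut.
#' @param box4_cut aPG-SGA box-4 (activity) cut; preserved activity is
#'   `<=` cut, impaired activity `>` cut.
#' @param wl_significant percent weight loss over 6 months separating minimal
#'   (`<=`) from significant (`>`) loss.
#' @param fearon_wl,fearon_bmi,fearon_wl_lowbmi dichotomous weight-loss
#'   status: cachectic when loss `>` `fearon_wl` percent, or BMI `<`
#'   `fearon_bmi` with loss `>` `fearon_wl_lowbmi` percent.
#' @param esas_severe ESAS-r item/subscore value at and above which a symptom
#'   is moderate-to-severe.
#' @return a named list of class `"cachexia_thresholds"`.
#' @export
#' @examples
#' th <- cachexia_thresholds()
#' th$crp_high
cachexia_thresholds <- function(crp_high = 10,
                                alb_low = 3.2,
                                alb_severe = 2.5,
                                wbc_high = 11000,
                                hgb_low_male = 12,
                                hgb_low_female = 11,
                                ca19_9_high = 37,
                                nlr_high = 5,
                                platelets_high = 300,
                                bilirubin_high = 1.1,
                                gps_crp = 10,
                                gps_alb = 3.5,
                                box2_cut = 1,
                                box4_cut = 2,
                                wl_significant = 5,
                                fearon_wl = 5,
                                fearon_bmi = 20,
                                fearon_wl_lowbmi = 2,
                                esas_severe = 4) {
  th <- as.list(environment())
  stopifnot(vapply(th, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                   logical(1)))
  class(th) <- "cachexia_thresholds"
  th
}

#' Read a threshold set from a JSON file
#'
#' Alternate cut-offs can be evaluated without code change by shipping them
#' as a JSON object whose keys match the arguments of
#' [cachexia_thresholds()]; unlisted keys keep their defaults.
#'
#' @param path path to a JSON file.
#' @return a `"cachexia_thresholds"` list.
#' @export
thresholds_from_file <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cachexia_thresholds))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
  }
  do.call(cachexia_thresholds, vals)
}
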