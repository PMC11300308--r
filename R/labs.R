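# Laboratory derivations: the biochemistry staging criterion and the
# prognostic scores (GPS, NLR) and marker flags used in the criterion
# prevalence tables.

#' Working CRP value with provenance
#'
#' CRP is carried twice in the cohort: the standard-of-care EMR value and a
#' research-assay value measured on banked serum. The standard-of-care
#' value is preferred when present; the source actually used is recorded.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @return data.frame with columns `crp` (mg/L) and `crp_source`
#'   (`"soc"`, `"research"`, or `NA` when neither is measured).
#' @export
crp_value <- function(cohort) {
  soc <- cohort$crp_soc
  res <- cohort$crp_research
  crp <- ifelse(!is.na(soc), soc, res)
  source <- rep(NA_character_, length(crp))
  source[!is.na(soc)] <- "soc"
  source[is.na(soc) & !is.na(res)] <- "research"
  data.frame(crp = crp, crp_source = source)
}

#' Biochemistry criterion (criterion A)
#'
#' Abnormal biochemistry is an OR over four components: CRP above 10 mg/L,
#' albumin below 3.2 g/dL, WBC above 11,000 cells/uL, or sex-specific
#' anemia (hemoglobin below 12 g/dL in men, 11 g/dL in women). The OR is
#' missing-aware: any abnormal component makes the criterion `TRUE`; it is
#' `NA` only when every component is unmeasured; otherwise `FALSE`, with an
#' `incomplete` flag when some components were unmeasured.
#'
#' @param cohort a `cachexia_cohort` data.frame (`sex` must be known for
#'   the anemia component to contribute).
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame with logical columns `crp_high`, `alb_low`,
#'   `wbc_high`, `hgb_low`, `A`, and `incomplete`.
#' @export
criterion_biochem <- function(cohort, thresholds = cachexia_thresholds()) {
  crp <- crp_value(cohort)$crp
  hgb_cut <- ifelse(cohort$sex == "male", thresholds$hgb_low_male,
                    thresholds$hgb_low_female)
  comp <- data.frame(
    crp_high = crp > thresholds$crp_high,
    alb_low = cohort$albumin < thresholds$alb_low,
    wbc_high = cohort$wbc > thresholds$wbc_high,
    hgb_low = cohort$hgb < hgb_cut
  )
  comp$A <- or_na(comp$crp_high, comp$alb_low, comp$wbc_high, comp$hgb_low)
  comp$incomplete <- rowSums(is.na(comp[1:4])) > 0
  comp
}

#' Glasgow Prognostic Score
#'
#' GPS 2: CRP elevated (above 10 mg/L, i.e. 1.0 mg/dL) and hypoalbuminemia
#' (below 3.5 g/dL). GPS 1: exactly one of the two abnormalities. GPS 0:
#' neither. Because no single component forces a unique score, the score is
#' `NA` whenever either component is unmeasured.
#'
#' @param crp CRP in mg/L.
#' @param albumin albumin in g/dL.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return integer vector of scores in `{0, 1, 2}`, `NA` where
#'   undetermined.
#' @export
#' @examples
#' compute_gps(c(20, 20, 5), c(3.0, 4.0, 4.0)) # 2, 1, 0
compute_gps <- function(crp, albumin, thresholds = cachexia_thresholds()) {
  crp_ab <- crp > thresholds$gps_crp
  alb_ab <- albumin < thresholds$gps_alb
  as.integer(crp_ab) + as.integer(alb_ab)
}

#' Neutrophil-to-lymphocyte ratio
#'
#' Ratio of absolute neutrophil to absolute lymphocyte counts, flagged high
#' at `>= 5` (boundary inclusive). A zero lymphocyte count makes the ratio
#' undefined and is an error; unmeasured counts give `NA`.
#'
#' @param neutrophils,lymphocytes absolute counts, cells/uL.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame with columns `nlr` and logical `nlr_high`.
#' @export
compute_nlr <- function(neutrophils, lymphocytes,
                        thresholds = cachexia_thresholds()) {
  if (any(!is.na(lymphocytes) & lymphocytes == 0)) {
    stop("undefined ratio: lymphocyte count of 0")
  }
  nlr <- neutrophils / lymphocytes
  data.frame(nlr = nlr, nlr_high = nlr >= thresholds$nlr_high)
}

#' Prognostic marker flags
#'
#' Threshold flags for the serum markers tabulated alongside the staging
#' criteria: CA19-9 above 37 U/mL, platelets above 300 x 10^3/uL, total
#' bilirubin above 1.1 mg/dL. All comparators are strict, so a value
#' exactly at the cut is not flagged.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame with logical columns `ca19_9_high`, `platelets_high`,
#'   `bilirubin_high`.
#' @export
flag_markers <- function(cohort, thresholds = cachexia_thresholds()) {
  data.frame(
    ca19_9_high = cohort$ca19_9 > thresholds$ca19_9_high,
    platelets_high = cohort$platelets > thresholds$platelets_high,
    bilirubin_high = cohort$bilirubin > thresholds$bilirubin_high
  )
}

#' Full laboratory criterion panel
#'
#' Assembles the biochemistry criterion with its components, severe
#' hypoalbuminemia, GPS, NLR, and the marker flags into one per-patient
#' table.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame, one row per patient.
#' @export
lab_criteria <- function(cohort, thresholds = cachexia_thresholds()) {
  bio <- criterion_biochem(cohort, thresholds)
  crp <- crp_value(cohort)
  out <- cbind(
    crp,
    bio,
    alb_severe = cohort$albumin < thresholds$alb_severe,
    gps = compute_gps(crp$crp, cohort$albumin, thresholds),
    compute_nlr(cohort$neutrophils, cohort$lymphocytes, thresholds),
    flag_markers(cohort, thresholds)
  )
  rownames(out) <- NULL
  out
}
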