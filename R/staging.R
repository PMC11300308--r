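# Four-stage cachexia classification from criterion flags, plus the
# dichotomous weight-loss (Fearon) status.
#
# Criteria: A abnormal biochemistry; B decreased food intake; C minimal
# (0 < WL <= 5%) weight loss; D significant (> 5%) weight loss; E preserved
# activity (box 4 <= 2); F impaired activity (box 4 > 2); plus severe
# hypoalbuminemia (< 2.5 g/dL) opening the refractory routes.

stage_levels <- function() c("NCa", "PCa", "Ca", "RCa")

# The printed combination rules, in severity order; a stage matches when all
# required flags of any one of its combinations hold. Two modifications
# apply: hand-grip strength never enters, and any patient with significant
# weight loss who reaches no refractory combination is cachectic ("D" rule).
stage_rules <- function() {
  rule <- function(stage, id, req) list(stage = stage, id = id, req = req)
  list(
    rule("RCa", "A+D+F", c("A", "D", "F")),
    rule("RCa", "B+D+F", c("B", "D", "F")),
    rule("RCa", "A+B+D+F", c("A", "B", "D", "F")),
    rule("RCa", "Alb<2.5+D", c("alb_severe", "D")),
    rule("RCa", "Alb<2.5+E", c("alb_severe", "E")),
    rule("RCa", "Alb<2.5+D+F", c("alb_severe", "D", "F")),
    rule("Ca", "A+D+E", c("A", "D", "E")),
    rule("Ca", "B+D+E", c("B", "D", "E")),
    rule("Ca", "A+B+D+E", c("A", "B", "D", "E")),
    rule("Ca", "D", "D"),
    rule("PCa", "A+B", c("A", "B")),
    rule("PCa", "A+C", c("A", "C")),
    rule("PCa", "B+C", c("B", "C")),
    rule("PCa", "A+B+C", c("A", "B", "C"))
  )
}

#' Derive staging criterion flags for a cohort
#'
#' Assembles criteria A-F and severe hypoalbuminemia from the laboratory
#' panel and the aPG-SGA. A criterion whose inputs are unmeasured counts as
#' not met (`FALSE` in rule matching) — except the weight-loss pair: a
#' missing 6-month-prior weight makes the patient unstageable.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame of class `"criterion_flags"` with columns
#'   `patient_id`, logical `A`..`F` and `alb_severe` (possibly `NA`),
#'   `pct_loss`, and `stageable`.
#' @export
derive_criteria <- function(cohort, thresholds = cachexia_thresholds()) {
  labs <- lab_criteria(cohort, thresholds)
  wl <- weight_loss_criteria(cohort$weight_current, cohort$weight_6mo_prior,
                             thresholds)
  act <- criterion_activity(cohort$pgsga_box4, thresholds)
  out <- data.frame(
    patient_id = cohort$patient_id,
    A = labs$A,
    B = criterion_food_intake(cohort$pgsga_box2, thresholds),
    C = wl$C,
    D = wl$D,
    E = act$E,
    F = act$F,
    alb_severe = labs$alb_severe,
    pct_loss = wl$pct_loss,
    stageable = !is.na(wl$pct_loss)
  )
  class(out) <- c("criterion_flags", "data.frame")
  out
}

#' Classify cachexia stage from criterion flags
#'
#' Combination blocks are evaluated in severity order (refractory, then
#' cachectic, then pre-cachectic); the first matching combination wins and
#' is recorded for audit. Significant weight loss that reaches no
#' refractory combination is always at least cachectic (the `"D"` rule), so
#' no patient with criterion D can be staged below Ca. Patients matching no
#' combination are non-cachectic; unstageable patients are labelled
#' `Unstageable`. `NA` flags are treated as not met.
#'
#' @param flags a `"criterion_flags"` data.frame from [derive_criteria()],
#'   or any data.frame with logical columns `A`..`F` and `alb_severe`
#'   (a missing `stageable` column defaults to all stageable).
#' @return data.frame with `stage` (factor `NCa < PCa < Ca < RCa`, `NA` for
#'   unstageable rows), `label` (character, including `"Unstageable"`), and
#'   `rule_fired`.
#' @export
classify_stage <- function(flags) {
  needed <- c("A", "B", "C", "D", "E", "F", "alb_severe")
  stopifnot(all(needed %in% names(flags)))
  fl <- as.data.frame(lapply(flags[needed], isTRUE_vec))
  stageable <- if ("stageable" %in% names(flags)) flags$stageable
               else rep(TRUE, nrow(fl))
  label <- rep("NCa", nrow(fl))
  rule_fired <- rep("none", nrow(fl))
  unmatched <- rep(TRUE, nrow(fl))
  for (r in stage_rules()) {
    hit <- unmatched & Reduce(`&`, fl[r$req])
    label[hit] <- r$stage
    rule_fired[hit] <- paste0(r$stage, ":", r$id)
    unmatched[hit] <- FALSE
  }
  label[!stageable] <- "Unstageable"
  rule_fired[!stageable] <- "unstageable"
  stage <- factor(label, levels = stage_levels(), ordered = TRUE)
  data.frame(stage = stage, label = label, rule_fired = rule_fired)
}

#' Dichotomous cachexia status from weight loss (Fearon criteria)
#'
#' Cachectic: weight loss over the prior six months above 5%, or BMI below
#' 20 kg/m2 with any weight loss above 2%. Patients with no weight history
#' are unstageable; a missing BMI disables only the low-BMI arm.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return character vector: `"cachectic"`, `"non_cachectic"`, or
#'   `"unstageable"`.
#' @export
classify_fearon <- function(cohort, thresholds = cachexia_thresholds()) {
  wl <- weight_loss_criteria(cohort$weight_current, cohort$weight_6mo_prior,
                             thresholds)$pct_loss
  lowbmi_arm <- !is.na(cohort$bmi) & cohort$bmi < thresholds$fearon_bmi &
    wl > thresholds$fearon_wl_lowbmi
  cach <- wl > thresholds$fearon_wl | lowbmi_arm
  out <- ifelse(cach, "cachectic", "non_cachectic")
  out[is.na(wl)] <- "unstageable"
  out
}

#' Stage a whole cohort and tabulate prevalence
#'
#' Runs criterion derivation, four-stage classification, and the
#' dichotomous status over a cohort, and tabulates stage prevalence.
#' Percentages use the stageable patients only as denominator (unstageable
#' patients are excluded) and are rounded half-up to one decimal.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return list of class `"cachexia_staging"`:
#'   \describe{
#'     \item{labels}{per-patient data.frame: `patient_id`, `stage`,
#'       `label`, `rule_fired`, `fearon_status`}
#'     \item{prevalence}{data.frame `stage`, `n`, `pct` over the four
#'       stages (empty when no patient is stageable)}
#'     \item{n_stageable, n_unstageable}{denominator bookkeeping}
#'   }
#' @export
stage_cohort <- function(cohort, thresholds = cachexia_thresholds()) {
  flags <- derive_criteria(cohort, thresholds)
  cls <- classify_stage(flags)
  labels <- data.frame(patient_id = cohort$patient_id,
                       stage = cls$stage,
                       label = cls$label,
                       rule_fired = cls$rule_fired,
                       fearon_status = classify_fearon(cohort, thresholds))
  n_stageable <- sum(!is.na(cls$stage))
  if (n_stageable == 0) {
    prevalence <- data.frame(stage = character(), n = integer(),
                             pct = numeric())
  } else {
    counts <- table(cls$stage)
    prevalence <- data.frame(
      stage = names(counts),
      n = as.integer(counts),
      pct = round_half_up(100 * as.integer(counts) / n_stageable, 1)
    )
  }
  out <- list(labels = labels, prevalence = prevalence,
              n_stageable = n_stageable,
              n_unstageable = sum(is.na(cls$stage)))
  class(out) <- "cachexia_staging"
  out
}

#' @export
print.cachexia_staging <- function(x, ...) {
  cat("Cachexia staging:", x$n_stageable, "stageable,",
      x$n_unstageable, "unstageable\n")
  print(x$prevalence, row.names = FALSE)
  fearon <- table(x$labels$fearon_status)
  cat("Dichotomous status:",
      paste(names(fearon), fearon, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
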