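# Patient-reported instrument scoring: aPG-SGA criterion inputs, ESAS-r
# symptom subscores, EORTC QLQ-C30 / QLQ-PAN26 0-100 scale scores, and
# Canadian Problem Checklist domain tallies.

#' Food-intake criterion from the aPG-SGA (criterion B)
#'
#' Decreased food intake is flagged when the box-2 score exceeds the cut
#' (default `> 1`). A missing box-2 score yields `NA`, never `FALSE`:
#' an unanswered instrument is not evidence of preserved intake.
#'
#' @param box2 integer vector of aPG-SGA box-2 scores.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return logical vector (criterion B), `NA` where box2 is missing.
#' @export
criterion_food_intake <- function(box2, thresholds = cachexia_thresholds()) {
  ifelse(is.na(box2), NA, box2 > thresholds$box2_cut)
}

#' Activity criteria from the aPG-SGA (criteria E and F)
#'
#' Box 4 scores activities and function; a score `<= 2` means preserved
#' activity (E), `> 2` impaired activity (F; corresponds to ECOG
#' performance status above 3). E and F are mutually exclusive and
#' exhaustive when box 4 is answered; both are `NA` when it is not.
#'
#' @param box4 integer vector of aPG-SGA box-4 scores.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame with logical columns `E` and `F`.
#' @export
criterion_activity <- function(box4, thresholds = cachexia_thresholds()) {
  E <- ifelse(is.na(box4), NA, box4 <= thresholds$box4_cut)
  data.frame(E = E, F = !E)
}

#' Weight-loss criteria over the prior six months (criteria C and D)
#'
#' Percent loss is `100 * (prior - current) / prior`. Significant loss (D)
#' is `> 5%`; minimal loss (C) is strictly positive loss up to 5% — a
#' weight-stable or weight-gaining patient meets neither. Patients with a
#' missing prior weight cannot be staged; both criteria and the percentage
#' are `NA` for them.
#'
#' @param current,prior weights in kg.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame with columns `pct_loss`, `C`, `D`.
#' @export
weight_loss_criteria <- function(current, prior,
                                 thresholds = cachexia_thresholds()) {
  stopifnot(all(is.na(current) | current > 0),
            all(is.na(prior) | prior > 0))
  pct <- 100 * (prior - current) / prior
  cut <- thresholds$wl_significant
  data.frame(pct_loss = pct,
             C = ifelse(is.na(pct), NA, pct > 0 & pct <= cut),
             D = ifelse(is.na(pct), NA, pct > cut))
}

#' ESAS-r symptom subscores and per-item severity
#'
#' Physical subscore: mean of pain, tiredness, drowsiness, nausea, appetite
#' and shortness of breath. Psychological subscore: mean of anxiety and
#' depression. Total subscore: mean of all scored symptom items (wellbeing
#' included by default; the item list is configurable). Subscores over
#' partial panels use the mean of available items with no imputation; rows
#' with under half the items answered are flagged `low_coverage`. Each item
#' and subscore dichotomizes at `>= 4` into moderate-to-severe.
#'
#' @param cohort a `cachexia_cohort` data.frame (or any data.frame with
#'   `esas_*` columns).
#' @param total_items character vector of item names entering the total
#'   subscore.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return data.frame with `physical`, `psychological`, `total`,
#'   `low_coverage`, and logical `severe_<item>` columns
#'   (moderate-to-severe indicator per item).
#' @export
esas_subscores <- function(cohort, total_items = esas_item_names(),
                           thresholds = cachexia_thresholds()) {
  stopifnot(all(total_items %in% esas_item_names()))
  items <- as.matrix(cohort[paste0("esas_", esas_item_names())])
  colnames(items) <- esas_item_names()
  physical_items <- c("pain", "tiredness", "drowsiness", "nausea",
                      "appetite", "shortness_of_breath")
  psychological_items <- c("anxiety", "depression")
  row_mean <- function(cols) {
    m <- items[, cols, drop = FALSE]
    out <- rowMeans(m, na.rm = TRUE)
    out[rowSums(!is.na(m)) == 0] <- NA
    out
  }
  out <- data.frame(
    physical = row_mean(physical_items),
    psychological = row_mean(psychological_items),
    total = row_mean(total_items),
    low_coverage = rowSums(!is.na(items)) < length(esas_item_names()) / 2
  )
  sev <- items >= thresholds$esas_severe
  colnames(sev) <- paste0("severe_", colnames(items))
  cbind(out, as.data.frame(sev))
}

read_scale_map <- function(instrument = c("qlq_c30", "pan26")) {
  instrument <- match.arg(instrument)
  path <- system.file("extdata", "instrument_scales.json",
                      package = "cachexstage")
  jsonlite::read_json(path, simplifyVector = TRUE)[[instrument]]
}

# EORTC linear transform for one scale across patients.
# items: matrix of responses (patients x member items), already range-checked.
score_scale <- function(items, range, type) {
  answered <- rowSums(!is.na(items))
  rs <- rowMeans(items, na.rm = TRUE)
  # half-rule: a scale is scored from answered items when at least half of
  # its members are answered
  rs[answered < ncol(items) / 2 | answered == 0] <- NA
  switch(type,
         functional = (1 - (rs - 1) / range) * 100,
         symptom = (rs - 1) / range * 100,
         global = (rs - 1) / range * 100)
}

score_instrument <- function(cohort, instrument, prefix, n_items,
                             seven_point = integer()) {
  map <- read_scale_map(instrument)
  items <- as.matrix(cohort[sprintf("%s%02d", prefix, seq_len(n_items))])
  lo <- rep(1L, n_items)
  hi <- ifelse(seq_len(n_items) %in% seven_point, 7L, 4L)
  for (j in seq_len(n_items)) {
    x <- items[, j]
    if (any(!is.na(x) & (x < lo[j] | x > hi[j]))) {
      stop("response out of range ", lo[j], "-", hi[j], " in item ",
           sprintf("%s%02d", prefix, j))
    }
  }
  scores <- vapply(map, function(sc) {
    score_scale(items[, sc$items, drop = FALSE], sc$range, sc$type)
  }, numeric(nrow(cohort)))
  scores <- matrix(scores, nrow = nrow(cohort),
                   dimnames = list(NULL, names(map)))
  out <- as.data.frame(scores)
  attr(out, "direction") <- vapply(map, `[[`, character(1), "direction")
  class(out) <- c("qol_scores", "data.frame")
  out
}

#' Score the EORTC QLQ-C30
#'
#' Items 1-28 are 4-point Likert responses, items 29-30 (overall health and
#' overall quality of life) 7-point. Raw scale scores (means of member
#' items) are linearly transformed to 0-100: functional scales and global
#' health so that 100 is the best possible state, symptom scales so that
#' 100 is the worst. Scales with under half their member items answered
#' score `NA`.
#'
#' @param cohort a `cachexia_cohort` data.frame (columns `qlq01`..`qlq30`).
#' @return data.frame of per-patient 0-100 scale scores, one column per
#'   scale, with a `direction` attribute (`higher_is_better` /
#'   `higher_is_worse` per scale).
#' @export
score_qlq_c30 <- function(cohort) {
  score_instrument(cohort, "qlq_c30", "qlq", 30L, seven_point = c(29L, 30L))
}

#' Score the EORTC QLQ-PAN26
#'
#' 26 pancreatic-cancer-specific 4-point items transformed linearly to
#' 0-100. Higher scores signify poorer quality of life for all scales
#' except healthcare satisfaction, where higher is better (see the
#' `direction` attribute).
#'
#' @param cohort a `cachexia_cohort` data.frame (columns `pan01`..`pan26`).
#' @return data.frame of per-patient 0-100 scale scores with a `direction`
#'   attribute.
#' @export
score_pan26 <- function(cohort) {
  score_instrument(cohort, "pan26", "pan", 26L)
}

#' Canadian Problem Checklist domain summary
#'
#' Counts ticked problems per supportive-care domain and reports each
#' patient's top-ranked domain. Ties break by a fixed domain order:
#' emotional, physical, informational, practical, spiritual, social,
#' family. Patients with no ticks have `top_domain = NA`.
#'
#' @param cohort a `cachexia_cohort` data.frame; `cpc_<domain>` columns hold
#'   `";"`-separated ticked item identifiers.
#' @return data.frame with one count column per domain plus `top_domain`.
#' @export
cpc_summary <- function(cohort) {
  domains <- cpc_domain_names()
  counts <- vapply(domains, function(d) {
    x <- cohort[[paste0("cpc_", d)]]
    vapply(strsplit(ifelse(is.na(x), "", x), ";"),
           function(it) sum(nzchar(it)), integer(1))
  }, integer(nrow(cohort)))
  counts <- matrix(counts, nrow = nrow(cohort),
                   dimnames = list(NULL, domains))
  tie_order <- c("emotional", "physical", "informational", "practical",
                 "spiritual", "social", "family")
  ordered <- counts[, tie_order, drop = FALSE]
  top <- tie_order[apply(ordered, 1L, which.max)]
  top[rowSums(counts) == 0] <- NA
  out <- as.data.frame(counts)
  out$top_domain <- top
  out
}
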