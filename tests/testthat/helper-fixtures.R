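# Fixture builders, all constructed in code at test time.

# A cohort of n clinically unremarkable patients; any column can be
# overridden with a recycled vector.
make_cohort <- function(n = 1, ...) {
  n1 <- max(n, 1L)
  base <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n1)),
    sex = "female", race_ethnicity = "NHW", age_at_diagnosis = 65,
    bmi = 25, weight_current = 70, weight_6mo_prior = 70,
    crp_research = 5, albumin = 4.0, wbc = 8000, hgb = 13,
    neutrophils = 3000, lymphocytes = 1500, ca19_9 = 20, platelets = 250,
    bilirubin = 0.8,
    pgsga_box2 = 0L, pgsga_box3 = 0L, pgsga_box4 = 0L,
    tumor_stage = "II", treatment = "surgery_only",
    survival_months = 12, event = "death"
  )
  for (item in cachexstage:::esas_item_names()) {
    base[[paste0("esas_", item)]] <- 0L
  }
  base <- base[seq_len(n), , drop = FALSE]
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- rep(over[[nm]], length.out = n)
  as_cachexia_cohort(base)
}

# weight history realizing a given percent loss (prior fixed at 80 kg)
weights_for_loss <- function(pct) {
  list(prior = 80, current = 80 * (1 - pct / 100))
}

# A 309-patient cohort built to the printed per-stage counts:
# stages 40 / 76 / 167 / 26; food-intake criterion in 8 + 28 + 10 = 46;
# impaired activity in 3 + 22 = 25; weight loss > 5% in 167 + 26 = 193;
# refractory cases with research CRP 14 yes / 4 no / 8 unmeasured.
printed_counts_cohort <- function() {
  nca <- make_cohort(40)
  pca <- make_cohort(
    76,
    patient_id = sprintf("PCA%03d", 1:76),
    wbc = 12000,                                   # criterion A for all
    weight_current = weights_for_loss(3)$current,  # minimal loss (C)
    weight_6mo_prior = weights_for_loss(3)$prior,
    pgsga_box2 = rep(c(3L, 0L), c(8, 68)),
    pgsga_box4 = rep(c(3L, 0L), c(3, 73))
  )
  ca <- make_cohort(
    167,
    patient_id = sprintf("CA%03d", 1:167),
    wbc = 12000,
    weight_current = weights_for_loss(7)$current,  # significant loss (D)
    weight_6mo_prior = weights_for_loss(7)$prior,
    pgsga_box2 = rep(c(3L, 0L), c(28, 139))
  )
  rca <- make_cohort(
    26,
    patient_id = sprintf("RCA%03d", 1:26),
    wbc = 12000,
    weight_current = weights_for_loss(8)$current,
    weight_6mo_prior = weights_for_loss(8)$prior,
    pgsga_box2 = rep(c(3L, 0L), c(10, 16)),
    pgsga_box4 = rep(c(4L, 0L), c(22, 4)),
    # the 4 preserved-activity refractory cases enter via severe
    # hypoalbuminemia with significant weight loss
    albumin = rep(c(4.0, 2.0), c(22, 4)),
    crp_research = rep(c(20, 5, NA), c(14, 4, 8))
  )
  out <- rbind(nca, pca, ca, rca)
  as_cachexia_cohort(out)
}

# flags data.frame for direct classify_stage calls
flags_df <- function(A = FALSE, B = FALSE, C = FALSE, D = FALSE,
                     E = FALSE, F = FALSE, alb_severe = FALSE,
                     stageable = TRUE) {
  data.frame(A = A, B = B, C = C, D = D, E = E, F = F,
             alb_severe = alb_severe, stageable = stageable)
}
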