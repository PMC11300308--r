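# Synthetic cohort generator. Emulates the statistical structure the
# analyses assume: a stage mix drawn from the published enrollment counts,
# stage-conditional criterion patterns sampled so that derived flags match
# the generating stage's combination rules exactly ("stage-consistent"
# generation), raw values placed strictly inside/outside each threshold,
# and stage-dependent proportional-hazards survival.

default_criterion_rates <- function() {
  # proposal marginals per stage for the staging flags; realized prevalences
  # are conditional on each stage's rule set (see generate_cohort)
  m <- rbind(
    NCa = c(A = 0,    B = 0,        C = 0.30, D = 0, F = 0,       alb_severe = 0),
    PCa = c(A = 0.55, B = 8 / 76,   C = 0.60, D = 0, F = 3 / 76,  alb_severe = 1 / 76),
    Ca  = c(A = 0.45, B = 28 / 167, C = 0,    D = 1, F = 0,       alb_severe = 0),
    RCa = c(A = 0.75, B = 10 / 26,  C = 0,    D = 1, F = 22 / 26, alb_severe = 6 / 26)
  )
  m
}

default_marker_rates <- function() {
  # per-stage prevalence of the non-staging marker abnormalities
  rbind(
    NCa = c(nlr = 4 / 40,  ca19_9 = 24 / 40,  platelets = 4 / 40,
            bilirubin = 3 / 40),
    PCa = c(nlr = 11 / 76, ca19_9 = 43 / 76,  platelets = 23 / 76,
            bilirubin = 20 / 76),
    Ca  = c(nlr = 37 / 167, ca19_9 = 113 / 167, platelets = 40 / 167,
            bilirubin = 91 / 167),
    RCa = c(nlr = 9 / 26,  ca19_9 = 12 / 26,  platelets = 8 / 26,
            bilirubin = 13 / 26)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the enrollment-time structure of the emulated cohort:
#' stage mix 40:76:167:26 over 309 stageable cases; per-stage criterion and
#' marker prevalences from the published criterion table; demographic mix
#' (50.6% female; NHW/AA/HL 236:35:47); survival exponential with
#' reference-arm median 14.6 months and stage hazard ratios 1 / 1.50 /
#' 1.87 / 3.24; censoring fraction 0.43 (the cohort's alive-or-unknown
#' fraction at analysis).
#'
#' @param seed integer seed; every draw the generator makes is reproducible
#'   from it.
#' @param n cohort size.
#' @param stage_mix probabilities over the four stages (named
#'   `NCa, PCa, Ca, RCa`); must sum to 1.
#' @param sampling `"multinomial"` (stage counts random, for simulation
#'   studies) or `"quota"` (exact largest-remainder counts, for table
#'   reproduction).
#' @param criterion_rates 4 x 6 matrix of per-stage proposal rates for
#'   flags `A, B, C, D, F, alb_severe`. Patterns are drawn from the
#'   conditional distribution given the generating stage's rule set, so a
#'   rate is a proposal marginal, not a realized prevalence.
#' @param marker_rates 4 x 4 matrix of per-stage rates for
#'   `nlr, ca19_9, platelets, bilirubin` abnormalities (non-staging).
#' @param sex_p probability of female.
#' @param race_p probabilities over `NHW, AA, HL`.
#' @param baseline_median reference-arm (NCa) median survival, months.
#' @param hazard_ratios per-stage hazard multipliers (NCa is reference).
#' @param censor_frac target fraction of patients censored by an
#'   independent uniform censoring time.
#' @param shape Weibull shape of the survival model (1 = exponential;
#'   hazard ratios act proportionally for any shape).
#' @param esas_mean per-stage mean used when drawing ESAS-r items.
#' @param soc_crp_p probability that the standard-of-care CRP is recorded
#'   (the research-assay value is always drawn).
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed,
                          n = 309,
                          stage_mix = c(NCa = 40, PCa = 76, Ca = 167,
                                        RCa = 26) / 309,
                          sampling = c("multinomial", "quota"),
                          criterion_rates = default_criterion_rates(),
                          marker_rates = default_marker_rates(),
                          sex_p = 161 / 318,
                          race_p = c(NHW = 236, AA = 35, HL = 47) / 318,
                          baseline_median = 14.6,
                          hazard_ratios = c(NCa = 1, PCa = 1.50, Ca = 1.87,
                                            RCa = 3.24),
                          censor_frac = 0.43,
                          shape = 1,
                          esas_mean = c(NCa = 1, PCa = 1.5, Ca = 2,
                                        RCa = 3.5),
                          soc_crp_p = 0.07) {
  if (missing(seed)) stop("config error: seed is mandatory")
  sampling <- match.arg(sampling)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n >= 1,
    length(stage_mix) == 4, abs(sum(stage_mix) - 1) < 1e-8,
    all(stage_mix >= 0),
    is.matrix(criterion_rates), nrow(criterion_rates) == 4,
    all(criterion_rates >= 0 & criterion_rates <= 1),
    all(marker_rates >= 0 & marker_rates <= 1),
    sex_p >= 0, sex_p <= 1,
    abs(sum(race_p) - 1) < 1e-8,
    baseline_median > 0, all(hazard_ratios > 0),
    censor_frac >= 0, censor_frac < 1, shape > 0,
    soc_crp_p >= 0, soc_crp_p <= 1
  )
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# All stage-consistent flag patterns with their stage labels. Patterns with
# both weight-loss criteria, or with severe hypoalbuminemia but a normal
# biochemistry criterion (impossible in raw-value space: albumin < 2.5
# implies albumin < 3.2 implies A), are excluded. E is the complement of F.
flag_pattern_space <- function() {
  g <- expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE),
                   C = c(FALSE, TRUE), D = c(FALSE, TRUE),
                   F = c(FALSE, TRUE), alb_severe = c(FALSE, TRUE))
  g <- g[!(g$C & g$D), ]
  g <- g[!(g$alb_severe & !g$A), ]
  g$E <- !g$F
  g$stage <- classify_stage(g)$label
  rownames(g) <- NULL
  g
}

# Conditional pattern distribution for one stage given proposal marginals.
stage_pattern_weights <- function(space, stage, rates) {
  flags <- c("A", "B", "C", "D", "F", "alb_severe")
  w <- rep(1, nrow(space))
  for (f in flags) {
    w <- w * ifelse(space[[f]], rates[[f]], 1 - rates[[f]])
  }
  keep <- space$stage == stage & w > 0
  if (!any(keep)) {
    stop("config error: no feasible criterion pattern for stage ", stage)
  }
  for (f in flags) {
    if (rates[[f]] > 0 && !any(space[[f]][keep])) {
      stop("config error: rate for flag ", f, " > 0 is infeasible for ",
           "stage ", stage, " in stage-consistent mode")
    }
  }
  list(idx = which(keep), w = w[keep] / sum(w[keep]))
}

runif_band <- function(n, lo, hi) stats::runif(n, lo, hi)

#' Generate a synthetic cohort with known truth
#'
#' Draws a stage for each patient, a criterion pattern from the conditional
#' distribution over stage-consistent patterns, raw laboratory and
#' instrument values strictly on the correct side of each threshold (so the
#' derived flags reproduce the pattern exactly), demographics, and
#' proportional-hazards survival with independent uniform censoring.
#' Identical config (including seed) gives a byte-identical cohort.
#'
#' @param config a [cohort_config()] list.
#' @return list with elements `cohort` (a `cachexia_cohort`) and `truth`
#'   (data.frame: `patient_id`, `true_stage`, `pattern`,
#'   `hazard_multiplier`, `event_time`, `censored`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(config$seed))
  n <- config$n
  th <- cachexia_thresholds()
  stages <- stage_levels()

  # --- stage assignment ---
  if (config$sampling == "quota") {
    quota <- floor(config$stage_mix * n)
    rem <- config$stage_mix * n - quota
    short <- n - sum(quota)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      quota[add] <- quota[add] + 1
    }
    stage <- sample(rep(stages, times = quota))
  } else {
    stage <- sample(stages, n, replace = TRUE, prob = config$stage_mix)
  }
  stage_i <- match(stage, stages)

  # --- criterion patterns, conditional on stage ---
  space <- flag_pattern_space()
  pat <- integer(n)
  for (s in stages) {
    sw <- stage_pattern_weights(space, s, config$criterion_rates[s, ])
    who <- which(stage == s)
    if (length(who)) {
      pat[who] <- sw$idx[sample.int(length(sw$w), length(who),
                                    replace = TRUE, prob = sw$w)]
    }
  }
  A <- space$A[pat]; B <- space$B[pat]; C <- space$C[pat]
  D <- space$D[pat]; Fimp <- space$F[pat]; S <- space$alb_severe[pat]

  # --- demographics ---
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(config$sex_p, 1 - config$sex_p))
  race <- sample(names(config$race_p), n, replace = TRUE,
                 prob = config$race_p)
  age <- pmin(pmax(round(stats::rnorm(n, 69.4, 9.8)), 30), 95)
  bmi <- round(pmin(pmax(stats::rnorm(n, 26.5, 4.5), 16), 45), 1)

  # --- weight history realizing C / D / neither ---
  prior <- round(runif_band(n, 55, 95), 1)
  loss <- numeric(n)
  loss[D] <- runif_band(sum(D), 5.6, 15)
  loss[C] <- runif_band(sum(C), 0.8, 4.6)
  loss[!C & !D] <- runif_band(sum(!C & !D), -3, -0.4)
  current <- round(prior * (1 - loss / 100), 1)

  # --- biochemistry components realizing A (and severe hypoalbuminemia) ---
  crp_hi <- alb_lo <- wbc_hi <- hgb_lo <- rep(FALSE, n)
  if (any(A)) {
    na_ <- sum(A)
    crp_hi[A] <- stats::runif(na_) < 0.35
    alb_lo[A] <- stats::runif(na_) < 0.30
    wbc_hi[A] <- stats::runif(na_) < 0.30
    hgb_lo[A] <- stats::runif(na_) < 0.45
  }
  alb_lo[S] <- TRUE
  none <- A & !(crp_hi | alb_lo | wbc_hi | hgb_lo)
  hgb_lo[none] <- TRUE

  crp <- ifelse(crp_hi, runif_band(n, th$crp_high * 1.05, th$crp_high * 1.5),
                runif_band(n, th$crp_high * 0.5, th$crp_high * 0.95))
  albumin <- ifelse(S, runif_band(n, 1.6, th$alb_severe - 0.05),
             ifelse(alb_lo, runif_band(n, th$alb_severe + 0.05,
                                       th$alb_low - 0.05),
                    runif_band(n, th$gps_alb, 4.7)))
  wbc <- ifelse(wbc_hi, runif_band(n, th$wbc_high * 1.01, th$wbc_high * 1.5),
                runif_band(n, th$wbc_high * 0.5, th$wbc_high * 0.99))
  hgb_cut <- ifelse(sex == "male", th$hgb_low_male, th$hgb_low_female)
  hgb <- ifelse(hgb_lo, hgb_cut - runif_band(n, 0.1, 3.5),
                hgb_cut + runif_band(n, 0.1, 3.5))
  crp_soc <- ifelse(stats::runif(n) < config$soc_crp_p, crp, NA_real_)

  # --- non-staging markers ---
  mr <- config$marker_rates[stage_i, , drop = FALSE]
  u <- matrix(stats::runif(4L * n), nrow = n)
  nlr_hi <- u[, 1] < mr[, "nlr"]
  lymph <- round(runif_band(n, 1000, 2500))
  neut <- round(lymph * ifelse(nlr_hi, runif_band(n, th$nlr_high, 8),
                               runif_band(n, 1.2, th$nlr_high - 0.2)))
  ca19 <- ifelse(u[, 2] < mr[, "ca19_9"],
                 runif_band(n, th$ca19_9_high * 1.01, th$ca19_9_high * 1.5),
                 runif_band(n, th$ca19_9_high * 0.5, th$ca19_9_high * 0.99))
  plt <- ifelse(u[, 3] < mr[, "platelets"],
                runif_band(n, th$platelets_high * 1.01,
                           th$platelets_high * 1.5),
                runif_band(n, th$platelets_high * 0.5,
                           th$platelets_high * 0.99))
  bili <- ifelse(u[, 4] < mr[, "bilirubin"],
                 runif_band(n, th$bilirubin_high * 1.05,
                            th$bilirubin_high * 1.5),
                 runif_band(n, th$bilirubin_high * 0.5,
                            th$bilirubin_high * 0.95))

  # --- aPG-SGA boxes realizing B and E/F ---
  box2 <- ifelse(B, sample(2:4, n, replace = TRUE),
                 sample(0:1, n, replace = TRUE))
  box4 <- ifelse(Fimp, sample(3:4, n, replace = TRUE),
                 sample(0:2, n, replace = TRUE))
  box3 <- stats::rpois(n, 1.5)

  # --- ESAS-r items (stage-shifted), CPC ticks, QoL items ---
  esas <- vapply(esas_item_names(), function(it) {
    pmin(pmax(round(stats::rnorm(n, config$esas_mean[stage_i], 2)), 0), 10)
  }, numeric(n))
  cpc_p <- c(emotional = 0.56, physical = 0.465, informational = 0.414,
             practical = 0.2, spiritual = 0.1, social = 0.15, family = 0.15)
  cpc <- lapply(cpc_domain_names(), function(d) {
    k <- stats::rbinom(n, 3, cpc_p[[d]])
    vapply(k, function(ki) {
      if (ki == 0) NA_character_
      else paste0(d, "_", seq_len(ki), collapse = ";")
    }, character(1))
  })
  names(cpc) <- paste0("cpc_", cpc_domain_names())
  qlq <- lapply(1:30, function(j) {
    if (j >= 29) sample(1:7, n, replace = TRUE)
    else sample(1:4, n, replace = TRUE)
  })
  names(qlq) <- sprintf("qlq%02d", 1:30)
  pan <- lapply(1:26, function(j) sample(1:4, n, replace = TRUE))
  names(pan) <- sprintf("pan%02d", 1:26)

  # --- proportional-hazards survival with independent uniform censoring ---
  hr <- config$hazard_ratios[stage_i]
  k <- config$shape
  b <- config$baseline_median / log(2)^(1 / k)
  t_event <- b * (-log(stats::runif(n)) / hr)^(1 / k)
  cens <- censor_uniform(t_event, config$censor_frac)

  esas_df <- as.data.frame(esas)
  names(esas_df) <- paste0("esas_", esas_item_names())
  cohort <- as_cachexia_cohort(cbind(
    data.frame(
      patient_id = sprintf("SYN%04d", seq_len(n)),
      sex = sex, race_ethnicity = race, age_at_diagnosis = age, bmi = bmi,
      weight_current = current, weight_6mo_prior = prior,
      crp_soc = round(crp_soc, 2), crp_research = round(crp, 2),
      albumin = round(albumin, 2), wbc = round(wbc),
      hgb = round(hgb, 1), neutrophils = neut, lymphocytes = lymph,
      ca19_9 = round(ca19, 1), platelets = round(plt),
      bilirubin = round(bili, 2),
      pgsga_box2 = box2, pgsga_box3 = box3, pgsga_box4 = box4,
      grip_hand = "not_at_all", grip_fingers = "not_at_all"
    ),
    esas_df,
    as.data.frame(cpc, stringsAsFactors = FALSE),
    as.data.frame(qlq), as.data.frame(pan),
    data.frame(
      tumor_stage = sample(tumor_stage_levels(), n, replace = TRUE,
                           prob = c(56, 78, 38, 84, 62) / 318),
      treatment = sample(treatment_levels(), n, replace = TRUE,
                         prob = c(98, 84, 111, 24) / 318),
      survival_months = round(cens$time, 3),
      event = ifelse(cens$event, "death", "censored")
    )
  ))
  pattern <- apply(cbind(A = A, B = B, C = C, D = D, E = !Fimp, F = Fimp,
                         `Alb<2.5` = S), 1L,
                   function(r) paste(names(r)[r], collapse = "+"))
  truth <- data.frame(patient_id = cohort$patient_id, true_stage = stage,
                      pattern = pattern, hazard_multiplier = unname(hr),
                      event_time = t_event, censored = !cens$event)
  list(cohort = cohort, truth = truth)
}

# Independent uniform censoring C ~ U(0, tau), with tau solved so the
# expected censored fraction matches the target. Because C is independent
# of the event time, the Kaplan-Meier estimator stays consistent.
censor_uniform <- function(t_event, frac) {
  n <- length(t_event)
  if (frac <= 0) {
    return(list(time = t_event, event = rep(TRUE, n)))
  }
  f <- function(tau) mean(pmin(t_event / tau, 1)) - frac
  tau <- stats::uniroot(f, lower = min(t_event) * 1e-6,
                        upper = max(t_event) * 1e6, tol = 1e-8)$root
  cens_time <- stats::runif(n, 0, tau)
  event <- t_event <= cens_time
  list(time = pmin(t_event, cens_time), event = event)
}

#' Simulate a single survival arm
#'
#' Draws `n` event times from a Weibull (default exponential) model whose
#' baseline median is `median_months`, multiplies the hazard by
#' `hazard_ratio`, and applies independent uniform censoring to the target
#' fraction. Uses the current RNG state; seed with `set.seed()`.
#'
#' @param n number of patients.
#' @param median_months baseline median survival.
#' @param hazard_ratio hazard multiplier versus baseline.
#' @param censor_frac target censored fraction.
#' @param shape Weibull shape (1 = exponential).
#' @return data.frame with `time` (months) and logical `event`.
#' @export
simulate_survival <- function(n, median_months = 14.6, hazard_ratio = 1,
                              censor_frac = 0, shape = 1) {
  stopifnot(n >= 1, median_months > 0, hazard_ratio > 0,
            censor_frac >= 0, censor_frac < 1, shape > 0)
  b <- median_months / log(2)^(1 / shape)
  t_event <- b * (-log(stats::runif(n)) / hazard_ratio)^(1 / shape)
  cens <- censor_uniform(t_event, censor_frac)
  data.frame(time = cens$time, event = cens$event)
}

#' Blank fields at configured rates
#'
#' Emulates the missing-data pattern of real registries (unrecorded labs,
#' absent weight histories) by independently setting each listed field to
#' `NA` at its rate. Rates of zero leave the cohort unchanged.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param rates named list/vector: field name -> missing rate in `[0, 1]`.
#' @return the perturbed cohort.
#' @export
perturb_missingness <- function(cohort, rates) {
  stopifnot(inherits(cohort, "cachexia_cohort"))
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) {
    stop("missing rates must be in [0, 1]")
  }
  absent <- setdiff(names(rates), names(cohort))
  if (length(absent)) stop("unknown field(s): ", paste(absent, collapse = ", "))
  for (f in names(rates)) {
    cohort[[f]][stats::runif(nrow(cohort)) < rates[[f]]] <- NA
  }
  cohort
}
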