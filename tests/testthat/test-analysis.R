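test_that("criterion prevalence tables reconcile and use full-stage denominators", {
  co <- printed_counts_cohort()
  st <- stage_cohort(co)
  crit <- derive_criteria(co)
  labs <- lab_criteria(co)
  tab <- criterion_prevalence_table(
    data.frame(B = crit$B, F = crit$F, crp_high = labs$crp_high),
    st$labels$label)
  # Yes + No + NA = stage n everywhere
  expect_true(all(tab$yes + tab$no + tab$na == tab$n_stage))
  # refractory research-CRP prevalence over the full 26 (8 unmeasured)
  rca_crp <- tab[tab$criterion == "crp_high" & tab$stage == "RCa", ]
  expect_equal(rca_crp$yes, 14)
  expect_equal(rca_crp$pct_yes, round_half_up(100 * 14 / 26, 2))
  # a zero-member stage yields a zero row, no division error
  tab2 <- criterion_prevalence_table(data.frame(B = c(TRUE, FALSE)),
                                     c("PCa", "PCa"))
  expect_equal(tab2$n_stage[tab2$stage == "RCa"], 0)
  expect_equal(tab2$pct_yes[tab2$stage == "RCa"], 0)
})

test_that("prevalence recovered from generator output matches configured rates", {
  g <- generate_cohort(cohort_config(seed = 51, n = 2000))
  st <- stage_cohort(g$cohort)
  crit <- derive_criteria(g$cohort)
  tab <- criterion_prevalence_table(data.frame(D = crit$D), st$labels$label)
  # significant weight loss is certain for Ca/RCa, absent for NCa/PCa
  expect_equal(tab$pct_yes[tab$criterion == "D"], c(0, 0, 100, 100))
})

test_that("chi-square wrapper matches the hand-computed statistic", {
  # homogeneous table: statistic 0, p 1
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square_test(even)$statistic, 0)
  expect_equal(chi_square_test(even)$p_value, 1)
  # 2x3 fixture, hand-computed Pearson statistic:
  # rows (20,30,50) / (40,30,30); expected under homogeneity from margins
  tab <- matrix(c(20, 40, 30, 30, 50, 30), nrow = 2)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  by_hand <- sum((tab - expected)^2 / expected)
  got <- chi_square_test(tab)
  expect_equal(got$statistic, by_hand, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_error(chi_square_test(matrix(1:3, nrow = 1)), "degenerate")
  expect_warning(chi_square_test(matrix(c(2, 3, 4, 1), 2)), "below 5")
})

test_that("Kruskal-Wallis wrapper behaves on identical and shifted samples", {
  x <- c(1, 2, 3, 4, 5)
  same <- kruskal_wallis(c(x, x), rep(c("a", "b"), each = 5))
  expect_lt(same$statistic, 1e-10)
  shifted <- kruskal_wallis(c(x, x + 100), rep(c("a", "b"), each = 5))
  expect_lt(shifted$p_value, 0.05)
  expect_error(kruskal_wallis(x, rep("a", 5)), "two non-empty groups")
})

test_that("Cochran-Armitage trend: nulls, direction, antisymmetry", {
  # equal rates across ordered groups: Z = 0
  null <- cochran_armitage_trend(c(10, 10, 10, 10), rep(100, 4))
  expect_equal(null$z, 0)
  expect_equal(null$p_value, 1)
  # strictly increasing rates at n = 100/group: positive, significant
  inc <- cochran_armitage_trend(c(10, 20, 30, 40), rep(100, 4))
  expect_gt(inc$z, 0)
  expect_lt(inc$p_value, 0.05)
  # reversing group order flips the sign
  rev_ <- cochran_armitage_trend(c(40, 30, 20, 10), rep(100, 4))
  expect_equal(rev_$z, -inc$z, tolerance = 1e-12)
  expect_warning(deg <- cochran_armitage_trend(c(0, 0, 0), rep(50, 3)),
                 "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("Cochran-Armitage agrees with a permutation oracle on random tables", {
  # permutation oracle: shuffle the 0/1 outcomes over patients, re-tally
  # per group, and use the score-sum statistic (the totals, pooled rate,
  # and variance term are permutation-invariant, so only the numerator of
  # Z changes)
  perm_p <- function(yes, total, n_perm = 10000) {
    obs <- cochran_armitage_trend(yes, total)$z
    w <- seq_along(yes) - 1
    outcomes <- rep(rep(c(1L, 0L), length(yes)),
                    as.vector(rbind(yes, total - yes)))
    grp <- factor(rep(seq_along(total), total))
    p_bar <- sum(yes) / sum(total)
    den <- sqrt(p_bar * (1 - p_bar) *
                  (sum(total * w^2) - sum(total * w)^2 / sum(total)))
    zs <- vapply(seq_len(n_perm), function(b) {
      ys <- as.vector(rowsum(sample(outcomes), grp))
      sum(w * (ys - total * p_bar)) / den
    }, numeric(1))
    # mid-p: half-weight to the permutation mass exactly at the observed
    # statistic, the standard comparison for a continuous approximation
    # to a discrete permutation distribution
    mean(abs(zs) > abs(obs) + 1e-12) +
      0.5 * mean(abs(abs(zs) - abs(obs)) <= 1e-12)
  }
  set.seed(77)
  for (i in 1:20) {
    total <- sample(30:60, 4, replace = TRUE)
    yes <- vapply(total, function(n) rbinom(1, n, runif(1, 0.2, 0.8)),
                  integer(1))
    if (sum(yes) == 0 || sum(yes) == sum(total)) next
    asym <- cochran_armitage_trend(yes, total)$p_value
    # the normal approximation tracks the skewed discrete permutation
    # distribution to a few hundredths at these group sizes
    expect_lt(abs(asym - perm_p(yes, total)), 0.04)
  }
})

test_that("KM estimator matches hand-computed product-limit values", {
  # no censoring: estimator equals the empirical survival function
  f <- km_fit(c(1, 2, 3, 4, 5), rep(TRUE, 5))
  expect_equal(f$curves$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(f$medians$median, 3)
  # all censored: flat at 1, median undefined
  f2 <- km_fit(c(1, 2, 3), rep(FALSE, 3))
  expect_equal(nrow(f2$curves), 0)
  expect_true(is.na(f2$medians$median))
  # interleaved censoring, hand-computed:
  # times 1(d) 2(c) 3(d) 4(d) 5(c) 6(d); risk sets 6,4,3,1
  # S = 5/6, 5/6*3/4, 5/6*3/4*2/3, ..., then * 0
  f3 <- km_fit(c(1, 2, 3, 4, 5, 6),
               c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(f3$curves$surv,
               c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(km_surv_at(f3, c(0.5, 3.5)), c(1, 5 / 6 * 3 / 4))
})

test_that("KM and log-rank agree with the survival package on a mixed fixture", {
  set.seed(9)
  time <- round(rexp(120, 1 / 10), 2)
  event <- runif(120) < 0.7
  grp <- rep(c("a", "b"), 60)
  f <- km_fit(time, event, grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  expect_equal(f$curves$surv[f$curves$group == "a"],
               summary(sf[1], times = sort(unique(time[event & grp == "a"])))$surv,
               tolerance = 1e-10)
  lr <- logrank_test(time, event, grp)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-8)
  # identical groups: statistic ~ 0
  dup <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("x", "y"), each = 120))
  expect_lt(dup$statistic, 1e-10)
  expect_error(logrank_test(time, event, rep("one", 120)), "two")
})

test_that("log-rank detects a threefold hazard at realistic power", {
  set.seed(33)
  hits <- 0L
  for (b in 1:40) {
    a <- simulate_survival(500, 14.6, 1, 0.2)
    d <- simulate_survival(500, 14.6, 3, 0.2)
    lr <- logrank_test(c(a$time, d$time), c(a$event, d$event),
                       rep(c("ref", "hr3"), each = 500))
    hits <- hits + (lr$p_value < 0.001)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Cox fit recovers null and strong hazard ratios and flags degenerate input", {
  set.seed(14)
  a <- simulate_survival(1000, 14.6, 1, 0.2)
  b <- simulate_survival(1000, 14.6, 1, 0.2)
  df <- data.frame(survival_months = c(a$time, b$time),
                   event = c(a$event, b$event),
                   arm = rep(c(0, 1), each = 1000))
  fit <- cox_ph_fit(df, covariates = "arm")
  expect_gt(fit$terms$hr, 0.9)
  expect_lt(fit$terms$hr, 1.1)
  expect_error(cox_ph_fit(transform(df, arm = 1), covariates = "arm"),
               "constant")
})

test_that("Cox CIs cover the generating stage hazard ratios", {
  hrs <- c(PCa = 1.50, Ca = 1.87, RCa = 3.24)
  set.seed(26)
  cover <- matrix(FALSE, 50, 3, dimnames = list(NULL, names(hrs)))
  for (b in 1:50) {
    arms <- lapply(c(NCa = 1, hrs),
                   function(h) simulate_survival(1250, 14.6, h, 0.2))
    df <- data.frame(
      survival_months = unlist(lapply(arms, `[[`, "time")),
      event = unlist(lapply(arms, `[[`, "event")),
      stage = factor(rep(c("NCa", names(hrs)), each = 1250),
                     levels = c("NCa", names(hrs))))
    fit <- cox_ph_fit(df, covariates = "stage")
    for (s in names(hrs)) {
      row <- fit$terms[fit$terms$term == paste0("stage", s), ]
      cover[b, s] <- row$lower <= hrs[[s]] && hrs[[s]] <= row$upper
    }
  }
  expect_true(all(colMeans(cover) >= 0.9))
})

test_that("symptom burden report counts moderate-to-severe subscores", {
  co <- make_cohort(10)
  rep0 <- symptom_burden_report(co)
  expect_true(all(rep0$overall$pct_severe == 0))
  co$esas_pain[1] <- 8L
  co$esas_tiredness[1] <- 4L
  co$esas_drowsiness[1] <- 6L
  co$esas_nausea[1] <- 4L
  co$esas_appetite[1] <- 4L
  co$esas_shortness_of_breath[1] <- 4L
  co$esas_anxiety[1] <- 5L
  co$esas_depression[1] <- 5L
  co$esas_wellbeing[1] <- 5L
  # tiny groups trip the expected-count warning by design
  r <- suppressWarnings(symptom_burden_report(co, by = rep(c("g1", "g2"),
                                                           each = 5)))
  expect_equal(r$overall$pct_severe[r$overall$subscore == "total"], 10)
  g1 <- r$by_group[r$by_group$group == "g1", ]
  expect_equal(g1$pct_severe[g1$subscore == "physical"], 20)
  expect_equal(nrow(r$tests), 3)
})

test_that("generator symptom severity is recovered by the report", {
  g <- generate_cohort(cohort_config(seed = 41, n = 600))
  r <- symptom_burden_report(g$cohort)
  s <- esas_subscores(g$cohort)
  truth_pct <- round_half_up(100 * mean(s$total >= 4, na.rm = TRUE), 1)
  expect_equal(r$overall$pct_severe[r$overall$subscore == "total"],
               truth_pct)
})
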