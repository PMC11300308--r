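test_that("food-intake and activity criteria follow the box-score cuts", {
  expect_equal(criterion_food_intake(c(2L, 1L, 0L, NA)),
               c(TRUE, FALSE, FALSE, NA))
  act <- criterion_activity(c(2L, 3L, 0L, NA))
  expect_equal(act$E, c(TRUE, FALSE, TRUE, NA))
  expect_equal(act$F, c(FALSE, TRUE, FALSE, NA))
  # mutually exclusive and exhaustive whenever box 4 is answered
  b4 <- 0:10
  a <- criterion_activity(b4)
  expect_true(all(xor(a$E, a$F)))
})

test_that("weight-loss criteria split at 5% with stability meeting neither", {
  wl <- weight_loss_criteria(c(94, 96, 100, 103), c(100, 100, 100, 100))
  expect_equal(wl$pct_loss, c(6, 4, 0, -3))
  expect_equal(wl$C, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(wl$D, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(!any(wl$C & wl$D))
  # missing prior weight propagates as NA, not FALSE
  wl2 <- weight_loss_criteria(70, NA)
  expect_true(is.na(wl2$C) && is.na(wl2$D))
})

test_that("ESAS subscores average the right items and dichotomize at 4", {
  co <- make_cohort(3)
  co$esas_anxiety <- c(0L, 4L, 0L)
  co$esas_pain <- c(0L, 0L, 6L)
  co$esas_tiredness <- c(0L, 0L, 6L)
  s <- esas_subscores(co)
  expect_equal(s$physical, c(0, 0, 2))       # (6+6)/6 physical items
  expect_equal(s$psychological, c(0, 2, 0))  # (4+0)/2
  expect_equal(s$total[1], 0)
  expect_equal(s$severe_anxiety, c(FALSE, TRUE, FALSE))
  expect_false(any(s$low_coverage))

  # partial panels: mean of available items, low-coverage flagged < 50%
  part <- make_cohort(1)
  for (it in cachexstage:::esas_item_names()) {
    part[[paste0("esas_", it)]] <- NA_integer_
  }
  part$esas_pain <- 6L
  part$esas_tiredness <- 2L
  sp <- esas_subscores(part)
  expect_equal(sp$physical, 4)
  expect_true(is.na(sp$psychological))
  expect_equal(sp$total, 4)
  expect_true(sp$low_coverage)

  # raising one item by 1 never lowers any subscore
  set.seed(31)
  for (rep in 1:20) {
    co <- make_cohort(1)
    items <- paste0("esas_", cachexstage:::esas_item_names())
    for (it in items) co[[it]] <- sample(0:9, 1)
    s0 <- esas_subscores(co)
    bump <- sample(items, 1)
    co[[bump]] <- co[[bump]] + 1L
    s1 <- esas_subscores(co)
    expect_true(all(unlist(s1[c("physical", "psychological", "total")]) >=
                      unlist(s0[c("physical", "psychological", "total")])))
  }
})

test_that("QLQ-C30 transforms anchor to 0-100 and match the manual formula", {
  co <- make_cohort(3)
  co$qlq29 <- c(7L, 1L, 4L)
  co$qlq30 <- c(7L, 1L, 4L)
  for (j in sprintf("qlq%02d", 1:28)) co[[j]] <- 1L
  # 2-item symptom scale (pain: items 9, 19) answered (1, 3): RS = 2,
  # score = (2 - 1) / 3 * 100 = 33.33
  co$qlq09 <- c(1L, 1L, 1L)
  co$qlq19 <- c(1L, 1L, 3L)
  sc <- score_qlq_c30(co)
  expect_equal(sc$global_health, c(100, 0, 50))
  expect_equal(sc$pain[3], 100 / 3, tolerance = 1e-10)
  # best-anchor responses give 100 on functional scales, 0 on symptoms
  expect_equal(sc$physical_functioning[1], 100)
  expect_equal(sc$fatigue[1], 0)
  expect_true(all(as.matrix(sc) >= 0 & as.matrix(sc) <= 100, na.rm = TRUE))
  # out-of-range response rejected
  co$qlq01 <- 5L
  expect_error(score_qlq_c30(co), "qlq01")
})

test_that("PAN26 endpoints and single-item transform are exact", {
  co <- make_cohort(3)
  for (j in sprintf("pan%02d", 1:26)) co[[j]] <- c(4L, 1L, 1L)
  co$pan08 <- c(4L, 1L, 3L)   # single-item taste scale: 3 -> 66.67
  sc <- score_pan26(co)
  expect_true(all(as.matrix(sc)[1, ] == 100))
  expect_true(all(as.matrix(sc)[2, ] == 0))
  expect_equal(sc$taste[3], 200 / 3, tolerance = 1e-10)
  dir <- attr(sc, "direction")
  expect_equal(unname(dir["healthcare_satisfaction"]), "higher_is_better")
  expect_true(all(dir[setdiff(names(dir), "healthcare_satisfaction")] ==
                    "higher_is_worse"))
})

test_that("symptom-scale scores are monotone in their items", {
  set.seed(17)
  for (rep in 1:10) {
    co <- make_cohort(1)
    for (j in sprintf("qlq%02d", 1:28)) co[[j]] <- sample(1:3, 1)
    co$qlq29 <- co$qlq30 <- 4L
    s0 <- score_qlq_c30(co)
    j <- sprintf("qlq%02d", sample(c(8:19, 28), 1))  # a symptom item
    co[[j]] <- co[[j]] + 1L
    s1 <- score_qlq_c30(co)
    sym <- c("fatigue", "nausea_vomiting", "pain", "dyspnoea", "insomnia",
             "appetite_loss", "constipation", "diarrhoea",
             "financial_difficulties")
    expect_true(all(unlist(s1[sym]) >= unlist(s0[sym])))
  }
})

test_that("CPC domain tallies count ticks and break ties by fixed order", {
  co <- make_cohort(3,
    cpc_emotional = c(NA, "fear;worry", "fear"),
    cpc_physical = c(NA, "sleep", "sleep"))
  s <- cpc_summary(co)
  expect_equal(s$emotional, c(0, 2, 1))
  expect_equal(s$physical, c(0, 1, 1))
  expect_true(is.na(s$top_domain[1]))
  expect_equal(s$top_domain[2], "emotional")
  expect_equal(s$top_domain[3], "emotional")  # tie -> emotional first
})
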