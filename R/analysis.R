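# Analytic outputs: criterion prevalence tables by stage, group-comparison
# wrappers (chi-square, Kruskal-Wallis), the Cochran-Armitage trend test
# across the ordered stages, and symptom-burden summaries.

#' Criterion prevalence table by stage
#'
#' Yes / No / NA counts for each criterion within each stage. Percentages
#' use the full stage count as denominator (NA rows included, matching the
#' convention of the emulated cohort's published table) and are rounded
#' half-up to two decimals. Counts always reconcile:
#' `Yes + No + NA = n` for every stage and criterion.
#'
#' @param criteria data.frame of logical criterion columns (`NA` =
#'   unmeasured), one row per patient — e.g. selected columns of
#'   [derive_criteria()] or [lab_criteria()] output.
#' @param labels vector of stage labels aligned with `criteria` rows
#'   (e.g. `stage_cohort(x)$labels$label`); unstageable patients are
#'   excluded.
#' @return data.frame of class `"criterion_table"` with columns
#'   `criterion`, `stage`, `n_stage`, `yes`, `no`, `na`, `pct_yes`,
#'   `pct_no`, `pct_na`.
#' @export
criterion_prevalence_table <- function(criteria, labels) {
  stopifnot(nrow(criteria) == length(labels))
  keep <- labels %in% stage_levels()
  criteria <- criteria[keep, , drop = FALSE]
  stage <- factor(labels[keep], levels = stage_levels())
  rows <- list()
  for (cr in names(criteria)) {
    x <- criteria[[cr]]
    for (s in stage_levels()) {
      xs <- x[stage == s]
      n <- length(xs)
      yes <- sum(xs %in% TRUE); no <- sum(xs %in% FALSE)
      nna <- sum(is.na(xs))
      pct <- function(k) if (n == 0) 0 else round_half_up(100 * k / n, 2)
      rows[[length(rows) + 1]] <- data.frame(
        criterion = cr, stage = s, n_stage = n, yes = yes, no = no,
        na = nna, pct_yes = pct(yes), pct_no = pct(no), pct_na = pct(nna))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("criterion_table", "data.frame")
  out
}

#' Chi-square test of homogeneity on a contingency table
#'
#' Pearson chi-square without continuity correction, via the standard
#' routine. Warns when any expected cell count is below 5; errors on a
#' degenerate (single row or column) table.
#'
#' @param table matrix of non-negative counts (groups x categories).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("degenerate table: need at least 2 rows and 2 columns")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected count below 5 in ", sum(ht$expected < 5), " cell(s)")
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Kruskal-Wallis rank test across groups
#'
#' @param values numeric outcome.
#' @param groups grouping vector (at least two non-empty groups).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  groups <- factor(as.character(groups)[keep])
  if (nlevels(groups) < 2) stop("need at least two non-empty groups")
  ht <- stats::kruskal.test(values[keep], groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Cochran-Armitage test for trend across ordered groups
#'
#' Tests for a linear trend in a binary outcome's prevalence over ordered
#' groups (here, the cachexia stages). With group scores `w_i`, successes
#' `y_i`, totals `n_i`, pooled rate `p`:
#' `Z = sum(w_i (y_i - n_i p)) / sqrt(p (1 - p) (sum(n_i w_i^2) -
#' (sum(n_i w_i))^2 / N))`,
#' with a two-sided p-value from the standard normal. Reversing the group
#' order flips the sign of `Z`. An all-zero or all-one outcome is
#' degenerate: `Z = 0`, `p = 1`, with a warning.
#'
#' @param counts_yes successes per group, in group order.
#' @param counts_total totals per group.
#' @param scores ordered group scores (default `0, 1, 2, ...`).
#' @return list with `z`, `p_value`, `scores`.
#' @export
cochran_armitage_trend <- function(counts_yes, counts_total,
                                   scores = seq_along(counts_yes) - 1) {
  stopifnot(length(counts_yes) == length(counts_total),
            length(scores) == length(counts_yes),
            all(counts_yes >= 0), all(counts_total >= counts_yes))
  N <- sum(counts_total)
  p <- sum(counts_yes) / N
  if (p %in% c(0, 1)) {
    warning("degenerate outcome (all ",
            if (p == 0) "failures" else "successes", "); p = 1")
    return(list(z = 0, p_value = 1, scores = scores))
  }
  num <- sum(scores * (counts_yes - counts_total * p))
  den <- sqrt(p * (1 - p) *
                (sum(counts_total * scores^2) -
                   sum(counts_total * scores)^2 / N))
  z <- num / den
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), scores = scores)
}

#' Symptom-burden report
#'
#' Frequencies of moderate-to-severe (subscore `>= 4`) physical,
#' psychological, and total ESAS-r subscores, overall and optionally
#' within groups (sex, race/ethnicity, stage), with chi-square
#' comparisons across groups where both severity levels occur.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param by optional grouping vector aligned with the cohort rows.
#' @param thresholds a [cachexia_thresholds()] list.
#' @return list with `overall` (data.frame `subscore`, `n`, `n_severe`,
#'   `pct_severe`) and, when `by` is given, `by_group` (adds `group`) and
#'   `tests` (chi-square per subscore, `NA` p-value when degenerate).
#' @export
symptom_burden_report <- function(cohort, by = NULL,
                                  thresholds = cachexia_thresholds()) {
  sub <- esas_subscores(cohort, thresholds = thresholds)
  cut <- thresholds$esas_severe
  scores <- c("physical", "psychological", "total")
  summarize <- function(idx, label = NULL) {
    do.call(rbind, lapply(scores, function(sc) {
      x <- sub[[sc]][idx]
      x <- x[!is.na(x)]
      out <- data.frame(subscore = sc, n = length(x),
                        n_severe = sum(x >= cut),
                        pct_severe = if (length(x)) {
                          round_half_up(100 * mean(x >= cut), 1)
                        } else NA_real_)
      if (!is.null(label)) out <- cbind(group = label, out)
      out
    }))
  }
  out <- list(overall = summarize(seq_len(nrow(sub))))
  if (!is.null(by)) {
    stopifnot(length(by) == nrow(cohort))
    groups <- unique(stats::na.omit(as.character(by)))
    out$by_group <- do.call(rbind, lapply(groups, function(g) {
      summarize(which(as.character(by) == g), g)
    }))
    out$tests <- do.call(rbind, lapply(scores, function(sc) {
      sev <- sub[[sc]] >= cut
      keep <- !is.na(sev) & !is.na(by)
      tab <- table(as.character(by)[keep], sev[keep])
      p <- if (nrow(tab) >= 2 && ncol(tab) >= 2) {
        chi_square_test(tab)$p_value
      } else NA_real_
      data.frame(subscore = sc, p_value = p)
    }))
  }
  out
}
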