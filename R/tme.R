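#' Aggregate ROI phenotypes to a patient sub-TME class
#'
#' Rules:
#' * `"any-h"` (default): a patient is high-complex (`HCs-TME`) iff at
#'   least one of its ROIs is h-ITH;
#' * `"non-uniform"`: `HCs-TME` iff the patient's ROIs span more than
#'   one phenotype;
#' * `"majority-h"`: `HCs-TME` iff more than half of the ROIs are h-ITH.
#'
#' @param phenotypes named character vector, ROI -> phenotype
#'   (`"h-ITH"`, `"m-ITH"`, `"l-ITH"`; bare `"h"/"m"/"l"` also accepted).
#' @param patients named character vector, ROI -> patient id.
#' @param rule aggregation rule, see above.
#' @param c_scores optional [c_score_table()] output; adds each
#'   patient's median C-score to the summary.
#' @return data.frame with `patient_id`, phenotype counts `n_h`, `n_m`,
#'   `n_l`, `tme_class`, and `median_c_score` (NA when `c_scores` is
#'   absent or the patient has no pair).
#' @export
classify_patient_tme <- function(phenotypes, patients,
                                 rule = c("any-h", "non-uniform", "majority-h"),
                                 c_scores = NULL) {
  rule <- match.arg(rule)
  check_that(!is.null(names(phenotypes)), "phenotypes must be named by ROI")
  miss <- setdiff(names(phenotypes), names(patients))
  check_that(length(miss) == 0, "ROI(s) without patient mapping: %s",
             paste(miss, collapse = ", "))
  ph <- sub("-ITH$", "", phenotypes)
  check_that(all(ph %in% c("h", "m", "l")),
             "unknown phenotype label(s): %s",
             paste(unique(phenotypes[!ph %in% c("h", "m", "l")]), collapse = ", "))
  pat <- patients[names(phenotypes)]
  per <- lapply(split(ph, pat), function(p) {
    n_h <- sum(p == "h"); n_m <- sum(p == "m"); n_l <- sum(p == "l")
    hcs <- switch(rule,
                  "any-h" = n_h >= 1,
                  "non-uniform" = length(unique(p)) > 1,
                  "majority-h" = n_h > length(p) / 2)
    data.frame(n_h = n_h, n_m = n_m, n_l = n_l,
               tme_class = if (hcs) "HCs-TME" else "LCs-TME",
               stringsAsFactors = FALSE)
  })
  out <- data.frame(patient_id = names(per), do.call(rbind, per),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$median_c_score <- NA_real_
  if (!is.null(c_scores)) {
    med <- vapply(split(c_scores$c_score, c_scores$patient_id),
                  stats::median, numeric(1), na.rm = TRUE)
    out$median_c_score <- unname(med[out$patient_id])
  }
  attr(out, "rule") <- rule
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the two-sided log-rank
#' chi-square test (1 df), via the `survival` package. With zero
#' observed events the statistic is 0 by convention (warning).
#'
#' @param surv data.frame with columns `patient_id`, `time`, `event`
#'   (1 = event, 0 = censored).
#' @param groups named character vector, patient id -> group label
#'   (exactly 2 distinct groups among matched patients).
#' @return list with `fit` (a [survival::survfit()] object),
#'   `logrank_stat`, `p`, and `n_per_group`.
#' @export
compare_survival <- function(surv, groups) {
  check_that(all(c("patient_id", "time", "event") %in% names(surv)),
             "surv must contain patient_id, time, event")
  check_that(all(surv$time > 0), "survival times must be positive")
  g <- groups[surv$patient_id]
  check_that(!anyNA(g), "patient(s) without group: %s",
             paste(surv$patient_id[is.na(g)], collapse = ", "))
  lv <- sort(unique(g))
  check_that(length(lv) == 2, "log-rank comparison needs exactly 2 groups")
  check_that(all(table(factor(g, lv)) >= 1), "empty group")
  df <- data.frame(time = surv$time, event = surv$event, group = factor(g, lv))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(df$event) == 0) {
    warning("no observed events: log-rank statistic is 0")
    return(list(fit = fit, logrank_stat = 0, p = 1,
                n_per_group = table(df$group)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(fit = fit, logrank_stat = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_per_group = table(df$group))
}

#' Fisher's exact test on a contingency table
#'
#' Exact two-sided p-value (for 2x2 tables, summing hypergeometric
#' probabilities not exceeding the observed table's) and the conditional
#' maximum-likelihood odds ratio, via [stats::fisher.test()].
#'
#' @param table matrix of non-negative integer counts (r x c; odds ratio
#'   reported for 2x2 only).
#' @return list with `table`, `odds_ratio` (NA unless 2x2), `p_exact`.
#' @export
fisher_association <- function(table) {
  table <- as.matrix(table)
  check_that(all(table >= 0) && all(table == round(table)),
             "contingency table must hold non-negative integers")
  check_that(sum(table) > 0, "degenerate all-zero contingency table")
  ft <- stats::fisher.test(table)
  list(table = table,
       odds_ratio = if (all(dim(table) == 2)) unname(ft$estimate) else NA_real_,
       p_exact = ft$p.value)
}

#' Rank-based group comparison
#'
#' Two-sided Wilcoxon rank-sum test for two groups or Kruskal-Wallis
#' test (tie-corrected) for two or more, the standard nonparametric
#' comparisons for per-ROI scores across phenotype groups.
#'
#' @param values numeric vector.
#' @param groups parallel vector of group labels (>= 2 non-empty groups).
#' @param test `"wilcoxon"` (exactly 2 groups) or `"kruskal"`.
#' @return list with `statistic`, `p`, `test`.
#' @export
group_compare <- function(values, groups, test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  check_that(length(values) == length(groups),
             "values and groups must have equal length")
  g <- factor(groups)
  check_that(nlevels(g) >= 2, "need >= 2 groups")
  check_that(all(table(g) >= 1), "empty group")
  if (test == "wilcoxon") {
    check_that(nlevels(g) == 2, "wilcoxon test requires exactly 2 groups")
    wt <- suppressWarnings(
      stats::wilcox.test(values[g == levels(g)[1]],
                         values[g == levels(g)[2]]))
    list(statistic = unname(wt$statistic), p = wt$p.value, test = "wilcoxon")
  } else {
    kt <- stats::kruskal.test(values, g)
    list(statistic = unname(kt$statistic), p = kt$p.value, test = "kruskal")
  }
}
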