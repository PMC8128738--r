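#' Intraclass correlation coefficient for interobserver agreement
#'
#' Computes the ICC from the two-way ANOVA decomposition of a complete
#' subjects x raters table. The default is the two-way random-effects,
#' single-rater, absolute-agreement form, ICC(2,1) — the form that answers
#' "would a different observer assign the same score to the same scan",
#' which is the interobserver question for hand-drawn scoring regions.
#' Consistency (ICC(3,1)) and one-way (ICC(1,1)) forms are available.
#' The 95 percent confidence interval uses the standard F-distribution
#' method (McGraw and Wong), and the point estimate is banded as
#' poor (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or excellent (>= 0.9).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; at
#'   least 5 subjects and 2 raters, no missing cells.
#' @param model \code{"agreement"} (ICC(2,1), default), \code{"consistency"}
#'   (ICC(3,1)) or \code{"oneway"} (ICC(1,1)).
#' @param conf_level confidence level for the interval.
#' @return Object of class \code{icc_result}: \code{icc}, \code{ci95},
#'   \code{model}, \code{n_subjects}, \code{n_raters}, \code{band}.
#' @export
macs_icc <- function(ratings, model = c("agreement", "consistency", "oneway"),
                     conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects (got ", n, ")")
  if (k < 2L) stop("need at least 2 raters (got ", k, ")")
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  if (all(abs(row_means - grand) < .Machine$double.eps^0.5 * (1 + abs(grand))))
    stop("ratings are constant across subjects; the ICC is undefined ",
         "(no between-subject variance)")
  # two-way ANOVA sums of squares
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  msw <- (ss_cols + ss_err) / (n * (k - 1))  # within-subject MS, one-way
  alpha <- 1 - conf_level
  if (model == "oneway") {
    icc <- (msr - msw) / (msr + (k - 1) * msw)
    fl <- (msr / msw) / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- (msr / msw) * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else if (model == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fl <- (msr / mse) / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- (msr / mse) * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse == 0 && msc == 0) {  # identical raters: perfect agreement
      lo <- hi <- icc
    } else {
      a <- k * icc / (n * (1 - icc))
      b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fstar <- stats::qf(1 - alpha / 2, n - 1, v)
      lo <- n * (msr - fstar * mse) /
        (fstar * (k * msc + (k * n - k - n) * mse) + n * msr)
      fstar2 <- stats::qf(1 - alpha / 2, v, n - 1)
      hi <- n * (fstar2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fstar2 * msr)
    }
  }
  band <- if (icc >= 0.9) "excellent" else if (icc >= 0.75) "good"
          else if (icc >= 0.5) "moderate" else "poor"
  structure(list(icc = icc, ci95 = c(lo, hi), model = model,
                 n_subjects = n, n_raters = k, band = band,
                 ms = c(rows = msr, cols = msc, error = mse, within = msw)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single rater): %.3f (95%% CI %.3f-%.3f) - %s\n",
              x$model, x$icc, x$ci95[1], x$ci95[2], x$band))
  cat(sprintf("  %d subjects, %d raters\n", x$n_subjects, x$n_raters))
  invisible(x)
}

#' ROC curve and AUC for a continuous screening score
#'
#' Builds the ROC curve with thresholds at the unique observed score values
#' (a case is test-positive when its score is >= the threshold), computes
#' the AUC by the trapezoidal rule — which under this construction equals
#' the Mann-Whitney probability with ties counted 1/2 — and attaches a
#' DeLong 95 percent confidence interval (via \pkg{pROC}). The AUC is
#' banded following the usual discrimination scale: < 0.7 poor,
#' 0.7-0.8 acceptable, 0.8-0.9 excellent, >= 0.9 outstanding (0.5 means no
#' discrimination).
#'
#' @param scores numeric score per subject.
#' @param diseased logical (or coercible) disease indicator, same length;
#'   both classes must be present.
#' @return Object of class \code{roc_result}: \code{thresholds},
#'   \code{tpr}, \code{fpr} (per threshold, descending threshold order),
#'   \code{auc}, \code{auc_ci95}, \code{discrimination_band}, plus the
#'   input \code{scores}/\code{diseased} for downstream cutoff selection.
#' @export
macs_roc <- function(scores, diseased) {
  diseased <- as.logical(diseased)
  if (length(scores) != length(diseased)) stop("length mismatch")
  keep <- !is.na(scores) & !is.na(diseased)
  scores <- scores[keep]; diseased <- diseased[keep]
  n1 <- sum(diseased); n0 <- sum(!diseased)
  if (n1 == 0L || n0 == 0L)
    stop("both diseased and healthy subjects are required for a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[diseased] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!diseased] >= t) / n0, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  ci <- tryCatch(suppressWarnings({
    r <- pROC::roc(response = diseased, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  }), error = function(e) c(NA_real_, NA_real_))
  band <- if (auc >= 0.9) "outstanding" else if (auc >= 0.8) "excellent"
          else if (auc >= 0.7) "acceptable" else "poor"
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc, auc_ci95 = ci, discrimination_band = band,
                 scores = scores, diseased = diseased),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f) - %s discrimination\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$discrimination_band))
  cat(sprintf("  %d diseased / %d healthy, %d thresholds\n",
              sum(x$diseased), sum(!x$diseased), length(x$thresholds)))
  invisible(x)
}

#' Select a screening cutoff from a ROC curve
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over candidate
#' cutoffs placed at the midpoints between consecutive unique scores (plus
#' one below the minimum and one above the maximum). A midpoint cutoff is
#' reported so that perfectly separated classes yield the midpoint of the
#' separating gap. Ties in J are broken toward higher sensitivity (the
#' screening use case: missing disease is the costly error). If every
#' cutoff gives J = 0 (all scores equal), the minimum score is returned
#' with a warning.
#'
#' @param roc a \code{\link{macs_roc}} result.
#' @return List: \code{cutoff}, \code{j}, \code{sensitivity},
#'   \code{specificity} (fractions, not percent).
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  s <- sort(unique(roc$scores))
  if (length(s) == 1L) {
    warning("all scores identical; J = 0 everywhere, returning the minimum score")
    return(list(cutoff = s[1], j = 0, sensitivity = 1, specificity = 0))
  }
  gap <- min(diff(s))
  cand <- c(s[1] - gap / 2, (utils::head(s, -1) + utils::tail(s, -1)) / 2,
            s[length(s)] + gap / 2)
  n1 <- sum(roc$diseased); n0 <- sum(!roc$diseased)
  sens <- vapply(cand, function(t) sum(roc$scores[roc$diseased] >= t) / n1,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(roc$scores[!roc$diseased] < t) / n0,
                 numeric(1))
  j <- sens + spec - 1
  if (max(j) <= 0) {
    warning("no cutoff improves on chance (max J <= 0); returning the minimum score")
    return(list(cutoff = s[1], j = 0, sensitivity = 1, specificity = 0))
  }
  best <- which(j >= max(j) - 1e-12)
  # sens is non-increasing in the cutoff, so the first tied candidate is the
  # most sensitive one
  best <- best[which.max(sens[best])]
  list(cutoff = cand[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Screening metrics from a 2x2 confusion table
#'
#' Derives sensitivity, specificity, PPV and NPV (as percentages) from the
#' four confusion counts. Unrounded values are kept in the object; the
#' print method rounds to one decimal. PPV is undefined (NA) when no
#' subject tests positive, NPV when none tests negative.
#'
#' @param tp,fp,tn,fn non-negative counts; \code{tp+fn > 0} and
#'   \code{tn+fp > 0}.
#' @param cutoff optional cutoff the table was built at (carried along for
#'   reporting).
#' @return Object of class \code{screening_metrics} with the counts, the
#'   unrounded percentage metrics, and \code{negative_fraction_non_cmi} —
#'   the percentage of the whole cohort that is both test-negative and
#'   disease-free (the fraction of workups a negative screen could spare).
#' @examples
#' classification_metrics(tp = 43, fp = 65, tn = 70, fn = 6)
#' @export
classification_metrics <- function(tp, fp, tn, fn, cutoff = NA_real_) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (tp + fn == 0) stop("no diseased subjects (tp + fn = 0)")
  if (tn + fp == 0) stop("no healthy subjects (tn + fp = 0)")
  total <- tp + fp + tn + fn
  structure(list(cutoff = cutoff,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 ppv = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
                 npv = if (tn + fn == 0) NA_real_ else 100 * tn / (tn + fn),
                 negative_fraction_non_cmi = 100 * tn / total),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  if (!is.na(x$cutoff)) cat(sprintf("Cutoff >= %.1f\n", x$cutoff))
  cat(sprintf("  2x2: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat("  sensitivity", fmt(x$sensitivity),
      " specificity", fmt(x$specificity), "\n")
  cat("  PPV        ", fmt(x$ppv), " NPV        ", fmt(x$npv), "\n")
  cat(sprintf("  test-negative and disease-free: %.0f%% of cohort\n",
              x$negative_fraction_non_cmi))
  invisible(x)
}

# Resolve a score field name to per-patient values on a cohort table.
cohort_score <- function(cohort, score_field) {
  score_field <- tolower(score_field)
  switch(score_field,
         "ca" = cohort$macs_ca,
         "sma" = cohort$macs_sma,
         "ima" = cohort$macs_ima,
         "ca_sma" = , "ca+sma" = cohort$macs_ca + cohort$macs_sma,
         "total" = cohort$macs_ca + cohort$macs_sma + cohort$macs_ima,
         stop("unknown score field '", score_field,
              "' (use ca, sma, ima, ca_sma or total)"))
}

#' Apply a score cutoff to a cohort
#'
#' Dichotomises the chosen score at the cutoff (test-positive iff
#' score >= cutoff), builds the 2x2 table against the CMI / non-CMI label
#' and delegates to \code{\link{classification_metrics}}.
#'
#' @param cohort data frame with columns \code{patient_id}, \code{group}
#'   (\code{"CMI"} / \code{"nonCMI"}), \code{macs_ca}, \code{macs_sma},
#'   \code{macs_ima}; see \code{\link{read_cohort}}.
#' @param score_field \code{"ca"}, \code{"sma"}, \code{"ima"},
#'   \code{"ca_sma"} or \code{"total"}.
#' @param cutoff score cutoff.
#' @return A \code{screening_metrics} object.
#' @export
apply_cutoff <- function(cohort, score_field, cutoff) {
  check_cohort(cohort)
  s <- cohort_score(cohort, score_field)
  diseased <- cohort$group == "CMI"
  if (!any(diseased) || all(diseased))
    stop("cohort must contain both CMI and non-CMI patients")
  pos <- s >= cutoff
  classification_metrics(tp = sum(pos & diseased),
                         fp = sum(pos & !diseased),
                         tn = sum(!pos & !diseased),
                         fn = sum(!pos & diseased),
                         cutoff = cutoff)
}

#' Compare two groups (baseline-table tests)
#'
#' Continuous variables: two-sided Wilcoxon rank-sum — exact for small
#' tie-free samples, otherwise the normal approximation with tie correction
#' (MACS distributions are heavily tied at zero). Categorical variables:
#' chi-square test of the group x category
#' table, switching to Fisher's exact test whenever any expected cell count
#' falls below 5.
#'
#' @param values_a,values_b the two groups; numeric for
#'   \code{kind = "continuous"}, category labels for
#'   \code{kind = "categorical"}.
#' @param kind variable type.
#' @return List: \code{statistic}, \code{p_value}, \code{method}.
#' @export
compare_groups <- function(values_a, values_b,
                           kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  if (kind == "continuous") {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Wilcoxon rank-sum")
  } else {
    tab <- table(group = rep(c("a", "b"), c(length(values_a), length(values_b))),
                 value = c(as.character(values_a), as.character(values_b)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ht <- stats::fisher.test(tab)
      list(statistic = NA_real_, p_value = ht$p.value,
           method = "Fisher's exact")
    } else {
      ht <- stats::chisq.test(tab)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "chi-square")
    }
  }
}

#' Exact sign test for paired scans
#'
#' Two-sided exact binomial test on the signs of the paired differences
#' \code{b - a}; zero differences carry no information about direction and
#' are dropped (their count is reported). Used to compare the score and
#' acquisition characteristics of two scans of the same patient.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return List: \code{p_value}, \code{n_positive} (b > a),
#'   \code{n_negative}, \code{n_dropped}.
#' @export
paired_sign_test <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stop("pairs must have equal length")
  if (!length(paired_a)) stop("need at least one pair")
  d <- paired_b - paired_a
  pos <- sum(d > 0); neg <- sum(d < 0); zero <- sum(d == 0)
  if (pos + neg == 0L) {
    warning("all paired differences are zero; sign test is uninformative")
    return(list(p_value = 1, n_positive = 0L, n_negative = 0L,
                n_dropped = zero))
  }
  p <- stats::binom.test(pos, pos + neg, p = 0.5,
                         alternative = "two.sided")$p.value
  list(p_value = p, n_positive = pos, n_negative = neg, n_dropped = zero)
}

#' Per-group median and interquartile range of a score
#'
#' Quartiles use R's default linear-interpolation convention
#' (\code{quantile} type 7), the same rule applied throughout the package's
#' reports.
#'
#' @param cohort cohort data frame (see \code{\link{apply_cutoff}}).
#' @param score_field score field name.
#' @return Data frame with one row per group: \code{group}, \code{n},
#'   \code{median}, \code{q1}, \code{q3}.
#' @export
summarize_scores <- function(cohort, score_field) {
  check_cohort(cohort)
  s <- cohort_score(cohort, score_field)
  groups <- unique(cohort$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- s[cohort$group == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}

check_cohort <- function(cohort) {
  need <- c("patient_id", "group", "macs_ca", "macs_sma", "macs_ima")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient_id values in cohort")
  bad <- setdiff(unique(cohort$group), c("CMI", "nonCMI"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected CMI / nonCMI)")
  invisible(cohort)
}

#' Read / write a cohort score table
#'
#' CSV with columns \code{patient_id}, \code{group} (CMI / nonCMI),
#' \code{macs_ca}, \code{macs_sma}, \code{macs_ima}. Combined scores
#' (CA+SMA, total) are always computed, never stored.
#'
#' @param path CSV path.
#' @return \code{read_cohort}: validated data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
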