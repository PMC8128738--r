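# Fixed 6 x 2 interobserver table (MACS-like, right-skewed). The expected
# ICCs were computed from the two-way ANOVA sums of squares with an
# independent implementation before this module was written.
icc_table <- cbind(obs1 = c(0, 12, 35, 120, 450, 2),
                   obs2 = c(5, 10, 40, 100, 500, 0))

test_that("ICC matches the ANOVA-decomposition oracle on a fixed table", {
  expect_equal(macs_icc(icc_table, "agreement")$icc, 0.992841724181,
               tolerance = 1e-10)
  expect_equal(macs_icc(icc_table, "consistency")$icc, 0.992043725657,
               tolerance = 1e-10)
  expect_equal(macs_icc(icc_table, "oneway")$icc, 0.992844602077,
               tolerance = 1e-10)
  res <- macs_icc(icc_table)
  expect_equal(res$band, "excellent")
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])
})

test_that("duplicate raters give ICC 1; disagreement degrades it monotonically", {
  dup <- macs_icc(cbind(icc_table[, 1], icc_table[, 1]))
  expect_equal(dup$icc, 1.0)
  set.seed(23)
  base <- c(0, 15, 40, 150, 420, 3, 80, 9)
  noise <- rnorm(8)
  iccs <- vapply(c(0, 5, 20, 60), function(s)
    macs_icc(cbind(base, base + s * noise))$icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
  # constant offset on one rater lowers absolute agreement, not consistency
  shifted <- cbind(icc_table[, 1], icc_table[, 1] + 50)
  expect_lt(macs_icc(shifted, "agreement")$icc, 1)
  expect_equal(macs_icc(shifted, "consistency")$icc, 1)
})

test_that("degenerate rating tables are rejected", {
  expect_error(macs_icc(matrix(5, 6, 2)), "constant")
  expect_error(macs_icc(icc_table[1:3, ]), "at least 5 subjects")
  expect_error(macs_icc(icc_table[, 1, drop = FALSE]), "at least 2 raters")
  na_tab <- icc_table; na_tab[2, 1] <- NA
  expect_error(macs_icc(na_tab), "missing")
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney count", {
  set.seed(41)
  for (rep in 1:10) {
    n1 <- sample(5:12, 1); n0 <- sample(5:12, 1)
    scores <- c(round(rlnorm(n1, 4, 1.5)), round(rlnorm(n0, 2, 1.5)))
    scores[sample(length(scores), 3)] <- 0   # force ties
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    roc <- macs_roc(scores, lab)
    expect_equal(roc$auc, oracle_auc(scores, lab), tolerance = 1e-12)
    flipped <- macs_roc(scores, !lab)
    expect_equal(roc$auc + flipped$auc, 1, tolerance = 1e-12)
  }
})

test_that("ROC handles separation, symmetry and single-class input", {
  roc <- macs_roc(c(10, 20, 30, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(roc$auc, 1)
  expect_equal(roc$discrimination_band, "outstanding")
  expect_error(macs_roc(1:5, rep(TRUE, 5)), "both")
  # curve endpoints: (0,0) at +Inf threshold, (1,1) at the minimum score
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]), c(1, 1))
})

test_that("cutoff selection equals exhaustive Youden-J search", {
  set.seed(43)
  for (rep in 1:10) {
    scores <- c(rlnorm(8, 4, 1), rlnorm(10, 2.5, 1))
    lab <- rep(c(TRUE, FALSE), c(8, 10))
    roc <- macs_roc(scores, lab)
    expect_equal(select_cutoff(roc)$cutoff, oracle_cutoff(scores, lab))
  }
  # perfect separation: midpoint of the separating gap
  sep <- macs_roc(c(100, 120, 140, 10, 20, 30), rep(c(TRUE, FALSE), each = 3))
  expect_equal(select_cutoff(sep)$cutoff, (30 + 100) / 2)
  expect_equal(select_cutoff(sep)$j, 1)
  flat <- macs_roc(rep(7, 6), rep(c(TRUE, FALSE), each = 3))
  expect_warning(res <- select_cutoff(flat), "minimum")
  expect_equal(res$cutoff, 7)
})

test_that("screening metrics satisfy their defining identities", {
  m <- classification_metrics(1, 0, 1, 0)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv),
               rep(100, 4))
  set.seed(47)
  for (rep in 1:10) {
    tab <- rmultinom(1, 200, c(0.2, 0.3, 0.4, 0.1))
    tp <- tab[1] + 1; fp <- tab[2]; tn <- tab[3] + 1; fn <- tab[4]
    m <- classification_metrics(tp, fp, tn, fn)
    expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    expect_equal(m$specificity, 100 * tn / (tn + fp))
    expect_equal(m$ppv, 100 * tp / (tp + fp))
    expect_equal(m$npv, 100 * tn / (tn + fn))
    # Bayes identity on unrounded fractions
    prev <- (tp + fn) / (tp + fp + tn + fn)
    sens <- m$sensitivity / 100; spec <- m$specificity / 100
    expect_equal(m$ppv / 100,
                 sens * prev / (sens * prev + (1 - spec) * (1 - prev)),
                 tolerance = 1e-12)
  }
  none_pos <- classification_metrics(0, 0, 5, 3)
  expect_true(is.na(none_pos$ppv))
  expect_error(classification_metrics(0, 0, 0, 5), "healthy")
})

test_that("cohort cutoffs build the 2x2 table with score >= cutoff positive", {
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:8),
                       group = rep(c("CMI", "nonCMI"), each = 4),
                       macs_ca = c(50, 10, 0, 200, 0, 5, 80, 0),
                       macs_sma = c(100, 0, 0, 300, 0, 0, 40, 10),
                       macs_ima = rep(0, 8))
  m <- apply_cutoff(cohort, "ca_sma", 60)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(2, 1, 3, 2))
  low <- apply_cutoff(cohort, "ca_sma", -Inf)
  expect_equal(c(low$sensitivity, low$specificity), c(100, 0))
  high <- apply_cutoff(cohort, "ca_sma", 1e9)
  expect_equal(c(high$tp, high$fp), c(0, 0))
  expect_error(apply_cutoff(cohort, "bogus", 10), "unknown score field")
  expect_equal(macscore:::cohort_score(cohort, "total"),
               cohort$macs_ca + cohort$macs_sma + cohort$macs_ima)
})

test_that("group comparisons pick the right test and match exact oracles", {
  same <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$p_value, 1)
  # small tie-free samples: exact Wilcoxon equals the permutation distribution
  a <- c(1.2, 3.4, 5.1, 9.3); b <- c(2.2, 4.5, 7.7, 11.1)
  got <- compare_groups(a, b)
  pooled <- c(a, b)
  w_obs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
  combs <- utils::combn(8, 4)
  w_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - 4 * 5 / 2)
  p_perm <- mean(abs(w_all - 8) >= abs(w_obs - 8))  # mean W under H0 is 8
  expect_equal(got$p_value, p_perm, tolerance = 1e-12)
  expect_equal(got$method, "Wilcoxon rank-sum")
  # sparse categorical table: Fisher's exact equals hypergeometric enumeration
  fish <- compare_groups(rep("x", 9), rep("y", 9), kind = "categorical")
  expect_equal(fish$method, "Fisher's exact")
  expect_equal(fish$p_value, 2 / choose(18, 9), tolerance = 1e-12)
  big <- compare_groups(rep(c("x", "y"), c(40, 20)),
                        rep(c("x", "y"), c(20, 40)), kind = "categorical")
  expect_equal(big$method, "chi-square")
})

test_that("the sign test is the exact binomial on non-zero differences", {
  all_up <- paired_sign_test(rep(0, 8), rep(1, 8))
  expect_equal(all_up$p_value, 2 * 0.5^8)  # 0.0078125
  expect_warning(ties <- paired_sign_test(1:5, 1:5), "zero")
  expect_equal(ties$p_value, 1)
  expect_equal(ties$n_dropped, 5)
  mixed <- paired_sign_test(rep(0, 10), c(rep(1, 7), rep(-1, 3)))
  # exact two-sided binomial tail: 2 * P(X >= 7), X ~ Bin(10, 1/2)
  expect_equal(mixed$p_value, 2 * sum(choose(10, 7:10)) / 2^10,
               tolerance = 1e-12)
  with_zero <- paired_sign_test(c(0, 0, 5), c(1, 0, 9))
  expect_equal(with_zero$n_dropped, 1)
  expect_error(paired_sign_test(1:3, 1:4), "equal length")
})

test_that("score summaries use linear-interpolation quartiles per group", {
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:8),
                       group = rep(c("CMI", "nonCMI"), c(5, 3)),
                       macs_ca = c(1, 2, 3, 4, 5, 0, 0, 0),
                       macs_sma = 0, macs_ima = 0)
  s <- summarize_scores(cohort, "ca")
  cmi <- s[s$group == "CMI", ]
  expect_equal(c(cmi$median, cmi$q1, cmi$q3), c(3, 2, 4))
  non <- s[s$group == "nonCMI", ]
  expect_equal(c(non$median, non$q1, non$q3), c(0, 0, 0))
})

test_that("cohort tables are validated on read and write", {
  cohort <- make_cohort(5, 7, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$macs_ca, cohort$macs_ca, tolerance = 1e-12)
  bad <- cohort; bad$group[1] <- "CASE"
  expect_error(macscore:::check_cohort(bad), "unknown group")
  dup <- cohort; dup$patient_id[2] <- dup$patient_id[1]
  expect_error(macscore:::check_cohort(dup), "duplicate")
  unlink(path)
})
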