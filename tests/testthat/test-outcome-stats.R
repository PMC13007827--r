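# Overlap scores and the outcome-differentiation statistics.

test_that("resected set applies the strict >10% rule", {
  ov <- data.frame(roi_id = c("a", "b", "c", "d"),
                   overlap_fraction = c(0.10, 0.101, 0.5, NA))
  expect_equal(resected_set(ov), c("b", "c"))
})

test_that("proportion of abnormal regions resected follows the contract", {
  expect_equal(proportion_abnormal_resected(c("A", "B", "C", "D"),
                                            c("A", "B"))$proportion, 0.5)
  expect_equal(proportion_abnormal_resected(c("A", "B"),
                                            c("A", "B", "X"))$proportion, 1)
  empty <- proportion_abnormal_resected(character(0), c("A"))
  expect_true(is.na(empty$proportion))
  expect_true(empty$empty)
})

test_that("AUC: perfect separation, ties, and the pair-counting oracle", {
  expect_equal(auc_mw(c(0.9, 0.8), c(0.2, 0.1))$auc, 1)
  expect_equal(auc_mw(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  set.seed(50)
  for (i in 1:100) {
    pos <- sample(0:10, sample(2:8, 1), replace = TRUE) / 10
    neg <- sample(0:10, sample(2:8, 1), replace = TRUE) / 10
    expect_equal(auc_mw(pos, neg)$auc, auc_pairs(pos, neg))
  }
})

test_that("Mann-Whitney AUC equals trapezoidal ROC integration", {
  set.seed(51)
  for (i in 1:25) {
    pos <- rnorm(10); neg <- rnorm(12)
    expect_equal(auc_mw(pos, neg)$auc, auc_trapezoid(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC: trivial orderings and the hand-enumerated case", {
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 1, 0, 0))$auprc, 1)
  # single positive ranked last among 4: only threshold catching it has
  # precision 1/4 at full recall
  expect_equal(auprc(c(4, 3, 2, 1), c(0, 0, 0, 1))$auprc, 0.25)
})

test_that("AUPRC of random scores matches prevalence on average", {
  set.seed(52)
  vals <- replicate(300, {
    labels <- c(rep(1, 120), rep(0, 280))
    auprc(runif(400), labels)$auprc
  })
  # average precision has a small positive finite-sample bias
  expect_equal(mean(vals), 0.3, tolerance = 0.05)
})

test_that("one-tailed rank-sum: exact enumeration and edge cases", {
  out <- ranksum_one_tailed(c(4, 5, 6), c(1, 2, 3))
  expect_equal(out$p, 0.05)             # 1 / choose(6, 3)
  expect_equal(out$method, "exact")
  expect_gte(ranksum_one_tailed(c(1, 2, 3), c(1, 2, 3))$p, 0.5)
  expect_equal(ranksum_one_tailed(c(2, 2), c(2, 2, 2))$p, 1)
})

test_that("normal approximation agrees with enumeration at n = 12", {
  set.seed(53)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pe <- ranksum_one_tailed(x, y, exact_max = 12)$p
    pn <- ranksum_one_tailed(x, y, exact_max = 0)$p
    expect_lt(abs(pe - pn), 0.01 + 0.02 * max(pe, pn))
  }
})

test_that("rank-sum cross-checks against wilcox.test where exact applies", {
  set.seed(54)
  for (i in 1:10) {
    x <- runif(5); y <- runif(6)       # continuous: no ties
    ours <- ranksum_one_tailed(x, y)$p
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("DeLong: identical scores give z = 0, p = 1", {
  set.seed(55)
  s <- runif(20); lab <- rep(c(TRUE, FALSE), 10)
  out <- delong_paired(s, s, lab)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
})

test_that("DeLong z is antisymmetric and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(56)
  lab <- c(rep(1, 15), rep(0, 25))
  a <- rnorm(40) + lab
  b <- 0.5 * a + rnorm(40)
  ours <- delong_paired(a, b, lab)
  swapped <- delong_paired(b, a, lab)
  expect_equal(ours$z, -swapped$z, tolerance = 1e-12)
  ref <- pROC::roc.test(pROC::roc(lab, a, quiet = TRUE),
                        pROC::roc(lab, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(unname(ours$z), unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong variance agrees with a paired bootstrap", {
  set.seed(57)
  lab <- c(rep(TRUE, 20), rep(FALSE, 20))
  a <- rnorm(40) + lab
  b <- 0.6 * a + 0.8 * rnorm(40)
  est <- delong_paired(a, b, lab)$var_delta
  boots <- replicate(2000, {
    i <- c(sample(which(lab), replace = TRUE),
           sample(which(!lab), replace = TRUE))
    auc_mw(a[i][lab[i]], a[i][!lab[i]])$auc -
      auc_mw(b[i][lab[i]], b[i][!lab[i]])$auc
  })
  ratio <- est / var(boots)
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.3)
})

test_that("colocalization coefficient equals the 2x2 log odds ratio", {
  set.seed(58)
  x <- rbinom(300, 1, 0.4)
  y <- rbinom(300, 1, plogis(-1 + 1.2 * x))
  out <- colocalization_logistic(y, x)
  tab <- table(x, y)
  lor <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
  expect_equal(out$coef, lor, tolerance = 1e-6)
})

test_that("colocalization null calibration keeps Wald z near nominal", {
  set.seed(59)
  zs <- replicate(200, {
    x <- rbinom(200, 1, 0.3); y <- rbinom(200, 1, 0.4)
    tryCatch(colocalization_logistic(y, x)$z, error = function(e) NA)
  })
  expect_gt(mean(abs(zs) < 1.96, na.rm = TRUE), 0.9)
})

test_that("complete separation raises an explicit error", {
  y <- c(1, 1, 1, 0, 0, 0)
  expect_error(colocalization_logistic(y, y),
               class = "epizmap_separation_error")
})

test_that("chi-square with Yates correction reproduces textbook values", {
  expect_equal(chi_square_yates(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "epizmap_config_error")
  expect_error(chi_square_yates(matrix(c(1.5, 2, 3, 4), 2)),
               class = "epizmap_config_error")
})

test_that("Kruskal-Wallis matches the base implementation and rank-sum order", {
  g <- list(c(1, 5, 8), c(2, 7, 9, 4))
  ours <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(kruskal_wallis(list(1:4, 1:4))$statistic, 0, tolerance = 1e-12)
  # two-group K is a monotone transform of the rank-sum statistic
  set.seed(60)
  stats_pairs <- t(replicate(30, {
    x <- rnorm(5); y <- rnorm(6)
    c(kruskal_wallis(list(x, y))$statistic,
      abs(ranksum_one_tailed(x, y)$W - 5 * (5 + 6 + 1) / 2))
  }))
  expect_equal(order(stats_pairs[, 1]), order(stats_pairs[, 2]))
})

test_that("LOO CV: perfect separation classifies perfectly; null is at chance", {
  scores <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15)
  labels <- c(1, 1, 1, 0, 0, 0)
  out <- loo_outcome_cv(scores, labels)   # wide margin: all folds correct
  expect_equal(out$accuracy, 1)
  set.seed(61)
  accs <- replicate(200, {
    s <- runif(16); l <- sample(rep(c(0, 1), 8))
    loo_outcome_cv(s, l)$accuracy
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.06)
})

test_that("LOO CV matches a hand-enumerated n = 6 example", {
  # scores 1..6, labels 0,0,0,1,1,1. Hand enumeration: with score 4
  # held out the remaining scores 1,2,3,5,6 put the lowest
  # balanced-accuracy-maximizing threshold at (3+5)/2 = 4, and the
  # strict rule 4 > 4 misclassifies it; every other fold picks a
  # threshold separating its held-out case correctly.
  out <- loo_outcome_cv(1:6, c(0, 0, 0, 1, 1, 1))
  expect_equal(out$predictions$predicted, c(FALSE, FALSE, FALSE,
                                            FALSE, TRUE, TRUE))
  expect_equal(out$accuracy, 5 / 6)
})

test_that("lateralization relabels regions relative to the surgical side", {
  rois <- data.frame(roi_id = c("L_01", "R_01", "M_01"),
                     hemisphere = c("L", "R", "M"))
  lat <- lateralize(rois, "right")
  expect_equal(lat$laterality, c("contra", "ipsi", "midline"))
  lat2 <- lateralize(rois, "left")
  expect_equal(lat2$laterality, c("ipsi", "contra", "midline"))
  expect_error(lateralize(rois, "up"), class = "epizmap_config_error")
})
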