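# Resection-overlap scoring and outcome-differentiation statistics:
# AUC/AUPRC, one-tailed rank-sum, DeLong paired ROC, colocalization
# logistic regression, cohort contingency tests, and leave-one-out CV.

#' Resected-region set from overlap fractions
#'
#' A region counts as resected when strictly more than `threshold`
#' (default 10%) of its volume overlaps the resection mask.
#'
#' @param overlap data.frame `roi_id`, `overlap_fraction`.
#' @param threshold strict overlap threshold (default 0.10).
#' @return character vector of resected ROI ids.
#' @export
resected_set <- function(overlap, threshold = 0.10) {
  as.character(overlap$roi_id[!is.na(overlap$overlap_fraction) &
                                overlap$overlap_fraction > threshold])
}

#' Proportion of abnormal regions resected
#'
#' The patient's surgical-overlap score: |abnormal AND resected| /
#' |abnormal|. Patients with an empty abnormal set get a missing score
#' and are flagged; they are excluded from group comparisons with an
#' explicit count rather than imputed.
#'
#' @param abnormal an `abnormal_set` (or character vector of ROI ids).
#' @param resected character vector of resected ROI ids.
#' @return list: `proportion` (numeric or NA), `n_abnormal`,
#'   `n_resected_abnormal`, `empty` (flag).
#' @export
proportion_abnormal_resected <- function(abnormal, resected) {
  rois <- if (inherits(abnormal, "abnormal_set")) abnormal$rois else
    as.character(abnormal)
  if (length(rois) == 0) {
    return(list(proportion = NA_real_, n_abnormal = 0L,
                n_resected_abnormal = 0L, empty = TRUE))
  }
  hit <- length(intersect(rois, resected))
  list(proportion = hit / length(rois), n_abnormal = length(rois),
       n_resected_abnormal = hit, empty = FALSE)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC = P(score in the positive group > score in the negative group)
#' + 1/2 P(tie), computed from midranks. Missing scores are excluded
#' and counted.
#'
#' @param pos scores of the positive group (seizure-free, ILAE 1-2).
#' @param neg scores of the negative group (ILAE 3+).
#' @return list: `auc`, `n_pos`, `n_neg`, `n_missing`.
#' @export
auc_mw <- function(pos, neg) {
  n_missing <- sum(is.na(pos)) + sum(is.na(neg))
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) stop_config("a group is empty")
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  list(auc = auc, n_pos = length(pos), n_neg = length(neg),
       n_missing = n_missing)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step rule: precision-recall points are computed at
#' every distinct score threshold (descending) and the area is the sum of
#' precision times recall increment. Positives are the seizure-free
#' (ILAE 1-2) group.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical or 0/1 vector; TRUE/1 = positive.
#' @return list: `auprc`, `n_pos`, `n`, `n_missing`.
#' @export
auprc <- function(scores, labels) {
  keep <- !is.na(scores)
  n_missing <- sum(!keep)
  scores <- scores[keep]; labels <- as.logical(labels)[keep]
  P <- sum(labels)
  if (P == 0) stop_config("no positive cases")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # cumulative TP/FP at each distinct-threshold boundary
  bounds <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[bounds]
  fp <- cumsum(!y)[bounds]
  recall <- tp / P
  precision <- tp / (tp + fp)
  dr <- diff(c(0, recall))
  list(auprc = sum(precision * dr), n_pos = P, n = length(s),
       n_missing = n_missing)
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Tests whether `x` is stochastically greater than `y`, using midranks
#' for ties. The p-value is exact (complete enumeration of rank
#' assignments, valid under ties) when the combined sample size is at
#' most `exact_max` (default 12), otherwise a normal approximation with
#' tie correction and continuity correction is used. If every pooled
#' value is identical, p = 1 is reported.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration cutoff on n_x + n_y (default 12).
#' @return list: `W` (rank sum of `x`), `p`, `method`.
#' @export
ranksum_one_tailed <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop_config("empty sample")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(list(W = sum(rank(pooled)[seq_along(x)]), p = 1,
                method = "degenerate"))
  }
  r <- rank(pooled)
  W <- sum(r[seq_along(x)])
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (n <= exact_max) {
    sets <- combn(n, nx)
    Ws <- colSums(matrix(r[sets], nrow = nx))
    p <- mean(Ws >= W - 1e-9)
    return(list(W = W, p = p, method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * (n + 1 - tie_corr)
  z <- (W - mu - 0.5) / sqrt(sigma2)
  list(W = W, p = pnorm(z, lower.tail = FALSE), method = "normal")
}

.placements <- function(pos, neg) {
  # V10_i = fraction of negatives below positive i (+ half ties); V01_j likewise
  v10 <- vapply(pos, function(p) mean(p > neg) + 0.5 * mean(p == neg),
                numeric(1))
  v01 <- vapply(neg, function(q) mean(pos > q) + 0.5 * mean(pos == q),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets measured on the same subjects,
#' using the placement-value (structural-component) estimate of
#' var(AUC_A - AUC_B) that accounts for the pairing. Subjects missing a
#' score in either set are dropped pairwise. z = (AUC_A - AUC_B) / SE;
#' the p-value is two-sided.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels logical/0-1; TRUE = positive class.
#' @return list: `auc_a`, `auc_b`, `delta`, `z`, `p`, `var_delta`,
#'   `n_pos`, `n_neg`, `n_dropped`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(labels) == length(scores_a))
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  n_dropped <- sum(!keep)
  a <- scores_a[keep]; b <- scores_b[keep]; y <- as.logical(labels)[keep]
  if (sum(y) < 2 || sum(!y) < 2) stop_config("need >= 2 subjects per class")
  if (identical(a, b)) {
    pa <- .placements(a[y], a[!y])
    return(list(auc_a = mean(pa$v10), auc_b = mean(pa$v10), delta = 0,
                z = 0, p = 1, var_delta = 0,
                n_pos = sum(y), n_neg = sum(!y), n_dropped = n_dropped))
  }
  pa <- .placements(a[y], a[!y]); pb <- .placements(b[y], b[!y])
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_delta <= 0) {
    stop_config("DeLong variance estimate is zero; the paired scores are ",
                "identical up to ordering within class")
  }
  z <- (auc_a - auc_b) / sqrt(var_delta)
  list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b, z = z,
       p = 2 * pnorm(-abs(z)), var_delta = var_delta,
       n_pos = m, n_neg = n, n_dropped = n_dropped)
}

#' Colocalization logistic regression
#'
#' Binomial logistic regression of a binary region-level response
#' (implanted, or iEEG-abnormal) on a binary predictor (MRI-abnormal),
#' pooling (patient, region) observations; fitted separately per outcome
#' group by the caller. Complete separation (a zero cell in the 2x2
#' aggregation that makes the odds ratio infinite) is reported as an
#' explicit error rather than a silent huge coefficient.
#'
#' @param response logical/0-1 response per (patient, region).
#' @param predictor logical/0-1 predictor per (patient, region).
#' @return list: `coef` (log odds ratio), `z` (Wald), `p` (two-sided),
#'   `n`.
#' @export
colocalization_logistic <- function(response, predictor) {
  keep <- !is.na(response) & !is.na(predictor)
  y <- as.numeric(response[keep]); x <- as.numeric(predictor[keep])
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  if (tab["1", "0"] == 0 || tab["0", "1"] == 0 ||
      tab["1", "1"] == 0 || tab["0", "0"] == 0) {
    stop(errorCondition(
      "complete separation: a 2x2 cell is empty, the odds ratio is not finite",
      class = c("epizmap_separation_error", "error")))
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  sm <- summary(fit)$coefficients
  list(coef = sm["x", "Estimate"], z = sm["x", "z value"],
       p = sm["x", "Pr(>|z|)"], n = length(y))
}

#' Chi-square test with Yates continuity correction
#'
#' Pearson chi-square on a 2x2 contingency table with Yates continuity
#' correction (df = 1), as used for cohort characteristic comparisons.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list: `statistic`, `p`, `df`.
#' @export
chi_square_yates <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_config("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_config("zero margin in contingency table")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based K statistic with tie correction, chi-square reference with
#' g - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list: `statistic`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop_config("need at least 2 groups")
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Leave-one-out cross-validated outcome classification
#'
#' For each patient the classification threshold on the overlap score is
#' chosen to maximize balanced accuracy on the remaining patients (ties
#' resolved to the lowest threshold); the held-out patient is classified
#' with that threshold (score > threshold = predicted seizure-free).
#'
#' @param scores overlap scores (missing scores dropped with their labels).
#' @param labels logical/0-1; TRUE = seizure-free (ILAE 1-2).
#' @return list: `predictions` (data.frame `score`, `label`, `threshold`,
#'   `predicted`), `accuracy`, `balanced_accuracy`, `auc`.
#' @export
loo_outcome_cv <- function(scores, labels) {
  keep <- !is.na(scores)
  s <- scores[keep]; y <- as.logical(labels)[keep]
  if (sum(y) < 3 || sum(!y) < 3) stop_config("need >= 3 patients per class")
  thr_grid <- function(v) {
    u <- sort(unique(v))
    c(min(u) - 1, (u[-1] + u[-length(u)]) / 2, max(u) + 1)
  }
  bal_acc <- function(v, lab, t) {
    pred <- v > t
    (mean(pred[lab]) + mean(!pred[!lab])) / 2
  }
  n <- length(s)
  thr <- numeric(n); pred <- logical(n)
  for (i in seq_len(n)) {
    cand <- thr_grid(s[-i])
    ba <- vapply(cand, function(t) bal_acc(s[-i], y[-i], t), numeric(1))
    thr[i] <- cand[which.max(ba)]   # first max = lowest threshold
    pred[i] <- s[i] > thr[i]
  }
  list(predictions = data.frame(score = s, label = y, threshold = thr,
                                predicted = pred),
       accuracy = mean(pred == y),
       balanced_accuracy = (mean(pred[y]) + mean(!pred[!y])) / 2,
       auc = auc_mw(as.numeric(pred[y]), as.numeric(pred[!y]))$auc)
}

#' Relabel regions as ipsilateral or contralateral to surgery
#'
#' Regions in the hemisphere of surgery become ipsilateral; the opposite
#' hemisphere contralateral. Midline regions and deep structures are
#' flagged from the parcellation lookup so cohort prevalence can be
#' reported in surgery-relative space.
#'
#' @param rois data.frame with `roi_id`, `hemisphere` (`"L"`/`"R"`/`"M"`),
#'   optional `deep`.
#' @param side surgery side, `"left"` or `"right"`.
#' @return `rois` with added `laterality` (`ipsi`/`contra`/`midline`).
#' @export
lateralize <- function(rois, side) {
  if (!side %in% c("left", "right")) stop_config("unknown side: ", side)
  surg <- if (side == "left") "L" else "R"
  lat <- ifelse(rois$hemisphere == "M", "midline",
                ifelse(rois$hemisphere == surg, "ipsi", "contra"))
  rois$laterality <- lat
  if (!"deep" %in% names(rois)) rois$deep <- FALSE
  rois
}
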