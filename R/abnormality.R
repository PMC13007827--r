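# Patient-specific abnormal-region identification: modality-specific
# ranking of regional z-scores, Bayesian mean-shift change-point
# thresholding of the ranked curve, and modality unions.

#' Rank regional abnormality scores for thresholding
#'
#' Orders a patient's regional scores by the modality's abnormality
#' convention: gray-matter volume z-scores ascending (most negative, i.e.
#' greatest atrophy, first); superficial-white-matter mean-diffusivity
#' z-scores descending (most positive first); iEEG max-absolute-z scores
#' descending. Ties are broken by ROI id so the ranking is deterministic.
#'
#' @param scores data.frame with columns `roi_id` and a score column
#'   (`z` or `score`); missing scores are dropped.
#' @param modality one of `"GM_volume"`, `"SWM_MD"`, `"iEEG"`.
#' @return data.frame `roi_id`, `score`, ordered; attribute `direction`.
#' @export
rank_regions <- function(scores, modality = c("GM_volume", "SWM_MD", "iEEG")) {
  modality <- match.arg(modality)
  col <- if ("score" %in% names(scores)) "score" else "z"
  d <- data.frame(roi_id = as.character(scores$roi_id),
                  score = scores[[col]], stringsAsFactors = FALSE)
  d <- d[!is.na(d$score), ]
  if (nrow(d) < 3) stop_config("need at least 3 scored regions to rank")
  asc <- modality == "GM_volume"
  o <- order(if (asc) d$score else -d$score, d$roi_id)
  d <- d[o, ]
  rownames(d) <- NULL
  attr(d, "direction") <- if (asc) "most_negative_first" else "most_positive_first"
  attr(d, "modality") <- modality
  d
}

#' Bayesian single change-point detection in a ranked sequence
#'
#' Fits a two-segment Bayesian regression model with one change point to
#' an ordered sequence and compares it against a no-change model. For
#' every admissible split k (first segment of length k, minimum segment
#' length `min_seg`) the marginal likelihood of the two segments is
#' computed in closed form under conjugate normal-inverse-gamma priors,
#' with a uniform prior over k; the change model's evidence (marginalized
#' over k) must exceed the no-change model's by more than `margin` log
#' units, otherwise k = 0 is returned (no abnormal regions).
#'
#' With the default `segment_model = "linear"` each segment carries its
#' own intercept and slope, so a mean shift is an intercept
#' discontinuity in the ranked curve while the smooth monotone ramp of a
#' null (well-calibrated) z-score sequence is explained by the no-change
#' model and yields an empty abnormal set. `segment_model = "constant"`
#' gives the classic piecewise-constant Gaussian mean model, appropriate
#' for sequences in their native (unranked) order.
#'
#' Priors are set empirically from the sequence (prior intercept mean =
#' sequence mean, prior scale from the sequence variance), which makes
#' the selected k and the log Bayes factor equivariant under affine
#' transforms of the scores.
#'
#' @param x numeric vector (the ranked scores), length >= 3.
#' @param min_seg minimum segment length (default 2).
#' @param margin log-Bayes-factor margin the change model must exceed
#'   (default 0).
#' @param segment_model `"linear"` (default) or `"constant"`.
#' @param max_frac largest admissible abnormal fraction: change points
#'   are searched in the first `max_frac` of the sequence (default 0.5),
#'   since the abnormal segment is by construction the extreme minority
#'   at the head of the ranking.
#' @param alpha0 inverse-gamma prior shape for the noise variance
#'   (default 2; prior scale is `alpha0 * var(x) / 4`).
#' @return list: `k` (change-point index, 0 for no change), `log_bf`
#'   (log evidence difference, change vs no-change), `logml_k` (per-k
#'   log marginal likelihoods, named by k), `logml_null`.
#' @export
detect_change_point <- function(x, min_seg = 2, margin = 0,
                                segment_model = c("linear", "constant"),
                                max_frac = 0.5, alpha0 = 2) {
  segment_model <- match.arg(segment_model)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop_config("sequence too short for change-point detection")
  if (sd(x) == 0) {
    return(list(k = 0L, log_bf = -Inf, logml_k = numeric(0),
                logml_null = NA_real_))
  }
  prior <- cp_prior(x, segment_model, alpha0)
  seg <- function(idx) .bayes_lm_evidence(x[idx], .cp_design(length(idx),
                                                            segment_model),
                                          prior)
  logml_null <- seg(seq_len(n))
  kmax <- min(n - min_seg, floor(n * max_frac))
  ks <- if (min_seg <= kmax) seq.int(min_seg, kmax) else integer(0)
  if (length(ks) == 0) {
    return(list(k = 0L, log_bf = -Inf, logml_k = numeric(0),
                logml_null = logml_null))
  }
  logml_k <- vapply(ks, function(k) seg(1:k) + seg((k + 1):n), numeric(1))
  names(logml_k) <- ks
  # evidence for the change model: uniform prior over admissible k
  ev_change <- logsumexp(logml_k) - log(length(ks))
  log_bf <- ev_change - logml_null
  k <- if (log_bf > margin) ks[which.max(logml_k)] else 0L
  list(k = as.integer(k), log_bf = log_bf, logml_k = logml_k,
       logml_null = logml_null)
}

# empirical conjugate prior shared by all segments of one sequence:
# intercept centered on the sequence mean, slope centered on zero with a
# scale allowing ~10 sd of total drift, noise variance IG(alpha0, b0)
# with b0 tied to the sequence variance
cp_prior <- function(x, segment_model, alpha0 = 2) {
  n <- length(x)
  p <- if (segment_model == "linear") 2L else 1L
  m0 <- c(mean(x), 0)[seq_len(p)]
  v0 <- c(100, (10 / n)^2)[seq_len(p)]
  list(m0 = m0, V0_inv = diag(1 / v0, p), logdet_V0 = sum(log(v0)),
       a0 = alpha0, b0 = alpha0 * var(x) / 4)
}

.cp_design <- function(m, segment_model) {
  if (segment_model == "linear") {
    t <- seq_len(m); cbind(1, t - mean(t))
  } else {
    matrix(1, nrow = m)
  }
}

# closed-form log marginal likelihood of a Gaussian linear model under a
# normal-inverse-gamma prior
.bayes_lm_evidence <- function(y, X, prior) {
  m <- length(y)
  Vn_inv <- prior$V0_inv + crossprod(X)
  mn <- solve(Vn_inv, prior$V0_inv %*% prior$m0 + crossprod(X, y))
  an <- prior$a0 + m / 2
  bn <- prior$b0 + 0.5 * (sum(y^2) +
                            drop(t(prior$m0) %*% prior$V0_inv %*% prior$m0) -
                            drop(t(mn) %*% Vn_inv %*% mn))
  -m / 2 * log(2 * pi) +
    0.5 * (-determinant(Vn_inv, logarithm = TRUE)$modulus - prior$logdet_V0) +
    prior$a0 * log(prior$b0) - an * log(bn) + lgamma(an) - lgamma(prior$a0)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Patient abnormal-region set for one modality
#'
#' Ranks regional scores by the modality convention and thresholds the
#' ranked curve with [detect_change_point()]: the regions before the
#' detected mean shift form the abnormal set. If the no-change model is
#' preferred the set is empty.
#'
#' @inheritParams rank_regions
#' @inheritParams detect_change_point
#' @param patient_id identifier stored in the result.
#' @return An `abnormal_set`: list with `patient_id`, `modality`, `rois`
#'   (character vector), `k`, `log_bf`, and `provenance` (per-ROI
#'   contributing modality).
#' @export
abnormal_set <- function(scores, modality, patient_id = NA_character_,
                         min_seg = 2, margin = 0) {
  rk <- rank_regions(scores, modality)
  cp <- detect_change_point(rk$score, min_seg = min_seg, margin = margin)
  rois <- if (cp$k > 0) rk$roi_id[seq_len(cp$k)] else character(0)
  structure(list(patient_id = patient_id, modality = modality,
                 rois = rois, k = cp$k, log_bf = cp$log_bf,
                 provenance = setNames(rep(modality, length(rois)), rois)),
            class = "abnormal_set")
}

#' @export
print.abnormal_set <- function(x, ...) {
  cat(sprintf("<abnormal_set %s [%s]: %d regions (k=%d, logBF=%.2f)>\n",
              x$patient_id, x$modality, length(x$rois), x$k, x$log_bf))
  invisible(x)
}

#' Union of per-modality abnormal sets
#'
#' Combines abnormal sets from one patient by set union: a region is
#' abnormal if any modality flags it. iEEG contributes only over its
#' sampled coverage (an unsampled region can never be vetoed in, nor
#' out, by iEEG). Provenance records which modalities flagged each ROI.
#'
#' @param sets list of `abnormal_set` objects from the same patient.
#' @param tag modality tag for the result (default "union").
#' @return An `abnormal_set` with combined `rois` and provenance.
#' @export
union_abnormalities <- function(sets, tag = "union") {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "abnormal_set")))
  pid <- unique(vapply(sets, function(s) s$patient_id, character(1)))
  if (length(pid) > 1) stop_config("sets from different patients: ",
                                   paste(pid, collapse = ", "))
  prov <- list()
  for (s in sets) {
    for (r in s$rois) prov[[r]] <- union(prov[[r]], s$modality)
  }
  rois <- sort(names(prov))
  structure(list(patient_id = pid, modality = tag, rois = rois,
                 k = length(rois), log_bf = NA_real_,
                 provenance = setNames(
                   vapply(prov[rois], paste, character(1), collapse = "+"),
                   rois)),
            class = "abnormal_set")
}

#' Cohort prevalence of abnormal regions
#'
#' Fraction of patients in which each region is abnormal, for spatial
#' distribution reporting.
#'
#' @param sets list of `abnormal_set` objects (one per patient).
#' @param roi_ids the ROI universe (character vector).
#' @return data.frame `roi_id`, `n_abnormal`, `fraction`.
#' @export
abnormality_prevalence <- function(sets, roi_ids) {
  roi_ids <- as.character(roi_ids)
  counts <- setNames(integer(length(roi_ids)), roi_ids)
  for (s in sets) {
    hit <- intersect(s$rois, roi_ids)
    counts[hit] <- counts[hit] + 1L
  }
  data.frame(roi_id = roi_ids, n_abnormal = as.integer(counts),
             fraction = as.numeric(counts) / length(sets),
             stringsAsFactors = FALSE, row.names = NULL)
}
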