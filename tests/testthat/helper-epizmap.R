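# Shared fixtures and independent oracles, built in code at test time.

# recording containing a pure sinusoid, amplitude 1
sine_recording <- function(freq_hz, fs = 200, duration_s = 70, channels = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(rep(sin(2 * pi * freq_hz * t), channels),
                       nrow = channels, byrow = TRUE), fs)
}

# independent evidence oracle: sequential one-step-ahead Student-t
# predictive decomposition of the normal-inverse-gamma marginal
# likelihood (recursive algebra, distinct from the batch closed form)
seq_predictive_evidence <- function(y, X, prior) {
  m0 <- prior$m0
  V <- solve(prior$V0_inv)
  a <- prior$a0
  b <- prior$b0
  ll <- 0
  for (i in seq_along(y)) {
    x <- X[i, ]
    loc <- sum(x * m0)
    s2 <- b / a * (1 + drop(t(x) %*% V %*% x))
    ll <- ll + stats::dt((y[i] - loc) / sqrt(s2), 2 * a, log = TRUE) -
      0.5 * log(s2)
    Vi <- solve(solve(V) + x %*% t(x))
    mi <- Vi %*% (solve(V) %*% m0 + x * y[i])
    b <- b + 0.5 * (y[i]^2 + drop(t(m0) %*% solve(V) %*% m0) -
                      drop(t(mi) %*% solve(Vi) %*% mi))
    a <- a + 0.5
    m0 <- drop(mi)
    V <- Vi
  }
  ll
}

# exhaustive change-point oracle: argmax over splits of the
# sequential-predictive segment evidences, mirroring the gate
cp_oracle <- function(x, min_seg = 2, margin = 0,
                      segment_model = "linear", max_frac = 0.5) {
  n <- length(x)
  if (stats::sd(x) == 0) return(0L)
  prior <- epizmap:::cp_prior(x, segment_model)
  ev <- function(idx) seq_predictive_evidence(
    x[idx], epizmap:::.cp_design(length(idx), segment_model), prior)
  null_ev <- ev(seq_len(n))
  kmax <- min(n - min_seg, floor(n * max_frac))
  ks <- if (min_seg <= kmax) seq.int(min_seg, kmax) else integer(0)
  if (!length(ks)) return(0L)
  lm_k <- vapply(ks, function(k) ev(1:k) + ev((k + 1):n), numeric(1))
  m <- max(lm_k)
  ev_change <- m + log(sum(exp(lm_k - m))) - log(length(ks))
  if (ev_change - null_ev > margin) ks[which.max(lm_k)] else 0L
}

# O(n^2) pair-counting AUC oracle
auc_pairs <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# trapezoidal ROC integration oracle
auc_trapezoid <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# tiny two-batch feature table with known structure
toy_feature_table <- function(n_per_batch = 20, n_rois = 6, offset = 0,
                              scale = 1, noise_sd = 1, seed = 1,
                              modality = "GM_volume") {
  set.seed(seed)
  subj <- sprintf("s%03d", seq_len(2 * n_per_batch))
  batch <- rep(c("A", "B"), each = n_per_batch)
  age <- runif(2 * n_per_batch, 20, 60)
  sex <- sample(c("M", "F"), 2 * n_per_batch, replace = TRUE)
  grid <- expand.grid(si = seq_len(2 * n_per_batch), roi = seq_len(n_rois))
  base <- 100 + 10 * grid$roi
  eps <- rnorm(nrow(grid), 0, noise_sd)
  off <- ifelse(batch[grid$si] == "B", offset, 0)
  sc <- ifelse(batch[grid$si] == "B", scale, 1)
  data.frame(subject_id = subj[grid$si],
             roi_id = paste0("r", grid$roi), modality = modality,
             value = base + off + sc * eps,
             age = age[grid$si], sex = sex[grid$si],
             batch = batch[grid$si], stringsAsFactors = FALSE)
}

# small cohort configuration for fast end-to-end tests
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(n_controls = 30, n_patients = 8, n_rois = 20,
                n_deep_rois = 2, n_ieeg_norms = 12,
                ieeg = list(fs = 200, duration_s = 70,
                            base_weights = c(delta = 0.35, theta = 0.25,
                                             alpha = 0.18, beta = 0.14,
                                             gamma = 0.08),
                            roi_log_sd = 0.15, subject_log_sd = 0.4,
                            n_rois_sampled = 12, n_implant = 8),
                seed = seed, ...)
}
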