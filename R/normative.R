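# Normative modelling of regional features: batch harmonization,
# covariate-adjusted normative maps, patient z-scoring, and a
# leave-one-out self-calibration harness for the control cohort.

.feature_key <- function(tbl) {
  band <- if ("band" %in% names(tbl)) ifelse(is.na(tbl$band), "", tbl$band) else ""
  paste(tbl$modality, tbl$roi_id, band, sep = "\r")
}

#' Harmonize batch effects in a regional feature table
#'
#' Removes additive and multiplicative batch (scanner/protocol) effects
#' per region with empirical-Bayes shrinkage of the batch parameters
#' across regions, while preserving age and sex covariate effects. The
#' location/scale model with parametric empirical-Bayes priors is fitted
#' by ComBat (\code{sva::ComBat}). A single-batch table is returned
#' unchanged.
#'
#' @param tbl regional feature table: data.frame with `subject_id`,
#'   `roi_id`, `modality`, optional `band`, `value`, `age`, `sex`,
#'   `batch`.
#' @param covariates covariate columns to preserve (default age, sex).
#' @return The table with harmonized `value`s.
#' @export
harmonize_batches <- function(tbl, covariates = c("age", "sex")) {
  miss <- covariates[!covariates %in% names(tbl)]
  if (length(miss)) stop_config("missing covariate column(s): ",
                                paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (anyNA(tbl[[cv]])) stop_config("missing values in covariate ", cv)
  }
  batches <- unique(tbl$batch)
  if (length(batches) < 2) return(tbl)

  key <- .feature_key(tbl)
  subjects <- unique(tbl$subject_id)
  mat <- matrix(NA_real_, nrow = length(unique(key)), ncol = length(subjects),
                dimnames = list(unique(key), subjects))
  mat[cbind(match(key, rownames(mat)), match(tbl$subject_id, subjects))] <- tbl$value

  demog <- unique(tbl[, c("subject_id", "batch", covariates)])
  if (nrow(demog) != length(subjects)) {
    stop_config("inconsistent demographics within subject")
  }
  demog <- demog[match(subjects, demog$subject_id), ]
  if (min(table(demog$batch)) < 2) {
    stop_config("each batch needs at least 2 subjects")
  }
  fm <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  mod <- model.matrix(fm, data = demog)
  harmonized <- suppressMessages(
    sva::ComBat(dat = mat, batch = demog$batch, mod = mod, par.prior = TRUE)
  )
  tbl$value <- harmonized[cbind(match(key, rownames(mat)),
                                match(tbl$subject_id, subjects))]
  tbl
}

#' Build a normative map from a control cohort
#'
#' For each region (and, for iEEG, each frequency band) a linear covariate
#' model `value ~ age + sex` is fitted on the control cohort; the
#' coefficients, the residual standard deviation, and the number of
#' controls are stored. Patients are later z-scored against the
#' covariate-predicted mean and the residual SD. Residual SDs below
#' `sd_floor` are clamped (with a warning) so degenerate regions cannot
#' produce infinite z-scores.
#'
#' @param controls regional feature table (ideally harmonized).
#' @param covariates covariate columns (default age, sex); use
#'   `character(0)` for an unadjusted map.
#' @param sd_floor lower bound on the stored SD, in feature units
#'   (default 1e-6).
#' @param n_min minimum controls per region (default 10); regions with
#'   fewer are dropped with a warning.
#' @return A `normative_map`: data.frame with `modality`, `roi_id`,
#'   `band`, `mean` (intercept at covariate reference), covariate
#'   coefficients, `sd`, `n_controls`.
#' @export
build_normative_map <- function(controls, covariates = c("age", "sex"),
                                sd_floor = 1e-6, n_min = 10) {
  if (!"band" %in% names(controls)) controls$band <- NA_character_
  key <- .feature_key(controls)
  groups <- split(controls, key)
  dropped <- 0L; clamped <- 0L
  rows <- lapply(groups, function(d) {
    if (nrow(d) < n_min) { dropped <<- dropped + 1L; return(NULL) }
    X <- cbind(intercept = rep(1, nrow(d)))
    if ("age" %in% covariates) X <- cbind(X, age = d$age)
    if ("sex" %in% covariates) X <- cbind(X, sexM = as.numeric(d$sex == "M"))
    # drop constant (non-intercept) columns so degenerate cohorts still fit
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(cl) var(cl) > 0))
    X <- X[, keep, drop = FALSE]
    fit <- stats::lm.fit(X, d$value)
    df <- nrow(d) - fit$rank
    s <- if (df > 0) sqrt(sum(fit$residuals^2) / df) else 0
    if (s < sd_floor) { clamped <<- clamped + 1L; s <- sd_floor }
    cf <- setNames(rep(0, 3), c("intercept", "age", "sexM"))
    cf[names(fit$coefficients)] <- ifelse(is.na(fit$coefficients), 0,
                                          fit$coefficients)
    data.frame(modality = d$modality[1], roi_id = as.character(d$roi_id[1]),
               band = d$band[1], mean = cf[["intercept"]],
               b_age = cf[["age"]], b_sexM = cf[["sexM"]],
               sd = s, n_controls = nrow(d), stringsAsFactors = FALSE)
  })
  if (dropped) warning(dropped, " region(s) dropped: fewer than ", n_min,
                       " controls")
  if (clamped) warning(clamped, " region(s) with residual SD below floor; ",
                       "clamped to ", sd_floor)
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_config("no region had enough controls")
  rownames(out) <- NULL
  class(out) <- c("normative_map", "data.frame")
  out
}

#' Z-score patients against a normative map
#'
#' z = (value - predicted control mean given age and sex) / control SD.
#' The sign is preserved: negative z marks gray-matter volume loss,
#' positive z marks increased superficial-white-matter diffusivity.
#' Regions (or bands) without normative coverage are returned as missing
#' with `coverage = "unsampled"` -- never zero-filled.
#'
#' @param patients regional feature table for patients.
#' @param map a `normative_map` from [build_normative_map()].
#' @return z-score map: data.frame `patient_id`, `roi_id`, `modality`,
#'   `band`, `z`, `coverage`.
#' @export
zscore_patients <- function(patients, map) {
  if (!"band" %in% names(patients)) patients$band <- NA_character_
  pk <- .feature_key(patients)
  mk <- .feature_key(map)
  i <- match(pk, mk)
  pred <- map$mean[i] + map$b_age[i] * patients$age +
    map$b_sexM[i] * as.numeric(patients$sex == "M")
  z <- (patients$value - pred) / map$sd[i]
  data.frame(patient_id = patients$subject_id,
             roi_id = as.character(patients$roi_id),
             modality = patients$modality, band = patients$band,
             z = z,
             coverage = ifelse(is.na(i), "unsampled", "sampled"),
             stringsAsFactors = FALSE)
}

#' Leave-one-out self-calibration of the control cohort
#'
#' Each control is z-scored against a normative map built from the other
#' controls. On a well-specified cohort the pooled z-scores should have
#' mean near 0 and SD near 1; heavy tails or model misfit show up as an
#' inflated SD, which is reported, not hidden.
#'
#' @inheritParams build_normative_map
#' @return list: `per_roi` (data.frame `roi_id`, `band`, `mean_z`,
#'   `sd_z`, `n`), `pooled_mean`, `pooled_sd`.
#' @export
control_self_calibration <- function(controls, covariates = c("age", "sex"),
                                     sd_floor = 1e-6, n_min = 10) {
  if (!"band" %in% names(controls)) controls$band <- NA_character_
  groups <- split(controls, .feature_key(controls))
  zs <- list()
  per_roi <- list()
  skipped <- 0L
  for (d in groups) {
    if (nrow(d) < n_min) { skipped <- skipped + 1L; next }
    z <- vapply(seq_len(nrow(d)), function(i) {
      m <- build_normative_map(d[-i, , drop = FALSE], covariates = covariates,
                               sd_floor = sd_floor, n_min = 2)
      zi <- zscore_patients(d[i, , drop = FALSE], m)
      zi$z
    }, numeric(1))
    zs[[length(zs) + 1L]] <- z
    per_roi[[length(per_roi) + 1L]] <-
      data.frame(roi_id = as.character(d$roi_id[1]), band = d$band[1],
                 mean_z = mean(z), sd_z = sd(z), n = length(z),
                 stringsAsFactors = FALSE)
  }
  if (skipped) warning(skipped, " region(s) skipped in self-calibration: n < ",
                       n_min)
  if (!length(zs)) stop_config("no region had enough controls to calibrate")
  pooled <- unlist(zs)
  list(per_roi = do.call(rbind, per_roi),
       pooled_mean = mean(pooled), pooled_sd = sd(pooled))
}

#' Serialize a normative map to JSON
#' @param map a `normative_map`.
#' @param path output file path.
#' @export
write_normative_map <- function(map, path) {
  jsonlite::write_json(as.data.frame(map), path, digits = NA, na = "null")
  invisible(path)
}

#' Read a normative map from JSON
#' @param path JSON file written by [write_normative_map()].
#' @return A `normative_map`.
#' @export
read_normative_map <- function(path) {
  m <- jsonlite::fromJSON(path)
  class(m) <- c("normative_map", "data.frame")
  m
}
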