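# Synthetic cohort generator. Emulates the data structure the analysis
# assumes: two-batch control cohorts for GM volume and SWM mean
# diffusivity, patients with planted regional structural abnormalities,
# interictal iEEG recordings with planted spectral shifts in implanted
# regions, implantation patterns that colocalize with abnormalities more
# in well-targeted patients, resections, and outcome labels whose
# probability increases with the proportion of abnormal regions resected.
# Every generator is seed-deterministic and returns the planted ground
# truth needed for parameter-recovery tests.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic parcellation lookup
#'
#' A bilateral parcellation of `n_rois` regions (half per hemisphere),
#' with `n_deep` regions per analysis flagged as deep structures (the
#' first deep region on each side is named hippocampus). Region
#' centroids are laid out deterministically in mm space, left hemisphere
#' at negative x.
#'
#' @param n_rois total number of regions (even, default 60).
#' @param n_deep number of deep regions (default 4, split across sides).
#' @return data.frame: `roi_id`, `name`, `hemisphere`, `deep`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @export
make_parcellation <- function(n_rois = 60, n_deep = 4) {
  if (n_rois < 2 || n_rois %% 2 != 0) stop_config("n_rois must be even, >= 2")
  half <- n_rois / 2
  nd <- n_deep / 2
  one_side <- function(hemi, sgn) {
    idx <- seq_len(half)
    deep <- idx > (half - nd)
    nm <- ifelse(deep,
                 ifelse(idx == half - nd + 1, "hippocampus",
                        paste0("deep_", idx - (half - nd))),
                 paste0("ctx_", sprintf("%02d", idx)))
    # cortical shell at |x| ~ 40-60 mm; deep structures nearer midline
    ang <- 2 * pi * idx / half
    data.frame(
      roi_id = paste0(hemi, "_", sprintf("%02d", idx)),
      name = paste0(tolower(hemi), "_", nm),
      hemisphere = hemi, deep = deep,
      x_mm = sgn * ifelse(deep, 25, 50),
      y_mm = round(60 * cos(ang), 1) + ifelse(deep, -10, 0),
      z_mm = round(40 * sin(ang), 1),
      stringsAsFactors = FALSE
    )
  }
  rbind(one_side("L", -1), one_side("R", +1))
}

#' Synthetic cohort configuration
#'
#' Bundles the generator's study conditions: cohort sizes, parcellation
#' scale, batch structure (additive offset and multiplicative noise scale
#' per batch, in feature units), demographics, per-modality feature
#' models, and the iEEG synthesis settings.
#'
#' @param n_controls MRI control cohort size (default 97).
#' @param n_patients patient cohort size (default 40).
#' @param n_rois parcellation size (default 60; even).
#' @param n_deep_rois deep regions (default 4).
#' @param n_ieeg_norms iEEG normative subjects (default 30).
#' @param n_abnormal planted epileptogenic regions per patient
#'   (default 6).
#' @param n_structural of those, regions also expressing structurally
#'   (default 3).
#' @param batches data.frame `batch`, `offset_gm` (mm^3), `offset_md`
#'   (mm^2/s), `scale` (noise multiplier). Default: two scanners, the
#'   second with offset +30 mm^3 / +2e-5 mm^2/s and scale 1.1.
#' @param age_range years, default 18-65.
#' @param sex_ratio proportion male, default 0.5.
#' @param gm,md per-modality feature models: lists with `baseline_range`,
#'   `age_slope`, `sex_effect`, `noise_sd` (feature units).
#' @param ieeg iEEG synthesis settings: `fs`, `duration_s`,
#'   `base_weights` (five bands), `roi_log_sd` (per-region band-profile
#'   spread), `subject_log_sd` (between-subject log jitter, the normative
#'   spread), `n_rois_sampled` (per normative subject), `n_implant`
#'   (contacts' regions per patient).
#' @param seed integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_controls = 97, n_patients = 40, n_rois = 60,
                          n_deep_rois = 4, n_ieeg_norms = 30,
                          n_abnormal = 6, n_structural = 3,
                          batches = NULL,
                          age_range = c(18, 65), sex_ratio = 0.5,
                          gm = list(baseline_range = c(2800, 4200),
                                    age_slope = -3, sex_effect = 100,
                                    noise_sd = 150),
                          md = list(baseline_range = c(7.5e-4, 8.5e-4),
                                    age_slope = 1.5e-6, sex_effect = 1e-5,
                                    noise_sd = 2.5e-5),
                          ieeg = list(fs = 200, duration_s = 70,
                                      base_weights = c(delta = 0.35,
                                                       theta = 0.25,
                                                       alpha = 0.18,
                                                       beta = 0.14,
                                                       gamma = 0.08),
                                      roi_log_sd = 0.15,
                                      subject_log_sd = 0.4,
                                      n_rois_sampled = 30,
                                      n_implant = 20),
                          seed = 1L) {
  if (n_controls <= 0 || n_rois <= 0) {
    stop_config("n_controls and n_rois must be positive")
  }
  if (is.null(batches)) {
    batches <- data.frame(batch = c("A", "B"),
                          offset_gm = c(0, 30), offset_md = c(0, 2e-5),
                          scale = c(1, 1.1), stringsAsFactors = FALSE)
  }
  if (any(batches$scale <= 0)) stop_config("batch scales must be positive")
  cfg <- list(n_controls = n_controls, n_patients = n_patients,
              n_rois = n_rois, n_deep_rois = n_deep_rois,
              n_ieeg_norms = n_ieeg_norms,
              n_abnormal = n_abnormal, n_structural = n_structural,
              batches = batches,
              age_range = age_range, sex_ratio = sex_ratio,
              gm = gm, md = md, ieeg = ieeg, seed = as.integer(seed))
  cfg$parcellation <- make_parcellation(n_rois, n_deep_rois)
  # region-specific baselines, fixed by the master seed so that controls
  # and patients share the same underlying feature model
  cfg$baselines <- with_seed(derive_seed(seed, "baselines"), {
    list(
      gm = setNames(runif(n_rois, gm$baseline_range[1], gm$baseline_range[2]),
                    cfg$parcellation$roi_id),
      md = setNames(runif(n_rois, md$baseline_range[1], md$baseline_range[2]),
                    cfg$parcellation$roi_id),
      ieeg_log_offsets = matrix(rnorm(n_rois * 5, 0, ieeg$roi_log_sd),
                                nrow = n_rois,
                                dimnames = list(cfg$parcellation$roi_id,
                                                canonical_bands()$band))
    )
  })
  class(cfg) <- "cohort_config"
  cfg
}

#' Patient specification with planted ground truth parameters
#'
#' @param side surgical side, `"left"` or `"right"`.
#' @param true_abnormal_rois character vector of planted abnormal ROI ids.
#' @param gm_effect planted GM volume shift in control-SD units
#'   (must be <= 0: atrophy).
#' @param swm_effect planted SWM MD shift in control-SD units
#'   (must be >= 0: increased diffusivity).
#' @param spectral_effect planted band-power shift, in units of the
#'   between-subject log spread, applied to `spectral_band` in implanted
#'   true-abnormal regions (>= 0).
#' @param spectral_band designated band (default `"delta"`).
#' @param structural_rois regions expressing the structural (GM volume,
#'   SWM MD) abnormality; default: all of `true_abnormal_rois`.
#' @param functional_rois regions expressing the functional (iEEG band
#'   power) abnormality when implanted; default: all of
#'   `true_abnormal_rois`. Disjoint structural and functional subsets
#'   model modality-discordant (mislocalized) pathology.
#' @param implant_fidelity probability each true-abnormal region is
#'   implanted (in `[0, 1]`).
#' @param resect_fraction proportion of true-abnormal regions resected.
#' @param outcome_intercept,outcome_slope logistic link mapping the
#'   realized proportion of true-abnormal regions resected to
#'   P(ILAE 1-2).
#' @return A `patient_spec` list.
#' @export
patient_spec <- function(side = "left", true_abnormal_rois,
                         gm_effect = -3, swm_effect = 3,
                         spectral_effect = 4, spectral_band = "delta",
                         structural_rois = NULL, functional_rois = NULL,
                         implant_fidelity = 0.9, resect_fraction = 0.85,
                         outcome_intercept = -5.5, outcome_slope = 10) {
  if (gm_effect > 0) stop_config("gm_effect must be <= 0 (volume loss)")
  if (swm_effect < 0) stop_config("swm_effect must be >= 0 (increased MD)")
  if (spectral_effect < 0) stop_config("spectral_effect must be >= 0")
  if (implant_fidelity < 0 || implant_fidelity > 1 ||
      resect_fraction < 0 || resect_fraction > 1) {
    stop_config("probabilities must be in [0, 1]")
  }
  if (!side %in% c("left", "right")) stop_config("side must be left or right")
  true_abnormal_rois <- as.character(true_abnormal_rois)
  structural_rois <- if (is.null(structural_rois)) true_abnormal_rois else
    as.character(structural_rois)
  functional_rois <- if (is.null(functional_rois)) true_abnormal_rois else
    as.character(functional_rois)
  extra <- setdiff(c(structural_rois, functional_rois), true_abnormal_rois)
  if (length(extra)) {
    stop_config("structural/functional rois must be subsets of ",
                "true_abnormal_rois: ", paste(extra, collapse = ", "))
  }
  structure(list(side = side,
                 true_abnormal_rois = true_abnormal_rois,
                 structural_rois = structural_rois,
                 functional_rois = functional_rois,
                 gm_effect = gm_effect, swm_effect = swm_effect,
                 spectral_effect = spectral_effect,
                 spectral_band = spectral_band,
                 implant_fidelity = implant_fidelity,
                 resect_fraction = resect_fraction,
                 outcome_intercept = outcome_intercept,
                 outcome_slope = outcome_slope),
            class = "patient_spec")
}

#' Default patient specifications for the study conditions
#'
#' Each patient has six planted epileptogenic regions on the surgical
#' side, always including the ipsilateral hippocampus; a subset
#' (default three of the six) express structurally (GM volume loss,
#' raised SWM MD). Half the specs
#' are well-characterized: concordant modalities (all six regions
#' express functionally when implanted), implantation targeted at the
#' epileptogenic set (fidelity 0.9), and most of it resected (0.85).
#' The other half are mislocalized: discordant modalities (only the
#' structurally silent regions express functionally), implantation at
#' chance level (fidelity = base implantation rate, i.e. effectively
#' uniform), and little of the epileptogenic set resected (0.3).
#'
#' @param config a [cohort_config()].
#' @param n_abnormal planted abnormal regions per patient (default from
#'   config).
#' @param n_structural regions of the epileptogenic set expressing
#'   structurally (default from config).
#' @return list of [patient_spec()]s of length `config$n_patients`.
#' @export
default_patient_specs <- function(config, n_abnormal = config$n_abnormal,
                                  n_structural = config$n_structural) {
  if (config$n_rois < 2 * n_abnormal) {
    stop_config("n_rois must be at least twice n_abnormal")
  }
  parc <- config$parcellation
  with_seed(derive_seed(config$seed, "specs"), {
    lapply(seq_len(config$n_patients), function(i) {
      side <- if (runif(1) < 0.5) "left" else "right"
      hemi <- if (side == "left") "L" else "R"
      side_rois <- parc$roi_id[parc$hemisphere == hemi]
      hip <- parc$roi_id[parc$hemisphere == hemi &
                           grepl("hippocampus", parc$name)]
      abn <- c(hip, sample(setdiff(side_rois, hip), n_abnormal - length(hip)))
      struct <- abn[seq_len(n_structural)]
      well <- i %% 2 == 1
      chance <- config$ieeg$n_implant / config$n_rois
      patient_spec(side = side, true_abnormal_rois = abn,
                   structural_rois = struct,
                   functional_rois = if (well) abn else setdiff(abn, struct),
                   implant_fidelity = if (well) 0.9 else chance,
                   resect_fraction = if (well) 0.85 else 0.3)
    })
  })
}

.demographics <- function(n, config, prefix, batch_rotate = TRUE) {
  data.frame(
    subject_id = sprintf("%s%03d", prefix, seq_len(n)),
    age = runif(n, config$age_range[1], config$age_range[2]),
    sex = ifelse(runif(n) < config$sex_ratio, "M", "F"),
    batch = config$batches$batch[(seq_len(n) - 1) %% nrow(config$batches) + 1],
    stringsAsFactors = FALSE
  )
}

.feature_values <- function(demog, config, modality) {
  p <- if (modality == "GM_volume") config$gm else config$md
  base <- if (modality == "GM_volume") config$baselines$gm else config$baselines$md
  off <- if (modality == "GM_volume") config$batches$offset_gm else
    config$batches$offset_md
  n_roi <- config$n_rois
  bi <- match(demog$batch, config$batches$batch)
  grid <- expand.grid(si = seq_len(nrow(demog)), ri = seq_len(n_roi))
  age_ref <- mean(config$age_range)
  value <- base[grid$ri] +
    p$age_slope * (demog$age[grid$si] - age_ref) +
    p$sex_effect * (demog$sex[grid$si] == "M") +
    off[bi[grid$si]] +
    config$batches$scale[bi[grid$si]] * rnorm(nrow(grid), 0, p$noise_sd)
  data.frame(subject_id = demog$subject_id[grid$si],
             roi_id = config$parcellation$roi_id[grid$ri],
             modality = modality, value = value,
             age = demog$age[grid$si], sex = demog$sex[grid$si],
             batch = demog$batch[grid$si], stringsAsFactors = FALSE)
}

#' Generate control feature tables
#'
#' One row per control per region per modality, following the generative
#' model: region baseline + age/sex covariate effect + batch offset +
#' batch-scaled Gaussian noise.
#'
#' @param config a [cohort_config()].
#' @return list of two regional feature tables: `GM_volume`, `SWM_MD`.
#' @export
generate_control_features <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "controls"), {
    demog <- .demographics(config$n_controls, config, "ctl")
    list(GM_volume = .feature_values(demog, config, "GM_volume"),
         SWM_MD = .feature_values(demog, config, "SWM_MD"))
  })
}

#' Generate patient feature tables with planted abnormalities
#'
#' Patients are drawn from the control model, then planted shifts are
#' applied in each patient's structurally expressing regions: GM volume
#' lowered by `|gm_effect|` control SDs, SWM MD raised by `swm_effect`
#' control SDs.
#'
#' @param config a [cohort_config()].
#' @param specs list of [patient_spec()]s (default
#'   [default_patient_specs()]).
#' @return list: `features` (list of GM/SWM tables), `ground_truth`
#'   (per-patient list: spec, true abnormal set).
#' @export
generate_patient_features <- function(config, specs = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(specs)) specs <- default_patient_specs(config)
  bad <- unlist(lapply(specs, function(s)
    setdiff(s$true_abnormal_rois, config$parcellation$roi_id)))
  if (length(bad)) stop_config("unknown true_abnormal_rois: ",
                               paste(unique(bad), collapse = ", "))
  with_seed(derive_seed(config$seed, "patients"), {
    demog <- .demographics(length(specs), config, "pat")
    gm <- .feature_values(demog, config, "GM_volume")
    md <- .feature_values(demog, config, "SWM_MD")
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      pid <- demog$subject_id[i]
      hit_gm <- gm$subject_id == pid & gm$roi_id %in% s$structural_rois
      gm$value[hit_gm] <- gm$value[hit_gm] + s$gm_effect * config$gm$noise_sd
      hit_md <- md$subject_id == pid & md$roi_id %in% s$structural_rois
      md$value[hit_md] <- md$value[hit_md] + s$swm_effect * config$md$noise_sd
    }
    gt <- lapply(seq_along(specs), function(i) {
      list(patient_id = demog$subject_id[i], spec = specs[[i]],
           true_abnormal_rois = specs[[i]]$true_abnormal_rois)
    })
    names(gt) <- demog$subject_id
    list(features = list(GM_volume = gm, SWM_MD = md),
         ground_truth = gt, demographics = demog)
  })
}

# synthesize one channel as band-limited noise: shaped random-phase
# spectrum inverted to the time domain; expected power in band b
# proportional to weights[b]
.synth_channel <- function(n, fs, weights, bands = canonical_bands()) {
  freq <- (0:(n - 1)) * fs / n
  S <- numeric(n)
  half <- freq <= fs / 2
  for (b in seq_len(nrow(bands))) {
    sel <- half & freq >= bands$lo[b] & freq < bands$hi[b]
    if (any(sel)) S[sel] <- weights[b] / sum(sel)
  }
  X <- complex(real = rnorm(n), imaginary = rnorm(n)) * sqrt(S / 2)
  X[1] <- 0
  # Hermitian symmetry -> real signal
  k <- 2:ceiling(n / 2)
  X[n + 2 - k] <- Conj(X[k])
  if (n %% 2 == 0) X[n / 2 + 1] <- complex(real = rnorm(1) *
                                             sqrt(S[n / 2 + 1]), imaginary = 0)
  Re(fft(X, inverse = TRUE))
}

.subject_band_weights <- function(config, rois, abnormal_rois = character(0),
                                  spectral_effect = 0, spectral_band = "delta") {
  bands <- canonical_bands()$band
  base <- config$ieeg$base_weights[bands]
  w <- matrix(NA_real_, nrow = length(rois), ncol = 5,
              dimnames = list(rois, bands))
  for (i in seq_along(rois)) {
    lo <- config$baselines$ieeg_log_offsets[rois[i], ]
    jit <- rnorm(5, 0, config$ieeg$subject_log_sd)
    w[i, ] <- base * exp(lo + jit)
    if (rois[i] %in% abnormal_rois && spectral_effect > 0) {
      w[i, spectral_band] <- w[i, spectral_band] *
        exp(spectral_effect * config$ieeg$subject_log_sd)
    }
  }
  w
}

.place_contacts <- function(parc, rois, prefix) {
  i <- match(rois, parc$roi_id)
  data.frame(
    contact_id = sprintf("%s_c%02d", prefix, seq_along(rois)),
    x_mm = parc$x_mm[i] + rnorm(length(rois), 0, 0.8),
    y_mm = parc$y_mm[i] + rnorm(length(rois), 0, 0.8),
    z_mm = parc$z_mm[i] + rnorm(length(rois), 0, 0.8),
    tissue = "GM", artifact = FALSE, stringsAsFactors = FALSE
  )
}

#' Generate an electrode study for one subject
#'
#' Places one contact near the centroid of each sampled region and
#' synthesizes each channel as a sum of band-limited noise components
#' with the subject's per-region band-power weights. In functionally
#' expressing sampled regions the designated band's power is scaled up
#' by the spec's `spectral_effect` (in units of the between-subject log
#' spread).
#'
#' @param config a [cohort_config()].
#' @param subject_id identifier.
#' @param rois regions sampled by the implantation.
#' @param spec optional [patient_spec()] carrying the planted spectral
#'   abnormality (omit for normative subjects).
#' @param seed integer seed for this study.
#' @param duration_s recording duration (default from config; must be
#'   >= 70 s).
#' @return An `electrode_study`: list with `subject_id`, `contacts`,
#'   `recording` (an [eeg_recording()]), `rois`.
#' @export
generate_ieeg_study <- function(config, subject_id, rois, spec = NULL,
                                seed = config$seed,
                                duration_s = config$ieeg$duration_s) {
  fs <- config$ieeg$fs
  if (fs < 160) stop_config("sampling rate must be >= 160 Hz (gamma band)")
  if (duration_s < 70) stop_config("duration must be >= 70 s")
  with_seed(seed, {
    abn <- if (is.null(spec)) character(0) else spec$functional_rois
    eff <- if (is.null(spec)) 0 else spec$spectral_effect
    bnd <- if (is.null(spec)) "delta" else spec$spectral_band
    w <- .subject_band_weights(config, rois, abn, eff, bnd)
    n <- round(duration_s * fs)
    dat <- t(vapply(seq_along(rois), function(i)
      .synth_channel(n, fs, w[i, ]), numeric(n)))
    contacts <- .place_contacts(config$parcellation, rois, subject_id)
    structure(list(subject_id = subject_id, contacts = contacts,
                   recording = eeg_recording(dat, fs, contacts$contact_id),
                   rois = rois),
              class = "electrode_study")
  })
}

#' Generate implantation, resection, and outcome for each patient
#'
#' Implanted set: each true-abnormal region with probability
#' `implant_fidelity`, topped up uniformly from the surgical-side
#' regions to `n_implant`. Resected set: `resect_fraction` of the
#' true-abnormal regions plus two adjacent same-side regions. Outcome is
#' Bernoulli with P(ILAE 1-2) given by the spec's logistic link on the
#' realized proportion of true-abnormal regions resected. Overlap
#' fractions: resected regions draw from U(0.3, 1), implanted
#' non-resected neighbours from U(0, 0.08).
#'
#' @param config a [cohort_config()].
#' @param ground_truth from [generate_patient_features()].
#' @return list: `surgery` (data.frame `patient_id`, `roi_id`,
#'   `overlap_fraction`, `implanted`), `outcomes` (data.frame
#'   `patient_id`, `outcome`, `side`, `prop_true_resected`),
#'   `ground_truth` augmented with implanted/resected sets.
#' @export
generate_surgery <- function(config, ground_truth) {
  parc <- config$parcellation
  with_seed(derive_seed(config$seed, "surgery"), {
    surgery <- list(); outcomes <- list()
    for (pid in names(ground_truth)) {
      gt <- ground_truth[[pid]]
      s <- gt$spec
      hemi <- if (s$side == "left") "L" else "R"
      side_rois <- parc$roi_id[parc$hemisphere == hemi]
      abn <- gt$true_abnormal_rois
      implanted <- abn[runif(length(abn)) < s$implant_fidelity]
      # top up with non-abnormal regions from both hemispheres, so that
      # P(implanted | abnormal) = implant_fidelity exactly
      pool <- setdiff(parc$roi_id, abn)
      extra <- config$ieeg$n_implant - length(implanted)
      if (extra > 0) implanted <- c(implanted,
                                    sample(pool, min(extra, length(pool))))
      n_res <- round(s$resect_fraction * length(abn))
      resected <- if (n_res > 0) sample(abn, n_res) else character(0)
      resected <- union(resected,
                        sample(setdiff(side_rois, abn), 2))
      prop <- length(intersect(resected, abn)) / length(abn)
      p_good <- plogis(s$outcome_intercept + s$outcome_slope * prop)
      outcome <- if (runif(1) < p_good) "ILAE12" else "ILAE3plus"
      frac <- setNames(numeric(length(parc$roi_id)), parc$roi_id)
      frac[resected] <- runif(length(resected), 0.3, 1)
      near <- setdiff(implanted, resected)
      frac[near] <- runif(length(near), 0, 0.08)
      surgery[[pid]] <- data.frame(patient_id = pid, roi_id = parc$roi_id,
                                   overlap_fraction = unname(frac),
                                   implanted = parc$roi_id %in% implanted,
                                   stringsAsFactors = FALSE)
      outcomes[[pid]] <- data.frame(patient_id = pid, outcome = outcome,
                                    side = s$side, prop_true_resected = prop,
                                    stringsAsFactors = FALSE)
      ground_truth[[pid]]$implanted <- implanted
      ground_truth[[pid]]$resected <- resected
      ground_truth[[pid]]$outcome <- outcome
    }
    list(surgery = do.call(rbind, c(surgery, make.row.names = FALSE)),
         outcomes = do.call(rbind, c(outcomes, make.row.names = FALSE)),
         ground_truth = ground_truth)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the whole generator: MRI control cohorts, patients with
#' planted structural abnormalities, implantations, interictal iEEG
#' studies for patients and normative subjects, resections, and
#' outcomes. All randomness derives from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param specs optional list of [patient_spec()]s.
#' @param with_ieeg generate iEEG studies (default TRUE; the slowest
#'   part).
#' @return A `synthetic_cohort` list: `config`, `parcellation`,
#'   `controls`, `patients`, `ground_truth`, `surgery`, `outcomes`,
#'   `ieeg_patients` (electrode studies), `ieeg_norms`.
#' @export
simulate_cohort <- function(config = cohort_config(), specs = NULL,
                            with_ieeg = TRUE) {
  controls <- generate_control_features(config)
  pat <- generate_patient_features(config, specs)
  surg <- generate_surgery(config, pat$ground_truth)
  ieeg_patients <- NULL; ieeg_norms <- NULL
  if (with_ieeg) {
    ieeg_patients <- lapply(names(surg$ground_truth), function(pid) {
      gt <- surg$ground_truth[[pid]]
      generate_ieeg_study(config, pid, gt$implanted, spec = gt$spec,
                          seed = derive_seed(config$seed, paste0("ieeg_", pid)))
    })
    names(ieeg_patients) <- names(surg$ground_truth)
    ieeg_norms <- lapply(seq_len(config$n_ieeg_norms), function(i) {
      sid <- sprintf("norm%03d", i)
      rois <- with_seed(derive_seed(config$seed, paste0("cov_", sid)),
                        sample(config$parcellation$roi_id,
                               config$ieeg$n_rois_sampled))
      generate_ieeg_study(config, sid, rois,
                          seed = derive_seed(config$seed, paste0("ieeg_", sid)))
    })
    names(ieeg_norms) <- sprintf("norm%03d", seq_len(config$n_ieeg_norms))
  }
  structure(list(config = config, parcellation = config$parcellation,
                 controls = controls, patients = pat$features,
                 ground_truth = surg$ground_truth, surgery = surg$surgery,
                 outcomes = surg$outcomes, ieeg_patients = ieeg_patients,
                 ieeg_norms = ieeg_norms),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to delimited files
#'
#' Feature tables, electrode tables, surgery and outcome tables, the
#' parcellation lookup, and the ground truth (JSON) are written under
#' `dir` in the package's documented CSV formats.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  w(rbind(cohort$controls$GM_volume, cohort$controls$SWM_MD), "controls.csv")
  w(rbind(cohort$patients$GM_volume, cohort$patients$SWM_MD), "patients.csv")
  w(cohort$surgery, "surgery.csv")
  w(cohort$outcomes, "outcomes.csv")
  w(cohort$parcellation, "parcellation.csv")
  if (!is.null(cohort$ieeg_patients)) {
    contacts <- do.call(rbind, lapply(cohort$ieeg_patients, function(st) {
      cbind(subject_id = st$subject_id, st$contacts)
    }))
    w(contacts, "contacts.csv")
  }
  gt <- lapply(cohort$ground_truth, function(g) {
    list(true_abnormal_rois = g$true_abnormal_rois,
         implanted = g$implanted, resected = g$resected,
         outcome = g$outcome, side = g$spec$side)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
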