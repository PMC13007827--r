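# End-to-end orchestration: simulate (or ingest) -> harmonize ->
# normative maps -> z-scores -> iEEG band power -> abnormal sets ->
# resection overlap -> outcome statistics, with a manifest and
# machine-readable outputs per stage.

#' Pipeline configuration
#'
#' Collects every tunable setting of the analysis with defaults at the
#' study's stated values: 200 Hz sampling, 2-s Hamming windows with 1-s
#' overlap, the five canonical bands, 70-s epochs, 5-mm region and 2-mm
#' WM-to-GM contact rules, and the strict 10% resection-overlap rule.
#'
#' @param simulate a [cohort_config()] (or NULL when `inputs` are given).
#' @param inputs optional named list of CSV paths: `controls`,
#'   `patients`, `surgery`, `outcomes`, `parcellation` (pre-extracted
#'   feature tables; iEEG stages require `simulate`).
#' @param target_rate,welch_window_s,welch_overlap_s,epoch_s Welch and
#'   epoch settings.
#' @param max_contact_dist_mm,wm_gm_max_mm contact assignment rules.
#' @param overlap_threshold strict resected-region rule (default 0.10).
#' @param sd_floor,n_min normative map settings.
#' @param cp_min_seg,cp_margin change-point settings.
#' @param modality `"MRI"` or `"MRI+iEEG"` (both are always computed when
#'   iEEG data are present; this names the primary result).
#' @param seed master seed (overrides the simulate block's).
#' @param out_dir output directory, or NULL to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_config(), inputs = NULL,
                            target_rate = 200, welch_window_s = 2,
                            welch_overlap_s = 1, epoch_s = 70,
                            max_contact_dist_mm = 5, wm_gm_max_mm = 2,
                            overlap_threshold = 0.10,
                            sd_floor = 1e-6, n_min = 10,
                            cp_min_seg = 2, cp_margin = 0,
                            modality = c("MRI+iEEG", "MRI"),
                            seed = NULL, out_dir = NULL) {
  modality <- match.arg(modality)
  if (!is.null(seed) && !is.null(simulate)) simulate$seed <- as.integer(seed)
  cfg <- list(simulate = simulate, inputs = inputs,
              target_rate = target_rate, welch_window_s = welch_window_s,
              welch_overlap_s = welch_overlap_s, epoch_s = epoch_s,
              max_contact_dist_mm = max_contact_dist_mm,
              wm_gm_max_mm = wm_gm_max_mm,
              overlap_threshold = overlap_threshold,
              sd_floor = sd_floor, n_min = n_min,
              cp_min_seg = cp_min_seg, cp_margin = cp_margin,
              modality = modality,
              seed = seed %||% (if (!is.null(simulate)) simulate$seed else 1L),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (YAML)
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) {
    cfg$simulate <- unclass(cfg$simulate)
    cfg$simulate$parcellation <- NULL   # derived, rebuilt on read
    cfg$simulate$baselines <- NULL
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    sim <- cohort_config(
      n_controls = s$n_controls, n_patients = s$n_patients,
      n_rois = s$n_rois, n_deep_rois = s$n_deep_rois,
      n_ieeg_norms = s$n_ieeg_norms,
      n_abnormal = s$n_abnormal, n_structural = s$n_structural,
      batches = as.data.frame(s$batches),
      age_range = unlist(s$age_range), sex_ratio = s$sex_ratio,
      gm = lapply(s$gm, unlist), md = lapply(s$md, unlist),
      ieeg = lapply(s$ieeg, unlist), seed = s$seed)
  }
  pipeline_config(simulate = sim, inputs = cfg$inputs,
                  target_rate = cfg$target_rate,
                  welch_window_s = cfg$welch_window_s,
                  welch_overlap_s = cfg$welch_overlap_s,
                  epoch_s = cfg$epoch_s,
                  max_contact_dist_mm = cfg$max_contact_dist_mm,
                  wm_gm_max_mm = cfg$wm_gm_max_mm,
                  overlap_threshold = cfg$overlap_threshold,
                  sd_floor = cfg$sd_floor, n_min = cfg$n_min,
                  cp_min_seg = cfg$cp_min_seg, cp_margin = cfg$cp_margin,
                  modality = cfg$modality, seed = cfg$seed,
                  out_dir = cfg$out_dir)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
      class = c("epizmap_stage_error", "error")))
  })
}

.ieeg_feature_table <- function(study, config, subject_demog = NULL) {
  rec <- preprocess_recording(study$recording, config$target_rate)
  ep <- extract_epoch(rec, config$epoch_s)
  spec <- welch_psd(ep, config$welch_window_s, config$welch_overlap_s)
  bp <- band_powers(spec)
  geom <- split(as.matrix(config$simulate$parcellation[, c("x_mm", "y_mm", "z_mm")]),
                config$simulate$parcellation$roi_id)
  geom <- lapply(geom, matrix, ncol = 3)
  asg <- assign_contacts(study$contacts, geom,
                         config$max_contact_dist_mm, config$wm_gm_max_mm)
  reg <- regional_band_power(bp, asg)
  if (nrow(reg) == 0) return(NULL)
  data.frame(subject_id = study$subject_id, roi_id = reg$roi_id,
             modality = "iEEG_bandpower", band = reg$band,
             value = reg$value,
             age = subject_demog$age %||% 40,
             sex = subject_demog$sex %||% "F",
             batch = "ieeg", stringsAsFactors = FALSE)
}

.read_inputs <- function(inputs) {
  need <- c("controls", "patients", "surgery", "outcomes", "parcellation")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop_config("missing input path(s): ",
                                paste(miss, collapse = ", "))
  rd <- function(p, cols) {
    d <- tryCatch(read.csv(p, stringsAsFactors = FALSE),
                  error = function(e) stop_config("cannot read ", p, ": ",
                                                  conditionMessage(e)))
    bad <- setdiff(cols, names(d))
    if (length(bad)) stop_config(p, " lacks column(s): ",
                                 paste(bad, collapse = ", "))
    d
  }
  list(controls = rd(inputs$controls,
                     c("subject_id", "roi_id", "modality", "value",
                       "age", "sex", "batch")),
       patients = rd(inputs$patients,
                     c("subject_id", "roi_id", "modality", "value",
                       "age", "sex", "batch")),
       surgery = rd(inputs$surgery,
                    c("patient_id", "roi_id", "overlap_fraction",
                      "implanted")),
       outcomes = rd(inputs$outcomes, c("patient_id", "outcome", "side")),
       parcellation = rd(inputs$parcellation,
                         c("roi_id", "hemisphere")))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate or ingest; batch harmonization
#' of the MRI feature tables; normative maps and patient z-scores; iEEG
#' band-power extraction, normative mapping, and abnormality scores;
#' ranked change-point abnormal sets per modality and their unions;
#' resection-overlap scores; and the outcome-differentiation statistics.
#' When `config$out_dir` is set, every stage's artifacts plus a manifest
#' (config hash, seed, package version) are written there.
#'
#' @param config a [pipeline_config()].
#' @return A results list: `scores` (per-patient overlap scores),
#'   `stats` (AUC/AUPRC/rank-sum/DeLong/colocalization), `abnormal_sets`,
#'   `prevalence`, `zmaps`, `normative_maps`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$inputs)) {
    ing <- .stage("ingest", .read_inputs(config$inputs))
    controls <- split(ing$controls, ing$controls$modality)
    patients <- split(ing$patients, ing$patients$modality)
    surgery <- ing$surgery; outcomes <- ing$outcomes
    parcellation <- ing$parcellation
    ieeg_tables <- NULL; ieeg_norm_tbl <- NULL
    demog <- NULL
  } else {
    cohort <- .stage("simulate", simulate_cohort(config$simulate))
    controls <- cohort$controls
    patients <- cohort$patients
    surgery <- cohort$surgery; outcomes <- cohort$outcomes
    parcellation <- cohort$parcellation
    demog <- unique(rbind(
      cohort$patients$GM_volume[, c("subject_id", "age", "sex")]))
    ieeg_tables <- .stage("bandpower", {
      lapply(cohort$ieeg_patients, function(st) {
        .ieeg_feature_table(st, config,
                            demog[demog$subject_id == st$subject_id, ])
      })
    })
    ieeg_norm_tbl <- .stage("bandpower", {
      do.call(rbind, lapply(cohort$ieeg_norms, function(st)
        .ieeg_feature_table(st, config)))
    })
  }

  # --- MRI normative maps and z-scores -------------------------------
  harmon <- .stage("harmonize", {
    lapply(names(controls), function(m) {
      joint <- rbind(controls[[m]], patients[[m]])
      harmonize_batches(joint)
    })
  })
  names(harmon) <- names(controls)

  zmaps <- list(); maps <- list()
  for (m in names(harmon)) {
    h <- harmon[[m]]
    ctl <- h[h$subject_id %in% controls[[m]]$subject_id, ]
    pat <- h[h$subject_id %in% patients[[m]]$subject_id, ]
    maps[[m]] <- .stage("normative",
                        build_normative_map(ctl, sd_floor = config$sd_floor,
                                            n_min = config$n_min))
    zmaps[[m]] <- .stage("normative", zscore_patients(pat, maps[[m]]))
  }

  # --- iEEG normative map and abnormality scores ---------------------
  ieeg_scores <- NULL
  if (!is.null(ieeg_norm_tbl)) {
    maps$iEEG <- .stage("normative",
                        build_normative_map(ieeg_norm_tbl,
                                            covariates = character(0),
                                            sd_floor = config$sd_floor,
                                            n_min = config$n_min))
    ieeg_scores <- lapply(ieeg_tables, function(tbl) {
      if (is.null(tbl)) return(NULL)
      z <- zscore_patients(tbl, maps$iEEG)
      ieeg_abnormality(z)
    })
  }

  # --- abnormal sets per patient -------------------------------------
  patient_ids <- unique(outcomes$patient_id)
  sets <- .stage("abnormality", lapply(patient_ids, function(pid) {
    gm <- zmaps$GM_volume[zmaps$GM_volume$patient_id == pid, ]
    sw <- zmaps$SWM_MD[zmaps$SWM_MD$patient_id == pid, ]
    s_gm <- abnormal_set(gm, "GM_volume", pid,
                         config$cp_min_seg, config$cp_margin)
    s_sw <- abnormal_set(sw, "SWM_MD", pid,
                         config$cp_min_seg, config$cp_margin)
    mri <- union_abnormalities(list(s_gm, s_sw), tag = "MRI")
    out <- list(GM = s_gm, SWM = s_sw, MRI = mri)
    if (!is.null(ieeg_scores) && !is.null(ieeg_scores[[pid]]) &&
        nrow(ieeg_scores[[pid]]) >= 3) {
      s_ie <- abnormal_set(ieeg_scores[[pid]], "iEEG", pid,
                           config$cp_min_seg, config$cp_margin)
      out$iEEG <- s_ie
      out$MRI_iEEG <- union_abnormalities(list(s_gm, s_sw, s_ie),
                                          tag = "MRI+iEEG")
    }
    out
  }))
  names(sets) <- patient_ids

  # --- resection overlap ---------------------------------------------
  scores <- .stage("overlap", {
    do.call(rbind, lapply(patient_ids, function(pid) {
      sd_ <- surgery[surgery$patient_id == pid, ]
      res <- resected_set(sd_, config$overlap_threshold)
      mri <- proportion_abnormal_resected(sets[[pid]]$MRI, res)
      mie <- if (!is.null(sets[[pid]]$MRI_iEEG))
        proportion_abnormal_resected(sets[[pid]]$MRI_iEEG, res)
      else list(proportion = NA_real_)
      data.frame(patient_id = pid,
                 prop_mri = mri$proportion,
                 prop_mri_ieeg = mie$proportion,
                 outcome = outcomes$outcome[outcomes$patient_id == pid],
                 stringsAsFactors = FALSE)
    }))
  })

  # --- outcome statistics --------------------------------------------
  stats <- .stage("stats", {
    good <- scores$outcome == "ILAE12"
    res <- list()
    res$mri <- .modality_stats(scores$prop_mri, good)
    if (any(!is.na(scores$prop_mri_ieeg))) {
      res$mri_ieeg <- .modality_stats(scores$prop_mri_ieeg, good)
      res$delong <- tryCatch(
        delong_paired(scores$prop_mri_ieeg, scores$prop_mri, good),
        error = function(e) list(error = conditionMessage(e)))
    }
    res$colocalization <- .colocalization_stats(sets, surgery, outcomes,
                                                ieeg_scores)
    res
  })

  prev <- abnormality_prevalence(lapply(sets, `[[`, "MRI"),
                                 parcellation$roi_id)

  manifest <- list(
    package_version = as.character(utils::packageVersion("epizmap")),
    seed = config$seed,
    modality = config$modality,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_patients = length(patient_ids),
    config_hash = .config_hash(config))

  results <- list(scores = scores, stats = stats, abnormal_sets = sets,
                  prevalence = prev, zmaps = zmaps, normative_maps = maps,
                  outcomes = outcomes, manifest = manifest)
  if (!is.null(config$out_dir)) .write_results(results, config)
  results
}

.modality_stats <- function(prop, good) {
  ok <- !is.na(prop)
  n_excluded <- sum(!ok)
  a <- auc_mw(prop[ok & good], prop[ok & !good])
  pr <- auprc(prop[ok], good[ok])
  rs <- ranksum_one_tailed(prop[ok & good], prop[ok & !good])
  cv <- tryCatch(loo_outcome_cv(prop[ok], good[ok]),
                 error = function(e) list(error = conditionMessage(e)))
  list(auc = a$auc, auprc = pr$auprc, W = rs$W, p = rs$p,
       n_excluded_empty = n_excluded,
       loo_accuracy = cv$accuracy %||% NA_real_)
}

.colocalization_stats <- function(sets, surgery, outcomes, ieeg_scores) {
  obs <- do.call(rbind, lapply(names(sets), function(pid) {
    sd_ <- surgery[surgery$patient_id == pid, ]
    mri <- sd_$roi_id %in% sets[[pid]]$MRI$rois
    ie_ab <- if (!is.null(sets[[pid]]$iEEG))
      sd_$roi_id %in% sets[[pid]]$iEEG$rois else rep(NA, nrow(sd_))
    data.frame(patient_id = pid, roi_id = sd_$roi_id,
               implanted = sd_$implanted, mri_abnormal = mri,
               ieeg_abnormal = ifelse(sd_$implanted, ie_ab, NA),
               outcome = outcomes$outcome[outcomes$patient_id == pid],
               stringsAsFactors = FALSE)
  }))
  fit_group <- function(resp, grp) {
    d <- obs[obs$outcome == grp & !is.na(obs[[resp]]), ]
    tryCatch(colocalization_logistic(d[[resp]], d$mri_abnormal),
             error = function(e) list(error = conditionMessage(e)))
  }
  list(implanted_good = fit_group("implanted", "ILAE12"),
       implanted_poor = fit_group("implanted", "ILAE3plus"),
       ieeg_good = fit_group("ieeg_abnormal", "ILAE12"),
       ieeg_poor = fit_group("ieeg_abnormal", "ILAE3plus"))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.write_results <- function(results, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write.csv(results$scores, p("overlap_scores.csv"), row.names = FALSE)
  write.csv(results$prevalence, p("prevalence.csv"), row.names = FALSE)
  sets_json <- lapply(results$abnormal_sets, function(s)
    lapply(s, function(a) list(modality = a$modality, rois = a$rois,
                               k = a$k, log_bf = a$log_bf)))
  jsonlite::write_json(sets_json, p("abnormal_sets.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(results$stats, p("stats.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  jsonlite::write_json(results$manifest, p("manifest.json"),
                       auto_unbox = TRUE)
  for (m in names(results$normative_maps)) {
    write_normative_map(results$normative_maps[[m]],
                        p(paste0("normative_", gsub("\\W", "_", m), ".json")))
  }
  invisible(config$out_dir)
}
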