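# Synthetic cohort generator: determinism, planted structure, and the
# statistical properties the downstream analysis assumes.

test_that("identical seeds give bit-identical feature tables", {
  cfg <- small_cohort_config(seed = 7)
  a <- generate_control_features(cfg)
  b <- generate_control_features(cfg)
  expect_identical(a, b)
  pa <- generate_patient_features(cfg)
  pb <- generate_patient_features(cfg)
  expect_identical(pa$features, pb$features)
})

test_that("different seeds give different tables", {
  a <- generate_control_features(small_cohort_config(seed = 7))
  b <- generate_control_features(small_cohort_config(seed = 8))
  expect_false(identical(a$GM_volume$value, b$GM_volume$value))
})

test_that("a planted batch offset is recovered at Monte-Carlo precision", {
  batches <- data.frame(batch = c("A", "B"), offset_gm = c(0, 10),
                        offset_md = c(0, 0), scale = c(1, 1))
  cfg <- cohort_config(n_controls = 200, n_patients = 2, n_rois = 10,
                       n_deep_rois = 2, batches = batches, seed = 3)
  gm <- generate_control_features(cfg)$GM_volume
  # per-region batch difference, averaged across regions
  d <- sapply(split(gm, gm$roi_id), function(g)
    mean(g$value[g$batch == "B"]) - mean(g$value[g$batch == "A"]))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 10), 3 * se + 1e-9)
})

test_that("zero noise, zero covariates, one batch reproduce the baselines", {
  cfg <- cohort_config(
    n_controls = 5, n_patients = 2, n_rois = 6, n_deep_rois = 2,
    batches = data.frame(batch = "A", offset_gm = 0, offset_md = 0,
                         scale = 1),
    gm = list(baseline_range = c(3000, 4000), age_slope = 0,
              sex_effect = 0, noise_sd = 0),
    md = list(baseline_range = c(7e-4, 9e-4), age_slope = 0,
              sex_effect = 0, noise_sd = 0),
    seed = 4)
  gm <- generate_control_features(cfg)$GM_volume
  expect_equal(gm$value, unname(cfg$baselines$gm[gm$roi_id]))
})

test_that("planted structural shifts equal effect times control SD exactly", {
  cfg <- small_cohort_config(seed = 9)
  rois <- cfg$parcellation$roi_id[1:6]
  mk_specs <- function(gm_eff, swm_eff) lapply(1:4, function(i)
    patient_spec(side = "left", true_abnormal_rois = rois,
                 gm_effect = gm_eff, swm_effect = swm_eff))
  with_ <- generate_patient_features(cfg, mk_specs(-3, 3))
  without <- generate_patient_features(cfg, mk_specs(0, 0))
  dg <- with_$features$GM_volume$value - without$features$GM_volume$value
  planted <- with_$features$GM_volume$roi_id %in% rois
  expect_true(all(abs(dg[planted] + 3 * cfg$gm$noise_sd) < 1e-9))
  expect_true(all(dg[!planted] == 0))
  dm <- with_$features$SWM_MD$value - without$features$SWM_MD$value
  expect_true(all(abs(dm[planted] - 3 * cfg$md$noise_sd) < 1e-12))
})

test_that("zero-effect patients are exchangeable with controls", {
  cfg <- small_cohort_config(seed = 10)
  specs <- lapply(1:8, function(i)
    patient_spec(side = "left",
                 true_abnormal_rois = cfg$parcellation$roi_id[1:6],
                 gm_effect = 0, swm_effect = 0, spectral_effect = 0))
  ctl <- generate_control_features(cfg)$GM_volume
  pat <- generate_patient_features(cfg, specs)$features$GM_volume
  ps <- sapply(split(seq_len(nrow(ctl)), ctl$roi_id)[1:10], function(i) {
    roi <- ctl$roi_id[i[1]]
    wilcox.test(ctl$value[i], pat$value[pat$roi_id == roi])$p.value
  })
  expect_gt(min(p.adjust(ps, "bonferroni")), 0.05)
})

test_that("spec validation rejects wrong-signed effects and bad regions", {
  expect_error(patient_spec("left", "r1", gm_effect = 1),
               class = "epizmap_config_error")
  expect_error(patient_spec("left", "r1", swm_effect = -1),
               class = "epizmap_config_error")
  expect_error(patient_spec("left", "r1", implant_fidelity = 1.2),
               class = "epizmap_config_error")
  cfg <- small_cohort_config()
  specs <- list(patient_spec("left", "no_such_roi"))
  expect_error(generate_patient_features(cfg, specs),
               class = "epizmap_config_error")
})

test_that("a saturating outcome link separates outcomes perfectly", {
  cfg <- small_cohort_config(seed = 12)
  rois <- cfg$parcellation$roi_id[1:6]
  specs <- lapply(1:8, function(i)
    patient_spec(side = "left", true_abnormal_rois = rois,
                 implant_fidelity = 1,
                 resect_fraction = ifelse(i <= 4, 1, 0),
                 outcome_intercept = -5e5, outcome_slope = 1e6))
  gt <- generate_patient_features(cfg, specs)$ground_truth
  surg <- generate_surgery(cfg, gt)
  good <- surg$outcomes$outcome == "ILAE12"
  expect_true(all(surg$outcomes$prop_true_resected[good] >
                    max(surg$outcomes$prop_true_resected[!good])))
  expect_equal(sort(as.vector(table(surg$outcomes$outcome))), c(4L, 4L))
})

test_that("iEEG studies are seed-deterministic and validate duration", {
  cfg <- small_cohort_config(seed = 13)
  rois <- cfg$parcellation$roi_id[1:5]
  a <- generate_ieeg_study(cfg, "s1", rois, seed = 99)
  b <- generate_ieeg_study(cfg, "s1", rois, seed = 99)
  expect_identical(a$recording$data, b$recording$data)
  expect_gte(ncol(a$recording$data) / cfg$ieeg$fs, 70)
  expect_error(generate_ieeg_study(cfg, "s1", rois, duration_s = 60),
               class = "epizmap_config_error")
})

test_that("a tenfold delta-power region attains the cohort-maximum delta z", {
  cfg <- small_cohort_config(seed = 14)
  pcfg <- pipeline_config(simulate = cfg)
  norm_tbl <- do.call(rbind, lapply(seq_len(15), function(i) {
    sid <- sprintf("norm%02d", i)
    st <- generate_ieeg_study(cfg, sid, cfg$parcellation$roi_id[1:12],
                              seed = 1000 + i)
    epizmap:::.ieeg_feature_table(st, pcfg)
  }))
  map <- suppressWarnings(build_normative_map(norm_tbl,
                                              covariates = character(0),
                                              n_min = 8))
  target <- cfg$parcellation$roi_id[3]
  spec <- patient_spec(side = "left",
                       true_abnormal_rois = target,
                       spectral_effect = log(10) / cfg$ieeg$subject_log_sd,
                       spectral_band = "delta")
  st <- generate_ieeg_study(cfg, "p1", cfg$parcellation$roi_id[1:12],
                            spec = spec, seed = 500)
  tbl <- epizmap:::.ieeg_feature_table(st, pcfg)
  z <- zscore_patients(tbl, map)
  zd <- z[z$band == "delta" & !is.na(z$z), ]
  expect_equal(zd$roi_id[which.max(abs(zd$z))], target)
})

test_that("null spectral effects give calibrated regional z-scores", {
  cfg <- small_cohort_config(seed = 15)
  pcfg <- pipeline_config(simulate = cfg)
  mk_tbl <- function(sid, seed) {
    st <- generate_ieeg_study(cfg, sid, cfg$parcellation$roi_id[1:12],
                              seed = seed)
    epizmap:::.ieeg_feature_table(st, pcfg)
  }
  norm_tbl <- do.call(rbind, lapply(1:15, function(i)
    mk_tbl(sprintf("n%02d", i), 2000 + i)))
  map <- suppressWarnings(build_normative_map(norm_tbl,
                                              covariates = character(0),
                                              n_min = 8))
  zs <- unlist(lapply(1:6, function(i) {
    z <- zscore_patients(mk_tbl(sprintf("p%02d", i), 3000 + i), map)
    z$z[!is.na(z$z)]
  }))
  expect_gt(length(zs), 200)
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(sd(zs), 0.8); expect_lt(sd(zs), 1.35)
})

test_that("null cohorts give small, non-lateralized MRI abnormal sets", {
  cfg <- cohort_config(n_controls = 40, n_patients = 100, n_rois = 20,
                       n_deep_rois = 2, seed = 16)
  specs <- lapply(1:100, function(i)
    patient_spec(side = ifelse(i %% 2 == 0, "left", "right"),
                 true_abnormal_rois = cfg$parcellation$roi_id[1:6],
                 gm_effect = 0, swm_effect = 0, spectral_effect = 0))
  ctl <- generate_control_features(cfg)
  pat <- generate_patient_features(cfg, specs)
  map_gm <- build_normative_map(harmonize_batches(ctl$GM_volume))
  map_md <- build_normative_map(harmonize_batches(ctl$SWM_MD))
  zg <- zscore_patients(harmonize_batches(
    rbind(ctl$GM_volume, pat$features$GM_volume)), map_gm)
  zg <- zg[grepl("^pat", zg$patient_id), ]
  zm <- zscore_patients(harmonize_batches(
    rbind(ctl$SWM_MD, pat$features$SWM_MD)), map_md)
  zm <- zm[grepl("^pat", zm$patient_id), ]
  sets <- lapply(unique(zg$patient_id), function(pid) {
    union_abnormalities(list(
      abnormal_set(zg[zg$patient_id == pid, ], "GM_volume", pid),
      abnormal_set(zm[zm$patient_id == pid, ], "SWM_MD", pid)), "MRI")
  })
  sizes <- vapply(sets, function(s) length(s$rois), numeric(1))
  expect_lte(median(sizes), 0.10 * cfg$n_rois)
  prev <- abnormality_prevalence(sets, cfg$parcellation$roi_id)
  expect_lte(max(prev$fraction), 0.30)
})

test_that("planted structural regions are recovered in the abnormal sets", {
  cohort <- simulate_cohort(cohort_config(seed = 17), with_ieeg = FALSE)
  h_gm <- harmonize_batches(rbind(cohort$controls$GM_volume,
                                  cohort$patients$GM_volume))
  h_md <- harmonize_batches(rbind(cohort$controls$SWM_MD,
                                  cohort$patients$SWM_MD))
  is_ctl <- function(d) d$subject_id %in% cohort$controls$GM_volume$subject_id
  map_gm <- build_normative_map(h_gm[is_ctl(h_gm), ])
  map_md <- build_normative_map(h_md[is_ctl(h_md), ])
  zg <- zscore_patients(h_gm[!is_ctl(h_gm), ], map_gm)
  zm <- zscore_patients(h_md[!is_ctl(h_md), ], map_md)
  hits <- 0; total <- 0
  for (pid in names(cohort$ground_truth)) {
    s <- union_abnormalities(list(
      abnormal_set(zg[zg$patient_id == pid, ], "GM_volume", pid),
      abnormal_set(zm[zm$patient_id == pid, ], "SWM_MD", pid)), "MRI")
    truth <- cohort$ground_truth[[pid]]$spec$structural_rois
    hits <- hits + length(intersect(truth, s$rois))
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.9)
})

test_that("ground truth is consistent with the parcellation and outcomes", {
  cohort <- simulate_cohort(small_cohort_config(seed = 18),
                            with_ieeg = FALSE)
  for (gt in cohort$ground_truth) {
    expect_true(all(gt$resected %in% cohort$parcellation$roi_id))
    expect_true(all(gt$implanted %in% cohort$parcellation$roi_id))
    expect_true(gt$outcome %in% c("ILAE12", "ILAE3plus"))
  }
})

test_that("cohorts serialize to the documented delimited formats", {
  cohort <- simulate_cohort(small_cohort_config(seed = 19),
                            with_ieeg = FALSE)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(cohort, dir)
  ctl <- read.csv(file.path(dir, "controls.csv"))
  expect_true(all(c("subject_id", "roi_id", "modality", "value", "age",
                    "sex", "batch") %in% names(ctl)))
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt), 8)
  unlink(dir, recursive = TRUE)
})
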