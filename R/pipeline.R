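# End-to-end orchestration: simulate -> preprocess -> ecology -> assoc ->
# hmi -> region-ml -> diet-assoc, one seed, one output directory, a manifest.

# per-stage seeds fan out from the global seed by fixed offsets, so any
# stage can be rerun independently from the manifest alone
.stage_seed <- function(seed, stage_index) as.integer(seed + 1000L * stage_index)

#' Run the full pipeline on a synthetic cohort
#'
#' Chains the seven stages on a generated cohort, writing every stage output
#' as TSV plus a JSON manifest (seeds, row counts, fallbacks, file
#' checksums). Rerunning with the same config and seed reproduces every file
#' bit-identically.
#'
#' @param outdir output directory (created if needed).
#' @param config a [run_config()]; `config$random_seed` drives every stage.
#' @param n_participants,n_provinces,truth forwarded to [generate_cohort()].
#' @param classifier_repeats repeats for the region classifier (default
#'   `config$n_classifier_repeats`; lower it for quick runs).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(outdir, config = run_config(),
                         n_participants = 2772, n_provinces = 15,
                         truth = synthetic_truth(),
                         classifier_repeats = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$random_seed
  manifest <- list(package_version = as.character(utils::packageVersion("glycobiome")),
                   random_seed = seed, stages = list())
  note <- function(stage, idx, ...) {
    manifest$stages[[stage]] <<- c(list(index = idx, seed = .stage_seed(seed, idx)), list(...))
  }
  path <- function(f) file.path(outdir, f)
  wtsv <- function(x, f) {
    utils::write.table(x, path(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }

  # 1 simulate
  sim <- generate_cohort(n_participants, n_provinces, truth,
                         seed = .stage_seed(seed, 1))
  write_abundance_table(sim$abundance, path("abundance.tsv"))
  write_cohort_table(sim$cohort, path("cohort.tsv"))
  truth_out <- sim$truth
  truth_out$genus_trait_betas <- as.data.frame(truth_out$genus_trait_betas)
  jsonlite::write_json(truth_out, path("truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  note("simulate", 1, n = nrow(sim$cohort),
       files = c("abundance.tsv", "cohort.tsv", "truth.json"))

  # 2 preprocess
  filt <- filter_prevalence(sim$abundance, config$prevalence_threshold)
  cohort <- impute_missing(sim$cohort)
  cohort <- add_homa_ir(cohort, config$insulin_conversion)
  write_abundance_table(filt$table, path("abundance_filtered.tsv"))
  note("preprocess", 2, genera_kept = ncol(filt$table),
       genera_dropped = length(filt$dropped),
       files = "abundance_filtered.tsv")

  # 3 ecology
  d <- bray_curtis(filt$table)
  ord <- pcoa(d, k = 2)
  perm <- permutation_test(d, cohort$region, config$n_permutations,
                           seed = .stage_seed(seed, 3))
  wtsv(data.frame(participant_id = rownames(ord$coordinates),
                  ord$coordinates), "pcoa.tsv")
  note("ecology", 3, pseudo_f = perm$f, p_value = perm$p_value,
       explained_variance = ord$explained_variance, files = "pcoa.tsv")

  # 4 assoc
  scan <- run_association_scan(filt$table, cohort, config)
  panel <- build_signed_panel(scan, config$alpha)
  wtsv(as.data.frame(scan), "assoc_scan.tsv")
  wtsv(as.data.frame(panel), "signed_panel.tsv")
  note("assoc", 4, n_records = nrow(scan), panel_size = nrow(panel),
       fallbacks = sum(scan$fallback_north != "none" | scan$fallback_south != "none"),
       files = c("assoc_scan.tsv", "signed_panel.tsv"))

  # 5 hmi
  followed <- !is.na(cohort$fasting_glucose_1)
  co_f <- cohort[followed, , drop = FALSE]
  hmi <- compute_hmi(unclass(filt$table)[match(co_f$participant_id,
                                               rownames(filt$table)), ,
                                         drop = FALSE],
                     if (nrow(panel)) panel else sim$truth$panel,
                     config$carriage_threshold)
  inc <- ascertain_t2d(co_f$fasting_glucose_1, co_f$hba1c_1,
                       co_f$diabetes_medication_1)
  covs <- .assoc_covariates(adjust_bmi = TRUE)
  risk <- tryCatch(hmi_risk_model(hmi$hmi_z, inc, co_f[, covs, drop = FALSE]),
                   error = function(e) NULL)
  sub_df <- data.frame(co_f, hmi_z = hmi$hmi_z, incident_t2d = inc,
                       check.names = FALSE)
  subs <- subgroup_scan(sub_df, covs)
  overall <- if (is.null(risk))
    data.frame(subgroup = "overall", rr = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, n = nrow(co_f), n_events = sum(inc),
               skipped = "risk model not estimable", stringsAsFactors = FALSE)
  else
    data.frame(subgroup = "overall", rr = risk$rr, ci_low = risk$ci_low,
               ci_high = risk$ci_high, n = risk$n, n_events = risk$n_events,
               skipped = NA_character_, stringsAsFactors = FALSE)
  wtsv(rbind(overall, subs), "hmi_risk.tsv")
  note("hmi", 5, n_followed = nrow(co_f), n_events = sum(inc),
       rr = overall$rr[1], files = "hmi_risk.tsv")

  # 6 region-ml
  reps <- classifier_repeats %||% config$n_classifier_repeats
  clf <- logo_region_classify(filt$table, cohort, n_repeats = reps,
                              seed = .stage_seed(seed, 6))
  disc <- select_discriminating_genera(clf, filt$table)
  sel <- disc$genus[disc$selected]
  wtsv(data.frame(participant_id = names(clf$probability),
                  p_south = clf$probability), "region_probability.tsv")
  wtsv(disc, "discriminating_genera.tsv")
  pref <- staple_ratio(cohort$wheat, cohort$rice)$preference
  ok <- !is.na(pref)
  diet_pred <- predict_diet_from_genera(
    unclass(filt$table)[match(cohort$participant_id[ok],
                              rownames(filt$table)), sel, drop = FALSE],
    as.numeric(pref[ok] == "wheat"), task = "classification",
    region = cohort$region[ok], folds = config$cv_folds,
    seed = .stage_seed(seed, 6))
  note("region_ml", 6, auc_region = clf$auc,
       n_discriminating = length(sel),
       auc_staple = diet_pred$performance$auc,
       files = c("region_probability.tsv", "discriminating_genera.tsv"))

  # 7 diet-assoc
  use_panel <- if (nrow(panel)) panel else sim$truth$panel
  outcomes <- panel_outcomes(filt$table, cohort, use_panel,
                             config$carriage_threshold)
  diet <- diet_genus_scan(cohort, outcomes)
  fib <- fibre_scan(cohort, outcomes)
  wtsv(diet, "diet_assoc.tsv")
  wtsv(fib, "fibre_assoc.tsv")
  note("diet_assoc", 7, n_records = nrow(diet),
       n_significant = sum(diet$significant),
       files = c("diet_assoc.tsv", "fibre_assoc.tsv"))

  files <- list.files(outdir, pattern = "\\.tsv$|\\.json$")
  files <- setdiff(files, "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
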