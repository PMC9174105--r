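# Synthetic cohort generator: two-region, province-nested cohorts with
# zero-inflated log-normal genus compositions, Table-1-calibrated covariates,
# planted genus->trait effects and a log-link Bernoulli incidence process.
# Every planted parameter is emitted so downstream estimation is testable.

# lognormal meanlog/sdlog matched to an arithmetic mean and SD
.lnorm_pars <- function(m, s) {
  cv2 <- (s / m)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.rlnorm_ms <- function(n, m, s) {
  p <- .lnorm_pars(m, s)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' Planted ground truth for a synthetic cohort
#'
#' Defines every parameter the generator plants: per-genus occupancy
#' probabilities and log-abundance means, the North/South log-scale abundance
#' shift, per-SD genus-to-trait effects, the signed panel driving the
#' Healthy Microbiome Index, the per-SD log risk ratio for incident
#' diabetes, and diet-to-genus effects. All fields are deterministic
#' functions of the arguments, so a truth object plus a seed fully
#' reproduces a cohort.
#'
#' Trait effects are planted on fasting glucose, fasting insulin (on the
#' log-insulin scale, since insulin is generated log-normally) and HbA1c;
#' HOMA-IR is a deterministic function of glucose and insulin, so its
#' effects are derived, never planted directly.
#'
#' @param n_genera number of genera (default 60).
#' @param panel_size number of planted panel genera, half favourable, half
#'   harmful (default 8).
#' @param panel_beta absolute per-SD genus effect for panel genera
#'   (default 0.12); favourable genera get negative sign.
#' @param hmi_log_rr per-SD log risk ratio of incident diabetes on the
#'   planted HMI (default `log(0.69)`).
#' @param baseline_incidence incidence at HMI_z = 0 among followed
#'   participants (default 0.067).
#' @param n_region_shifted number of genera with a North/South abundance
#'   shift (default 12).
#' @param region_shift_size absolute log-scale shift for shifted genera
#'   (default 1.2); signs alternate.
#' @param age_log_rr log risk ratio per SD of age in the incidence process
#'   (default 0.15), so covariate adjustment is non-trivial.
#' @param followup_rate fraction retained at follow-up (default 0.66).
#' @param diet_effects named list: diet factor -> list(genera = indices,
#'   effect = log-abundance change per SD of intake). Default plants wheat
#'   effects on five region-shifted genera and vegetable effects on two
#'   others.
#'
#' @return A list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(n_genera = 60,
                            panel_size = 8,
                            panel_beta = 0.12,
                            hmi_log_rr = log(0.69),
                            baseline_incidence = 0.067,
                            n_region_shifted = 12,
                            region_shift_size = 1.2,
                            age_log_rr = 0.15,
                            followup_rate = 0.66,
                            diet_effects = NULL) {
  stopifnot(n_genera >= panel_size, panel_size %% 2 == 0,
            baseline_incidence > 0, baseline_incidence < 1,
            followup_rate > 0, followup_rate <= 1)
  genus_names <- sprintf("Genus%03d", seq_len(n_genera))
  traits <- c("fasting_glucose", "fasting_insulin", "hba1c")

  # deterministic occupancy/log-mean grids; panel genera kept mid-occupancy
  # so carriage is informative for the HMI
  occupancy <- seq(0.15, 0.90, length.out = n_genera)
  occupancy[seq_len(panel_size)] <- seq(0.35, 0.65, length.out = panel_size)
  log_mean <- seq(-1.5, 1.5, length.out = n_genera)

  betas <- matrix(0, n_genera, length(traits),
                  dimnames = list(genus_names, traits))
  half <- panel_size / 2
  fav <- seq_len(half)
  harm <- half + seq_len(half)
  for (k in seq_len(half)) {
    betas[fav[k], traits[(k - 1) %% 3 + 1]] <- -panel_beta
    betas[harm[k], traits[(k - 1) %% 3 + 1]] <- panel_beta
  }
  panel <- data.frame(
    genus = genus_names[c(fav, harm)],
    direction = rep(c("favourable", "harmful"), each = half),
    stringsAsFactors = FALSE
  )

  region_shift <- numeric(n_genera)
  if (n_region_shifted > 0) {
    idx <- panel_size + seq_len(min(n_region_shifted, n_genera - panel_size))
    region_shift[idx] <- region_shift_size * rep_len(c(1, -1), length(idx))
  }

  if (is.null(diet_effects)) {
    shifted <- which(region_shift != 0)
    diet_effects <- list(
      wheat = list(genera = utils::head(shifted, 5), effect = 0.6),
      vegetable = list(genera = utils::head(setdiff(which(region_shift == 0),
                                                    seq_len(panel_size)), 2),
                       effect = 0.5)
    )
  }

  structure(list(
    n_genera = n_genera, genus_names = genus_names, traits = traits,
    occupancy = occupancy, log_mean = log_mean, log_sd = 1,
    genus_trait_betas = betas, panel = panel,
    hmi_log_rr = hmi_log_rr, baseline_incidence = baseline_incidence,
    region_shift = region_shift, diet_effects = diet_effects,
    age_log_rr = age_log_rr, followup_rate = followup_rate,
    trait_tracking = 0.30, age_effect = 0.10, bmi_effect = 0.10,
    province_sd = 0.15
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", x$n_genera, "genera;",
      nrow(x$panel), "panel genera;",
      sum(x$region_shift != 0), "region-shifted\n")
  cat(sprintf("  HMI log RR per SD %.4f (RR %.3f); baseline incidence %.3f\n",
              x$hmi_log_rr, exp(x$hmi_log_rr), x$baseline_incidence))
  invisible(x)
}

# region-specific covariate calibration (means/SDs of the emulated cohort)
.covariate_calibration <- list(
  North = list(
    age = c(50.9, 13.2), bmi = c(24.8, 3.4), female = 0.465,
    edu = c(0.621, 0.217, 0.162), married = 0.901, income = c(6.4, 8.6),
    urban = 0.318, urbanisation = c(69.1, 18.1), pa = c(138.8, 141.7),
    energy = c(8372.6, 2869.8), smoking = 0.255, alcohol = 0.286,
    rice = c(0.2, 0.2), wheat = c(0.2, 0.2), fruit = c(0.04, 0.07),
    vegetable = c(0.2, 0.1), nuts = c(0.003, 0.008), pork = c(0.04, 0.04),
    poultry = c(0.01, 0.03), milk = c(0.02, 0.07), egg = c(0.03, 0.04),
    fish = c(0.02, 0.03), vegetable_oil = c(0.02, 0.02),
    animal_oil = c(0.0004, 0.003),
    glucose = c(5.3, 0.6), hba1c = c(36.7, 4.1), insulin = c(47.4, 36.2)
  ),
  South = list(
    age = c(50.7, 12.5), bmi = c(23.7, 3.2), female = 0.487,
    edu = c(0.666, 0.221, 0.113), married = 0.850, income = c(7.8, 11.4),
    urban = 0.359, urbanisation = c(74.5, 16.8), pa = c(151.6, 155.5),
    energy = c(8285.9, 2819.6), smoking = 0.278, alcohol = 0.301,
    rice = c(0.3, 0.1), wheat = c(0.07, 0.07), fruit = c(0.04, 0.06),
    vegetable = c(0.3, 0.1), nuts = c(0.004, 0.01), pork = c(0.09, 0.07),
    poultry = c(0.02, 0.04), milk = c(0.01, 0.04), egg = c(0.02, 0.02),
    fish = c(0.03, 0.05), vegetable_oil = c(0.02, 0.03),
    animal_oil = c(0.007, 0.01),
    glucose = c(5.1, 0.6), hba1c = c(36.6, 4.4), insulin = c(52.4, 47.5)
  )
)

#' Generate a synthetic two-region cohort with planted effects
#'
#' Draws a province-nested cohort: covariates calibrated region-wise to the
#' emulated population, zero-inflated log-normal genus compositions with a
#' log-scale regional shift and diet effects, follow-up glycaemic traits
#' driven by the planted per-SD genus effects, and incident diabetes from a
#' Bernoulli process with log link
#' `log p = log(baseline_incidence) + hmi_log_rr * HMI_z + age_log_rr * age_z`,
#' where HMI_z is computed from the planted signed panel over the followed
#' subsample. Incident/non-incident status is reconciled with the follow-up
#' panel (medication flag or supra-threshold glucose/HbA1c for cases; traits
#' capped just below threshold for non-cases), so [ascertain_t2d()]
#' reproduces the drawn status exactly.
#'
#' @param n_participants cohort size at baseline (default 2772).
#' @param n_provinces number of provinces (default 15: 6 North, 9 South).
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed; the same seed and truth give a bit-identical
#'   cohort.
#'
#' @return List with `abundance` ([genus_table()]), `cohort`
#'   (`cohort_table`, follow-up columns `NA` for participants lost to
#'   follow-up), and `truth` (the input truth augmented with `seed`,
#'   realized `hmi` scores and the drawn `incident` flags, named by
#'   participant).
#' @export
generate_cohort <- function(n_participants = 2772, n_provinces = 15,
                            truth = synthetic_truth(), seed = 1) {
  stopifnot(n_provinces >= 2, n_participants >= 10)
  set.seed(seed)
  n <- n_participants
  G <- truth$n_genera

  n_north <- max(1L, round(n_provinces * 6 / 15))
  if (n_north >= n_provinces) n_north <- n_provinces - 1L
  provinces <- sprintf("P%02d", seq_len(n_provinces))
  prov_region <- ifelse(seq_len(n_provinces) <= n_north, "North", "South")
  # weight Northern provinces down so the regional split mirrors the
  # emulated cohort (~36% North)
  w <- ifelse(prov_region == "North", 0.84, 1.0)
  prov <- sample(provinces, n, replace = TRUE, prob = w / sum(w))
  region <- prov_region[match(prov, provinces)]
  ids <- sprintf("S%05d", seq_len(n))

  cal <- lapply(region, function(r) .covariate_calibration[[r]])
  pick <- function(field, j = NULL) {
    v <- vapply(cal, function(cc) if (is.null(j)) cc[[field]][1] else cc[[field]][j], 0)
    v
  }
  m2 <- function(field) list(m = pick(field, 1), s = pick(field, 2))

  rnorm2 <- function(field, floor = NULL) {
    p <- m2(field)
    x <- stats::rnorm(n, p$m, p$s)
    if (!is.null(floor)) x <- pmax(x, floor)
    x
  }
  rlnorm2 <- function(field) {
    p <- m2(field)
    pars <- .lnorm_pars(p$m, p$s)
    stats::rlnorm(n, pars$meanlog, pars$sdlog)
  }

  age <- rnorm2("age", floor = 18)
  bmi <- rnorm2("bmi", floor = 14)
  sex <- ifelse(stats::runif(n) < pick("female", 1), "female", "male")
  edu_p <- do.call(rbind, lapply(cal, function(cc) cc$edu))
  education <- vapply(seq_len(n), function(i)
    sample(c("middle_or_lower", "high_school", "university"), 1,
           prob = edu_p[i, ]), "")
  marital <- ifelse(stats::runif(n) < pick("married", 1), "married", "unmarried")
  income <- rlnorm2("income")
  residence <- ifelse(stats::runif(n) < pick("urban", 1), "urban", "rural")
  urbanisation_index <- rnorm2("urbanisation", floor = 0)
  physical_activity <- rlnorm2("pa")
  energy <- rnorm2("energy", floor = 500)
  smoking <- as.numeric(stats::runif(n) < pick("smoking", 1))
  alcohol <- as.numeric(stats::runif(n) < pick("alcohol", 1))
  diet_cols <- c("rice", "wheat", "fruit", "vegetable", "nuts", "pork",
                 "poultry", "milk", "egg", "fish", "vegetable_oil", "animal_oil")
  diet <- lapply(diet_cols, function(d) rlnorm2(d))
  names(diet) <- diet_cols
  fibre <- .rlnorm_ms(n, 11, 5)

  # --- abundances: zero-inflated log-normal, closed to sum 1 ---
  present <- matrix(stats::rbinom(n * G, 1, rep(truth$occupancy, each = n)), n, G)
  logab <- matrix(rep(truth$log_mean, each = n), n, G) +
    outer(as.numeric(region == "South"), truth$region_shift) +
    matrix(stats::rnorm(n * G, 0, truth$log_sd), n, G)
  for (f in names(truth$diet_effects)) {
    de <- truth$diet_effects[[f]]
    src <- if (f %in% diet_cols) diet[[f]] else fibre
    z <- (src - mean(src)) / stats::sd(src)
    logab[, de$genera] <- logab[, de$genera] + de$effect * z
  }
  raw <- present * exp(logab)
  zero_rows <- rowSums(raw) == 0
  if (any(zero_rows)) {  # guarantee at least one detected genus per row
    g_top <- which.max(truth$occupancy)
    raw[zero_rows, g_top] <- exp(truth$log_mean[g_top])
  }
  abundance <- raw / rowSums(raw)
  dimnames(abundance) <- list(ids, truth$genus_names)

  # --- baseline glycaemic panel ---
  glu <- m2("glucose"); hb <- m2("hba1c"); ins <- m2("insulin")
  fasting_glucose_0 <- pmax(stats::rnorm(n, glu$m, glu$s), 3)
  hba1c_0 <- pmax(stats::rnorm(n, hb$m, hb$s), 20)
  ins_pars <- Map(function(m, s) .lnorm_pars(m, s), ins$m, ins$s)
  fasting_insulin_0 <- stats::rlnorm(n,
    vapply(ins_pars, `[[`, 0, "meanlog"), vapply(ins_pars, `[[`, 0, "sdlog"))

  # --- follow-up ---
  followed <- stats::runif(n) < truth$followup_rate
  nf <- sum(followed)
  if (nf < 10) stop("follow-up sample too small; increase n_participants")
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  u_prov <- stats::setNames(stats::rnorm(n_provinces, 0, truth$province_sd), provinces)

  genus_z_f <- apply(abundance[followed, , drop = FALSE], 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, nf) else (v - mean(v)) / s
  })
  age_z_f <- zs(age[followed]); bmi_z_f <- zs(bmi[followed])
  prov_eff_f <- u_prov[prov[followed]]

  trait1_lin <- function(trait, baseline_z) {
    b <- truth$genus_trait_betas[, trait]
    sys <- truth$trait_tracking * baseline_z +
      as.numeric(genus_z_f %*% b) +
      truth$age_effect * age_z_f + truth$bmi_effect * bmi_z_f + prov_eff_f
    var_expl <- truth$trait_tracking^2 + sum(b^2) +
      truth$age_effect^2 + truth$bmi_effect^2 + truth$province_sd^2
    noise_sd <- sqrt(max(0.05, 1 - var_expl))
    sys + stats::rnorm(nf, 0, noise_sd)
  }

  fasting_glucose_1 <- hba1c_1 <- fasting_insulin_1 <- rep(NA_real_, n)
  glu_lin <- trait1_lin("fasting_glucose", zs(fasting_glucose_0[followed]))
  hb_lin  <- trait1_lin("hba1c", zs(hba1c_0[followed]))
  ins_lin <- trait1_lin("fasting_insulin", zs(log(fasting_insulin_0[followed])))
  fasting_glucose_1[followed] <- pmax(glu$m[followed] + glu$s[followed] * glu_lin, 3)
  hba1c_1[followed] <- pmax(hb$m[followed] + hb$s[followed] * hb_lin, 20)
  ml <- vapply(ins_pars, `[[`, 0, "meanlog")[followed]
  sl <- vapply(ins_pars, `[[`, 0, "sdlog")[followed]
  fasting_insulin_1[followed] <- exp(ml + sl * ins_lin)

  # --- incidence: log-link Bernoulli on planted HMI ---
  hmi_f <- .hmi_count(abundance[followed, , drop = FALSE], truth$panel, 0)
  if (stats::sd(hmi_f) == 0) stop("planted HMI is constant; panel uninformative")
  hmi_z_f <- zs(hmi_f)
  p_inc <- truth$baseline_incidence *
    exp(truth$hmi_log_rr * hmi_z_f + truth$age_log_rr * age_z_f)
  if (any(p_inc >= 1))
    stop(sprintf("infeasible incidence configuration: max probability %.3f >= 1",
                 max(p_inc)))
  incident_f <- stats::rbinom(nf, 1, p_inc)

  # reconcile the follow-up panel with drawn status so ascertainment is exact
  # cases split across the three ascertainment routes (medication, fasting
  # glucose, HbA1c) so no single trait absorbs the diagnostic elevation
  meds_f <- rep(0, nf)
  gl1 <- fasting_glucose_1[followed]; hb1 <- hba1c_1[followed]
  case <- incident_f == 1
  route <- stats::runif(nf)
  on_meds <- case & route < 0.5
  meds_f[on_meds] <- 1
  via_glu <- case & !on_meds & route < 0.75
  via_hb <- case & !on_meds & !via_glu
  gl1[via_glu] <- pmax(gl1[via_glu], 7.0 + abs(stats::rnorm(sum(via_glu), 0, 0.5)))
  hb1[via_hb] <- pmax(hb1[via_hb], 47.5 + abs(stats::rnorm(sum(via_hb), 0, 3)))
  gl1[!case] <- pmin(gl1[!case], 6.99)
  hb1[!case] <- pmin(hb1[!case], 47.4)
  fasting_glucose_1[followed] <- gl1
  hba1c_1[followed] <- hb1
  diabetes_medication_1 <- rep(NA_real_, n)
  diabetes_medication_1[followed] <- meds_f
  followup_years <- rep(NA_real_, n)
  followup_years[followed] <- pmax(stats::rnorm(nf, 3.0, 0.09), 2)

  cohort <- data.frame(
    participant_id = ids, province = prov, region = region,
    age = age, sex = sex, bmi = bmi, income = income, marital = marital,
    education = education, residence = residence,
    urbanisation_index = urbanisation_index, energy = energy,
    smoking = smoking, alcohol = alcohol, physical_activity = physical_activity,
    diet, fibre = fibre,
    fasting_glucose_0 = fasting_glucose_0,
    fasting_insulin_0 = fasting_insulin_0, hba1c_0 = hba1c_0,
    fasting_glucose_1 = fasting_glucose_1,
    fasting_insulin_1 = fasting_insulin_1, hba1c_1 = hba1c_1,
    diabetes_medication_1 = diabetes_medication_1,
    followup_years = followup_years,
    stringsAsFactors = FALSE
  )
  cohort <- as_cohort_table(cohort)

  truth$seed <- seed
  truth$hmi <- stats::setNames(hmi_f, ids[followed])
  truth$incident <- stats::setNames(incident_f, ids[followed])
  glyco_log("simulate", n = n, followed = nf, events = sum(incident_f), seed = seed)
  list(abundance = genus_table(abundance), cohort = cohort, truth = truth)
}

#' Mask covariate cells completely at random
#'
#' Each maskable covariate cell (demographics, anthropometrics, lifestyle and
#' diet; never outcomes, region, province or IDs) is independently set
#' missing with probability `rate` (MCAR).
#'
#' @param cohort a cohort table.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed; a fixed seed gives an identical mask.
#' @return The cohort with injected `NA`s.
#' @export
inject_missingness <- function(cohort, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  set.seed(seed)
  outcome_cols <- c("fasting_glucose_0", "fasting_insulin_0", "hba1c_0",
                    "fasting_glucose_1", "fasting_insulin_1", "hba1c_1",
                    "diabetes_medication_1", "followup_years")
  maskable <- setdiff(cohort_required_cols(),
                      c("participant_id", "province", "region", outcome_cols))
  for (nm in maskable) {
    mask <- stats::runif(nrow(cohort)) < rate
    cohort[[nm]][mask] <- NA
  }
  cohort
}

#' Construct disjoint exclusion flags for a participant list
#'
#' Testing helper mirroring a baseline exclusion cascade: picks disjoint
#' sets of participants flagged for antibiotic use, intestinal disease and
#' prevalent diabetes.
#'
#' @param participant_ids character vector of IDs.
#' @param n_antibiotics,n_intestinal,n_prevalent counts per criterion.
#' @param seed integer seed.
#' @return A data frame suitable for [apply_exclusions()].
#' @export
make_exclusion_flags <- function(participant_ids, n_antibiotics = 0,
                                 n_intestinal = 0, n_prevalent = 0, seed = 1) {
  n <- length(participant_ids)
  tot <- n_antibiotics + n_intestinal + n_prevalent
  if (tot > n) stop("more flags than participants")
  set.seed(seed)
  idx <- sample(n, tot)
  f <- data.frame(participant_id = participant_ids,
                  antibiotics = FALSE, intestinal_disease = FALSE,
                  prevalent_t2d = FALSE, stringsAsFactors = FALSE)
  f$antibiotics[idx[seq_len(n_antibiotics)]] <- TRUE
  f$intestinal_disease[idx[n_antibiotics + seq_len(n_intestinal)]] <- TRUE
  f$prevalent_t2d[idx[n_antibiotics + n_intestinal + seq_len(n_prevalent)]] <- TRUE
  f
}
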