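# Exclusion cascade, prevalence filter, region-wise imputation, derived
# glycaemic variables and per-SD standardization.

#' Apply the baseline exclusion cascade
#'
#' Participants are excluded sequentially for (1) recent antibiotic use,
#' (2) history of intestinal disease, (3) prevalent type 2 diabetes at
#' baseline. A participant meeting several criteria is counted once, at the
#' first criterion met, so the exclusion counts are disjoint and
#' `n_retained = n_input - sum(exclusions)`.
#'
#' @param cohort a cohort table.
#' @param flags data frame with columns `participant_id`, `antibiotics`,
#'   `intestinal_disease`, `prevalent_t2d` (logical or 0/1), covering every
#'   participant.
#'
#' @return A list with `cohort` (retained rows) and `report`, an
#'   `"exclusion_report"` with the disjoint counts.
#' @export
apply_exclusions <- function(cohort, flags) {
  need <- c("participant_id", "antibiotics", "intestinal_disease", "prevalent_t2d")
  if (!all(need %in% names(flags)))
    stop("flags must contain: ", paste(need, collapse = ", "))
  i <- match(cohort$participant_id, flags$participant_id)
  if (anyNA(i)) stop("flags do not cover all participants")
  ab  <- as.logical(flags$antibiotics[i])
  gi  <- as.logical(flags$intestinal_disease[i]) & !ab
  t2d <- as.logical(flags$prevalent_t2d[i]) & !ab & !as.logical(flags$intestinal_disease[i])
  keep <- !(ab | gi | t2d)
  report <- structure(list(
    n_input = nrow(cohort),
    n_excluded_antibiotics = sum(ab),
    n_excluded_intestinal_disease = sum(gi),
    n_excluded_prevalent_t2d = sum(t2d),
    n_retained = sum(keep)
  ), class = "exclusion_report")
  stopifnot(report$n_retained ==
    report$n_input - report$n_excluded_antibiotics -
    report$n_excluded_intestinal_disease - report$n_excluded_prevalent_t2d)
  glyco_log("exclusions", input = report$n_input, retained = report$n_retained)
  out <- cohort[keep, , drop = FALSE]
  class(out) <- class(cohort)
  list(cohort = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade\n")
  cat(sprintf("  input                %6d\n", x$n_input))
  cat(sprintf("  - antibiotics        %6d\n", x$n_excluded_antibiotics))
  cat(sprintf("  - intestinal disease %6d\n", x$n_excluded_intestinal_disease))
  cat(sprintf("  - prevalent diabetes %6d\n", x$n_excluded_prevalent_t2d))
  cat(sprintf("  retained             %6d\n", x$n_retained))
  invisible(x)
}

#' Filter genera by carriage prevalence
#'
#' A genus is kept iff it is detected (abundance strictly > 0) in at least
#' `threshold` of the participants; the boundary is inclusive.
#'
#' @param table a [genus_table()].
#' @param threshold fraction in (0, 1); default 0.10.
#' @return A list with `table` (retained genera) and `dropped` (character
#'   vector of removed genus names).
#' @export
filter_prevalence <- function(table, threshold = 0.10) {
  if (!nrow(table) || !ncol(table)) stop("empty abundance table")
  stopifnot(threshold > 0, threshold < 1)
  prev <- colMeans(table > 0)
  keep <- prev >= threshold
  glyco_log("prevalence_filter", kept = sum(keep), dropped = sum(!keep))
  list(table = genus_table(unclass(table)[, keep, drop = FALSE]),
       dropped = colnames(table)[!keep],
       prevalence = prev)
}

#' Impute missing covariates within region
#'
#' Continuous covariates are replaced by the mean of the observed values in
#' the participant's region; categorical covariates by the region's modal
#' category (ties broken by lexicographic order of the category labels).
#' Glycaemic outcome columns are never imputed.
#'
#' @param cohort a cohort table with a complete `region` column.
#' @return The cohort with no missing covariate values.
#' @export
impute_missing <- function(cohort) {
  if (anyNA(cohort$region)) stop("region column must be complete")
  outcome_cols <- c("fasting_glucose_0", "fasting_insulin_0", "hba1c_0",
                    "fasting_glucose_1", "fasting_insulin_1", "hba1c_1",
                    "diabetes_medication_1", "followup_years")
  cats <- setdiff(cohort_categorical_cols(), "region")
  maskable <- setdiff(cohort_required_cols(),
                      c("participant_id", "region", outcome_cols))
  for (nm in maskable) {
    miss <- is.na(cohort[[nm]])
    if (!any(miss)) next
    for (rg in unique(cohort$region[miss])) {
      sel <- miss & cohort$region == rg
      obs <- cohort[[nm]][!is.na(cohort[[nm]]) & cohort$region == rg]
      if (!length(obs))
        stop(sprintf("no observed values for '%s' in region '%s'", nm, rg))
      fill <- if (nm %in% cats) {
        tab <- table(obs)
        names(tab)[which(tab == max(tab))[1]]  # table() is label-sorted: lexicographic tie-break
      } else mean(obs)
      cohort[[nm]][sel] <- fill
    }
  }
  cohort
}

#' Homeostatic model assessment of insulin resistance
#'
#' `HOMA-IR = glucose [mmol/l] x insulin [uU/ml] / 22.5`. Insulin measured
#' in pmol/l is first converted to uU/ml by dividing by `conversion`
#' (default 6.945 pmol/l per uU/ml).
#'
#' @param glucose fasting glucose, mmol/l.
#' @param insulin fasting insulin, pmol/l.
#' @param conversion pmol/l per uU/ml; set to 1 if `insulin` is already in
#'   uU/ml.
#' @return HOMA-IR (unitless), vectorized.
#' @export
#' @examples
#' compute_homa_ir(5.2, 50.7)  # ~1.7 at cohort-mean inputs
compute_homa_ir <- function(glucose, insulin, conversion = 6.945) {
  if (any(glucose < 0, na.rm = TRUE) || any(insulin < 0, na.rm = TRUE))
    stop("glucose and insulin must be non-negative")
  stopifnot(conversion > 0)
  glucose * (insulin / conversion) / 22.5
}

#' Convert HbA1c from NGSP percent to IFCC mmol/mol
#'
#' Uses the NGSP master equation `(percent - 2.15) x 10.929`.
#'
#' @param hba1c_percent HbA1c in NGSP %.
#' @param digits decimals to report (default 1, the clinical convention).
#' @return HbA1c in mmol/mol.
#' @export
#' @examples
#' ngsp_to_ifcc(6.5)  # 47.5, the diabetes diagnostic threshold
ngsp_to_ifcc <- function(hba1c_percent, digits = 1) {
  if (any(hba1c_percent < 0, na.rm = TRUE)) stop("HbA1c must be non-negative")
  round((hba1c_percent - 2.15) * 10.929, digits)
}

#' Ascertain incident type 2 diabetes at follow-up
#'
#' A case is any participant with fasting glucose >= 7.0 mmol/l, or HbA1c
#' >= 47.5 mmol/mol (6.5%), or currently under diabetes medication.
#' Thresholds are inclusive. Inputs must be complete (run after imputation).
#'
#' @param glucose_1 follow-up fasting glucose, mmol/l.
#' @param hba1c_1 follow-up HbA1c, mmol/mol.
#' @param on_medication 0/1 diabetes-medication flag at follow-up.
#' @return Integer 0/1 vector.
#' @export
ascertain_t2d <- function(glucose_1, hba1c_1, on_medication) {
  if (anyNA(glucose_1) || anyNA(hba1c_1) || anyNA(on_medication))
    stop("ascertainment inputs must be complete (impute first)")
  as.integer(glucose_1 >= 7.0 | hba1c_1 >= 47.5 | on_medication > 0)
}

#' Standardize a numeric vector to z-scores
#'
#' Centres and scales by the analysis sample's mean and (sample) SD, and
#' returns the scaling constants so effects can be reported back on the
#' original scale.
#'
#' @param values numeric vector (NAs propagate).
#' @param name label used in the error message for a constant column.
#' @return List with `z`, `mean`, `sd`.
#' @export
standardize <- function(values, name = deparse(substitute(values))) {
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize constant column '", name, "'")
  list(z = (values - m) / s, mean = m, sd = s)
}

#' Staple-food preference from wheat and rice intake
#'
#' The staple ratio is wheat intake over rice intake; a ratio >= 1 marks a
#' wheat preference, otherwise rice. Zero rice with positive wheat gives an
#' infinite ratio (wheat preference); zero intake of both leaves the label
#' undefined (`NA`) and the participant flagged.
#'
#' @param wheat wheat intake, kg/day.
#' @param rice rice intake, kg/day.
#' @return List with `ratio`, `preference` (`"wheat"`/`"rice"`/`NA`) and
#'   `flagged` (logical, both intakes zero).
#' @export
staple_ratio <- function(wheat, rice) {
  if (any(wheat < 0, na.rm = TRUE) || any(rice < 0, na.rm = TRUE))
    stop("intakes must be non-negative")
  flagged <- wheat == 0 & rice == 0
  ratio <- ifelse(flagged, NA_real_, wheat / rice)
  pref <- ifelse(flagged, NA_character_, ifelse(ratio >= 1, "wheat", "rice"))
  if (any(flagged, na.rm = TRUE))
    glyco_log("staple_ratio", undefined = sum(flagged, na.rm = TRUE))
  list(ratio = ratio, preference = pref, flagged = flagged)
}

#' Derive HOMA-IR columns on a cohort table
#'
#' Adds `homa_ir_0` and `homa_ir_1` from the stored glucose/insulin panels.
#'
#' @param cohort a cohort table.
#' @param conversion pmol/l per uU/ml (see [compute_homa_ir()]).
#' @return The cohort with the two derived columns.
#' @export
add_homa_ir <- function(cohort, conversion = 6.945) {
  cohort$homa_ir_0 <- compute_homa_ir(cohort$fasting_glucose_0,
                                      cohort$fasting_insulin_0, conversion)
  cohort$homa_ir_1 <- compute_homa_ir(cohort$fasting_glucose_1,
                                      cohort$fasting_insulin_1, conversion)
  cohort
}
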