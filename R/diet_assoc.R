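# Cross-sectional diet/lifestyle associations with the glycaemic
# trait-related genera and the HMI, and trait regressions with/without HMI.

.diet_factors <- c("wheat", "rice", "staple_ratio", "fruit", "vegetable",
                   "nuts", "pork", "poultry", "milk", "egg", "fish",
                   "alcohol", "smoking", "physical_activity")
.diet_binary <- c("alcohol", "smoking")
.diet_covariates <- c("age", "sex", "bmi", "energy", "income", "marital",
                      "education", "residence", "urbanisation_index",
                      "animal_oil", "vegetable_oil")

#' Standardized panel-genus outcomes plus HMI
#'
#' Builds the outcome matrix for the diet scans: a z-scored column per panel
#' genus plus `HMI` (z-scored index), aligned to the cohort rows.
#'
#' @param abundance a [genus_table()].
#' @param cohort a cohort table.
#' @param panel a [build_signed_panel()] result.
#' @param threshold carriage threshold for the HMI (default 0).
#' @return Numeric matrix, one column per panel genus plus `"HMI"`.
#' @export
panel_outcomes <- function(abundance, cohort, panel, threshold = 0) {
  ab <- unclass(abundance)[match(cohort$participant_id, rownames(abundance)), ,
                           drop = FALSE]
  if (anyNA(ab)) stop("abundance table does not cover the cohort")
  cols <- intersect(panel$genus, colnames(ab))
  z <- vapply(cols, function(g) standardize(ab[, g], g)$z, numeric(nrow(ab)))
  hmi <- compute_hmi(ab, panel, threshold)
  cbind(z, HMI = hmi$hmi_z)
}

# assemble the factor columns (continuous ones standardized) and the
# per-factor adjustment sets under the wheat/rice/ratio exclusion rule
.diet_design <- function(cohort, factors) {
  vals <- list()
  for (f in factors) {
    v <- if (f == "staple_ratio") staple_ratio(cohort$wheat, cohort$rice)$ratio
         else cohort[[f]]
    if (!(f %in% .diet_binary)) {
      ok <- is.finite(v)
      v[!ok] <- NA
      v <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    }
    vals[[f]] <- v
  }
  # collinearity guard: later factor of an |r| > 0.99 pair is dropped
  dropped <- character()
  cont <- setdiff(factors, .diet_binary)
  for (i in seq_along(cont)) for (j in seq_len(i - 1)) {
    a <- cont[j]; b <- cont[i]
    if (a %in% dropped || b %in% dropped) next
    r <- suppressWarnings(stats::cor(vals[[a]], vals[[b]],
                                     use = "pairwise.complete.obs"))
    if (is.finite(r) && abs(r) > 0.99) {
      dropped <- c(dropped, b)
      glyco_log("diet_assoc", dropped = b, reason = paste("collinear with", a))
    }
  }
  factors <- setdiff(factors, dropped)
  adj <- lapply(factors, function(f) {
    others <- setdiff(factors, f)
    if (f == "staple_ratio") others <- setdiff(others, c("wheat", "rice"))
    if (f %in% c("wheat", "rice")) others <- setdiff(others, "staple_ratio")
    others
  })
  names(adj) <- factors
  list(values = vals, factors = factors, adjust = adj, dropped = dropped)
}

#' Diet/lifestyle association scan over panel genera and the HMI
#'
#' For each tested dietary or lifestyle factor and each outcome column
#' (panel-genus z-scores and the HMI), fits a linear regression of the
#' outcome on the factor (continuous factors per SD, binary factors per
#' category), mutually adjusted for the other tested factors and for the
#' confounder set (age, sex, BMI, energy, income, marital status, education,
#' residence, urbanisation index, animal and vegetable oil). Wheat, rice and
#' the wheat/rice staple ratio are never co-included in one model. BH FDR
#' is applied over the whole factor x outcome grid.
#'
#' @param cohort an imputed cohort table.
#' @param outcomes matrix from [panel_outcomes()].
#' @param factors factors to test (default: the 14 standard ones).
#' @return Data frame: `factor`, `outcome`, `beta`, `se`, `p`, `q`,
#'   `significant` (q < 0.05), `direction`.
#' @export
diet_genus_scan <- function(cohort, outcomes,
                            factors = .diet_factors) {
  des <- .diet_design(cohort, factors)
  covs <- cohort[, .diet_covariates, drop = FALSE]
  rows <- list()
  for (f in des$factors) {
    X <- data.frame(.f = des$values[[f]], des$values[des$adjust[[f]]],
                    covs, check.names = FALSE)
    for (oc in colnames(outcomes)) {
      df <- data.frame(.y = outcomes[, oc], X, check.names = FALSE)
      df <- df[stats::complete.cases(df), , drop = FALSE]
      fit <- stats::lm(.y ~ ., data = df)
      cf <- summary(fit)$coefficients
      rows[[length(rows) + 1]] <- data.frame(
        factor = f, outcome = oc,
        beta = cf[".f", "Estimate"], se = cf[".f", "Std. Error"],
        p = cf[".f", "Pr(>|t|)"], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < 0.05
  res$direction <- ifelse(res$beta > 0, "positive", "inverse")
  res
}

#' Dietary fibre association scan
#'
#' Same regression form as [diet_genus_scan()] but with fibre intake (per
#' SD) as the sole dietary exposure alongside the standard confounders.
#'
#' @inheritParams diet_genus_scan
#' @return Data frame with the same schema as [diet_genus_scan()].
#' @export
fibre_scan <- function(cohort, outcomes) {
  fz <- standardize(cohort$fibre, "fibre")$z
  covs <- cohort[, .diet_covariates, drop = FALSE]
  rows <- list()
  for (oc in colnames(outcomes)) {
    df <- data.frame(.y = outcomes[, oc], .f = fz, covs, check.names = FALSE)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    fit <- stats::lm(.y ~ ., data = df)
    cf <- summary(fit)$coefficients
    rows[[length(rows) + 1]] <- data.frame(
      factor = "fibre", outcome = oc,
      beta = cf[".f", "Estimate"], se = cf[".f", "Std. Error"],
      p = cf[".f", "Pr(>|t|)"], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < 0.05
  res$direction <- ifelse(res$beta > 0, "positive", "inverse")
  res
}

#' Food-group to glycaemic-trait regressions with and without the HMI
#'
#' Fits, per trait, two linear models of the follow-up trait on the 12 food
#' groups plus confounders, differing only by inclusion of the HMI z-score,
#' and returns the paired food-group coefficients. Attenuation of a food
#' coefficient when the HMI enters indicates mediation through the panel
#' genera.
#'
#' @param cohort an imputed cohort table with follow-up traits.
#' @param trait one of `"fasting_glucose"`, `"fasting_insulin"`, `"hba1c"`,
#'   `"homa_ir"` (follow-up value; HOMA-IR requires [add_homa_ir()]).
#' @param hmi_z standardized HMI aligned to the cohort rows.
#' @param foods food-group columns (default the 12 intakes).
#' @return Data frame: `food`, `beta_without`, `se_without`, `beta_with`,
#'   `se_with`.
#' @export
trait_regression_with_without_hmi <- function(cohort, trait, hmi_z,
    foods = c("rice", "wheat", "fruit", "vegetable", "nuts", "pork",
              "poultry", "milk", "egg", "fish", "vegetable_oil", "animal_oil")) {
  y <- cohort[[paste0(trait, "_1")]]
  if (is.null(y)) stop("unknown trait: ", trait)
  covs <- c("age", "sex", "bmi", "energy", "income", "marital", "education",
            "residence", "urbanisation_index")
  base <- data.frame(.y = y, cohort[, c(foods, covs), drop = FALSE],
                     check.names = FALSE)
  with_h <- data.frame(base, .hmi = hmi_z, check.names = FALSE)
  f0 <- stats::lm(.y ~ ., data = base[stats::complete.cases(base), ])
  f1 <- stats::lm(.y ~ ., data = with_h[stats::complete.cases(with_h), ])
  c0 <- summary(f0)$coefficients
  c1 <- summary(f1)$coefficients
  data.frame(food = foods,
             beta_without = c0[foods, "Estimate"],
             se_without = c0[foods, "Std. Error"],
             beta_with = c1[foods, "Estimate"],
             se_with = c1[foods, "Std. Error"],
             row.names = NULL, stringsAsFactors = FALSE)
}
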