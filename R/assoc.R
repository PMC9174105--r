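# Region-stratified linear mixed-effects genus-trait association,
# DerSimonian-Laird random-effects pooling, BH FDR, signed-panel extraction.

.assoc_traits <- c("fasting_glucose", "fasting_insulin", "hba1c", "homa_ir")

.assoc_covariates <- function(adjust_bmi = TRUE, adjust_diet = FALSE) {
  covs <- c("age", "sex", "income", "marital", "education", "residence",
            "urbanisation_index", "energy", "alcohol", "smoking",
            "physical_activity")
  if (adjust_bmi) covs <- c(covs, "bmi")
  if (adjust_diet)
    covs <- c(covs, "rice", "wheat", "fruit", "vegetable", "nuts", "pork",
              "poultry", "milk", "egg", "fish", "vegetable_oil", "animal_oil")
  covs
}

#' Fit the within-region mixed model for one genus and trait
#'
#' Linear mixed-effects model of the standardized follow-up trait on the
#' standardized genus abundance, adjusted for the raw baseline trait and the
#' covariates, with a random intercept and random genus slope by province
#' (REML). If the random-effects fit is singular or fails to converge, the
#' model is refit with a random intercept only and the fallback is recorded.
#'
#' @param genus_z standardized genus abundance (z-scores in the analysis
#'   sample).
#' @param trait_1_z standardized follow-up trait.
#' @param trait_0 raw baseline trait.
#' @param covariates data frame of adjustment covariates.
#' @param province grouping factor (>= 2 provinces).
#' @return List with `beta`, `se` (per-SD fixed effect for the genus) and
#'   `fallback` (`"none"` or `"intercept_only"`).
#' @export
fit_region_model <- function(genus_z, trait_1_z, trait_0, covariates, province) {
  df <- data.frame(.y = trait_1_z, .g = genus_z, .t0 = trait_0,
                   covariates, .prov = as.factor(province),
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 30)
    stop("refusing to fit: only ", nrow(df), " usable observations (< 30)")
  if (nlevels(droplevels(df$.prov)) < 2)
    stop("need >= 2 provinces within the region")
  covs <- paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(action = "ignore",
                                                                tol = 1e-4))
  fit_one <- function(re_term) {
    f <- stats::as.formula(paste(".y ~ .g + .t0 +", covs, "+", re_term))
    warned <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(f, data = df, REML = TRUE, control = ctrl),
        warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }
      ),
      error = function(e) NULL
    )
    list(fit = fit, warned = warned)
  }
  r <- fit_one("(1 + .g | .prov)")
  fallback <- "none"
  if (is.null(r$fit) || r$warned || lme4::isSingular(r$fit, tol = 1e-4)) {
    r <- fit_one("(1 | .prov)")
    fallback <- "intercept_only"
    if (is.null(r$fit)) stop("mixed model failed to fit in both configurations")
  }
  cf <- summary(r$fit)$coefficients
  list(beta = cf[".g", "Estimate"], se = cf[".g", "Std. Error"],
       fallback = fallback)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-stratum estimates with inverse-variance weights and the
#' method-of-moments between-stratum variance:
#' `w = 1/se^2`, `Q = sum w (b - b_fixed)^2`,
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`,
#' `w* = 1/(se^2 + tau2)`, pooled beta `sum(w* b)/sum(w*)`,
#' pooled SE `sqrt(1/sum(w*))`, two-sided normal p value.
#'
#' @param beta vector of per-stratum estimates (typically North and South).
#' @param se vector of their standard errors (> 0).
#' @return List with `beta_pooled`, `se_pooled`, `tau2`, `p`.
#' @export
#' @examples
#' meta_combine(c(1, 3), c(1, 1))  # pooled 2, tau2 = 1, se = 1
meta_combine <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 2, all(se > 0))
  w <- 1 / se^2
  b_fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fixed)^2)
  k <- length(beta)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  beta_pooled <- sum(ws * beta) / sum(ws)
  se_pooled <- sqrt(1 / sum(ws))
  list(beta_pooled = beta_pooled, se_pooled = se_pooled, tau2 = tau2,
       p = 2 * stats::pnorm(-abs(beta_pooled / se_pooled)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} p_(j) m / j`, capped at 1),
#' mapped back to the input order.
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @return q values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Genus-by-trait association scan with regional meta-analysis
#'
#' For every retained genus and each of the four glycaemic traits (fasting
#' glucose, fasting insulin, HbA1c, HOMA-IR), fits the within-region mixed
#' model ([fit_region_model()]) independently in the North and South strata
#' (genus and follow-up trait standardized within each region's analysis
#' sample), pools the two estimates by DerSimonian-Laird random-effects
#' meta-analysis, and applies BH FDR across the whole scan. Three variants
#' are available: primary (BMI-adjusted), with dietary covariates added, and
#' without BMI.
#'
#' @param abundance a [genus_table()] (already prevalence-filtered).
#' @param cohort a cohort table (imputed); participants without follow-up
#'   data are dropped.
#' @param config a [run_config()].
#' @param adjust_bmi include BMI among covariates (default `TRUE`).
#' @param adjust_diet add the 12 food-group intakes (default `FALSE`).
#' @return A data frame of class `"assoc_scan"`, one row per genus x trait:
#'   per-region betas/SEs and fallback flags, pooled beta/SE, `tau2`,
#'   `p_pooled`, `q_bh`, and the variant flags.
#' @export
run_association_scan <- function(abundance, cohort, config = run_config(),
                                 adjust_bmi = TRUE, adjust_diet = FALSE) {
  cohort <- add_homa_ir(cohort, config$insulin_conversion)
  keep <- !is.na(cohort$fasting_glucose_1) & !is.na(cohort$fasting_insulin_1) &
    !is.na(cohort$hba1c_1)
  cohort <- cohort[keep, , drop = FALSE]
  ab <- unclass(abundance)[match(cohort$participant_id, rownames(abundance)), ,
                           drop = FALSE]
  if (anyNA(ab)) stop("abundance table does not cover the analysis sample")
  covs <- .assoc_covariates(adjust_bmi, adjust_diet)
  genera <- colnames(ab)
  out <- list()
  for (rg in c("North", "South")) {
    sel <- cohort$region == rg
    co <- cohort[sel, , drop = FALSE]
    abr <- ab[sel, , drop = FALSE]
    if (config$clr_transform) {
      pseudo <- min(abr[abr > 0]) / 2
      labr <- log(abr + pseudo)
      abr <- labr - rowMeans(labr)
    }
    cov_df <- co[, covs, drop = FALSE]
    for (trait in .assoc_traits) {
      y1 <- co[[paste0(trait, "_1")]]
      y0 <- co[[paste0(trait, "_0")]]
      y1z <- standardize(y1, trait)$z
      for (g in genera) {
        v <- abr[, g]
        if (stats::sd(v) == 0) {
          glyco_log("assoc", region = rg, genus = g, reason = "constant, skipped")
          next
        }
        gz <- standardize(v, g)$z
        rec <- tryCatch(fit_region_model(gz, y1z, y0, cov_df, co$province),
                        error = function(e) NULL)
        if (is.null(rec)) {
          glyco_log("assoc", region = rg, genus = g, trait = trait,
                    reason = "fit failed, dropped from pooling")
          next
        }
        out[[length(out) + 1]] <- data.frame(
          genus = g, trait = trait, region = rg,
          beta = rec$beta, se = rec$se, fallback = rec$fallback,
          stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, out)
  recs <- list()
  for (g in unique(long$genus)) for (trait in .assoc_traits) {
    n_row <- long[long$genus == g & long$trait == trait & long$region == "North", ]
    s_row <- long[long$genus == g & long$trait == trait & long$region == "South", ]
    if (nrow(n_row) != 1 || nrow(s_row) != 1) next  # failed in one region
    mc <- meta_combine(c(n_row$beta, s_row$beta), c(n_row$se, s_row$se))
    recs[[length(recs) + 1]] <- data.frame(
      genus = g, trait = trait,
      beta_north = n_row$beta, se_north = n_row$se,
      beta_south = s_row$beta, se_south = s_row$se,
      fallback_north = n_row$fallback, fallback_south = s_row$fallback,
      beta_pooled = mc$beta_pooled, se_pooled = mc$se_pooled,
      tau2 = mc$tau2, p_pooled = mc$p,
      adjusted_for_bmi = adjust_bmi, adjusted_for_diet = adjust_diet,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, recs)
  res$q_bh <- bh_fdr(res$p_pooled)
  class(res) <- c("assoc_scan", "data.frame")
  res
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: %d genus x trait records (%d genera, %s)\n",
              nrow(x), length(unique(x$genus)),
              if (x$adjusted_for_bmi[1]) "BMI-adjusted" else "no BMI adjustment"))
  cat(sprintf("  p < 0.05: %d; q < 0.05: %d\n",
              sum(x$p_pooled < 0.05), sum(x$q_bh < 0.05)))
  invisible(x)
}

#' Extract the signed genus panel for the Healthy Microbiome Index
#'
#' A genus enters the panel iff its pooled p value is below `alpha` for at
#' least one trait. Its direction is the sign of the minimum-p admitting
#' association: favourable for a negative pooled beta (lower glycaemic
#' values), harmful for a positive one. A genus whose minimum-p admitting
#' associations carry conflicting signs is excluded with a warning.
#'
#' @param records an `"assoc_scan"` (primary, BMI-adjusted variant).
#' @param alpha admission threshold on the pooled p value (default 0.05).
#' @return A data frame of class `"signed_panel"` with columns `genus`,
#'   `direction`; attribute `"provenance"` lists every admitting
#'   trait/beta/p per genus.
#' @export
build_signed_panel <- function(records, alpha = 0.05) {
  prov <- list()
  entries <- list()
  for (g in unique(records$genus)) {
    sub <- records[records$genus == g & records$p_pooled < alpha, , drop = FALSE]
    if (!nrow(sub)) next
    mn <- min(sub$p_pooled)
    top <- sub[sub$p_pooled == mn, , drop = FALSE]
    signs <- unique(sign(top$beta_pooled))
    if (length(signs) > 1) {
      warning("genus '", g, "' excluded: conflicting directions at minimum p")
      next
    }
    entries[[length(entries) + 1]] <- data.frame(
      genus = g,
      direction = if (signs < 0) "favourable" else "harmful",
      stringsAsFactors = FALSE)
    prov[[g]] <- sub[, c("trait", "beta_pooled", "p_pooled")]
  }
  panel <- if (length(entries)) do.call(rbind, entries) else
    data.frame(genus = character(), direction = character())
  attr(panel, "provenance") <- prov
  class(panel) <- c("signed_panel", "data.frame")
  panel
}

#' @export
print.signed_panel <- function(x, ...) {
  cat(sprintf("signed_panel: %d genera (%d favourable, %d harmful)\n",
              nrow(x), sum(x$direction == "favourable"),
              sum(x$direction == "harmful")))
  invisible(x)
}
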