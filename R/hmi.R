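# Healthy Microbiome Index: additive carriage score over the signed panel,
# and its Poisson risk model for incident type 2 diabetes.

#' Genus carriage indicator
#'
#' A genus is carried when its relative abundance exceeds the detection
#' threshold (default 0: strictly positive abundance).
#'
#' @param abundance relative abundance (vector or matrix).
#' @param threshold detection threshold (default 0).
#' @return Integer 0/1 of the same shape.
#' @export
carries <- function(abundance, threshold = 0) {
  if (any(abundance < 0, na.rm = TRUE)) stop("abundance must be non-negative")
  (abundance > threshold) * 1L
}

# internal: HMI counts for a plain abundance matrix and a panel data frame;
# panel genera absent from the table contribute as never-carried
.hmi_count <- function(ab, panel, threshold = 0) {
  if (!nrow(panel)) stop("empty signed panel")
  miss <- setdiff(panel$genus, colnames(ab))
  if (length(miss)) {
    zf <- matrix(0, nrow(ab), length(miss),
                 dimnames = list(rownames(ab), miss))
    ab <- cbind(ab, zf)
  }
  car <- carries(ab[, panel$genus, drop = FALSE], threshold)
  fav <- panel$direction == "favourable"
  g <- car
  g[, !fav] <- 1L - car[, !fav, drop = FALSE]
  as.integer(rowSums(g))
}

#' Compute the Healthy Microbiome Index
#'
#' `HMI_i = sum_j g_ij` over the panel genera, where `g_ij = 1` when
#' participant i carries a favourable genus j or does not carry a harmful
#' one, else 0. The z-score is taken over the rows supplied, so pass the
#' analysis sample (typically the followed participants) to standardize on
#' the modelled population.
#'
#' @param abundance a [genus_table()] or plain abundance matrix; panel
#'   genera absent from the table are zero-filled.
#' @param panel a [build_signed_panel()] result or any data frame with
#'   `genus` and `direction` in `{favourable, harmful}`.
#' @param threshold carriage detection threshold (default 0).
#' @return Data frame with `participant_id`, `hmi` (integer in `[0, m]`) and
#'   `hmi_z`.
#' @export
compute_hmi <- function(abundance, panel, threshold = 0) {
  ab <- unclass(abundance)
  hmi <- .hmi_count(ab, panel, threshold)
  s <- stats::sd(hmi)
  data.frame(participant_id = rownames(ab), hmi = hmi,
             hmi_z = if (s > 0) (hmi - mean(hmi)) / s else rep(NA_real_, length(hmi)),
             stringsAsFactors = FALSE)
}

#' Poisson risk model for incident diabetes per SD of HMI
#'
#' Modified Poisson regression on the binary incident-diabetes outcome:
#' log-link Poisson fit with robust (HC0 sandwich) standard errors for the
#' Wald 95% CI, so the exponentiated HMI coefficient is a risk ratio per SD.
#'
#' @param hmi_z standardized HMI.
#' @param incident_t2d 0/1 outcome.
#' @param covariates data frame of adjustment covariates (may have zero
#'   columns for an unadjusted fit).
#' @param robust use sandwich standard errors (default `TRUE`); otherwise
#'   model-based SEs.
#' @param subgroup label stored on the estimate (default `"overall"`).
#' @return A list of class `"risk_estimate"`: `rr`, `ci_low`, `ci_high`,
#'   `log_rr`, `se`, `p`, `n`, `n_events`, `subgroup`, `flagged`
#'   (non-convergence / near-separation diagnostic) and `fit` (the
#'   underlying `glm`).
#' @export
hmi_risk_model <- function(hmi_z, incident_t2d, covariates = NULL,
                           robust = TRUE, subgroup = "overall") {
  if (!all(incident_t2d %in% c(0, 1))) stop("outcome must be binary 0/1")
  df <- data.frame(.y = incident_t2d, .h = hmi_z)
  if (!is.null(covariates) && ncol(covariates)) df <- data.frame(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_events <- sum(df$.y)
  if (n_events == 0) stop("zero events: cannot fit risk model")
  if (n_events < 10) stop("refusing to fit: only ", n_events, " events (< 10)")
  near_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::poisson(link = "log")),
    warning = function(w) {
      near_sep <<- TRUE  # e.g. fitted rates numerically zero
      invokeRestart("muffleWarning")
    })
  V <- if (robust) sandwich::vcovHC(fit, type = "HC0") else stats::vcov(fit)
  b <- unname(stats::coef(fit)[".h"])
  se <- unname(sqrt(V[".h", ".h"]))
  flagged <- !fit$converged || abs(b) > 10 || near_sep
  est <- list(rr = exp(b), ci_low = exp(b - 1.959964 * se),
              ci_high = exp(b + 1.959964 * se),
              log_rr = b, se = se,
              p = 2 * stats::pnorm(-abs(b / se)),
              n = nrow(df), n_events = n_events,
              subgroup = subgroup, flagged = flagged, fit = fit)
  class(est) <- "risk_estimate"
  est
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("%s: RR per SD of HMI %.3f (95%% CI %.3f, %.3f); n=%d, events=%d%s\n",
              x$subgroup, x$rr, x$ci_low, x$ci_high, x$n, x$n_events,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Subgroup analysis of the HMI risk model
#'
#' Refits [hmi_risk_model()] within each level of each stratifying variable,
#' removing that variable from the covariate set for its own strata. Strata
#' with too few events are skipped with a logged reason. Default strata:
#' region, age group (< / >= 50 years), sex, BMI level (< / >= 24 kg/m2,
#' the Chinese overweight threshold) and residence (urban/rural).
#'
#' @param df data frame holding `hmi_z`, `incident_t2d`, the covariates and
#'   the stratifying columns.
#' @param covariate_names covariate columns for the overall model.
#' @param strata named list mapping stratum label -> list(values = factor of
#'   stratum membership, drop = covariate to remove). `NULL` builds the
#'   default five stratifications.
#' @return Data frame, one row per stratum level, with the risk-estimate
#'   fields and a `skipped` reason column (`NA` when fitted).
#' @export
subgroup_scan <- function(df, covariate_names, strata = NULL) {
  if (is.null(strata)) {
    strata <- list(
      region = list(values = df$region, drop = "region"),
      age_group = list(values = ifelse(df$age < 50, "age<50", "age>=50"),
                       drop = "age"),
      sex = list(values = df$sex, drop = "sex"),
      bmi_level = list(values = ifelse(df$bmi < 24, "bmi<24", "bmi>=24"),
                       drop = "bmi"),
      urbanisation = list(values = df$residence, drop = "residence")
    )
  }
  rows <- list()
  for (sname in names(strata)) {
    sp <- strata[[sname]]
    covs <- setdiff(covariate_names, sp$drop)
    for (lev in sort(unique(stats::na.omit(sp$values)))) {
      sel <- !is.na(sp$values) & sp$values == lev
      lab <- paste0(sname, ":", lev)
      est <- tryCatch(
        hmi_risk_model(df$hmi_z[sel], df$incident_t2d[sel],
                       df[sel, covs, drop = FALSE], subgroup = lab),
        error = function(e) e$message)
      if (is.character(est)) {
        glyco_log("subgroup", stratum = lab, reason = est)
        rows[[length(rows) + 1]] <- data.frame(
          subgroup = lab, rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n = sum(sel), n_events = sum(df$incident_t2d[sel], na.rm = TRUE),
          skipped = est, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          subgroup = lab, rr = est$rr, ci_low = est$ci_low,
          ci_high = est$ci_high, n = est$n, n_events = est$n_events,
          skipped = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
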