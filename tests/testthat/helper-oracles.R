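# Independent brute-force oracles used for dual-route checks. These stay
# deliberately naive and separate from the package implementations.

# step-up FDR straight from the definition: q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Bray-Curtis by double loop over the textbook formula
bray_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}

# DerSimonian-Laird by direct evaluation of the moment equations
dl_oracle <- function(beta, se) {
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bf)^2)
  tau2 <- max(0, (Q - (length(beta) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(beta = sum(ws * beta) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# AUC as the Mann-Whitney U statistic over all case/control pairs
auc_mwu_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  u <- 0
  for (a in pos) u <- u + sum(a > neg) + 0.5 * sum(a == neg)
  u / (length(pos) * length(neg))
}

# small in-memory cohorts shared across tests (built once per run)
local_sim_cache <- new.env()
cached_sim <- function(key, builder) {
  if (is.null(local_sim_cache[[key]])) local_sim_cache[[key]] <- builder()
  local_sim_cache[[key]]
}

# minimal valid cohort data frame for I/O and preprocessing tests
tiny_cohort_df <- function(n = 6) {
  prov <- rep(c("P01", "P02"), length.out = n)
  data.frame(
    participant_id = sprintf("S%03d", seq_len(n)),
    province = prov,
    region = ifelse(prov == "P01", "North", "South"),
    age = seq(40, 60, length.out = n), sex = rep(c("female", "male"), length.out = n),
    bmi = seq(21, 27, length.out = n), income = rep(7, n),
    marital = rep("married", n), education = rep("middle_or_lower", n),
    residence = rep(c("urban", "rural"), length.out = n),
    urbanisation_index = rep(70, n), energy = rep(8300, n),
    smoking = rep(0, n), alcohol = rep(0, n), physical_activity = rep(140, n),
    rice = rep(0.25, n), wheat = rep(0.1, n), fruit = rep(0.04, n),
    vegetable = rep(0.3, n), nuts = rep(0.003, n), pork = rep(0.08, n),
    poultry = rep(0.02, n), milk = rep(0.01, n), egg = rep(0.03, n),
    fish = rep(0.03, n), vegetable_oil = rep(0.02, n), animal_oil = rep(0.004, n),
    fibre = rep(11, n),
    fasting_glucose_0 = rep(5.2, n), fasting_insulin_0 = rep(50, n),
    hba1c_0 = rep(36, n),
    fasting_glucose_1 = rep(5.3, n), fasting_insulin_1 = rep(52, n),
    hba1c_1 = rep(37, n),
    diabetes_medication_1 = rep(0, n), followup_years = rep(3, n),
    stringsAsFactors = FALSE
  )
}
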