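test_that("DerSimonian-Laird pooling matches closed forms and metafor", {
  # homogeneous case collapses to fixed-effect inverse-variance pooling
  h <- meta_combine(c(2, 2), c(1, 1))
  expect_equal(h$beta_pooled, 2)
  expect_equal(h$tau2, 0)
  expect_equal(h$se_pooled, 1 / sqrt(2))
  # heterogeneous hand case: Q = 2, tau2 = 1, pooled 2, se 1
  g <- meta_combine(c(1, 3), c(1, 1))
  expect_equal(g$beta_pooled, 2)
  expect_equal(g$tau2, 1)
  expect_equal(g$se_pooled, 1)
  # order symmetry
  s <- meta_combine(c(3, 1), c(1, 1))
  expect_equal(s[c("beta_pooled", "se_pooled", "tau2", "p")],
               g[c("beta_pooled", "se_pooled", "tau2", "p")])
  # random cases against the moment-equation oracle and metafor
  set.seed(8)
  for (i in 1:20) {
    b <- rnorm(2)
    se <- runif(2, 0.2, 2)
    got <- meta_combine(b, se)
    ora <- dl_oracle(b, se)
    expect_equal(got$beta_pooled, ora$beta, tolerance = 1e-12)
    expect_equal(got$tau2, ora$tau2, tolerance = 1e-12)
    if (requireNamespace("metafor", quietly = TRUE)) {
      mf <- metafor::rma(yi = b, sei = se, method = "DL")
      expect_equal(got$beta_pooled, as.numeric(mf$beta), tolerance = 1e-8)
      expect_equal(got$tau2, mf$tau2, tolerance = 1e-8)
    }
  }
  # tau2 = 0 equals the fixed-effect closed form
  b <- c(0.5, 0.55); se <- c(0.3, 0.4)
  got <- meta_combine(b, se)
  w <- 1 / se^2
  expect_equal(got$beta_pooled, sum(w * b) / sum(w))
  expect_error(meta_combine(1, 1), "length")
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

# build one region's data with a known per-SD genus effect and province
# random structure; the oracle is the generating equation itself
make_region_data <- function(n, n_prov, beta, sd_intercept = 0.2,
                             sd_slope = 0, seed = 1) {
  set.seed(seed)
  prov <- sample(sprintf("P%02d", 1:n_prov), n, replace = TRUE)
  g <- rnorm(n)
  u0 <- rnorm(n_prov, 0, sd_intercept)
  u1 <- if (sd_slope > 0) rnorm(n_prov, 0, sd_slope) else rep(0, n_prov)
  covs <- data.frame(age = rnorm(n, 50, 10), bmi = rnorm(n, 24, 3))
  t0 <- rnorm(n, 5.2, 0.6)
  noise_sd <- sqrt(max(0.1, 1 - beta^2 - 0.3^2 - sd_intercept^2))
  y <- 0.3 * scale(t0)[, 1] + (beta + u1[match(prov, sprintf("P%02d", 1:n_prov))]) * g +
    u0[match(prov, sprintf("P%02d", 1:n_prov))] + rnorm(n, 0, noise_sd)
  list(g = g, y_raw = y, t0 = t0, covs = covs, prov = prov)
}

test_that("the region mixed model recovers a planted per-SD effect", {
  hits <- 0
  n_seed <- 20
  for (s in seq_len(n_seed)) {
    d <- make_region_data(1200, 8, beta = 0.10, seed = s)
    fit <- fit_region_model(scale(d$g)[, 1], scale(d$y_raw)[, 1], d$t0,
                            d$covs, d$prov)
    # the standardization of y shrinks the planted slope by sd(y); undo it
    target <- 0.10 / sd(d$y_raw)
    if (abs(fit$beta - target) <= 1.96 * fit$se) hits <- hits + 1
  }
  expect_gte(hits / n_seed, 0.9)
})

test_that("a null genus stays within three standard errors", {
  ok <- 0
  for (s in 1:15) {
    d <- make_region_data(800, 6, beta = 0, seed = 100 + s)
    fit <- fit_region_model(scale(d$g)[, 1], scale(d$y_raw)[, 1], d$t0,
                            d$covs, d$prov)
    if (abs(fit$beta) < 3 * fit$se) ok <- ok + 1
  }
  expect_gte(ok, 14)  # |z| > 3 should essentially never occur
})

test_that("with no province variance the slope matches ordinary least squares", {
  d <- make_region_data(1500, 6, beta = 0.12, sd_intercept = 0, seed = 7)
  gz <- scale(d$g)[, 1]
  yz <- scale(d$y_raw)[, 1]
  fit <- fit_region_model(gz, yz, d$t0, d$covs, d$prov)
  ols <- coef(lm(yz ~ gz + d$t0 + age + bmi, data = d$covs))["gz"]
  expect_lt(abs(fit$beta - unname(ols)), 1e-3)
})

test_that("planted random-slope heterogeneity keeps the full model", {
  d <- make_region_data(3000, 10, beta = 0.15, sd_intercept = 0.25,
                        sd_slope = 0.15, seed = 3)
  fit <- fit_region_model(scale(d$g)[, 1], scale(d$y_raw)[, 1], d$t0,
                          d$covs, d$prov)
  expect_identical(fit$fallback, "none")
  expect_equal(fit$beta, 0.15 / sd(d$y_raw), tolerance = 4 * fit$se)
})

test_that("the mixed model refuses underpowered fits", {
  d <- make_region_data(40, 4, beta = 0, seed = 1)
  d$covs$age[1:15] <- NA
  expect_error(fit_region_model(d$g, d$y_raw, d$t0, d$covs, d$prov), "< 30")
})

test_that("effect estimates are invariant to affine rescaling of abundance", {
  d <- make_region_data(800, 6, beta = 0.1, seed = 5)
  yz <- scale(d$y_raw)[, 1]
  f1 <- fit_region_model(standardize(d$g)$z, yz, d$t0, d$covs, d$prov)
  f2 <- fit_region_model(standardize(1e-4 * d$g + 0.02)$z, yz, d$t0, d$covs, d$prov)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("signed panel admission, direction and conflicts follow the rule", {
  rec <- function(genus, trait, beta, p) {
    data.frame(genus = genus, trait = trait, beta_pooled = beta, p_pooled = p,
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("A", "fasting_glucose", -0.1, 0.01),   # favourable via glucose
    rec("A", "hba1c", 0.02, 0.6),
    rec("B", "fasting_glucose", 0.05, 0.2),    # nothing under alpha
    rec("B", "homa_ir", 0.08, 0.3),
    rec("C", "fasting_glucose", 0.1, 0.001),   # harmful on two traits
    rec("C", "fasting_insulin", 0.08, 0.04),
    rec("D", "fasting_glucose", 0.1, 0.02),    # conflicting at identical min p
    rec("D", "hba1c", -0.1, 0.02)
  )
  expect_warning(panel <- build_signed_panel(records, alpha = 0.05),
                 "conflicting")
  expect_identical(panel$direction[panel$genus == "A"], "favourable")
  expect_false("B" %in% panel$genus)
  expect_identical(panel$direction[panel$genus == "C"], "harmful")
  expect_false("D" %in% panel$genus)
  prov <- attr(panel, "provenance")
  expect_equal(nrow(prov[["C"]]), 2)           # both admitting traits listed
})
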