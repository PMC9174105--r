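test_that("exclusion cascade counts sequentially and reconciles", {
  sim <- cached_sim("tiny3248", function() {
    generate_cohort(n_participants = 3248, n_provinces = 4,
                    truth = synthetic_truth(n_genera = 8), seed = 42)
  })
  flags <- make_exclusion_flags(sim$cohort$participant_id, 71, 26, 379, seed = 2)
  res <- apply_exclusions(sim$cohort, flags)
  expect_equal(res$report$n_retained, 2772)
  expect_equal(nrow(res$cohort), 2772)

  # a participant flagged twice is counted once, at the first criterion
  flags2 <- flags
  flags2$antibiotics[which(flags2$intestinal_disease)[1]] <- TRUE
  res2 <- apply_exclusions(sim$cohort, flags2)
  expect_equal(res2$report$n_excluded_antibiotics, 72)
  expect_equal(res2$report$n_excluded_intestinal_disease, 25)
  expect_equal(res2$report$n_retained, 2772)
  with(res2$report, expect_equal(
    n_retained,
    n_input - n_excluded_antibiotics - n_excluded_intestinal_disease -
      n_excluded_prevalent_t2d))

  # no flags -> identity
  none <- make_exclusion_flags(sim$cohort$participant_id)
  expect_equal(nrow(apply_exclusions(sim$cohort, none)$cohort), 3248)
})

test_that("prevalence filter keeps the inclusive boundary and matches recount", {
  n <- 100
  prevs <- c(0, 0.05, 0.09, 0.10, 0.5, 1)
  m <- sapply(prevs, function(p) c(rep(0.5, round(p * n)), rep(0, n - round(p * n))))
  m <- m / pmax(rowSums(m), 1)
  dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("g%d", seq_along(prevs)))
  # avoid all-zero rows for construction only
  m[rowSums(m) == 0, 6] <- 1
  res <- filter_prevalence(genus_table(m), 0.10)
  expect_identical(colnames(res$table), c("g4", "g5", "g6"))  # 10% boundary kept
  expect_true("g1" %in% res$dropped)                          # all-zero genus dropped

  # oracle equivalence on random tables
  set.seed(9)
  for (i in 1:5) {
    r <- matrix(rbinom(200, 1, 0.3) * runif(200), 20, 10,
                dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
    r[rowSums(r) == 0, 1] <- 0.2
    r <- r / rowSums(r) # close rows; zeros preserved
    thr <- sample(c(0.1, 0.25, 0.5), 1)
    kept <- filter_prevalence(genus_table(r), thr)$table
    manual <- colnames(r)[colSums(r > 0) / nrow(r) >= thr]
    expect_identical(colnames(kept), manual)
  }
  expect_error(filter_prevalence(matrix(numeric(0), 0, 3)), "empty")
})

test_that("imputation fills region-wise means and lexicographic modal categories", {
  df <- as_cohort_table(tiny_cohort_df(8))
  df$bmi <- c(24.8, 24.8, NA, 24.8, 23.0, 23.4, 23.8, NA)  # N,N,N?,N,S,S,S,S?
  df$region <- rep(c("North", "North", "North", "North",
                     "South", "South", "South", "South"))
  df$province <- rep(c("P01", "P02"), each = 4)
  df$sex <- c("female", "male", NA, NA, "female", "female", "male", NA)
  out <- impute_missing(df)
  expect_equal(out$bmi[3], 24.8)               # North mean among observed
  expect_equal(out$bmi[8], mean(c(23.0, 23.4, 23.8)))
  expect_equal(out$sex[8], "female")           # South mode
  expect_equal(out$sex[3], "female")           # North tie {female, male} -> lexicographic
  expect_equal(out$sex[4], "female")
  expect_false(anyNA(out$bmi))
  expect_equal(out$bmi[1], 24.8)               # observed cells untouched

  expect_identical(impute_missing(as_cohort_table(tiny_cohort_df())),
                   as_cohort_table(tiny_cohort_df()))  # no missing -> identity

  df$bmi[5:8] <- NA                             # a region with nothing observed
  expect_error(impute_missing(df), "bmi.*South")
})

test_that("HOMA-IR formula and unit conversion reproduce worked values", {
  expect_equal(round(compute_homa_ir(5.2, 50.7, 6.945), 1), 1.7)
  expect_equal(compute_homa_ir(5.0, 0), 0)
  expect_equal(compute_homa_ir(7.0, 69.45, 6.945), 7 * 10 / 22.5,
               tolerance = 1e-12)  # 10 uU/ml equivalent -> 3.111
  expect_error(compute_homa_ir(-1, 50), "non-negative")
})

test_that("NGSP to IFCC conversion matches the master equation anchors", {
  expect_equal(ngsp_to_ifcc(6.5), 47.5)
  expect_equal(ngsp_to_ifcc(5.5), 36.6)
  expect_equal(ngsp_to_ifcc(2.15), 0)
})

test_that("diabetes ascertainment is inclusive at thresholds and monotone", {
  expect_equal(ascertain_t2d(7.0, 30, 0), 1L)   # glucose boundary
  expect_equal(ascertain_t2d(5.0, 47.5, 0), 1L) # HbA1c boundary
  expect_equal(ascertain_t2d(5.0, 36, 0), 0L)
  expect_equal(ascertain_t2d(5.0, 36, 1), 1L)   # medication alone suffices
  expect_error(ascertain_t2d(NA, 36, 0), "complete")
  # monotone in each continuous argument
  g <- seq(4, 9, by = 0.5)
  expect_true(all(diff(ascertain_t2d(g, rep(30, length(g)), 0)) >= 0))
  h <- seq(30, 60, by = 2)
  expect_true(all(diff(ascertain_t2d(rep(5, length(h)), h, 0)) >= 0))
})

test_that("standardization returns sample-SD z-scores and is idempotent", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(standardize(s$z)$z, s$z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5), "flat"), "flat")
  set.seed(4)
  x <- rnorm(1e4, 5, 2)
  r <- standardize(x)
  expect_equal(r$mean, 5, tolerance = 3 * 2 / sqrt(1e4))
  expect_equal(r$sd, 2, tolerance = 3 * 2 / sqrt(1e4))
})

test_that("staple ratio labels wheat at ratio >= 1 and flags double zeros", {
  r <- staple_ratio(c(0.2, 0, 0.3, 0), c(0.2, 0.3, 0, 0))
  expect_equal(r$preference[1], "wheat")   # ratio exactly 1 -> wheat
  expect_equal(r$preference[2], "rice")
  expect_equal(r$preference[3], "wheat")   # infinite ratio convention
  expect_true(is.na(r$preference[4]) && r$flagged[4])
  expect_error(staple_ratio(-0.1, 0.2), "non-negative")
})
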