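shifted_sim <- function() {
  cached_sim("ml_shift", function() {
    generate_cohort(n_participants = 1200, n_provinces = 10,
                    truth = synthetic_truth(n_genera = 20), seed = 31)
  })
}

test_that("the leave-one-province-out classifier is reproducible and fold-clean", {
  sim <- shifted_sim()
  filt <- filter_prevalence(sim$abundance, 0.10)$table
  c1 <- logo_region_classify(filt, sim$cohort, n_repeats = 2, seed = 9,
                             nrounds = 30)
  c2 <- logo_region_classify(filt, sim$cohort, n_repeats = 2, seed = 9,
                             nrounds = 30)
  expect_identical(c1$probability, c2$probability)
  expect_true(all(c1$probability >= 0 & c1$probability <= 1))
  # fold hygiene: every participant is scored by a model that never saw
  # their province
  for (p in names(c1$models[[1]])) {
    test_idx <- c1$models[[1]][[p]]$test
    expect_true(all(sim$cohort$province[test_idx] == p))
  }
  # every participant scored exactly once per repeat
  expect_false(anyNA(c1$prob_by_repeat))
})

test_that("discrimination tracks the planted regional shift", {
  sim <- shifted_sim()
  filt <- filter_prevalence(sim$abundance, 0.10)$table
  clf <- logo_region_classify(filt, sim$cohort, n_repeats = 2, seed = 9,
                              nrounds = 30)
  expect_gt(clf$auc, 0.9)

  # with the shift removed the classifier cannot beat chance
  tr0 <- synthetic_truth(n_genera = 20, n_region_shifted = 0,
                         diet_effects = list())
  sim0 <- generate_cohort(n_participants = 1200, n_provinces = 10,
                          truth = tr0, seed = 32)
  filt0 <- filter_prevalence(sim0$abundance, 0.10)$table
  clf0 <- logo_region_classify(filt0, sim0$cohort, n_repeats = 2, seed = 9,
                               nrounds = 30)
  expect_gt(clf0$auc, 0.45)
  expect_lt(clf0$auc, 0.55)
})

test_that("a single-province region is refused as untrainable", {
  sim <- shifted_sim()
  co <- sim$cohort
  co$province[co$region == "North"] <- "P01"
  expect_error(logo_region_classify(sim$abundance, co, 1, 1), ">= 2 provinces")
})

test_that("SHAP attributions are locally accurate and select the shifted genera", {
  sim <- shifted_sim()
  filt <- filter_prevalence(sim$abundance, 0.10)$table
  clf <- logo_region_classify(filt, sim$cohort, n_repeats = 2, seed = 9)
  # local accuracy: contributions + bias reconstruct the model margin
  fold <- clf$models[[1]][[1]]
  Xt <- unclass(filt)[fold$test, , drop = FALSE]
  contrib <- predict(fold$model, Xt, predcontrib = TRUE)
  margin <- predict(fold$model, Xt, outputmargin = TRUE)
  expect_equal(unname(rowSums(contrib)), unname(margin), tolerance = 1e-6)

  disc <- select_discriminating_genera(clf, filt)
  shifted <- sim$truth$genus_names[sim$truth$region_shift != 0]
  shifted <- intersect(shifted, colnames(filt))
  expect_true(all(shifted %in% disc$genus[disc$selected]))
  expect_true(all(diff(disc$mean_abs_attribution) <= 1e-12))

  # a constant feature receives exactly zero attribution
  aug <- cbind(unclass(filt), Flat = 0.0)
  co <- sim$cohort
  clf2 <- logo_region_classify(genus_table(aug / rowSums(aug)), co,
                               n_repeats = 1, seed = 4, nrounds = 20)
  disc2 <- select_discriminating_genera(clf2, genus_table(aug / rowSums(aug)))
  expect_false(disc2$selected[disc2$genus == "Flat"])
})

test_that("AUC equals the Mann-Whitney statistic on the same scores", {
  sim <- shifted_sim()
  filt <- filter_prevalence(sim$abundance, 0.10)$table
  clf <- logo_region_classify(filt, sim$cohort, n_repeats = 2, seed = 9,
                              nrounds = 30)
  expect_equal(clf$auc, auc_mwu_oracle(clf$probability, clf$y),
               tolerance = 1e-10)
})

test_that("diet prediction finds planted dependence and stays null otherwise", {
  sim <- shifted_sim()
  co <- sim$cohort
  filt <- filter_prevalence(sim$abundance, 0.10)$table
  wheat_genera <- sim$truth$genus_names[sim$truth$diet_effects$wheat$genera]
  wheat_genera <- intersect(wheat_genera, colnames(filt))
  X <- unclass(filt)

  r_wheat <- predict_diet_from_genera(X, co$wheat, "regression",
                                      region = co$region, folds = 5, seed = 2,
                                      nrounds = 40)
  expect_gt(r_wheat$performance$pearson_r, 0.5)
  # out-of-fold: every participant predicted once
  expect_equal(sort(unique(r_wheat$fold)), 1:5)

  set.seed(99)
  noise <- rlnorm(nrow(co), 0, 1)   # a diet factor unrelated to any genus
  r_null <- predict_diet_from_genera(X, noise, "regression",
                                     region = co$region, folds = 5, seed = 2,
                                     nrounds = 40)
  expect_lt(abs(r_null$performance$pearson_r), 2 / sqrt(nrow(co)) + 0.05)

  # classification: a perfectly separable toy outcome reaches AUC 1
  toy <- as.numeric(X[, wheat_genera[1]] > median(X[, wheat_genera[1]]))
  Xsep <- cbind(X, sep = toy)
  r_cls <- predict_diet_from_genera(Xsep, toy, "classification",
                                    folds = 4, seed = 3, nrounds = 40)
  expect_equal(r_cls$performance$auc, 1.0, tolerance = 1e-9)
  expect_error(predict_diet_from_genera(X, rep(1, nrow(co)), "regression"),
               "constant")
})
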